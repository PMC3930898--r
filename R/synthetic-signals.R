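#' Ground-truth methylation states for a simulated study
#'
#' Draws per-probe, per-group true total-methylation fractions and true
#' 5-hmC fractions (5-hmC never exceeds total), per-chip batch offsets on
#' the logit scale, and an optional set of planted differentially methylated
#' loci with a fixed effect size.
#'
#' Baseline total methylation is drawn from a symmetric Beta(1.5, 1.5)
#' rescaled to \[0.05, 0.95\] — a broad bimodal-ish spread typical of array
#' beta distributions. By default the 5-hmC fraction is a Beta(1.2, 2.5)
#' multiple of the total. When `hmc_above` is given, the 5-hmC level is
#' instead drawn as a two-component mixture calibrated so that the expected
#' fraction of probes exceeding `hmc_cutoff` equals `hmc_above` (used to
#' plant species abundance hierarchies).
#'
#' @param manifest probe manifest (only `probe_id` is used).
#' @param groups character vector of group labels.
#' @param chips character vector of chip ids.
#' @param prop_dml fraction of probes given a planted group effect.
#' @param delta_beta planted effect size on the beta scale (added to the
#'   second group).
#' @param batch_sd standard deviation of per-chip logit-scale offsets.
#' @param hmc_above optional target fraction of probes with 5-hmC above
#'   `hmc_cutoff`.
#' @param hmc_cutoff cutoff used by `hmc_above` (default 0.2).
#' @param seed integer seed.
#' @return a `truth_table` with matrices `total` and `hmc`
#'   (probes x groups), named numeric `batch`, and a `dml` table of planted
#'   loci.
#' @export
generate_truth <- function(manifest, groups = c("placenta", "fetal"),
                           chips = paste0("chip", 1:3),
                           prop_dml = 0, delta_beta = 0.2, batch_sd = 0,
                           hmc_above = NULL, hmc_cutoff = 0.2, seed = 1L) {
  probe_ids <- manifest$probe_id
  n <- length(probe_ids)
  assert_fraction(prop_dml, "prop_dml")
  seed <- assert_count(seed, "seed", positive = FALSE)

  withr::with_seed(seed, {
    base <- 0.05 + 0.9 * stats::rbeta(n, 1.5, 1.5)
    if (is.null(hmc_above)) {
      hmc <- base * stats::rbeta(n, 1.2, 2.5)
    } else {
      assert_fraction(hmc_above, "hmc_above")
      above <- stats::runif(n) < hmc_above
      hmc <- ifelse(above,
                    stats::runif(n, hmc_cutoff + 0.05, min(hmc_cutoff + 0.4, 0.9)),
                    stats::runif(n, 0, max(hmc_cutoff - 0.05, 0.01)))
      base <- pmin(0.95, pmax(base, hmc + stats::runif(n, 0.01, 0.15)))
    }
    total <- matrix(base, n, length(groups),
                    dimnames = list(probe_ids, groups))
    dml <- data.frame(probe_id = character(0), delta_beta = numeric(0))
    if (prop_dml > 0 && length(groups) >= 2) {
      n_dml <- max(1L, round(prop_dml * n))
      eligible <- which(base > 0.1 & base + delta_beta < 0.95 & hmc < base - abs(delta_beta))
      if (length(eligible) < n_dml) eligible <- which(base + delta_beta < 0.95)
      idx <- sort(sample(eligible, n_dml))
      total[idx, 2] <- total[idx, 2] + delta_beta
      dml <- data.frame(probe_id = probe_ids[idx], delta_beta = delta_beta)
    }
    hmc_m <- matrix(hmc, n, length(groups), dimnames = list(probe_ids, groups))
    hmc_m <- pmin(hmc_m, total)  # invariant: 5-hmC <= total everywhere
    batch <- stats::setNames(
      if (batch_sd > 0) stats::rnorm(length(chips), 0, batch_sd) else rep(0, length(chips)),
      chips)
    structure(list(total = total, hmc = hmc_m, batch = batch, dml = dml,
                   groups = groups, chips = chips),
              class = "truth_table")
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d probes, groups: %s, %d planted DML, batch sd %.3g\n",
              nrow(x$total), paste(x$groups, collapse = "/"), nrow(x$dml),
              stats::sd(x$batch)))
  invisible(x)
}

#' Build a sample design table
#'
#' Convenience constructor: `n_per_group` samples per group, dealt across
#' chips round-robin so chips carry a mix of groups (as arrays are run in
#' practice, and as the mixed model requires for within-chip information).
#'
#' @param groups group labels.
#' @param n_per_group samples per group (recycled).
#' @param chips chip ids.
#' @return `data.frame` with `sample_id`, `group`, `chip`.
#' @export
make_design <- function(groups = c("placenta", "fetal"), n_per_group = 5L,
                        chips = paste0("chip", 1:3)) {
  n_per_group <- rep_len(n_per_group, length(groups))
  group <- rep(groups, n_per_group)
  sample_id <- unlist(lapply(seq_along(groups), function(i) {
    sprintf("%s_%02d", groups[i], seq_len(n_per_group[i]))
  }))
  data.frame(sample_id = sample_id, group = group,
             chip = rep_len(chips, length(group)))
}

#' Simulate dual-aliquot array signals from a truth table
#'
#' Produces the BS-aliquot (total methylation) and TAB-aliquot (5-hmC)
#' signal matrices for a design. The generator inverts the beta formula
#' exactly: with target total intensity T, `M = beta * (T + 100)` and
#' `U = T - M`, so that noise-free [compute_beta()] returns the truth value
#' to machine precision. Chip batch offsets shift beta on the logit scale
#' before inversion; Gaussian noise (truncated at zero) is then added to M
#' and U on the intensity scale. A configurable fraction of (probe, sample)
#' cells is "failed": their intensities are drawn from the background
#' distribution, and detection p-values (computed rank-wise against a
#' simulated negative-control background) flag them as undetected.
#'
#' Truth fractions exceeding the intensity ceiling `T/(T+100)` cannot be
#' encoded; they are clamped to the ceiling with a warning.
#'
#' @param manifest probe manifest.
#' @param design sample design table from [make_design()].
#' @param truth a `truth_table` covering the design's groups and chips.
#' @param total_intensity target total intensity T per probe.
#' @param intensity_noise_sd additive Gaussian noise sd on M and U.
#' @param fail_fraction fraction of cells simulated as failed probes.
#' @param n_background number of negative-control background draws per
#'   sample used for detection p-values.
#' @param seed integer seed.
#' @return list with `bs` and `tab` (each a [signal_matrix()]) and
#'   `background` (background draws, samples in columns).
#' @export
simulate_signals <- function(manifest, design, truth,
                             total_intensity = 5000,
                             intensity_noise_sd = 0,
                             fail_fraction = 0,
                             n_background = 500L,
                             seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  if (!all(c("sample_id", "group", "chip") %in% names(design))) {
    stop_invalid("design needs sample_id, group and chip columns")
  }
  if (!all(design$group %in% colnames(truth$total))) {
    stop_invalid("truth table does not cover design groups: %s",
                 paste(setdiff(design$group, colnames(truth$total)), collapse = ", "))
  }
  if (!all(design$chip %in% names(truth$batch))) {
    stop_invalid("truth table does not cover design chips: %s",
                 paste(setdiff(design$chip, names(truth$batch)), collapse = ", "))
  }
  if (!all(manifest$probe_id %in% rownames(truth$total))) {
    stop_invalid("truth table does not cover every manifest probe")
  }
  assert_fraction(fail_fraction, "fail_fraction")
  seed <- assert_count(seed, "seed", positive = FALSE)

  probe_ids <- manifest$probe_id
  withr::with_seed(seed, {
    bg <- matrix(pmax(1, stats::rnorm(n_background * nrow(design), 200, 50)),
                 n_background, nrow(design),
                 dimnames = list(NULL, design$sample_id))
    aliquots <- list(BS = truth$total[probe_ids, , drop = FALSE],
                     TAB = truth$hmc[probe_ids, , drop = FALSE])
    out <- lapply(names(aliquots), function(aq) {
      simulate_one_aliquot(aliquots[[aq]], design, truth$batch, aq,
                           total_intensity, intensity_noise_sd,
                           fail_fraction, bg)
    })
    names(out) <- names(aliquots)
    list(bs = out$BS, tab = out$TAB, background = bg)
  })
}

simulate_one_aliquot <- function(truth_beta, design, batch, aliquot,
                                 total_intensity, noise_sd, fail_fraction, bg) {
  n_p <- nrow(truth_beta); n_s <- nrow(design)
  Tq <- total_intensity
  beta_cap <- Tq / (Tq + 100)
  M <- matrix(0, n_p, n_s,
              dimnames = list(rownames(truth_beta),
                              paste0(design$sample_id, "_", aliquot)))
  U <- M
  n_clamped <- 0L
  for (j in seq_len(n_s)) {
    b <- truth_beta[, design$group[j]]
    off <- batch[[design$chip[j]]]
    if (off != 0) {
      b <- stats::plogis(stats::qlogis(pmin(pmax(b, 1e-6), 1 - 1e-6)) + off)
    }
    over <- b > beta_cap
    n_clamped <- n_clamped + sum(over)
    b[over] <- beta_cap
    M[, j] <- b * (Tq + 100)
    U[, j] <- Tq - M[, j]
  }
  if (n_clamped > 0) {
    warning(sprintf(
      "%d truth fraction(s) exceeded the intensity ceiling %.4f and were clamped",
      n_clamped, beta_cap), call. = FALSE)
  }
  if (noise_sd > 0) {
    M <- pmax(M + stats::rnorm(length(M), 0, noise_sd), 0)
    U <- pmax(U + stats::rnorm(length(U), 0, noise_sd), 0)
  }
  if (fail_fraction > 0) {
    fail <- stats::runif(length(M)) < fail_fraction
    n_fail <- sum(fail)
    M[fail] <- pmax(1, stats::rnorm(n_fail, 200, 50)) / 2
    U[fail] <- pmax(1, stats::rnorm(n_fail, 200, 50)) / 2
  }
  samples <- data.frame(sample_id = colnames(M),
                        chip = design$chip, group = design$group,
                        aliquot = aliquot,
                        replicate_of = design$replicate_of %||% NA_character_)
  sm <- signal_matrix(M, U, detection_p = NULL, samples = samples)
  colnames(bg) <- colnames(M)
  detection_pvalues(sm, bg)
}
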