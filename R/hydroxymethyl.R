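#' Pair BS and TAB aliquots into a 5-hmC profile
#'
#' The BS (bisulfite-only) aliquot reports total modification
#' (5-mC + 5-hmC); the TAB (Tet-assisted bisulfite) aliquot reports 5-hmC
#' directly, since glucosylation protects 5-hmC while Tet oxidation erases
#' the 5-mC signal. The 5-mC-only level is derived by subtraction,
#' `mc_only = max(0, total - hmc)`; noise can invert the order, so negative
#' differences are clamped at zero and counted. Entries undetected in
#' either aliquot are masked in both. Per-probe median 5-hmC is computed
#' over detected entries only.
#'
#' @param bs `beta_matrix` of the BS aliquot.
#' @param tab `beta_matrix` of the TAB aliquot.
#' @param pairing `data.frame` with columns `sample`, `bs_sample`,
#'   `tab_sample` mapping each biological sample to one column of each
#'   aliquot.
#' @param species_label label stored in the profile.
#' @return an `hmc_profile`: matrices `total`, `hmc`, `mc_only`, `mask`
#'   (probes x biological samples), per-probe `median_hmc` and
#'   `median_total`, clamp count, species label.
#' @export
pair_aliquots <- function(bs, tab, pairing, species_label = "sample") {
  stopifnot(inherits(bs, "beta_matrix"), inherits(tab, "beta_matrix"))
  need <- c("sample", "bs_sample", "tab_sample")
  if (!all(need %in% names(pairing))) {
    stop_invalid("pairing needs columns: %s", paste(need, collapse = ", "))
  }
  miss_bs <- setdiff(pairing$bs_sample, colnames(bs$beta))
  miss_tab <- setdiff(pairing$tab_sample, colnames(tab$beta))
  if (length(miss_bs) || length(miss_tab)) {
    stop_invalid("unmatched sample(s): %s",
                 paste(c(miss_bs, miss_tab), collapse = ", "))
  }
  if (anyDuplicated(pairing$sample)) {
    stop_invalid("each biological sample must appear exactly once in the pairing")
  }
  probes <- intersect(rownames(bs$beta), rownames(tab$beta))
  if (!length(probes)) stop_invalid("aliquots share no probes")
  total <- bs$beta[probes, pairing$bs_sample, drop = FALSE]
  hmc <- tab$beta[probes, pairing$tab_sample, drop = FALSE]
  mask <- bs$mask[probes, pairing$bs_sample, drop = FALSE] &
    tab$mask[probes, pairing$tab_sample, drop = FALSE]
  colnames(total) <- colnames(hmc) <- colnames(mask) <- pairing$sample
  n_clamped <- sum(hmc > total & mask)
  mc_only <- pmax(total - hmc, 0)
  med <- function(m) {
    x <- m; x[!mask] <- NA
    apply(x, 1, stats::median, na.rm = TRUE)
  }
  structure(list(total = total, hmc = hmc, mc_only = mc_only, mask = mask,
                 median_hmc = med(hmc), median_total = med(total),
                 n_clamped = n_clamped, species_label = species_label),
            class = "hmc_profile")
}

#' @export
print.hmc_profile <- function(x, ...) {
  cat(sprintf("<hmc_profile:%s> %d probes x %d samples, median total %.3f, median 5-hmC %.3f, %d clamped\n",
              x$species_label, nrow(x$total), ncol(x$total),
              stats::median(x$median_total, na.rm = TRUE),
              stats::median(x$median_hmc, na.rm = TRUE), x$n_clamped))
  invisible(x)
}

#' Count probes above a 5-hmC abundance cutoff
#'
#' A probe is "above" when its per-probe median 5-hmC strictly exceeds the
#' cutoff (probes with median exactly at the cutoff do not count).
#'
#' @param profile an `hmc_profile`.
#' @param cutoff abundance cutoff in (0,1); conventional values are 0.2,
#'   0.4 and 0.6.
#' @return one-row `data.frame`: `species`, `cutoff`, `n_probes`, `count`,
#'   `fraction`.
#' @export
classify_by_cutoff <- function(profile, cutoff = 0.2) {
  stopifnot(inherits(profile, "hmc_profile"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1) {
    stop_invalid("cutoff must lie strictly inside (0,1)")
  }
  med <- profile$median_hmc[!is.na(profile$median_hmc)]
  if (!length(med)) stop_invalid("profile has no detected probes")
  data.frame(species = profile$species_label, cutoff = cutoff,
             n_probes = length(med), count = sum(med > cutoff),
             fraction = mean(med > cutoff))
}

#' Cross-species overlap of above-cutoff probes
#'
#' Restricts every species' above-cutoff set to a shared probe panel and
#' reports pairwise (and full) intersection counts, with a hypergeometric
#' enrichment p-value for each pairwise overlap against a chance draw.
#'
#' @param profiles named list of `hmc_profile` objects.
#' @param shared character vector of shared probe ids (default: probes
#'   common to all profiles).
#' @param cutoff abundance cutoff.
#' @return list with `shared_n`, per-species above-cutoff counts,
#'   `pairwise` table (`species_a`, `species_b`, `n_a`, `n_b`, `overlap`,
#'   `expected`, `hyper_p`), and `n_common_all`.
#' @export
species_overlap <- function(profiles, shared = NULL, cutoff = 0.2) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  if (is.null(names(profiles))) names(profiles) <- paste0("species", seq_along(profiles))
  probe_sets <- lapply(profiles, function(p) rownames(p$total))
  if (is.null(shared)) shared <- Reduce(intersect, probe_sets)
  for (nm in names(profiles)) {
    if (!length(intersect(shared, probe_sets[[nm]]))) {
      stop_invalid("species '%s' shares no probes with the panel", nm)
    }
  }
  above <- lapply(profiles, function(p) {
    med <- p$median_hmc[shared]
    shared[!is.na(med) & med > cutoff]
  })
  nm <- names(profiles)
  pairs <- utils::combn(nm, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- length(above[[a]]); nb <- length(above[[b]])
    ov <- length(intersect(above[[a]], above[[b]]))
    n <- length(shared)
    data.frame(species_a = a, species_b = b, n_a = na, n_b = nb,
               overlap = ov, expected = na * nb / n,
               hyper_p = stats::phyper(ov - 1, na, n - na, nb,
                                       lower.tail = FALSE))
  }))
  list(shared_n = length(shared),
       above_counts = vapply(above, length, integer(1)),
       pairwise = pairwise,
       n_common_all = length(Reduce(intersect, above)))
}

#' Binned beta-density summary, optionally stratified
#'
#' Bins levels on a fixed 100-bin grid over \[0,1\] and reports per-stratum
#' bin counts normalized to a density (so each stratum's density integrates
#' to one), along with per-stratum medians and counts. This is the tabular
#' backbone of beta-density plots by island relation, gene structure or
#' chromosome.
#'
#' @param profile an `hmc_profile`.
#' @param annotation output of [assign_categories()] covering the profile's
#'   probes (required unless `stratify = "none"`).
#' @param stratify one of `"none"`, `"island"`, `"gene"`, `"chromosome"`.
#' @param measure `"hmc"` or `"total"` (per-probe medians).
#' @return list with `density` (long `data.frame`: `stratum`, `bin_mid`,
#'   `count`, `density`) and `strata` (`stratum`, `n`, `median`).
#' @export
density_summary <- function(profile, annotation = NULL,
                            stratify = c("none", "island", "gene", "chromosome"),
                            measure = c("hmc", "total")) {
  stopifnot(inherits(profile, "hmc_profile"))
  stratify <- match.arg(stratify)
  measure <- match.arg(measure)
  vals <- if (measure == "hmc") profile$median_hmc else profile$median_total
  ids <- rownames(profile$total)
  keep <- !is.na(vals)
  vals <- vals[keep]; ids <- ids[keep]
  strata <- if (stratify == "none") {
    rep("all", length(ids))
  } else {
    if (is.null(annotation)) stop_invalid("stratified summaries need an annotation")
    ann <- annotation[match(ids, annotation$probe_id), ]
    if (anyNA(ann$probe_id)) {
      stop_invalid("annotation is missing %d profile probe(s)",
                   sum(is.na(ann$probe_id)))
    }
    switch(stratify,
           island = ann$island_relation,
           chromosome = ann$chromosome,
           gene = ann$gene_groups)
  }
  if (stratify == "gene") {
    # multiple membership: one entry per (probe, group)
    lst <- lapply(strata, split_field)
    reps <- lengths(lst)
    vals <- rep(vals, reps)
    strata <- unlist(lst)
    if (!length(strata)) stop_invalid("no gene-annotated probes in the profile")
  }
  if (stratify == "island" && !all(strata %in% ISLAND_RELATIONS)) {
    stop_invalid("unknown island stratum label: %s",
                 paste(setdiff(strata, ISLAND_RELATIONS), collapse = ", "))
  }
  breaks <- seq(0, 1, length.out = 101)
  mids <- (breaks[-1] + breaks[-101]) / 2
  dens <- do.call(rbind, lapply(sort(unique(strata)), function(sv) {
    v <- vals[strata == sv]
    cnt <- graphics::hist(v, breaks = breaks, plot = FALSE,
                          include.lowest = TRUE, right = FALSE)$counts
    data.frame(stratum = sv, bin_mid = mids, count = cnt,
               density = cnt / (length(v) * 0.01))
  }))
  strata_tab <- do.call(rbind, lapply(sort(unique(strata)), function(sv) {
    v <- vals[strata == sv]
    data.frame(stratum = sv, n = length(v), median = stats::median(v))
  }))
  list(density = dens, strata = strata_tab)
}
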