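#' Fit the per-locus differential-methylation model
#'
#' Fits, for one CpG locus, a linear model of beta on a two-level group
#' factor with a per-BeadChip random intercept (REML via [nlme::lme()]),
#' optionally adjusting for a per-sample mean-intensity covariate. The
#' p-value is the conditional t-test on the group coefficient. When the
#' chip random effect is unidentifiable (every chip carries a single
#' sample, or only one chip is present) or the mixed fit fails, the model
#' falls back to ordinary least squares and is flagged `fixed-fallback`.
#' Loci with fewer than 3 residual degrees of freedom are flagged `failed`
#' with no p-value.
#'
#' @param betas numeric vector of beta values over samples (NAs dropped
#'   listwise).
#' @param design `data.frame` with per-sample `group` (exactly two levels),
#'   `chip`, and optionally `intensity`.
#' @param use_intensity include the intensity covariate when present.
#' @return one-row `data.frame`: `effect` (second group minus first, beta
#'   scale), `se`, `statistic`, `df`, `p`, `n_used`, `flag` (one of
#'   `"mixed"`, `"fixed-fallback"`, `"failed"`).
#' @export
fit_locus <- function(betas, design, use_intensity = FALSE) {
  keep <- !is.na(betas)
  y <- betas[keep]
  d <- design[keep, , drop = FALSE]
  d$group <- droplevels(factor(d$group))
  d$chip <- droplevels(factor(d$chip))
  failed <- data.frame(effect = NA_real_, se = NA_real_, statistic = NA_real_,
                       df = NA_real_, p = NA_real_, n_used = length(y),
                       flag = "failed")
  if (nlevels(d$group) != 2) return(failed)
  use_intensity <- use_intensity && "intensity" %in% names(d) &&
    !all(is.na(d$intensity))
  n_fixed <- 2L + as.integer(use_intensity)
  if (length(y) - n_fixed < 3) return(failed)
  d$y <- y
  fixed <- if (use_intensity) y ~ group + intensity else y ~ group
  chip_ok <- nlevels(d$chip) > 1 && max(table(d$chip)) > 1
  coef_name <- paste0("group", levels(d$group)[2])

  if (chip_ok) {
    fit <- tryCatch(
      suppressWarnings(
        nlme::lme(fixed, random = ~ 1 | chip, data = d, method = "REML",
                  control = nlme::lmeControl(returnObject = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$fixDF$X[[coef_name]] >= 1) {
      co <- fit$coefficients$fixed
      se <- sqrt(diag(fit$varFix))
      dfree <- fit$fixDF$X
      tt <- co[[coef_name]] / se[[coef_name]]
      return(data.frame(effect = co[[coef_name]], se = se[[coef_name]],
                        statistic = tt, df = dfree[[coef_name]],
                        p = 2 * stats::pt(-abs(tt), dfree[[coef_name]]),
                        n_used = length(y), flag = "mixed"))
    }
    # zero conditional df: group confounded with chip -> fixed-effects fallback
  }
  fit <- stats::lm(fixed, data = d)
  sm <- summary(fit)$coefficients
  if (!coef_name %in% rownames(sm)) return(failed)
  data.frame(effect = sm[coef_name, 1], se = sm[coef_name, 2],
             statistic = sm[coef_name, 3], df = fit$df.residual,
             p = sm[coef_name, 4], n_used = length(y), flag = "fixed-fallback")
}

check_design <- function(design) {
  need <- c("sample_id", "group", "chip")
  if (!all(need %in% names(design))) {
    stop_invalid("design needs columns: %s", paste(need, collapse = ", "))
  }
  tab <- table(design$group)
  if (length(tab) != 2) {
    stop_invalid("exactly two groups are supported (collapse others first); got %d",
                 length(tab))
  }
  if (any(tab < 2)) stop_invalid("every group needs at least 2 samples")
  invisible(design)
}

#' Genome-wide per-CpG differential methylation
#'
#' Runs [fit_locus()] for every probe of a QC-filtered beta matrix,
#' computes Benjamini-Hochberg and Bonferroni adjustments over exactly the
#' tested probes, and declares significance by Bonferroni-adjusted
#' p < `alpha` (the conservative family-wise criterion appropriate for
#' small sample sizes).
#'
#' @param betas a `beta_matrix` (masked entries treated as missing) or a
#'   plain numeric matrix.
#' @param design per-sample design (`sample_id`, `group`, `chip`);
#'   `intensity` is filled from the attribute `mean_intensity` of `design`
#'   or passed explicitly.
#' @param alpha significance level for the Bonferroni criterion.
#' @param use_intensity adjust for per-sample mean intensity when a column
#'   `intensity` is present in the design.
#' @return `data.frame` (class `dml_result`), one row per tested probe:
#'   `probe_id`, `effect`, `se`, `statistic`, `df`, `p`, `fdr`,
#'   `bonferroni`, `flag`, `significant`; attribute `n_significant`.
#' @export
run_dml <- function(betas, design, alpha = 0.05, use_intensity = FALSE) {
  mat <- if (inherits(betas, "beta_matrix")) {
    m <- betas$beta
    m[!betas$mask] <- NA
    m
  } else {
    as.matrix(betas)
  }
  # samples dropped upstream (e.g. by QC) silently leave the design
  design <- design[design$sample_id %in% colnames(mat), , drop = FALSE]
  check_design(design)
  mat <- mat[, design$sample_id, drop = FALSE]
  design$group <- factor(design$group)
  design$chip <- factor(design$chip)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    fit_locus(mat[i, ], design, use_intensity = use_intensity)
  })
  out <- do.call(rbind, rows)
  out <- cbind(probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))), out)
  tested <- !is.na(out$p)
  if (!any(tested)) stop_invalid("model fitting failed at every locus")
  out$fdr <- NA_real_
  out$bonferroni <- NA_real_
  out$fdr[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$bonferroni[tested] <- stats::p.adjust(out$p[tested], method = "bonferroni")
  out$significant <- !is.na(out$bonferroni) & out$bonferroni < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- sum(tested)
  attr(out, "n_significant") <- sum(out$significant)
  class(out) <- c("dml_result", class(out))
  out
}

#' Label-permutation validation of differential methylation
#'
#' Re-runs the identical per-locus model `n_perm` times with group labels
#' permuted uniformly across samples (chip assignments untouched). The
#' permutation p-value of a locus is the number of permutations in which
#' that locus achieved a smaller asymptotic p-value than observed, divided
#' by `n_perm` — so 0 means the observed association beat every
#' permutation. An add-one-corrected column `perm_p_add1`
#' ((k + 1)/(n_perm + 1)) is also provided for users who need strictly
#' positive p-values. The Pearson correlation between -log10 asymptotic
#' and -log10 add-one permutation p-values (plus the Spearman rank
#' correlation of the raw p-values) summarizes how well the asymptotic
#' reference distribution holds at the study's sample size.
#'
#' @param betas as in [run_dml()].
#' @param design as in [run_dml()].
#' @param n_perm number of label permutations (default 100).
#' @param seed integer seed.
#' @param dml observed [run_dml()] result; computed when omitted.
#' @param use_intensity as in [run_dml()].
#' @return list: `table` (probe_id, observed p, `perm_p`, `perm_p_add1`),
#'   `cor_neglog10` (Pearson, -log10 scale), `cor_spearman`, `n_perm`.
#' @export
permute_dml <- function(betas, design, n_perm = 100L, seed = 1L, dml = NULL,
                        use_intensity = FALSE) {
  n_perm <- assert_count(n_perm, "n_perm")
  seed <- assert_count(seed, "seed", positive = FALSE)
  check_design(design)
  if (is.null(dml)) dml <- run_dml(betas, design, use_intensity = use_intensity)
  obs_p <- dml$p
  count_smaller <- integer(length(obs_p))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pd <- design
      pd$group <- sample(pd$group)
      perm <- run_dml(betas, pd, use_intensity = use_intensity)
      smaller <- !is.na(perm$p) & !is.na(obs_p) & perm$p < obs_p
      count_smaller <- count_smaller + smaller
    }
  })
  perm_p <- count_smaller / n_perm
  perm_p_add1 <- (count_smaller + 1) / (n_perm + 1)
  tested <- !is.na(obs_p)
  tab <- data.frame(probe_id = dml$probe_id, p = obs_p,
                    perm_p = ifelse(tested, perm_p, NA_real_),
                    perm_p_add1 = ifelse(tested, perm_p_add1, NA_real_))
  list(table = tab,
       cor_neglog10 = stats::cor(-log10(obs_p[tested]),
                                 -log10(perm_p_add1[tested])),
       cor_spearman = stats::cor(obs_p[tested], perm_p[tested],
                                 method = "spearman"),
       n_perm = n_perm)
}

#' Restrict a DML table to a gene list and readjust
#'
#' Keeps the probes annotated (via the manifest's `gene_names`) to any
#' listed gene and recomputes the BH and Bonferroni adjustments over the
#' restricted family only — the correct procedure when a targeted
#' hypothesis (e.g. tumor suppressor genes) is specified a priori.
#'
#' @param results a `dml_result` table.
#' @param genes character vector of gene names.
#' @param manifest manifest with `probe_id` and `gene_names`.
#' @param alpha significance level (default: the one stored on `results`).
#' @return the restricted `dml_result` (possibly empty, with a warning).
#' @export
subset_dml <- function(results, genes, manifest, alpha = NULL) {
  if (!length(genes)) stop_invalid("gene list is empty")
  alpha <- alpha %||% attr(results, "alpha") %||% 0.05
  gene_lists <- lapply(manifest$gene_names, split_field)
  match_probe <- manifest$probe_id[vapply(gene_lists, function(g) {
    any(g %in% genes)
  }, logical(1))]
  out <- results[results$probe_id %in% match_probe, , drop = FALSE]
  if (!nrow(out)) {
    warning("no probes annotated to the requested genes", call. = FALSE)
    return(out)
  }
  tested <- !is.na(out$p)
  out$fdr[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$bonferroni[tested] <- stats::p.adjust(out$p[tested], method = "bonferroni")
  out$significant <- !is.na(out$bonferroni) & out$bonferroni < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- sum(tested)
  attr(out, "n_significant") <- sum(out$significant)
  rownames(out) <- NULL
  out
}
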