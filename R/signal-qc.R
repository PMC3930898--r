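#' Compute beta values from methylated/unmethylated intensities
#'
#' The methylation fraction is `beta = M / (M + U + 100)`; the +100 offset
#' regularizes low-intensity probes and keeps beta strictly below 1.
#' The default method is vectorized over numeric inputs; the
#' `signal_matrix` method converts a whole signal container into a
#' [beta_matrix()], masking entries whose detection p-value exceeds
#' `detection_p`.
#'
#' @param x numeric M intensities, or a `signal_matrix`.
#' @param ... passed to methods.
#' @return numeric beta values, or a `beta_matrix`.
#' @examples
#' compute_beta(900, 0)    # 0.9
#' compute_beta(500, 500)  # 500/1100
#' @export
compute_beta <- function(x, ...) UseMethod("compute_beta")

#' @rdname compute_beta
#' @param U numeric unmethylated intensities (default method).
#' @export
compute_beta.default <- function(x, U, ...) {
  if (any(x < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    stop_invalid("intensities must be non-negative")
  }
  x / (x + U + 100)
}

#' @rdname compute_beta
#' @param detection_p detection p-value threshold for the mask
#'   (default 0.01).
#' @export
compute_beta.signal_matrix <- function(x, detection_p = 0.01, ...) {
  beta <- x$M / (x$M + x$U + 100)
  mask <- if (is.null(x$detection_p)) {
    matrix(TRUE, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  } else {
    x$detection_p <= detection_p
  }
  beta_matrix(beta, mask, x$samples, normalization = x$normalization %||% "none")
}

#' Empirical detection p-values against negative-control background
#'
#' A probe is "detected" when its total intensity M + U is implausibly large
#' under the background distribution of negative controls. The p-value is
#' the rank-based upper-tail probability with the (r + 1)/(n + 1)
#' convention, where r is the number of background observations at or above
#' the observed total: a total above every background value gets
#' p = 1/(n + 1), a total at the background median gets p near 0.5.
#'
#' @param signals a `signal_matrix`.
#' @param background numeric matrix of background totals with one column
#'   per sample (colnames matching the signal columns), or a single numeric
#'   vector shared by all samples. At least 30 observations per sample.
#' @return the `signal_matrix` with its `detection_p` slot filled.
#' @export
detection_pvalues <- function(signals, background) {
  stopifnot(inherits(signals, "signal_matrix"))
  total <- signals$M + signals$U
  if (is.null(dim(background))) {
    background <- matrix(background, length(background), ncol(total),
                         dimnames = list(NULL, colnames(total)))
  }
  missing <- setdiff(colnames(total), colnames(background))
  if (length(missing)) {
    stop_invalid("no background observations for sample(s): %s",
                 paste(missing, collapse = ", "))
  }
  if (nrow(background) < 30) {
    stop_invalid("need at least 30 background observations per sample, got %d",
                 nrow(background))
  }
  p <- total
  for (j in colnames(total)) {
    bg <- sort(background[, j])
    n <- length(bg)
    # r = #background >= observed, via position in the sorted background
    r <- n - findInterval(total[, j], bg, left.open = TRUE)
    p[, j] <- (r + 1) / (n + 1)
  }
  signals$detection_p <- p
  signals
}

#' Quantile-normalize signal intensities across samples
#'
#' Within each aliquot, the M and U channels are each quantile-normalized
#' across samples: every sample's sorted intensity vector is mapped onto the
#' cross-sample mean of order statistics, preserving within-sample ranks
#' (ties averaged). With a single sample the transform is the identity, with
#' a warning. Joint normalization of M and U together (one shared target
#' distribution) is available via `joint = TRUE`.
#'
#' @param signals a `signal_matrix`.
#' @param joint normalize M and U against a shared target distribution.
#' @return a `signal_matrix` with normalized intensities.
#' @export
quantile_normalize <- function(signals, joint = FALSE) {
  stopifnot(inherits(signals, "signal_matrix"))
  if (ncol(signals$M) < 2) {
    warning("single sample: quantile normalization is the identity", call. = FALSE)
    return(signals)
  }
  for (aq in unique(signals$samples$aliquot)) {
    idx <- which(signals$samples$aliquot == aq)
    if (length(idx) < 2) next
    if (joint) {
      both <- rbind(signals$M[, idx, drop = FALSE], signals$U[, idx, drop = FALSE])
      norm <- limma::normalizeQuantiles(both, ties = TRUE)
      signals$M[, idx] <- norm[seq_len(nrow(signals$M)), ]
      signals$U[, idx] <- norm[-seq_len(nrow(signals$M)), ]
    } else {
      signals$M[, idx] <- limma::normalizeQuantiles(signals$M[, idx, drop = FALSE],
                                                    ties = TRUE)
      signals$U[, idx] <- limma::normalizeQuantiles(signals$U[, idx, drop = FALSE],
                                                    ties = TRUE)
    }
  }
  signals$normalization <- if (joint) "quantile-joint" else "quantile"
  signals
}

#' QC configuration
#'
#' Thresholds for [qc_filter()]. Defaults follow standard array QC
#' practice: samples with mean total intensity below 2000 or with fewer
#' than 99% of loci detected (detection p <= 0.01) are removed; probes
#' undetected in more than 20% of the surviving samples are discarded.
#'
#' @param min_mean_intensity sample rule: minimum mean M + U.
#' @param min_detection_rate sample rule: minimum fraction of detected loci.
#' @param detection_p detection p-value threshold defining "detected".
#' @param max_probe_undetected probe rule: maximum tolerated fraction of
#'   samples in which a probe is undetected (strictly-greater comparison).
#' @param outlier_check flag dissimilarity outliers (median one-minus-Pearson
#'   dissimilarity to the other samples exceeding the cohort median by
#'   `outlier_iqr_mult` IQRs).
#' @param outlier_iqr_mult IQR multiplier for the outlier rule.
#' @param drop_samples manual override: sample ids to remove (reason
#'   "control failure").
#' @return a list of thresholds.
#' @export
qc_config <- function(min_mean_intensity = 2000, min_detection_rate = 0.99,
                      detection_p = 0.01, max_probe_undetected = 0.20,
                      outlier_check = TRUE, outlier_iqr_mult = 3,
                      drop_samples = NULL) {
  list(min_mean_intensity = min_mean_intensity,
       min_detection_rate = min_detection_rate,
       detection_p = detection_p,
       max_probe_undetected = max_probe_undetected,
       outlier_check = outlier_check,
       outlier_iqr_mult = outlier_iqr_mult,
       drop_samples = drop_samples)
}

#' Sample and probe quality filtering
#'
#' Applies the sample rules first (manual override, low mean intensity, low
#' detection rate, then cluster-outlier flagging), then removes probes
#' undetected in strictly more than `max_probe_undetected` of the surviving
#' samples. Each removal is logged with exactly one primary reason. The
#' operation is idempotent on its own output for the intensity, detection
#' and probe rules.
#'
#' @param betas a `beta_matrix`.
#' @param signals the matching `signal_matrix` (used for mean intensities).
#' @param config thresholds from [qc_config()].
#' @return list with `betas` (filtered) and `report` (a `qc_report`:
#'   removed samples/probes with reasons, thresholds used).
#' @export
qc_filter <- function(betas, signals, config = qc_config()) {
  stopifnot(inherits(betas, "beta_matrix"), inherits(signals, "signal_matrix"))
  samp_ids <- colnames(betas$beta)
  total <- signals$M + signals$U
  if (!all(samp_ids %in% colnames(total))) {
    stop_invalid("signals do not cover all beta samples")
  }
  removed_samples <- data.frame(sample_id = character(0), reason = character(0))
  drop <- function(ids, reason) {
    ids <- setdiff(ids, removed_samples$sample_id)
    if (length(ids)) {
      removed_samples <<- rbind(removed_samples,
                                data.frame(sample_id = ids, reason = reason))
    }
  }
  drop(intersect(config$drop_samples, samp_ids), "control failure")
  mean_int <- colMeans(total[, samp_ids, drop = FALSE])
  drop(samp_ids[mean_int < config$min_mean_intensity], "low mean intensity")
  det_rate <- colMeans(betas$mask[, samp_ids, drop = FALSE])
  drop(samp_ids[det_rate < config$min_detection_rate], "low detection rate")

  keep <- setdiff(samp_ids, removed_samples$sample_id)
  if (config$outlier_check && length(keep) >= 4) {
    d <- tryCatch(dissimilarity_matrix(subset_beta(betas, samples = keep),
                                       metric = "one-minus-pearson"),
                  error = function(e) NULL)
    if (!is.null(d)) {
      med <- apply(d + diag(NA_real_, nrow(d)), 1, stats::median, na.rm = TRUE)
      cut <- stats::median(med) + config$outlier_iqr_mult * stats::IQR(med)
      if (stats::IQR(med) > 0) drop(keep[med > cut], "cluster outlier")
    }
  }
  keep <- setdiff(samp_ids, removed_samples$sample_id)
  if (!length(keep)) stop_invalid("all samples removed by QC")

  undetected <- rowMeans(!betas$mask[, keep, drop = FALSE])
  bad_probe <- undetected > config$max_probe_undetected
  removed_probes <- data.frame(
    probe_id = rownames(betas$beta)[bad_probe],
    reason = if (any(bad_probe)) "undetected in > 20% of samples" else character(0))

  out <- subset_beta(betas, probes = rownames(betas$beta)[!bad_probe],
                     samples = keep)
  report <- structure(list(removed_samples = removed_samples,
                           removed_probes = removed_probes,
                           thresholds = config,
                           n_samples_in = length(samp_ids),
                           n_probes_in = nrow(betas$beta),
                           n_samples_out = ncol(out$beta),
                           n_probes_out = nrow(out$beta)),
                      class = "qc_report")
  list(betas = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> samples %d -> %d, probes %d -> %d\n",
              x$n_samples_in, x$n_samples_out, x$n_probes_in, x$n_probes_out))
  if (nrow(x$removed_samples)) {
    cat("removed samples:\n")
    print(x$removed_samples, row.names = FALSE)
  }
  invisible(x)
}

#' Pairwise correlation of technical replicates
#'
#' Pearson correlation of beta values over commonly detected probes for
#' every pair of samples within a replicate group, plus per-group and
#' overall means. Groups of size one are skipped with a warning.
#'
#' @param betas a `beta_matrix`.
#' @param replicates named character vector mapping sample id to replicate
#'   group; defaults to the `replicate_of` column of the sample table.
#' @return a `data.frame` with one row per within-group pair
#'   (`group`, `sample_a`, `sample_b`, `r`, `r_squared`, `n_probes`) and
#'   attributes `group_means` and `mean_r`.
#' @export
replicate_correlation <- function(betas, replicates = NULL) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (is.null(replicates)) {
    if (!"replicate_of" %in% names(betas$samples)) {
      stop_invalid("no replicate map given and no replicate_of column present")
    }
    replicates <- stats::setNames(as.character(betas$samples$replicate_of),
                                  betas$samples$sample_id)
    replicates <- replicates[!is.na(replicates)]
  }
  groups <- split(names(replicates), replicates)
  rows <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], colnames(betas$beta))
    if (length(ids) < 2) {
      warning(sprintf("replicate group '%s' has fewer than 2 samples; skipped", g),
              call. = FALSE)
      next
    }
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        a <- ids[i]; b <- ids[j]
        common <- betas$mask[, a] & betas$mask[, b]
        if (sum(common) < 3) next
        r <- stats::cor(betas$beta[common, a], betas$beta[common, b])
        rows[[length(rows) + 1]] <- data.frame(
          group = g, sample_a = a, sample_b = b,
          r = r, r_squared = r^2, n_probes = sum(common))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), sample_a = character(0),
               sample_b = character(0), r = numeric(0), r_squared = numeric(0),
               n_probes = integer(0))
  attr(out, "group_means") <- if (nrow(out)) tapply(out$r, out$group, mean) else numeric(0)
  attr(out, "mean_r") <- if (nrow(out)) mean(out$r) else NA_real_
  out
}
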