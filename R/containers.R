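#' Raw signal container: M/U intensities with detection p-values
#'
#' Rectangular probes-by-samples container for GenomeStudio-level array
#' signals: methylated intensity `M`, unmethylated intensity `U`, detection
#' p-values, plus a per-sample annotation table (BeadChip, group, aliquot,
#' optional replicate grouping).
#'
#' @param M,U numeric matrices (probes x samples), non-negative, with
#'   rownames = probe ids and colnames = sample ids.
#' @param detection_p matrix of detection p-values in \[0,1\], same shape;
#'   may be `NULL` until [detection_pvalues()] is run.
#' @param samples `data.frame` with columns `sample_id`, `chip`, `group`,
#'   `aliquot` (one of `"BS"`, `"TAB"`) and optionally `replicate_of`.
#' @return a `signal_matrix`.
#' @export
signal_matrix <- function(M, U, detection_p = NULL, samples) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (!identical(dim(M), dim(U))) stop_invalid("M and U must have identical shape")
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop_invalid("M must carry probe rownames and sample colnames")
  }
  if (anyNA(M) || anyNA(U) || any(!is.finite(M)) || any(!is.finite(U))) {
    stop_invalid("intensities must be finite")
  }
  if (any(M < 0) || any(U < 0)) {
    bad <- which(M < 0 | U < 0, arr.ind = TRUE)[1, ]
    stop_invalid("negative intensity at probe %s, sample %s",
                 rownames(M)[bad[1]], colnames(M)[bad[2]])
  }
  req <- c("sample_id", "chip", "group", "aliquot")
  if (!all(req %in% names(samples))) {
    stop_invalid("samples table needs columns: %s", paste(req, collapse = ", "))
  }
  if (!identical(as.character(samples$sample_id), colnames(M))) {
    stop_invalid("samples$sample_id must match the signal columns in order")
  }
  if (!all(samples$aliquot %in% c("BS", "TAB"))) {
    stop_invalid("aliquot labels must be 'BS' or 'TAB'")
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(M))) {
      stop_invalid("detection_p must match the signal shape")
    }
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      stop_invalid("detection p-values must lie in [0,1]")
    }
    dimnames(detection_p) <- dimnames(M)
  }
  dimnames(U) <- dimnames(M)
  structure(list(M = M, U = U, detection_p = detection_p,
                 samples = as.data.frame(samples)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d probes x %d samples (%s aliquot%s)\n",
              nrow(x$M), ncol(x$M),
              paste(unique(x$samples$aliquot), collapse = "+"),
              if (length(unique(x$samples$aliquot)) > 1) "s" else ""))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$M)

#' Beta-value container with detection mask
#'
#' @param beta numeric matrix of methylation fractions in \[0,1).
#' @param mask logical matrix, `TRUE` where the locus was detected
#'   (detection p <= threshold); masked entries are excluded from
#'   downstream statistics.
#' @param samples per-sample annotation as in [signal_matrix()].
#' @param normalization provenance string (e.g. `"quantile"` or `"none"`).
#' @return a `beta_matrix`.
#' @export
beta_matrix <- function(beta, mask = NULL, samples, normalization = "none") {
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta >= 1, na.rm = TRUE)) {
    stop_invalid("beta values must lie in [0,1)")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(beta), ncol(beta))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(beta))) stop_invalid("mask must match beta shape")
  dimnames(mask) <- dimnames(beta)
  structure(list(beta = beta, mask = mask, samples = as.data.frame(samples),
                 normalization = normalization),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, %.1f%% detected, normalization: %s\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(x$mask), x$normalization))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

# subset helper used by QC filtering
subset_beta <- function(x, probes = NULL, samples = NULL) {
  p <- probes %||% rownames(x$beta)
  s <- samples %||% colnames(x$beta)
  beta_matrix(x$beta[p, s, drop = FALSE], x$mask[p, s, drop = FALSE],
              x$samples[match(s, x$samples$sample_id), , drop = FALSE],
              x$normalization)
}
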