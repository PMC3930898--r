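#' Sample dissimilarity matrix
#'
#' Pairwise sample dissimilarities over commonly detected probes:
#' `one-minus-pearson` (1 - Pearson correlation of beta vectors, so
#' identical samples score 0 and perfectly anticorrelated samples score 2)
#' or plain `euclidean` distance.
#'
#' @param betas a `beta_matrix` (or plain numeric matrix, samples in
#'   columns).
#' @param metric `"one-minus-pearson"` or `"euclidean"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(betas, metric = c("one-minus-pearson", "euclidean")) {
  metric <- match.arg(metric)
  mat <- if (inherits(betas, "beta_matrix")) {
    m <- betas$beta
    m[!betas$mask] <- NA
    m
  } else {
    as.matrix(betas)
  }
  if (ncol(mat) < 2) stop_invalid("need at least 2 samples")
  common <- stats::complete.cases(mat)
  if (sum(common) < 2) stop_invalid("fewer than 2 commonly detected probes")
  mat <- mat[common, , drop = FALSE]
  d <- if (metric == "one-minus-pearson") {
    1 - stats::cor(mat)
  } else {
    as.matrix(stats::dist(t(mat)))
  }
  d <- (d + t(d)) / 2   # enforce exact symmetry against rounding
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Agglomerative hierarchical clustering of samples
#'
#' Average- or complete-linkage clustering of a dissimilarity matrix, as
#' used for unsupervised tissue/species dendrograms and QC outlier
#' inspection.
#'
#' @param dissim symmetric dissimilarity matrix with zero diagonal.
#' @param linkage `"average"` or `"complete"`.
#' @return a `meth_dendrogram`: the underlying `hclust` object plus metric
#'   and linkage provenance. Use [cut_dendrogram()] for flat labels and
#'   [dendrogram_newick()] for a Newick export.
#' @export
hierarchical_cluster <- function(dissim, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  dissim <- as.matrix(dissim)
  if (nrow(dissim) != ncol(dissim) ||
      !isTRUE(all.equal(dissim, t(dissim), tolerance = 1e-8))) {
    stop_invalid("dissimilarity matrix must be symmetric")
  }
  if (any(diag(dissim) != 0)) stop_invalid("dissimilarity diagonal must be zero")
  hc <- stats::hclust(stats::as.dist(dissim), method = linkage)
  structure(list(hclust = hc, linkage = linkage,
                 labels = hc$labels, merge = hc$merge, height = hc$height),
            class = "meth_dendrogram")
}

#' @export
print.meth_dendrogram <- function(x, ...) {
  cat(sprintf("<meth_dendrogram> %d leaves, %s linkage\n",
              length(x$labels), x$linkage))
  invisible(x)
}

#' Cut a dendrogram into k flat clusters
#'
#' @param dendrogram a `meth_dendrogram`.
#' @param k number of clusters.
#' @return named integer vector of cluster labels.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "meth_dendrogram"))
  stats::cutree(dendrogram$hclust, k = k)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are differences of merge heights (via
#' [ape::as.phylo.hclust()]).
#'
#' @param dendrogram a `meth_dendrogram`.
#' @param path optional file path; when omitted the Newick string is
#'   returned.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "meth_dendrogram"))
  phy <- ape::as.phylo(dendrogram$hclust)
  if (is.null(path)) ape::write.tree(phy) else ape::write.tree(phy, file = path)
}

#' Assemble a consolidated run report
#'
#' Collects the tabular outputs of a pipeline run (QC report, DML table,
#' enrichment table, cutoff summaries, dendrograms) into one
#' machine-readable structure; any subset of inputs may be given and
#' absent sections are marked as such. Serialize with [write_report()].
#'
#' @param qc a `qc_report` or NULL.
#' @param dml a `dml_result` table or NULL.
#' @param enrichment an enrichment table or NULL.
#' @param cutoffs a cutoff-summary `data.frame` or NULL.
#' @param dendrograms named list of `meth_dendrogram` objects or NULL.
#' @param parameters free-form named list recording run parameters.
#' @return a `crossmeth_report` list.
#' @export
assemble_report <- function(qc = NULL, dml = NULL, enrichment = NULL,
                            cutoffs = NULL, dendrograms = NULL,
                            parameters = NULL) {
  if (is.null(qc) && is.null(dml) && is.null(enrichment) &&
      is.null(cutoffs) && is.null(dendrograms)) {
    warning("assembling an empty report", call. = FALSE)
  }
  absent <- list(present = FALSE)
  rep <- list(
    parameters = parameters %||% list(),
    qc = if (is.null(qc)) absent else list(
      present = TRUE,
      n_samples_in = qc$n_samples_in, n_samples_out = qc$n_samples_out,
      n_probes_in = qc$n_probes_in, n_probes_out = qc$n_probes_out,
      removed_samples = qc$removed_samples, removed_probes_n = nrow(qc$removed_probes)),
    dml = if (is.null(dml)) absent else list(
      present = TRUE,
      n_tested = attr(dml, "n_tested"),
      n_significant = attr(dml, "n_significant"),
      alpha = attr(dml, "alpha"),
      significant = dml[dml$significant,
                        c("probe_id", "effect", "p", "fdr", "bonferroni")]),
    enrichment = if (is.null(enrichment)) absent else list(
      present = TRUE, table = enrichment),
    cutoffs = if (is.null(cutoffs)) absent else list(
      present = TRUE, table = cutoffs),
    dendrograms = if (is.null(dendrograms)) absent else list(
      present = TRUE,
      newick = lapply(dendrograms, dendrogram_newick))
  )
  structure(rep, class = "crossmeth_report")
}

#' @export
print.crossmeth_report <- function(x, ...) {
  sections <- vapply(x[setdiff(names(x), "parameters")],
                     function(s) isTRUE(s$present), logical(1))
  cat(sprintf("<crossmeth_report> sections: %s\n",
              paste(names(sections)[sections], collapse = ", ")))
  invisible(x)
}

#' Serialize a report to structured text (JSON)
#'
#' @param report a `crossmeth_report`.
#' @param path output file path.
#' @return the JSON string, invisibly.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "crossmeth_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                           digits = 10, dataframe = "rows")
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}
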