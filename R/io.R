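# Readers and writers for the plain-text interchange formats: FASTA genomes,
# BED island tracks, CSV gene models / manifests, TSV signal and beta tables.

#' Write / read a genome as FASTA
#' @param genome a `synth_genome`.
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "synth_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$chromosomes), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  chroms <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  synth_genome(chroms)
}

#' Write / read CpG islands as BED (0-based half-open)
#' @param track an `annotation_track`.
#' @param path file path.
#' @export
write_islands_bed <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  isl <- track$islands
  gr <- GenomicRanges::GRanges(
    isl$chrom,
    IRanges::IRanges(start = isl$start + 1L, end = isl$end),  # BED is 0-based on disk
    name = sprintf("island_%d", seq_len(nrow(isl))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_islands_bed
#' @export
read_islands_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Write / read gene models and probe manifests as CSV
#' @param x gene table or manifest `data.frame`.
#' @param path file path.
#' @export
write_genes_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_csv
#' @export
read_genes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reassemble an annotation track from its island and gene tables
#' @param islands island `data.frame` (`chrom`, `start`, `end`).
#' @param genes gene `data.frame` as written by [write_genes_csv()].
#' @export
make_annotation_track <- function(islands = NULL, genes = NULL) {
  annotation_track(islands = islands, genes = genes)
}

#' @rdname write_genes_csv
#' @export
write_manifest_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_csv
#' @export
read_manifest_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("gene_names", "gene_groups", "island_relation")) {
    if (col %in% names(m)) m[[col]][is.na(m[[col]])] <- ""
  }
  m
}

#' Write / read a signal matrix as TSV plus a sample sheet CSV
#'
#' The TSV carries one row per probe and, per sample, three columns in
#' GenomeStudio export style: `<sample>.Methylated`, `<sample>.Unmethylated`
#' and `<sample>.Detection.Pval`. The sample sheet CSV carries the chip,
#' group, aliquot and replicate annotation.
#'
#' @param signals a `signal_matrix`.
#' @param path TSV path for the signals.
#' @param samplesheet CSV path for the sample annotation.
#' @export
write_signals_tsv <- function(signals, path, samplesheet = NULL) {
  stopifnot(inherits(signals, "signal_matrix"))
  ids <- colnames(signals$M)
  out <- data.frame(probe_id = rownames(signals$M))
  for (s in ids) {
    out[[paste0(s, ".Methylated")]] <- signals$M[, s]
    out[[paste0(s, ".Unmethylated")]] <- signals$U[, s]
    out[[paste0(s, ".Detection.Pval")]] <-
      if (is.null(signals$detection_p)) NA_real_ else signals$detection_p[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samplesheet)) {
    utils::write.csv(signals$samples, samplesheet, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_signals_tsv
#' @export
read_signals_tsv <- function(path, samplesheet) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  samples <- utils::read.csv(samplesheet, stringsAsFactors = FALSE)
  ids <- samples$sample_id
  probe_id <- tab$probe_id
  get <- function(suffix) {
    m <- as.matrix(tab[, paste0(ids, suffix), drop = FALSE])
    dimnames(m) <- list(probe_id, ids)
    m
  }
  M <- get(".Methylated"); U <- get(".Unmethylated")
  dp <- get(".Detection.Pval")
  if (all(is.na(dp))) dp <- NULL
  signal_matrix(M, U, dp, samples)
}

#' Write / read a beta matrix (values TSV + mask TSV)
#' @param betas a `beta_matrix`.
#' @param path TSV path for beta values.
#' @param mask_path TSV path for the detection mask.
#' @param samplesheet CSV path for the sample annotation.
#' @export
write_betas_tsv <- function(betas, path, mask_path = NULL, samplesheet = NULL) {
  stopifnot(inherits(betas, "beta_matrix"))
  write_one <- function(m, p) {
    utils::write.table(data.frame(probe_id = rownames(m), m, check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(betas$beta, path)
  if (!is.null(mask_path)) write_one(betas$mask * 1L, mask_path)
  if (!is.null(samplesheet)) {
    utils::write.csv(betas$samples, samplesheet, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_betas_tsv
#' @export
read_betas_tsv <- function(path, mask_path = NULL, samplesheet = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  beta <- as.matrix(tab[, -1, drop = FALSE])
  rownames(beta) <- tab$probe_id
  mask <- NULL
  if (!is.null(mask_path)) {
    mt <- utils::read.table(mask_path, sep = "\t", header = TRUE, check.names = FALSE)
    mask <- as.matrix(mt[, -1, drop = FALSE]) == 1
    rownames(mask) <- mt$probe_id
  }
  samples <- if (is.null(samplesheet)) {
    data.frame(sample_id = colnames(beta), chip = NA, group = NA, aliquot = "BS")
  } else {
    utils::read.csv(samplesheet, stringsAsFactors = FALSE)
  }
  beta_matrix(beta, mask, samples)
}
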