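#' Scan a 50-mer probe sequence against a genome with bounded mismatches
#'
#' Finds every position, on either strand, where the probe matches the
#' genome with Hamming distance (substitutions only, no indels) at most
#' `max_mismatch`. Minus-strand hits are positions where the reverse
#' complement of the probe matches the forward genome sequence; their
#' coordinates are reported on the forward strand. The interrogated CpG
#' sits at probe offsets 25-26, which map to genome offsets 24-25 (0-based)
#' of the hit window on both strands (CG is its own reverse complement),
#' and `cpg_preserved` records whether the target carries CG there.
#'
#' Ambiguity codes in the probe are rejected; ambiguity codes in the genome
#' (e.g. N) simply never match an A/C/G/T probe base and therefore count as
#' mismatches (a message is emitted once per scan when present).
#'
#' @param probe_seq a 50-character ACGT string.
#' @param genome a `synth_genome`, a named character vector of chromosome
#'   sequences, or a [Biostrings::DNAStringSet].
#' @param max_mismatch maximum Hamming distance.
#' @return `data.frame` of hits sorted by (mismatch_count, chromosome,
#'   start): `chromosome`, `start` (0-based half-open), `strand`,
#'   `mismatch_count`, `cpg_preserved`.
#' @export
scan_probe <- function(probe_seq, genome, max_mismatch = 4L) {
  max_mismatch <- assert_count(max_mismatch, "max_mismatch", positive = FALSE)
  probe_seq <- as.character(probe_seq)
  if (nchar(probe_seq) != PROBE_WIDTH) {
    stop_invalid("probe sequence must be exactly %d bases, got %d",
                 PROBE_WIDTH, nchar(probe_seq))
  }
  if (grepl("[^ACGT]", probe_seq)) {
    stop_invalid("probe sequence contains ambiguity codes: %s", probe_seq)
  }
  subject <- as_dna_subject(genome)
  if (any(Biostrings::alphabetFrequency(subject, baseOnly = TRUE)[, "other"] > 0)) {
    message("genome contains ambiguity codes; they are counted as mismatches")
  }
  pat_fwd <- Biostrings::DNAString(probe_seq)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  hits <- rbind(
    match_one_strand(pat_fwd, subject, max_mismatch, "+"),
    match_one_strand(pat_rev, subject, max_mismatch, "-")
  )
  if (nrow(hits)) {
    # CpG window: genome offsets 24-25 of the 50-base hit on either strand
    win <- substring(as.character(subject[hits$chromosome]),
                     hits$start + CPG_OFFSET, hits$start + CPG_OFFSET + 1L)
    hits$cpg_preserved <- win == "CG"
    hits <- hits[order(hits$mismatch_count, hits$chromosome, hits$start), ]
    rownames(hits) <- NULL
  }
  hits
}

as_dna_subject <- function(genome) {
  if (inherits(genome, "synth_genome")) {
    Biostrings::DNAStringSet(genome$chromosomes)
  } else if (inherits(genome, "DNAStringSet")) {
    genome
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop_invalid("genome sequences must be named")
    Biostrings::DNAStringSet(genome)
  } else {
    stop_invalid("unsupported genome representation: %s", class(genome)[1])
  }
}

match_one_strand <- function(pattern, subject, max_mismatch, strand) {
  m <- Biostrings::vmatchPattern(pattern, subject, max.mismatch = max_mismatch,
                                 with.indels = FALSE, fixed = TRUE)
  rows <- lapply(seq_along(subject), function(i) {
    st <- Biostrings::startIndex(m)[[i]]
    if (is.null(st) || !length(st)) return(NULL)
    # clip matches that would run off the chromosome (vmatchPattern can
    # report out-of-bounds starts at max.mismatch > 0)
    ok <- st >= 1 & st + PROBE_WIDTH - 1L <= length(subject[[i]])
    st <- st[ok]
    if (!length(st)) return(NULL)
    mm <- Biostrings::neditStartingAt(pattern, subject[[i]], starting.at = st,
                                      with.indels = FALSE, fixed = TRUE)
    data.frame(chromosome = names(subject)[i], start = st - 1L,
               strand = strand, mismatch_count = as.integer(mm))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(0), start = integer(0),
                      strand = character(0), mismatch_count = integer(0))
  }
  out$cpg_preserved <- logical(nrow(out))
  out
}

#' Identify species-competent probes
#'
#' Scans every manifest probe against a target genome and builds the two
#' probe sets used for cross-species array analysis: the exact set (probes
#' with a perfect-match locus) and the mismatch set (probes matching with
#' at most `max_mismatch` substitutions). A hit is acceptable only if it
#' preserves the interrogated CpG (configurable); probes whose best
#' acceptable locus is not unique ("unique-best" policy) are excluded and
#' counted, since a probe reporting two loci is uninterpretable. The exact
#' set is always a subset of the mismatch set built from the same inputs.
#'
#' @param manifest probe manifest with `probe_id` and `source_seq`.
#' @param genome target genome (see [scan_probe()]).
#' @param max_mismatch mismatch bound for the mismatch set (default 4).
#' @param require_cpg reject hits whose target lacks CG at the interrogated
#'   position (default TRUE).
#' @param species_label label stored in the result.
#' @return list with `exact` and `mismatch`, each a `competent_set`:
#'   accepted hits (one per probe), parameters, and a summary with
#'   retention counts/fractions and exclusion tallies.
#' @export
build_competent_sets <- function(manifest, genome, max_mismatch = 4L,
                                 require_cpg = TRUE,
                                 species_label = "target") {
  if (!nrow(manifest)) stop_invalid("manifest is empty")
  max_mismatch <- assert_count(max_mismatch, "max_mismatch", positive = FALSE)
  subject <- as_dna_subject(genome)
  if (sum(lengths(subject)) == 0) stop_invalid("genome is empty")

  all_hits <- lapply(seq_len(nrow(manifest)), function(i) {
    h <- scan_probe(manifest$source_seq[i], subject, max_mismatch)
    if (nrow(h)) h$probe_id <- manifest$probe_id[i]
    h
  })
  build_set <- function(threshold, kind) {
    accepted <- list(); n_multi <- 0L; n_cpg_lost <- 0L
    for (h in all_hits) {
      if (!nrow(h)) next
      ok <- h[h$mismatch_count <= threshold, , drop = FALSE]
      if (require_cpg) {
        lost <- nrow(ok) > 0 && !any(ok$cpg_preserved)
        if (lost) n_cpg_lost <- n_cpg_lost + 1L
        ok <- ok[ok$cpg_preserved, , drop = FALSE]
      }
      if (!nrow(ok)) next
      best <- min(ok$mismatch_count)
      at_best <- ok[ok$mismatch_count == best, , drop = FALSE]
      if (nrow(at_best) > 1) { n_multi <- n_multi + 1L; next }
      accepted[[length(accepted) + 1]] <- at_best
    }
    hits <- if (length(accepted)) do.call(rbind, accepted) else
      data.frame(chromosome = character(0), start = integer(0),
                 strand = character(0), mismatch_count = integer(0),
                 cpg_preserved = logical(0), probe_id = character(0))
    rownames(hits) <- NULL
    structure(list(
      species_label = species_label,
      set_kind = kind,
      hits = hits[, c("probe_id", "chromosome", "start", "strand",
                      "mismatch_count", "cpg_preserved")],
      parameters = list(max_mismatch = threshold, require_cpg = require_cpg,
                        uniqueness = "unique-best"),
      summary = list(n_manifest = nrow(manifest),
                     n_retained = nrow(hits),
                     retention = nrow(hits) / nrow(manifest),
                     n_multi_dropped = n_multi,
                     n_cpg_lost = n_cpg_lost)),
      class = "competent_set")
  }
  list(exact = build_set(0L, "exact"),
       mismatch = build_set(max_mismatch, "mismatch"))
}

#' @export
print.competent_set <- function(x, ...) {
  cat(sprintf("<competent_set:%s> %s: %d / %d probes retained (%.1f%%), %d multi-mapping dropped, %d lost CpG\n",
              x$set_kind, x$species_label, x$summary$n_retained,
              x$summary$n_manifest, 100 * x$summary$retention,
              x$summary$n_multi_dropped, x$summary$n_cpg_lost))
  invisible(x)
}

#' Expected mismatch-set retention under uniform substitution
#'
#' Closed-form prediction for the fraction of probes surviving
#' [build_competent_sets()] against a genome diverged by independent
#' per-base substitutions at rate `rate`: the two CpG bases must be intact
#' (a CpG-destroying substitution rejects the locus) and at most
#' `max_mismatch` of the remaining 48 bases may be substituted.
#'
#' @param rate per-base substitution rate.
#' @param max_mismatch mismatch bound.
#' @param require_cpg whether CpG preservation is enforced.
#' @return expected retention fraction.
#' @export
expected_retention <- function(rate, max_mismatch = 4L, require_cpg = TRUE) {
  if (require_cpg) {
    (1 - rate)^2 * stats::pbinom(max_mismatch, PROBE_WIDTH - 2L, rate)
  } else {
    stats::pbinom(max_mismatch, PROBE_WIDTH, rate)
  }
}

#' Re-annotate competent probes against target-species tracks
#'
#' Translates each accepted hit to the target genome coordinate of its
#' interrogated CpG and recomputes island relation and gene annotation from
#' the target-species annotation track with [assign_categories()]. The
#' original (source-species) annotation is preserved alongside with a
#' `source_` prefix when the manifest is supplied.
#'
#' @param set a `competent_set`.
#' @param target_track the target-species `annotation_track`.
#' @param manifest optional source manifest for carrying source annotation.
#' @return `data.frame` with one row per retained probe: target coordinates
#'   and annotation, plus source annotation columns when available.
#' @export
reannotate <- function(set, target_track, manifest = NULL) {
  stopifnot(inherits(set, "competent_set"), inherits(target_track, "annotation_track"))
  hits <- set$hits
  if (!nrow(hits)) stop_invalid("competent set has no hits to re-annotate")
  probes <- data.frame(
    probe_id = hits$probe_id,
    chromosome = hits$chromosome,
    position = hits$start + CPG_OFFSET,  # 1-based C of the interrogated CpG
    strand = hits$strand)
  ann <- assign_categories(probes, target_track)
  out <- cbind(probes, ann[, c("island_relation", "gene_names", "gene_groups",
                               "tss_island")])
  out$mismatch_count <- hits$mismatch_count
  if (!is.null(manifest)) {
    src <- manifest[match(out$probe_id, manifest$probe_id),
                    c("chromosome", "position", "gene_names", "gene_groups",
                      "island_relation")]
    names(src) <- paste0("source_", names(src))
    out <- cbind(out, src)
  }
  rownames(out) <- NULL
  out
}
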