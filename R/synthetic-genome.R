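#' Generate a synthetic genome with CpG islands and gene models
#'
#' Builds a toy multi-chromosome genome of i.i.d. A/C/G/T background sequence
#' into which CpG-enriched island intervals and non-overlapping gene models
#' are planted. The returned annotation track records exactly what was
#' planted, so island/shore/shelf and gene-structure assignments made
#' downstream can be checked against known coordinates.
#'
#' Islands are fixed-width intervals whose sequence is drawn from a
#' CpG-enriched token process (roughly one CpG every seven bases, against a
#' background rate near 1/16). Genes are 3 kb models laid out as
#' 5'UTR (100 b), first exon (200 b), body (2.5 kb) and 3'UTR (200 b),
#' oriented by a random strand; gene placement avoids gene-gene overlap but
#' genes may overlap islands, as in real genomes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param lengths integer vector of chromosome lengths (recycled to
#'   `n_chromosomes`).
#' @param island_density target fraction of bases inside CpG islands.
#' @param gene_density target fraction of bases inside gene models.
#' @param seed integer seed; identical seed and parameters give a
#'   byte-identical genome.
#' @return a list with `genome` (a `synth_genome`: named character vector of
#'   chromosome sequences) and `track` (an `annotation_track` with 0-based
#'   half-open `islands` and `genes` tables).
#' @examples
#' g <- generate_genome(2, c(10000, 8000), seed = 1)
#' nchar(g$genome$chromosomes)
#' head(g$track$islands)
#' @export
generate_genome <- function(n_chromosomes = 2L, lengths = 50000L,
                            island_density = 0.05, gene_density = 0.3,
                            seed = 1L) {
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  assert_fraction(island_density, "island_density")
  assert_fraction(gene_density, "gene_density")
  seed <- assert_count(seed, "seed", positive = FALSE)
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop_invalid("chromosome lengths must all be positive")
  }
  lengths <- as.integer(rep_len(lengths, n_chromosomes))
  chrom_names <- paste0("chr", seq_len(n_chromosomes))

  withr::with_seed(seed, {
    chroms <- character(n_chromosomes)
    islands <- vector("list", n_chromosomes)
    genes <- vector("list", n_chromosomes)
    for (i in seq_len(n_chromosomes)) {
      L <- lengths[i]
      bases <- sample(BASES, L, replace = TRUE)
      isl <- place_intervals(L, island_density, width = 500L)
      for (j in seq_len(nrow(isl))) {
        w <- isl$end[j] - isl$start[j]
        bases[(isl$start[j] + 1L):isl$end[j]] <- island_sequence(w)
      }
      gn <- place_genes(L, gene_density, chrom_names[i])
      chroms[i] <- paste(bases, collapse = "")
      if (nrow(isl)) isl$chrom <- chrom_names[i]
      islands[[i]] <- isl
      genes[[i]] <- gn
    }
    names(chroms) <- chrom_names
    track <- annotation_track(
      islands = do.call(rbind, islands),
      genes = do.call(rbind, genes)
    )
    list(
      genome = synth_genome(chroms, seed = seed),
      track = track
    )
  })
}

synth_genome <- function(chromosomes, seed = NA_integer_) {
  if (length(chromosomes) == 0 || any(!nzchar(chromosomes))) {
    stop_invalid("every chromosome must be a non-empty sequence")
  }
  if (any(grepl("[^ACGT]", chromosomes))) {
    stop_invalid("synthetic genome alphabet must be strictly ACGT")
  }
  structure(list(chromosomes = chromosomes, seed = seed), class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("<synth_genome> %d chromosome(s), %s bases total\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

annotation_track <- function(islands = NULL, genes = NULL) {
  empty_islands <- data.frame(chrom = character(0), start = integer(0),
                              end = integer(0))
  if (is.null(islands) || !nrow(islands)) islands <- empty_islands
  islands <- islands[order(islands$chrom, islands$start), c("chrom", "start", "end")]
  rownames(islands) <- NULL
  # islands must be non-overlapping within a chromosome
  by_chrom <- split(islands, islands$chrom)
  for (d in by_chrom) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop_invalid("island intervals overlap on %s", d$chrom[1])
    }
  }
  if (is.null(genes)) {
    genes <- data.frame(name = character(0), chrom = character(0),
                        strand = character(0), tss = integer(0))
  }
  structure(list(islands = islands, genes = genes), class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d island(s), %d gene(s)\n",
              nrow(x$islands), nrow(x$genes)))
  invisible(x)
}

# Place non-overlapping fixed-width intervals covering ~density of [0, L).
# One interval per equal block keeps them disjoint and evenly spread.
place_intervals <- function(L, density, width = 500L) {
  width <- min(width, as.integer(L))
  n <- round(density * L / width)
  if (n < 1 || density == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  block <- L %/% n
  if (block < width) {
    n <- max(1L, L %/% width)
    block <- L %/% n
  }
  offsets <- vapply(seq_len(n), function(i) {
    as.integer(sample.int(block - width + 1L, 1L) - 1L)
  }, integer(1))
  start <- (seq_len(n) - 1L) * block + offsets
  data.frame(chrom = NA_character_, start = as.integer(start),
             end = as.integer(start + width))
}

# CpG-enriched sequence: tokens are 'CG' with probability 0.25, else a single
# uniform base.
island_sequence <- function(width) {
  n_tok <- width  # upper bound; trimmed below
  tok <- ifelse(stats::runif(n_tok) < 0.25, "CG",
                sample(BASES, n_tok, replace = TRUE))
  s <- strsplit(paste(tok, collapse = ""), "")[[1]]
  s[seq_len(width)]
}

GENE_LAYOUT <- list(utr5 = 100L, exon1 = 200L, body = 2500L, utr3 = 200L)
GENE_WIDTH <- sum(unlist(GENE_LAYOUT))

place_genes <- function(L, density, chrom) {
  cols <- c("name", "chrom", "strand", "tss",
            "utr5_start", "utr5_end", "exon1_start", "exon1_end",
            "body_start", "body_end", "utr3_start", "utr3_end")
  empty <- as.data.frame(stats::setNames(
    c(list(character(0), character(0), character(0)),
      rep(list(integer(0)), 9)), cols))
  n <- round(density * L / GENE_WIDTH)
  if (n < 1 || density == 0 || L < GENE_WIDTH) return(empty)
  block <- L %/% n
  if (block < GENE_WIDTH) {
    n <- max(1L, L %/% GENE_WIDTH)
    block <- L %/% n
  }
  starts <- vapply(seq_len(n), function(i) {
    as.integer((i - 1L) * block + sample.int(block - GENE_WIDTH + 1L, 1L) - 1L)
  }, integer(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  g <- lapply(seq_len(n), function(i) gene_model(starts[i], strand[i]))
  g <- do.call(rbind, g)
  g$name <- sprintf("%s_G%03d", toupper(chrom), seq_len(n))
  g$chrom <- chrom
  g[, cols]
}

# 0-based half-open intervals for one 3 kb gene starting at `s`
gene_model <- function(s, strand) {
  w <- GENE_LAYOUT
  if (strand == "+") {
    utr5 <- c(s, s + w$utr5)
    exon1 <- c(utr5[2], utr5[2] + w$exon1)
    body <- c(exon1[2], exon1[2] + w$body)
    utr3 <- c(body[2], body[2] + w$utr3)
    tss <- s
  } else {
    e <- s + GENE_WIDTH
    utr5 <- c(e - w$utr5, e)
    exon1 <- c(utr5[1] - w$exon1, utr5[1])
    body <- c(exon1[1] - w$body, exon1[1])
    utr3 <- c(s, s + w$utr3)
    tss <- e - 1L
  }
  data.frame(name = NA_character_, chrom = NA_character_, strand = strand,
             tss = as.integer(tss),
             utr5_start = as.integer(utr5[1]), utr5_end = as.integer(utr5[2]),
             exon1_start = as.integer(exon1[1]), exon1_end = as.integer(exon1[2]),
             body_start = as.integer(body[1]), body_end = as.integer(body[2]),
             utr3_start = as.integer(utr3[1]), utr3_end = as.integer(utr3[2]))
}

#' Mutate a genome by independent base substitutions
#'
#' Creates a diverged "species" genome: every base is independently replaced
#' by one of the three other bases with the given probability. Coordinates
#' are preserved (substitutions only, no indels), so probes designed on the
#' source genome can be scanned against the mutant at the same loci.
#'
#' @param genome a `synth_genome`.
#' @param substitution_rate per-base substitution probability in \[0,1).
#' @param seed integer seed.
#' @return a `synth_genome` with the same chromosome names and lengths.
#' @export
mutate_genome <- function(genome, substitution_rate, seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"))
  if (!is.numeric(substitution_rate) || length(substitution_rate) != 1 ||
      substitution_rate < 0 || substitution_rate >= 1) {
    stop_invalid("substitution_rate must be in [0,1), got %s",
                 format(substitution_rate))
  }
  seed <- assert_count(seed, "seed", positive = FALSE)
  if (substitution_rate == 0) {
    out <- genome
    out$seed <- seed
    return(out)
  }
  withr::with_seed(seed, {
    chroms <- vapply(genome$chromosomes, function(s) {
      b <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(b)) < substitution_rate)
      if (length(hit)) {
        old <- match(b[hit], BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        b[hit] <- BASES[((old - 1L + shift) %% 4L) + 1L]
      }
      paste(b, collapse = "")
    }, character(1))
    names(chroms) <- names(genome$chromosomes)
    synth_genome(chroms, seed = seed)
  })
}

#' Design a probe manifest on a synthetic genome
#'
#' Samples `n_probes` CpG dinucleotides (with 50 bases of flank available)
#' and emits one 50-mer probe per CpG, centered so the interrogated C sits at
#' probe offset 25. Island relation and gene annotation are computed from the
#' supplied track with the same rules used by [assign_categories()], so the
#' manifest is internally consistent with downstream enrichment analysis.
#'
#' @param genome a `synth_genome`.
#' @param track the matching `annotation_track`.
#' @param n_probes number of probes to design.
#' @param seed integer seed.
#' @return a manifest `data.frame` with columns `probe_id`, `source_seq`,
#'   `chromosome`, `position` (1-based coordinate of the interrogated C),
#'   `strand`, `gene_names`, `gene_groups`, `island_relation`.
#' @export
generate_manifest <- function(genome, track, n_probes = 500L, seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"), inherits(track, "annotation_track"))
  n_probes <- assert_count(n_probes, "n_probes")
  seed <- assert_count(seed, "seed", positive = FALSE)

  sites <- find_cpg_sites(genome)
  if (nrow(sites) < n_probes) {
    stop_invalid(
      "genome has only %d usable CpG sites with 50 bases of flank; %d more needed for %d probes",
      nrow(sites), n_probes - nrow(sites), n_probes)
  }
  withr::with_seed(seed, {
    keep <- sort(sample.int(nrow(sites), n_probes))
  })
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[order(sites$chromosome, sites$position), , drop = FALSE]
  seqs <- substring(genome$chromosomes[sites$chromosome],
                    sites$position - (CPG_OFFSET - 1L),
                    sites$position + PROBE_WIDTH - CPG_OFFSET)
  manifest <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    source_seq = unname(seqs),
    chromosome = sites$chromosome,
    position = sites$position,
    strand = "+",
    stringsAsFactors = FALSE
  )
  ann <- assign_categories(manifest, track)
  manifest$gene_names <- ann$gene_names
  manifest$gene_groups <- ann$gene_groups
  manifest$island_relation <- ann$island_relation
  rownames(manifest) <- NULL
  manifest
}

# all CpG positions (1-based position of the C) with full probe flank
find_cpg_sites <- function(genome) {
  out <- lapply(names(genome$chromosomes), function(cn) {
    s <- genome$chromosomes[[cn]]
    pos <- gregexpr("CG", s, fixed = TRUE)[[1]]
    pos <- pos[pos > 0]
    pos <- pos[pos >= CPG_OFFSET & pos + (PROBE_WIDTH - CPG_OFFSET) <= nchar(s)]
    if (!length(pos)) return(NULL)
    data.frame(chromosome = cn, position = as.integer(pos))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chromosome = character(0), position = integer(0)) else out
}
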