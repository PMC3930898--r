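#' Assign CpG-island relation and gene-structure categories to probes
#'
#' Island relation is computed from the distance between the interrogated
#' CpG and the nearest island: `Island` inside an island interval, shores
#' within (0, 2000] bases of the island, shelves within (2000, 4000], and
#' `OpenSea` beyond. The `N_` (north) flank lies 5' of the island and `S_`
#' (south) 3', following the array-manifest convention. A probe equidistant
#' from two islands takes the 5' island. Islands are flagged TSS-associated
#' when any transcription start site lies within 1500 bases of the island
#' interval; island probes inherit that flag (`tss_island`, NA off-island).
#'
#' Gene-structure membership allows multiple genes per probe: `TSS200`
#' (within 200 bases upstream of a TSS), `TSS1500` (200-1500 upstream),
#' `5UTR`, `1stExon`, `Body` and `3UTR` by interval containment, all
#' strand-aware.
#'
#' @param probes `data.frame` with `probe_id`, `chromosome` and `position`
#'   (1-based coordinate of the interrogated C).
#' @param track an `annotation_track`.
#' @return `data.frame` with `probe_id`, `chromosome`, `position`,
#'   `island_relation`, `tss_island`, `gene_names`, `gene_groups`
#'   (parallel ';'-joined lists).
#' @export
assign_categories <- function(probes, track) {
  stopifnot(inherits(track, "annotation_track"))
  need <- c("probe_id", "chromosome", "position")
  if (!all(need %in% names(probes))) {
    stop_invalid("probes need columns: %s", paste(need, collapse = ", "))
  }
  known <- unique(c(track$islands$chrom, track$genes$chrom))
  bad <- setdiff(unique(probes$chromosome), known)
  if (length(bad)) {
    stop_invalid("chromosome(s) absent from the annotation track: %s",
                 paste(bad, collapse = ", "))
  }
  tss_flags <- island_tss_flags(track)
  out <- probes[, need]
  out$island_relation <- "OpenSea"
  out$tss_island <- NA
  out$gene_names <- ""
  out$gene_groups <- ""
  for (cn in unique(probes$chromosome)) {
    idx <- which(probes$chromosome == cn)
    rel <- island_relation_for(probes$position[idx],
                               track$islands[track$islands$chrom == cn, , drop = FALSE],
                               tss_flags[track$islands$chrom == cn])
    out$island_relation[idx] <- rel$relation
    out$tss_island[idx] <- rel$tss_island
    g <- gene_groups_for(probes$position[idx],
                         track$genes[track$genes$chrom == cn, , drop = FALSE])
    out$gene_names[idx] <- g$names
    out$gene_groups[idx] <- g$groups
  }
  rownames(out) <- NULL
  out
}

# TRUE for islands with a TSS within 1500 bases of the interval
island_tss_flags <- function(track) {
  isl <- track$islands
  if (!nrow(isl)) return(logical(0))
  flags <- logical(nrow(isl))
  for (cn in unique(isl$chrom)) {
    ii <- which(isl$chrom == cn)
    tss <- track$genes$tss[track$genes$chrom == cn]
    if (!length(tss)) next
    for (k in ii) {
      # island 0-based [start, end); distance 0 when the TSS is inside
      d <- ifelse(tss >= isl$start[k] & tss < isl$end[k], 0,
                  pmin(abs(tss - isl$start[k]), abs(tss - (isl$end[k] - 1L))))
      flags[k] <- any(d <= 1500)
    }
  }
  flags
}

# island relation for 1-based probe positions vs islands of one chromosome
island_relation_for <- function(pos, islands, tss_flags) {
  n <- length(pos)
  if (!nrow(islands)) {
    return(list(relation = rep("OpenSea", n), tss_island = rep(NA, n)))
  }
  s1 <- islands$start + 1L   # 1-based first island base
  e1 <- islands$end          # 1-based last island base
  relation <- character(n)
  tss_isl <- rep(NA, n)
  for (i in seq_len(n)) {
    p <- pos[i]
    inside <- p >= s1 & p <= e1
    d <- ifelse(inside, 0L, ifelse(p < s1, s1 - p, p - e1))
    nearest <- which(d == min(d))
    # tie between two islands: take the 5' one (smaller start)
    k <- nearest[which.min(islands$start[nearest])]
    if (inside[k]) {
      relation[i] <- "Island"
      tss_isl[i] <- tss_flags[k]
    } else if (d[k] <= 2000) {
      relation[i] <- if (p < s1[k]) "N_Shore" else "S_Shore"
    } else if (d[k] <= 4000) {
      relation[i] <- if (p < s1[k]) "N_Shelf" else "S_Shelf"
    } else {
      relation[i] <- "OpenSea"
    }
  }
  list(relation = relation, tss_island = tss_isl)
}

# ';'-joined gene names / groups for 1-based positions vs genes of one chrom
gene_groups_for <- function(pos, genes) {
  n <- length(pos)
  if (!nrow(genes)) return(list(names = rep("", n), groups = rep("", n)))
  windows <- gene_windows(genes)
  hits <- IRanges::findOverlaps(IRanges::IRanges(pos, width = 1L), windows$ranges)
  nm <- rep("", n); gr <- rep("", n)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) {
      sel <- s[q == i]
      ord <- order(windows$gene[sel], windows$group[sel])
      nm[i] <- collapse_field(windows$gene[sel][ord])
      gr[i] <- collapse_field(windows$group[sel][ord])
    }
  }
  list(names = nm, groups = gr)
}

# 1-based inclusive windows for every gene-structure category of each gene
gene_windows <- function(genes) {
  starts <- integer(0); ends <- integer(0); gene <- character(0); group <- character(0)
  add <- function(s, e, g, lab) {
    keep <- e >= s
    starts <<- c(starts, s[keep]); ends <<- c(ends, e[keep])
    gene <<- c(gene, g[keep]); group <<- c(group, rep(lab, sum(keep)))
  }
  plus <- genes$strand == "+"
  tss1 <- genes$tss + 1L  # 1-based TSS coordinate
  # upstream promoter windows, strand-aware
  add(ifelse(plus, tss1 - 200L, tss1 + 1L),
      ifelse(plus, tss1 - 1L, tss1 + 200L), genes$name, "TSS200")
  add(ifelse(plus, tss1 - 1500L, tss1 + 201L),
      ifelse(plus, tss1 - 201L, tss1 + 1500L), genes$name, "TSS1500")
  add(genes$utr5_start + 1L, genes$utr5_end, genes$name, "5UTR")
  add(genes$exon1_start + 1L, genes$exon1_end, genes$name, "1stExon")
  add(genes$body_start + 1L, genes$body_end, genes$name, "Body")
  add(genes$utr3_start + 1L, genes$utr3_end, genes$name, "3UTR")
  starts <- pmax(1L, starts)
  ok <- ends >= starts   # drop windows clipped entirely off the chromosome
  list(ranges = IRanges::IRanges(starts[ok], ends[ok]),
       gene = gene[ok], group = group[ok])
}

# logical membership of each assignment row in a named category
category_membership <- function(assignment, category) {
  if (category %in% ISLAND_RELATIONS) {
    assignment$island_relation == category
  } else if (category %in% GENE_GROUPS) {
    vapply(assignment$gene_groups, function(g) category %in% split_field(g),
           logical(1), USE.NAMES = FALSE)
  } else if (category %in% assignment$chromosome) {
    assignment$chromosome == category
  } else {
    stop_invalid("unknown category '%s'", category)
  }
}

#' Fisher's exact test for category enrichment of a hit set
#'
#' Builds the 2x2 table (hit / non-hit) x (in / out of category) over the
#' probe panel and reports the exact two-sided p-value (point-probability
#' rule), both one-sided p-values, and the sample odds ratio (with 0.5
#' added to every cell when any cell is zero, flagged in the output).
#'
#' @param assignment output of [assign_categories()] for the whole panel.
#' @param hits character vector of probe ids forming the hit set (must be a
#'   subset of the panel).
#' @param category a category label: an island relation, a gene-structure
#'   group, or a chromosome name.
#' @return one-row `data.frame`: `category`, `n_panel`, `n_in_category`,
#'   `n_hits`, `n_hits_in_category`, `fisher_p`, `fisher_p_over`,
#'   `fisher_p_under`, `odds_ratio`, `or_continuity`.
#' @export
fisher_category <- function(assignment, hits, category) {
  if (!nrow(assignment)) stop_invalid("empty probe panel")
  if (!all(hits %in% assignment$probe_id)) {
    stop_invalid("hit set contains probes outside the panel")
  }
  in_cat <- category_membership(assignment, category)
  is_hit <- assignment$probe_id %in% hits
  a <- sum(is_hit & in_cat); b <- sum(is_hit & !in_cat)
  cc <- sum(!is_hit & in_cat); d <- sum(!is_hit & !in_cat)
  tab <- matrix(c(a, cc, b, d), 2, 2)
  p_two <- stats::fisher.test(tab)$p.value
  p_over <- stats::fisher.test(tab, alternative = "greater")$p.value
  p_under <- stats::fisher.test(tab, alternative = "less")$p.value
  continuity <- any(tab == 0)
  or <- if (continuity) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  if (all(in_cat) || !any(in_cat)) or <- NA_real_  # degenerate margin
  data.frame(category = category, n_panel = nrow(assignment),
             n_in_category = sum(in_cat), n_hits = sum(is_hit),
             n_hits_in_category = a,
             fisher_p = p_two, fisher_p_over = p_over, fisher_p_under = p_under,
             odds_ratio = or, or_continuity = continuity)
}

#' Permutation test for category enrichment of a hit set
#'
#' Each permutation draws `|hits|` probes uniformly without replacement
#' from the panel; the permuted proportion of a category is the share of
#' the drawn set falling in it. The over-representation p-value of a
#' category is the fraction of permutations whose permuted proportion
#' meets or exceeds the actual proportion (under-representation
#' analogously with <=), so p-values lie on the grid k/n_perm.
#'
#' With `family_correct = TRUE` (the chromosome analysis) a family-wide
#' correction is applied: category sizes differ, so proportions are first
#' converted to enrichment ratios (observed / expected proportion), and
#' the actual ratio of each category is compared against the most extreme
#' permuted ratio of *any* category in each permutation. The corrected
#' p-value can never be smaller than the uncorrected one.
#'
#' @param assignment output of [assign_categories()] for the panel.
#' @param hits probe ids forming the hit set.
#' @param categories category labels to test (default: all island
#'   relations present).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param family_correct apply the cross-category max-ratio correction.
#' @return `data.frame` with one row per category: counts, actual
#'   proportion, `perm_p_over`, `perm_p_under`, and when requested
#'   `perm_p_over_corrected`, `perm_p_under_corrected`; plus `n_perm`.
#' @export
permute_enrichment <- function(assignment, hits, categories = NULL,
                               n_perm = 10000L, seed = 1L,
                               family_correct = FALSE) {
  n_perm <- assert_count(n_perm, "n_perm")
  if (n_perm < 100) stop_invalid("n_perm must be at least 100")
  seed <- assert_count(seed, "seed", positive = FALSE)
  n <- nrow(assignment)
  if (!all(hits %in% assignment$probe_id)) {
    stop_invalid("hit set contains probes outside the panel")
  }
  k <- length(unique(hits))
  if (k > n) stop_invalid("hit set larger than the panel")
  if (is.null(categories)) {
    categories <- intersect(ISLAND_RELATIONS, unique(assignment$island_relation))
  }
  memb <- vapply(categories, function(cat) category_membership(assignment, cat),
                 logical(n))
  is_hit <- assignment$probe_id %in% hits
  actual_count <- colSums(memb & is_hit)
  n_in_cat <- colSums(memb)

  withr::with_seed(seed, {
    draws <- replicate(n_perm, sample.int(n, k))  # k x n_perm index matrix
  })
  perm_counts <- vapply(seq_along(categories), function(ci) {
    colSums(matrix(memb[draws, ci], k, n_perm))
  }, numeric(n_perm))  # n_perm x n_cat

  res <- data.frame(
    category = categories,
    n_panel = n, n_in_category = n_in_cat, n_hits = k,
    n_hits_in_category = actual_count,
    actual_proportion = actual_count / k,
    perm_p_over = vapply(seq_along(categories), function(ci) {
      mean(perm_counts[, ci] >= actual_count[ci])
    }, numeric(1)),
    perm_p_under = vapply(seq_along(categories), function(ci) {
      mean(perm_counts[, ci] <= actual_count[ci])
    }, numeric(1)),
    n_perm = n_perm)
  if (family_correct) {
    expected <- n_in_cat / n          # expected proportion of the draw
    actual_ratio <- (actual_count / k) / expected
    perm_ratio <- sweep(perm_counts / k, 2, expected, "/")
    max_ratio <- apply(perm_ratio, 1, max)
    min_ratio <- apply(perm_ratio, 1, min)
    res$perm_p_over_corrected <- vapply(seq_along(categories), function(ci) {
      mean(max_ratio >= actual_ratio[ci])
    }, numeric(1))
    res$perm_p_under_corrected <- vapply(seq_along(categories), function(ci) {
      mean(min_ratio <= actual_ratio[ci])
    }, numeric(1))
  }
  rownames(res) <- NULL
  res
}

#' Combined Fisher + permutation enrichment table
#'
#' Convenience wrapper producing one table mirroring the layout of standard
#' enrichment reports: per category, panel/hit counts, Fisher p-value and
#' odds ratio, and the permutation p-values.
#'
#' @inheritParams permute_enrichment
#' @param cutoff the 5-hmC cutoff that defined the hit set (recorded in the
#'   output).
#' @return `data.frame` with columns `category`, `cutoff`,
#'   `n_probes_dataset`, `n_probes_cutoff`, `n_probes_region`,
#'   `n_common_probes`, `fisher_p`, `odds_ratio`, `perm_p_over`,
#'   `perm_p_under` (and corrected columns when `family_correct`).
#' @export
enrichment_table <- function(assignment, hits, categories = NULL,
                             cutoff = NA_real_, n_perm = 10000L, seed = 1L,
                             family_correct = FALSE) {
  if (is.null(categories)) {
    categories <- intersect(ISLAND_RELATIONS, unique(assignment$island_relation))
  }
  fish <- do.call(rbind, lapply(categories, function(cat) {
    fisher_category(assignment, hits, cat)
  }))
  perm <- permute_enrichment(assignment, hits, categories, n_perm = n_perm,
                             seed = seed, family_correct = family_correct)
  out <- data.frame(
    category = fish$category, cutoff = cutoff,
    n_probes_dataset = fish$n_panel, n_probes_cutoff = fish$n_hits,
    n_probes_region = fish$n_in_category, n_common_probes = fish$n_hits_in_category,
    fisher_p = fish$fisher_p, fisher_p_over = fish$fisher_p_over,
    fisher_p_under = fish$fisher_p_under,
    odds_ratio = fish$odds_ratio,
    perm_p_over = perm$perm_p_over, perm_p_under = perm$perm_p_under,
    n_perm = perm$n_perm)
  if (family_correct) {
    out$perm_p_over_corrected <- perm$perm_p_over_corrected
    out$perm_p_under_corrected <- perm$perm_p_under_corrected
  }
  out
}

#' Split island probes by TSS association and compare 5-hmC levels
#'
#' Partitions island probes into those on TSS-associated islands versus
#' intragenic/other islands, and tests whether the TSS stratum has lower
#' levels with a label-permutation test on the difference of medians
#' (one-sided for "TSS lower"; the symmetric "higher" p-value is also
#' reported).
#'
#' @param assignment output of [assign_categories()].
#' @param levels named numeric vector of per-probe levels (e.g. median
#'   5-hmC), names = probe ids.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with the two probe-id sets, their medians, the observed
#'   difference (TSS minus non-TSS), and `p_lower` / `p_higher`.
#' @export
split_islands_by_tss <- function(assignment, levels, n_perm = 10000L, seed = 1L) {
  n_perm <- assert_count(n_perm, "n_perm")
  seed <- assert_count(seed, "seed", positive = FALSE)
  isl <- assignment[assignment$island_relation == "Island", ]
  tss_ids <- isl$probe_id[isl$tss_island %in% TRUE]
  non_ids <- isl$probe_id[isl$tss_island %in% FALSE]
  tss_ids <- intersect(tss_ids, names(levels))
  non_ids <- intersect(non_ids, names(levels))
  if (!length(tss_ids) || !length(non_ids)) {
    stop_invalid("island probes must be present in both TSS strata")
  }
  x <- levels[tss_ids]; y <- levels[non_ids]
  obs <- stats::median(x) - stats::median(y)
  pool <- c(x, y); nx <- length(x)
  withr::with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(pool), nx)
      stats::median(pool[idx]) - stats::median(pool[-idx])
    }, numeric(1))
  })
  list(tss_island_probes = tss_ids, non_tss_island_probes = non_ids,
       median_tss = stats::median(x), median_non_tss = stats::median(y),
       observed_diff = obs,
       p_lower = mean(perm <= obs),
       p_higher = mean(perm >= obs),
       n_perm = n_perm)
}
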