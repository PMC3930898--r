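# a hand-laid annotation track for boundary arithmetic: one island at
# [5000, 5500) (0-based half-open) plus a second far island, and one + gene
boundary_track <- function() {
  make_annotation_track(
    islands = data.frame(chrom = "chr1",
                         start = c(5000L, 50000L), end = c(5500L, 50500L)),
    genes = data.frame(
      name = "G1", chrom = "chr1", strand = "+", tss = 20000L,
      utr5_start = 20000L, utr5_end = 20100L,
      exon1_start = 20100L, exon1_end = 20300L,
      body_start = 20300L, body_end = 22800L,
      utr3_start = 22800L, utr3_end = 23000L))
}

probe_at <- function(pos) {
  data.frame(probe_id = sprintf("p%d", seq_along(pos)), chromosome = "chr1",
             position = as.integer(pos))
}

test_that("island relation boundaries follow the (0,2000]/(2000,4000] rule", {
  tr <- boundary_track()
  # island occupies 1-based positions 5001..5500
  cases <- rbind(
    c(5001, "Island"),    # first island base
    c(5500, "Island"),    # last island base
    c(5000, "N_Shore"),   # 1 base 5'
    c(3501, "N_Shore"),   # 1500 bases 5'
    c(3001, "N_Shore"),   # exactly 2000 bases 5' (boundary inclusive)
    c(3000, "N_Shelf"),   # 2001 bases 5'
    c(1001, "N_Shelf"),   # exactly 4000 bases 5'
    c(1000, "OpenSea"),   # 4001 bases 5'
    c(5501, "S_Shore"),   # 1 base 3'
    c(7500, "S_Shore"),   # 2000 bases 3'
    c(8500, "S_Shelf"),   # 3000 bases 3'
    c(9500, "S_Shelf"),   # 4000 bases 3'
    c(9501, "OpenSea"))   # 4001 bases 3'
  ann <- assign_categories(probe_at(as.integer(cases[, 1])), tr)
  expect_equal(ann$island_relation, cases[, 2])
})

test_that("every probe gets exactly one island relation (partition)", {
  g <- fixture_genome(seed = 17)
  man <- fixture_manifest(g, n_probes = 250, seed = 5)
  ann <- assign_categories(man, g$track)
  expect_true(all(ann$island_relation %in%
                    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")))
  expect_equal(sum(table(ann$island_relation)), 250)
  expect_error(assign_categories(
    data.frame(probe_id = "x", chromosome = "chrZ", position = 5L), g$track),
    "absent")
})

test_that("equidistant probes resolve ties to the 5' island", {
  tr <- make_annotation_track(
    islands = data.frame(chrom = "chr1", start = c(1000L, 3000L),
                         end = c(1500L, 3500L)))
  # islands at 1-based 1001..1500 and 3001..3500; midpoint 2250 is 750 from
  # both -> N-side shore would mean the 3' island, S-side the 5' island;
  # the tie goes to the 5' island, so the probe is on its S (3') shore
  ann <- assign_categories(probe_at(2250), tr)
  expect_equal(ann$island_relation, "S_Shore")
})

test_that("gene-structure windows are strand-aware and allow multi-membership", {
  tr <- boundary_track()
  # + strand gene, TSS at 0-based 20000 = 1-based 20001
  ann <- assign_categories(
    probe_at(c(20001, 20000, 19801, 19800, 18501, 18500, 20101, 20301, 22801, 23000)),
    tr)
  expect_equal(ann$gene_groups,
               c("5UTR", "TSS200", "TSS200", "TSS1500", "TSS1500", "",
                 "1stExon", "Body", "3UTR", "3UTR"))
  # - strand gene: promoter windows flip downstream of the 3' coordinate
  tr2 <- make_annotation_track(
    islands = data.frame(chrom = "chr1", start = 90000L, end = 90100L),
    genes = data.frame(
      name = "G2", chrom = "chr1", strand = "-", tss = 22999L,
      utr5_start = 22900L, utr5_end = 23000L,
      exon1_start = 22700L, exon1_end = 22900L,
      body_start = 20200L, body_end = 22700L,
      utr3_start = 20000L, utr3_end = 20200L))
  ann2 <- assign_categories(probe_at(c(23000, 23001, 23200, 23201, 24500, 24501)), tr2)
  expect_equal(ann2$gene_groups,
               c("5UTR", "TSS200", "TSS200", "TSS1500", "TSS1500", ""))
  # overlapping genes: a probe may be TSS200 of one gene and Body of another
  tr3 <- make_annotation_track(
    islands = data.frame(chrom = "chr1", start = 90000L, end = 90100L),
    genes = rbind(boundary_track()$genes,
                  within(boundary_track()$genes, {
                    name <- "G3"; tss <- 18000L
                    utr5_start <- 18000L; utr5_end <- 18100L
                    exon1_start <- 18100L; exon1_end <- 18300L
                    body_start <- 18300L; body_end <- 20800L
                    utr3_start <- 20800L; utr3_end <- 21000L
                  })))
  ann3 <- assign_categories(probe_at(19900), tr3)
  expect_equal(sort(strsplit(ann3$gene_names, ";")[[1]]), c("G1", "G3"))
  expect_setequal(strsplit(ann3$gene_groups, ";")[[1]], c("TSS200", "Body"))
})

test_that("islands are flagged TSS-associated within 1500 bases of a TSS", {
  tr <- make_annotation_track(
    islands = data.frame(chrom = "chr1",
                         start = c(5000L, 50000L), end = c(5500L, 50500L)),
    genes = data.frame(
      name = "G1", chrom = "chr1", strand = "+", tss = 6999L,
      utr5_start = 6999L, utr5_end = 7099L,
      exon1_start = 7099L, exon1_end = 7299L,
      body_start = 7299L, body_end = 9799L,
      utr3_start = 9799L, utr3_end = 9999L))
  # TSS 6999 is 1500 from the last island base 5499 -> associated;
  # the far island is not
  ann <- assign_categories(probe_at(c(5100, 50100)), tr)
  expect_equal(ann$island_relation, c("Island", "Island"))
  expect_equal(ann$tss_island, c(TRUE, FALSE))
})

test_that("Fisher p-values agree with exhaustive enumeration to 1e-10", {
  # the worked table: hits-in 8, hits-out 2, nonhits-in 12, nonhits-out 78
  panel <- data.frame(
    probe_id = sprintf("p%03d", 1:100),
    chromosome = "chr1", position = 1:100,
    island_relation = rep(c("Island", "OpenSea"), c(20, 80)),
    gene_names = "", gene_groups = "", tss_island = NA)
  panel$island_relation[1:20] <- "Island"
  hits <- c(panel$probe_id[1:8], panel$probe_id[21:22])
  res <- fisher_category(panel, hits, "Island")
  expect_equal(res$n_hits_in_category, 8)
  expect_equal(res$fisher_p, oracle_fisher_two_sided(8, 2, 12, 78),
               tolerance = 1e-10)
  expect_equal(res$fisher_p, fisher.test(matrix(c(8, 12, 2, 78), 2))$p.value,
               tolerance = 1e-12)
  # random tables with margins <= 200 against the enumeration oracle
  withr::with_seed(23, {
    for (i in 1:50) {
      n_in <- sample(5:100, 1); n_out <- sample(5:100, 1)
      k <- sample(2:(n_in + n_out - 1), 1)
      a <- max(0, k - n_out):min(k, n_in)
      a <- sample(rep(a, 2), 1)
      pan <- data.frame(
        probe_id = sprintf("q%04d", seq_len(n_in + n_out)),
        chromosome = "chr1", position = seq_len(n_in + n_out),
        island_relation = rep(c("Island", "OpenSea"), c(n_in, n_out)),
        gene_names = "", gene_groups = "", tss_island = NA)
      hit_ids <- c(pan$probe_id[seq_len(a)],
                   pan$probe_id[n_in + seq_len(k - a)])
      got <- fisher_category(pan, hit_ids, "Island")
      expect_equal(got$fisher_p,
                   oracle_fisher_two_sided(a, k - a, n_in - a, n_out - (k - a)),
                   tolerance = 1e-10)
    }
  })
})

test_that("degenerate Fisher tables are handled explicitly", {
  panel <- data.frame(
    probe_id = sprintf("p%03d", 1:50),
    chromosome = "chr1", position = 1:50,
    island_relation = rep(c("Island", "OpenSea"), c(10, 40)),
    gene_names = "", gene_groups = "", tss_island = NA)
  # empty hit set -> p = 1
  res0 <- fisher_category(panel, character(0), "Island")
  expect_equal(res0$fisher_p, 1)
  # category = entire panel -> over p = 1, odds ratio undefined (flagged NA)
  panel2 <- panel; panel2$island_relation <- "Island"
  res1 <- fisher_category(panel2, panel2$probe_id[1:5], "Island")
  expect_equal(res1$fisher_p_over, 1)
  expect_true(is.na(res1$odds_ratio))
  # zero cell -> continuity-corrected odds ratio, flagged
  res2 <- fisher_category(panel, panel$probe_id[11:15], "Island")
  expect_true(res2$or_continuity)
  expect_equal(res2$odds_ratio, (0.5 * 35.5) / (5.5 * 10.5))
})

test_that("null permutation p-values are calibrated per category", {
  g <- fixture_genome(seed = 19)
  man <- fixture_manifest(g, n_probes = 300, seed = 6)
  ann <- assign_categories(man, g$track)
  # hits drawn uniformly from the panel: p approximately uniform over repeats
  ps <- vapply(1:60, function(seed) {
    withr::with_seed(seed + 500, hits <- sample(ann$probe_id, 60))
    permute_enrichment(ann, hits, categories = "Island", n_perm = 200,
                       seed = seed)$perm_p_over
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(60) + 1 / 200)
})

test_that("planted over-representation is detected with small permutation p", {
  # category occupying 10% of a 4000-probe panel; hits 2x over-represented
  n <- 4000
  panel <- data.frame(
    probe_id = sprintf("p%05d", 1:n),
    chromosome = "chr1", position = 1:n,
    island_relation = rep(c("Island", "OpenSea"), c(n / 10, n - n / 10)),
    gene_names = "", gene_groups = "", tss_island = NA)
  withr::with_seed(29, {
    in_ids <- sample(panel$probe_id[1:(n / 10)], 80)       # 20% of 400 hits
    out_ids <- sample(panel$probe_id[-(1:(n / 10))], 320)
  })
  res <- permute_enrichment(panel, c(in_ids, out_ids),
                            categories = c("Island", "OpenSea"),
                            n_perm = 2000, seed = 31)
  expect_lt(res$perm_p_over[res$category == "Island"], 0.01)
  expect_gt(res$perm_p_under[res$category == "Island"], 0.99)
})

test_that("family-corrected permutation p dominates the uncorrected p", {
  g <- fixture_genome(seed = 37)
  man <- fixture_manifest(g, n_probes = 300, seed = 8)
  ann <- assign_categories(man, g$track)
  withr::with_seed(41, hits <- sample(ann$probe_id, 70))
  res <- permute_enrichment(ann, hits, categories = unique(ann$chromosome),
                            n_perm = 400, seed = 43, family_correct = TRUE)
  expect_true(all(res$perm_p_over_corrected >= res$perm_p_over))
  expect_true(all(res$perm_p_under_corrected >= res$perm_p_under))
  # p-values live on the k/n_perm grid
  expect_true(all(abs(res$perm_p_over * 400 - round(res$perm_p_over * 400)) < 1e-9))
})

test_that("permutation machinery is seed-deterministic", {
  g <- fixture_genome(seed = 47)
  man <- fixture_manifest(g, n_probes = 150, seed = 9)
  ann <- assign_categories(man, g$track)
  withr::with_seed(49, hits <- sample(ann$probe_id, 40))
  r1 <- permute_enrichment(ann, hits, n_perm = 300, seed = 7)
  r2 <- permute_enrichment(ann, hits, n_perm = 300, seed = 7)
  expect_identical(r1, r2)
  expect_error(permute_enrichment(ann, ann$probe_id[1:10], n_perm = 50, seed = 1),
               "at least 100")
  expect_error(permute_enrichment(ann, c(ann$probe_id, "zz"), n_perm = 100,
                                  seed = 1),
               "outside the panel")
})

test_that("permutation and Fisher one-sided p-values rank categories alike", {
  g <- fixture_genome(seed = 53)
  man <- fixture_manifest(g, n_probes = 400, seed = 10)
  ann <- assign_categories(man, g$track)
  rhos <- vapply(1:12, function(seed) {
    withr::with_seed(seed + 900, hits <- sample(ann$probe_id, 80))
    et <- enrichment_table(ann, hits, n_perm = 400, seed = seed)
    # add-one smoothing for rank stability at the p = 0 grid edge
    cor(rank(et$fisher_p_over), rank(et$perm_p_over + 1e-9), method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.95)
})

test_that("TSS-island stratification detects planted level differences", {
  g <- fixture_genome(seed = 59, lengths = c(40000, 40000), gene_density = 0.5)
  man <- generate_manifest(g$genome, g$track, n_probes = 400, seed = 11)
  ann <- assign_categories(man, g$track)
  isl <- ann[ann$island_relation == "Island", ]
  has_both <- sum(isl$tss_island %in% TRUE) >= 5 && sum(isl$tss_island %in% FALSE) >= 5
  expect_true(has_both)
  withr::with_seed(61, {
    levels <- setNames(runif(nrow(ann), 0.3, 0.5), ann$probe_id)
    # plant lower levels on TSS islands
    tss_ids <- isl$probe_id[isl$tss_island %in% TRUE]
    levels[tss_ids] <- runif(length(tss_ids), 0.05, 0.2)
  })
  sp <- split_islands_by_tss(ann, levels, n_perm = 1000, seed = 2)
  expect_lt(sp$p_lower, 0.005)
  # antisymmetry: swapping the strata labels swaps the one-sided p-values
  ann_sw <- ann
  ann_sw$tss_island <- !ann$tss_island
  sp_sw <- split_islands_by_tss(ann_sw, levels, n_perm = 1000, seed = 2)
  expect_equal(sp_sw$observed_diff, -sp$observed_diff)
  # under the null the test is calibrated (no small p for identical strata)
  withr::with_seed(67, flat <- setNames(runif(nrow(ann), 0.2, 0.4), ann$probe_id))
  sp0 <- vapply(1:20, function(s) {
    split_islands_by_tss(ann, flat, n_perm = 200, seed = s)$p_lower
  }, numeric(1))
  expect_gt(mean(sp0 > 0.05), 0.7)
})
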