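hmc_fixture <- function(total, hmc, mask_bs = NULL, mask_tab = NULL) {
  n <- nrow(total)
  rownames(total) <- rownames(hmc) <- sprintf("p%04d", seq_len(n))
  colnames(total) <- paste0("s", seq_len(ncol(total)), "_BS")
  colnames(hmc) <- paste0("s", seq_len(ncol(hmc)), "_TAB")
  bs <- fixture_betas(total, mask = mask_bs)
  tab <- fixture_betas(hmc, mask = mask_tab)
  pairing <- data.frame(sample = paste0("s", seq_len(ncol(total))),
                        bs_sample = colnames(total),
                        tab_sample = colnames(hmc))
  pair_aliquots(bs, tab, pairing)
}

test_that("aliquot pairing derives mc_only by clamped subtraction", {
  withr::with_seed(1, total <- matrix(runif(60, 0.1, 0.9), 20, 3))
  # TAB identically zero: hmc all zero, mc_only equals total
  prof <- hmc_fixture(total, total * 0)
  expect_true(all(prof$hmc == 0))
  expect_equal(prof$mc_only, prof$total)
  expect_equal(prof$n_clamped, 0)

  # inverted locus: clamped at zero and counted
  total2 <- matrix(0.25, 1, 3); hmc2 <- matrix(0.30, 1, 3)
  prof2 <- hmc_fixture(total2, hmc2)
  expect_equal(unname(prof2$mc_only[1, ]), c(0, 0, 0))
  expect_equal(prof2$n_clamped, 3)

  # conservation where no clamping occurred
  withr::with_seed(2, {
    t3 <- matrix(runif(60, 0.3, 0.9), 20, 3)
    h3 <- t3 * matrix(runif(60, 0, 0.9), 20, 3)
  })
  prof3 <- hmc_fixture(t3, h3)
  expect_equal(prof3$mc_only + prof3$hmc, prof3$total, tolerance = 1e-12)
  expect_equal(prof3$n_clamped, 0)
})

test_that("pairing masks entries undetected in either aliquot", {
  total <- matrix(0.5, 4, 2); hmc <- matrix(0.2, 4, 2)
  mask_bs <- matrix(TRUE, 4, 2); mask_tab <- matrix(TRUE, 4, 2)
  mask_bs[1, 1] <- FALSE
  mask_tab[2, 2] <- FALSE
  prof <- hmc_fixture(total, hmc, mask_bs, mask_tab)
  expect_false(prof$mask[1, 1])
  expect_false(prof$mask[2, 2])
  expect_equal(sum(!prof$mask), 2)
  # medians computed over detected entries only
  expect_equal(unname(prof$median_hmc), rep(0.2, 4))
})

test_that("pairing errors on unmatched samples", {
  b <- matrix(0.5, 3, 2, dimnames = list(paste0("p", 1:3), c("a_BS", "b_BS")))
  h <- matrix(0.2, 3, 2, dimnames = list(paste0("p", 1:3), c("a_TAB", "b_TAB")))
  bs <- fixture_betas(b); tab <- fixture_betas(h)
  pairing <- data.frame(sample = c("a", "b"),
                        bs_sample = c("a_BS", "missing_BS"),
                        tab_sample = c("a_TAB", "b_TAB"))
  expect_error(pair_aliquots(bs, tab, pairing), "missing_BS")
})

test_that("constructed medians are reported exactly", {
  # per-probe medians 0.53 (total) and 0.21 (hmc) by construction
  total <- matrix(rep(c(0.40, 0.53, 0.70), each = 10), 10, 3)
  hmc <- matrix(rep(c(0.10, 0.21, 0.35), each = 10), 10, 3)
  prof <- hmc_fixture(total, hmc)
  expect_equal(unname(prof$median_total), rep(0.53, 10))
  expect_equal(unname(prof$median_hmc), rep(0.21, 10))
})

test_that("cutoff classification is strict and monotone", {
  med <- c(rep(0.5, 6), rep(0.2, 3), rep(0.05, 11))
  total <- matrix(rep(pmin(med + 0.2, 0.9), 3), 20, 3)
  hmc <- matrix(rep(med, 3), 20, 3)
  prof <- hmc_fixture(total, hmc)
  expect_equal(classify_by_cutoff(prof, 0.2)$count, 6)  # 0.2 itself excluded
  expect_equal(classify_by_cutoff(prof, 0.199)$count, 9)
  expect_equal(classify_by_cutoff(prof, 0.4)$fraction, 6 / 20)
  # monotone: raising the cutoff never increases the count
  counts <- vapply(c(0.1, 0.2, 0.4, 0.6),
                   function(ct) classify_by_cutoff(prof, ct)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # all medians 0.5 above 0.2 -> fraction 1
  prof2 <- hmc_fixture(matrix(0.7, 5, 3), matrix(0.5, 5, 3))
  expect_equal(classify_by_cutoff(prof2, 0.2)$fraction, 1)
  expect_error(classify_by_cutoff(prof, 1.2), "\\(0,1\\)")
})

test_that("species overlap counts match set arithmetic and chance", {
  withr::with_seed(5, {
    n <- 400
    medA <- ifelse(seq_len(n) <= 200, 0.5, 0.05)
    medB <- ifelse(seq_len(n) %in% 101:300, 0.5, 0.05)
  })
  mk <- function(med) hmc_fixture(matrix(rep(pmin(med + 0.3, 0.9), 3), n, 3),
                                  matrix(rep(med, 3), n, 3))
  profs <- list(A = mk(medA), B = mk(medB))
  ov <- species_overlap(profs, cutoff = 0.2)
  expect_equal(unname(ov$above_counts), c(200, 200))
  expect_equal(ov$pairwise$overlap, 100)
  expect_equal(ov$n_common_all, 100)
  # identical profiles: overlap equals the marginal count
  ov2 <- species_overlap(list(A = profs$A, A2 = profs$A), cutoff = 0.2)
  expect_equal(ov2$pairwise$overlap, 200)
  expect_lt(ov2$pairwise$hyper_p, 1e-10)
  # disjoint planted sets: overlap 0 and no enrichment signal
  medC <- ifelse(seq_len(n) <= 200, 0.05, 0.5)
  ov3 <- species_overlap(list(A = profs$A, C = mk(medC)), cutoff = 0.2)
  expect_equal(ov3$pairwise$overlap, 0)
  expect_gt(ov3$pairwise$hyper_p, 0.999)
})

test_that("random above-cutoff sets overlap at the hypergeometric mean", {
  n <- 300; a <- 60; b <- 90
  ovs <- vapply(1:300, function(seed) {
    withr::with_seed(seed, {
      ia <- sample.int(n, a); ib <- sample.int(n, b)
    })
    length(intersect(ia, ib))
  }, numeric(1))
  expect_lt(abs(mean(ovs) - a * b / n), 3 * sd(ovs) / sqrt(length(ovs)))
})

test_that("density summaries put the mass where the values are", {
  prof <- hmc_fixture(matrix(0.8, 30, 3), matrix(0.5, 30, 3))
  ds <- density_summary(prof, stratify = "none", measure = "hmc")
  hot <- ds$density[ds$density$count > 0, ]
  expect_equal(nrow(hot), 1)
  expect_true(hot$bin_mid > 0.49 && hot$bin_mid < 0.52)
  expect_equal(ds$strata$median, 0.5)
  expect_equal(sum(ds$density$count), 30)
  # density integrates to 1 (bin width 0.01)
  expect_equal(sum(ds$density$density) * 0.01, 1)
})

test_that("uniform levels give a flat density profile", {
  withr::with_seed(8, med <- runif(2000, 0.001, 0.999))
  prof <- hmc_fixture(matrix(rep(0.999 * pmax(med, 0.5), 3), 2000, 3),
                      matrix(rep(med, 3), 2000, 3))
  ds <- density_summary(prof, stratify = "none", measure = "hmc")
  cnt <- ds$density$count
  chi <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_lt(chi, qchisq(0.99, df = 99))
})

test_that("island-stratified densities partition the probe panel", {
  g <- fixture_genome(seed = 3)
  man <- fixture_manifest(g, n_probes = 150, seed = 4)
  ann <- assign_categories(man, g$track)
  withr::with_seed(9, med <- runif(150, 0.01, 0.95))
  total <- matrix(rep(pmin(med + 0.04, 0.99), 3), 150, 3)
  hmc <- matrix(rep(med, 3), 150, 3)
  rownames(total) <- rownames(hmc) <- man$probe_id
  colnames(total) <- paste0("s", 1:3, "_BS"); colnames(hmc) <- paste0("s", 1:3, "_TAB")
  prof <- pair_aliquots(fixture_betas(total), fixture_betas(hmc),
                        data.frame(sample = paste0("s", 1:3),
                                   bs_sample = colnames(total),
                                   tab_sample = colnames(hmc)))
  ds <- density_summary(prof, annotation = ann, stratify = "island")
  expect_equal(sum(ds$strata$n), 150)
  expect_true(all(ds$strata$stratum %in%
                    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")))
})

test_that("recovered species hierarchy matches planted above-cutoff fractions", {
  # planted fractions 0.53 / 0.42 / 0.17 recovered in order
  fracs <- c(human = 0.53, rhesus = 0.42, mouse = 0.17)
  ok <- vapply(1:20, function(seed) {
    profs <- lapply(seq_along(fracs), function(i) {
      g <- fixture_genome(seed = 3)
      man <- fixture_manifest(g, n_probes = 300, seed = 4)
      truth <- generate_truth(man, groups = "brain", hmc_above = fracs[i],
                              seed = seed * 10 + i)
      des <- make_design(groups = "brain", n_per_group = 3,
                         chips = paste0("chip", 1:3))
      sim <- simulate_signals(man, des, truth, intensity_noise_sd = 60,
                              seed = seed * 100 + i)
      pairing <- data.frame(sample = des$sample_id,
                            bs_sample = paste0(des$sample_id, "_BS"),
                            tab_sample = paste0(des$sample_id, "_TAB"))
      pair_aliquots(compute_beta(sim$bs), compute_beta(sim$tab), pairing,
                    species_label = names(fracs)[i])
    })
    got <- vapply(profs, function(p) classify_by_cutoff(p, 0.2)$fraction,
                  numeric(1))
    all(order(got, decreasing = TRUE) == c(1, 2, 3))
  }, logical(1))
  expect_true(all(ok))
})
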