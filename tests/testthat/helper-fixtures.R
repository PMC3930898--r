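# Shared fixture builders. Everything is generated in code at test time.

fixture_genome <- function(seed = 7, lengths = c(20000, 15000),
                           island_density = 0.1, gene_density = 0.3) {
  generate_genome(length(lengths), lengths, island_density = island_density,
                  gene_density = gene_density, seed = seed)
}

fixture_manifest <- function(g = fixture_genome(), n_probes = 200, seed = 3) {
  generate_manifest(g$genome, g$track, n_probes = n_probes, seed = seed)
}

# a random ACGT genome with no planted structure
random_genome <- function(len, seed, name = "chr1") {
  withr::with_seed(seed, {
    chroms <- stats::setNames(
      vapply(seq_along(len), function(i) {
        paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
      }, character(1)),
      paste0(name, seq_along(len)))
  })
  chroms
}

# random 50-mer probes (ACGT)
random_probes <- function(n, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# minimal beta_matrix from a plain matrix
fixture_betas <- function(beta, groups = NULL, chips = NULL, mask = NULL) {
  samples <- data.frame(
    sample_id = colnames(beta),
    chip = chips %||% rep("chip1", ncol(beta)),
    group = groups %||% rep("g", ncol(beta)),
    aliquot = "BS")
  beta_matrix(beta, mask, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a ready-to-analyze simulated two-group study (BS aliquot only)
fixture_study <- function(n_probes = 200, n_per_group = 5, prop_dml = 0,
                          delta_beta = 0.2, batch_sd = 0, noise_sd = 50,
                          seed = 1) {
  g <- fixture_genome(seed = seed)
  man <- generate_manifest(g$genome, g$track, n_probes = n_probes,
                           seed = seed + 1)
  truth <- generate_truth(man, prop_dml = prop_dml, delta_beta = delta_beta,
                          batch_sd = batch_sd, seed = seed + 2)
  des <- make_design(n_per_group = n_per_group)
  sim <- simulate_signals(man, des, truth, intensity_noise_sd = noise_sd,
                          seed = seed + 3)
  des_bs <- des
  des_bs$sample_id <- paste0(des$sample_id, "_BS")
  list(genome = g, manifest = man, truth = truth, design = des,
       design_bs = des_bs, sim = sim,
       betas = compute_beta(sim$bs))
}
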