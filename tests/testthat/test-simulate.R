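small_cfg <- function(...) {
  sim_config(n_proteins = 300,
             genotypes = c("Control", "KO_A", "KO_B"),
             cell_types = c("iN", "iDA"), n_replicates = 3,
             annotations = data.frame(label = c("mito", "lyso"),
                                      size = c(80, 60), parent = NA),
             seed = 42, ...)
}

test_that("identical configuration reproduces byte-identical data", {
  cfg <- small_cfg(noise_sd = 0.3, missing_rate = 0.1)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$abundance$values, b$abundance$values)
  expect_identical(a$catalog$sets, b$catalog$sets)
  expect_identical(a$truth$shifts, b$truth$shifts)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_abundance(a$abundance, f1)
  write_abundance(b$abundance, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); simulate_landscape(cfg); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless null model yields exactly zero fold changes", {
  cfg <- small_cfg(noise_sd = 0, missing_rate = 0)
  sim <- simulate_landscape(cfg)
  fc <- compute_all_contrasts(sim$abundance, sim$design)
  expect_lt(max(abs(fc$log2fc)), 1e-12)
})

test_that("noiseless planted effect is recovered exactly and only where planted", {
  cfg <- small_cfg(noise_sd = 0, missing_rate = 0,
                   effects = data.frame(genotype = "KO_A", cell_type = "iDA",
                                        annotation = "mito", delta = -1))
  sim <- simulate_landscape(cfg)
  fc <- compute_all_contrasts(sim$abundance, sim$design)
  mito <- sim$catalog$sets$mito
  hit <- fc$genotype == "KO_A" & fc$cell_type == "iDA" &
    fc$protein_id %in% mito
  expect_lt(max(abs(fc$log2fc[hit] + 1)), 1e-12)
  expect_lt(max(abs(fc$log2fc[!hit])), 1e-12)
})

test_that("planted truth composes additively over overlapping annotations", {
  cfg <- sim_config(n_proteins = 100, genotypes = c("Control", "KO"),
                    cell_types = "iN",
                    annotations = data.frame(label = c("outer", "inner"),
                                             size = c(50, 20),
                                             parent = c(NA, "outer")),
                    effects = data.frame(genotype = "KO", cell_type = "iN",
                                         annotation = c("outer", "inner"),
                                         delta = c(1, 0.5)),
                    noise_sd = 0, missing_rate = 0, seed = 5)
  sim <- simulate_landscape(cfg)
  inner <- sim$catalog$sets$inner
  outer_only <- setdiff(sim$catalog$sets$outer, inner)
  shifts <- sim$truth$shifts[, condition_id("KO", "iN")]
  expect_equal(unname(shifts[inner]), rep(1.5, length(inner)))
  expect_equal(unname(shifts[outer_only]), rep(1, length(outer_only)))
})

test_that("contradictory effects and oversized annotations are rejected", {
  expect_error(small_cfg(effects = data.frame(
    genotype = "KO_A", cell_type = "iN", annotation = c("mito", "mito"),
    delta = c(1, 2))), "contradictory")
  expect_error(sim_config(n_proteins = 10, annotations = data.frame(
    label = "big", size = 50, parent = NA)), "size")
  expect_error(small_cfg(effects = data.frame(
    genotype = "Control", cell_type = "iN", annotation = "mito", delta = 1)),
    "control")
})

test_that("realized missingness tracks the configured rate", {
  cfg <- sim_config(n_proteins = 5000, genotypes = c("Control", "KO"),
                    cell_types = "iN", missing_rate = 0.1, seed = 8)
  sim <- simulate_landscape(cfg)
  expect_lt(abs(mean(is.na(sim$abundance$values)) - 0.1), 0.02)
})

test_that("LysoIP simulation plants enrichment and KO shifts exactly at zero noise", {
  cfg <- sim_config(n_proteins = 200, genotypes = c("Control", "ASAH1_KO"),
                    cell_types = "HeLa",
                    annotations = data.frame(label = c("lysosome", "ER"),
                                             size = c(50, 60), parent = NA),
                    noise_sd = 0, missing_rate = 0, disjoint = TRUE, seed = 3)
  sim <- simulate_lysoip(cfg, lyso_enrichment = 3,
                         ko_organelle_shifts = data.frame(annotation = "ER",
                                                          delta = 1))
  e_ctl <- enrichment_vs_untagged(sim$abundance, sim$design, "Control")
  e_ko <- enrichment_vs_untagged(sim$abundance, sim$design, "ASAH1_KO")
  lyso <- sim$catalog$sets$lysosome
  er <- sim$catalog$sets$ER
  expect_lt(max(abs(e_ctl$log2fc[e_ctl$protein_id %in% lyso] - 3)), 1e-12)
  expect_lt(max(abs(e_ctl$log2fc[!e_ctl$protein_id %in% lyso])), 1e-12)
  ko_er <- e_ko$log2fc[e_ko$protein_id %in% er]
  ctl_er <- e_ctl$log2fc[e_ctl$protein_id %in% er]
  expect_equal(mean(ko_er) - mean(ctl_er), 1, tolerance = 1e-12)
  expect_identical(simulate_lysoip(cfg, 3)$abundance$values,
                   simulate_lysoip(cfg, 3)$abundance$values)
  cfg_nolyso <- sim_config(n_proteins = 50, genotypes = c("Control", "KO"),
                           annotations = data.frame(label = "ER", size = 10,
                                                    parent = NA))
  expect_error(simulate_lysoip(cfg_nolyso, 3), "lysosome")
})

test_that("spatial simulation feeds the ratio-of-ratios exactly at zero noise", {
  cfg <- sim_config(n_proteins = 200, genotypes = c("Control", "KO"),
                    cell_types = "iN",
                    annotations = data.frame(
                      label = c("mito", "synapse"), size = c(60, 50),
                      parent = NA),
                    noise_sd = 0, missing_rate = 0, disjoint = TRUE, seed = 6)
  sim <- simulate_spatial(
    cfg,
    compartment_profiles = data.frame(annotation = "synapse", soma_delta = 0,
                                      projection_delta = 2),
    ko_projection_shifts = data.frame(annotation = "mito", delta = -0.75))
  r_ko <- fraction_log_ratio(sim$abundance, sim$design, "KO")
  r_ctl <- fraction_log_ratio(sim$abundance, sim$design, "Control")
  ror <- ratio_of_ratios(r_ko, r_ctl)
  mito <- sim$catalog$sets$mito
  syn <- sim$catalog$sets$synapse
  expect_lt(max(abs(ror$log2_ror[ror$protein_id %in% mito] + 0.75)), 1e-12)
  # genotype-shared projection enrichment cancels in the RoR
  expect_lt(max(abs(ror$log2_ror[ror$protein_id %in% syn])), 1e-12)
  expect_lt(max(abs(r_ko$ratio_log2[syn] - 2)), 1e-12)
  expect_lt(max(abs(r_ctl$ratio_log2[syn] - 2)), 1e-12)

  null_sim <- simulate_spatial(cfg)
  nr <- ratio_of_ratios(
    fraction_log_ratio(null_sim$abundance, null_sim$design, "KO"),
    fraction_log_ratio(null_sim$abundance, null_sim$design, "Control"))
  expect_lt(max(abs(nr$log2_ror)), 1e-12)
  expect_error(simulate_spatial(cfg, compartment_profiles = data.frame(
    annotation = "nope", soma_delta = 1, projection_delta = 1)), "nope")
})
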