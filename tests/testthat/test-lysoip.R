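enrich_table <- function(ids, log2fc) {
  data.frame(protein_id = ids, genotype = "KO", cell_type = "HeLa",
             fraction = "lysoip", log2fc = log2fc, p = NA_real_,
             q = NA_real_, n_test = 3L, n_ref = 3L, stringsAsFactors = FALSE)
}

test_that("co-enrichment threshold is the mean lysosomal enrichment, boundary inclusive", {
  e <- enrich_table(c("L1", "L2", "A", "B"), c(2, 4, 3.5, 2.5))
  cat <- annotation_catalog(list(lysosome = c("L1", "L2"),
                                 other = c("A", "B")))
  co <- coenrichment_flags(e, cat)
  expect_equal(co$threshold, 3)
  flags <- setNames(co$proteins$co_enriched, co$proteins$protein_id)
  expect_true(flags[["A"]])     # 3.5 >= 3
  expect_false(flags[["B"]])    # 2.5 < 3
  expect_true(flags[["L2"]])
  expect_equal(co$counts$n_co_enriched[co$counts$annotation == "other"], 1L)

  # all lysosomal proteins equal -> threshold equals that value, all flagged
  e2 <- enrich_table(c("L1", "L2", "A"), c(2, 2, 1))
  co2 <- coenrichment_flags(e2, cat)
  expect_equal(co2$threshold, 2)
  expect_true(all(co2$proteins$co_enriched[co2$proteins$protein_id %in%
                                             c("L1", "L2")]))
  expect_error(coenrichment_flags(enrich_table("A", 1), cat), "lysosome")
})

test_that("co-enrichment flags equal exhaustive recomputation on a large instance", {
  set.seed(91)
  ids <- sprintf("P%04d", 1:1000)
  vals <- rnorm(1000, 1, 2)
  lyso <- sample(ids, 120)
  cat <- annotation_catalog(list(lysosome = lyso,
                                 ER = sample(ids, 200),
                                 mito = sample(ids, 150)))
  e <- enrich_table(ids, vals)
  co <- coenrichment_flags(e, cat)
  thr <- mean(vals[ids %in% lyso])
  expect_equal(co$threshold, thr, tolerance = 1e-15)
  expect_equal(co$proteins$co_enriched, vals >= thr)
  for (ann in names(cat$sets)) {
    expect_equal(co$counts$n_co_enriched[co$counts$annotation == ann],
                 sum(ids %in% cat$sets[[ann]] & vals >= thr))
  }
  # threshold recomputable from the output's own table
  own <- co$proteins
  expect_equal(mean(own$log2fc[own$protein_id %in% lyso]), co$threshold,
               tolerance = 1e-12)
})

test_that("co-enriched counts are monotone in any protein's enrichment", {
  e <- enrich_table(c("L1", "L2", "A", "B"), c(2, 4, 2.9, 2.5))
  cat <- annotation_catalog(list(lysosome = c("L1", "L2"),
                                 other = c("A", "B")))
  before <- coenrichment_flags(e, cat)$counts
  e$log2fc[e$protein_id == "A"] <- 3.2  # raise a non-lysosomal protein
  after <- coenrichment_flags(e, cat)$counts
  expect_true(all(after$n_co_enriched >= before$n_co_enriched))
})

test_that("rank-sum test is exact by enumeration for small samples", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p, 0.1)
  expect_equal(rs$statistic, 0)
  expect_true(rs$exact)

  tied <- rank_sum_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tied$p, 1)

  set.seed(71)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2), 1)
    expect_equal(rank_sum_test(x, y)$p, oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
    if (!anyDuplicated(c(x, y))) {
      ref <- wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(rank_sum_test(x, y)$p, ref, tolerance = 1e-12)
    }
  }
})

test_that("large-sample rank-sum approximation tracks wilcox.test", {
  set.seed(72)
  x <- rnorm(20, 0.5); y <- rnorm(25)
  ours <- rank_sum_test(x, y)$p
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_false(rank_sum_test(x, y)$exact)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("organelle shift test flags the planted compartment", {
  cfg <- sim_config(n_proteins = 1200, genotypes = c("Control", "KO"),
                    cell_types = "HeLa",
                    annotations = data.frame(
                      label = c("lysosome", "ER", "mito", "golgi"),
                      size = c(150, 200, 200, 150), parent = NA),
                    noise_sd = 0.25, missing_rate = 0, disjoint = TRUE,
                    seed = 19)
  sim <- simulate_lysoip(cfg, lyso_enrichment = 3,
                         ko_organelle_shifts = data.frame(annotation = "ER",
                                                          delta = 1))
  e_ctl <- enrichment_vs_untagged(sim$abundance, sim$design, "Control")
  e_ko <- enrichment_vs_untagged(sim$abundance, sim$design, "KO")
  sh <- organelle_shift_test(e_ctl, e_ko, sim$catalog)
  expect_lt(sh$q[sh$annotation == "ER"], 0.05)
  expect_gt(sh$delta_mean[sh$annotation == "ER"], 0.8)
  expect_gt(min(sh$q[sh$annotation %in% c("mito", "golgi")]), 0.05)
})

test_that("shifting every KO value upward never weakens the enrichment signal", {
  set.seed(73)
  ids <- sprintf("P%d", 1:30)
  cat <- annotation_catalog(list(lysosome = ids[1:5], s = ids[6:30]))
  base_ko <- rnorm(30)
  e_ctl <- enrich_table(ids, rnorm(30))
  p_at <- function(delta) {
    e_ko <- enrich_table(ids, base_ko + delta)
    sh <- organelle_shift_test(e_ctl, e_ko, cat, min_members = 3)
    sh$p[sh$annotation == "s"]
  }
  # two-sided p once the KO side dominates: growing delta cannot increase it
  ps <- vapply(c(1, 2, 4, 8), p_at, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("per-organelle significance counts delegate and are set-idempotent", {
  fc <- enrich_table(sprintf("P%d", 1:8),
                     c(1.5, -2, 0.2, 3, -0.1, -1.2, 0.6, 2.5))
  fc$q <- c(0.01, 0.002, 0.8, 0.01, 0.9, 0.04, 0.2, 0.03)
  cat <- annotation_catalog(list(A = sprintf("P%d", 1:4),
                                 B = sprintf("P%d", 3:8)))
  res <- per_organelle_significance(fc, cat, q_max = 0.05,
                                    min_abs_log2fc = 0.5)
  # brute force: sig & |fc|>=0.5 -> P1 up, P2 down, P4 up, P6 down, P8 up
  expect_equal(res$up[res$annotation == "A"], 2L)
  expect_equal(res$down[res$annotation == "A"], 1L)
  expect_equal(res$up[res$annotation == "B"], 2L)
  expect_equal(res$down[res$annotation == "B"], 1L)
  expect_equal(per_organelle_significance(fc, cat, 0)$up, c(0L, 0L),
               ignore_attr = TRUE)
  doubled <- annotation_catalog(list(A = c(cat$sets$A, cat$sets$A),
                                     B = cat$sets$B))
  expect_equal(per_organelle_significance(fc, doubled, 0.05, 0.5), res)
})

test_that("analyses without an untagged background are refused", {
  dat <- tiny_dataset(matrix(rnorm(12), 2), c("Control", "KO"), 3)
  expect_error(enrichment_vs_untagged(dat$abundance, dat$design, "KO"),
               "lysoip|untagged")
})
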