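# long fc table over explicit per-condition vectors
fc_from_vectors <- function(vectors, proteins) {
  do.call(rbind, lapply(names(vectors), function(id) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    toy_fc(proteins, vectors[[id]], genotype = parts[1], cell_type = parts[2])
  }))
}

test_that("annotation correlation equals the sum-of-products Pearson oracle", {
  proteins <- sprintf("P%d", 1:4)
  fc <- fc_from_vectors(list("A|iN" = c(1, 2, 3, 4), "B|iN" = c(2, 1, 4, 3)),
                        proteins)
  cat <- annotation_catalog(list(all4 = proteins))
  acm <- annotation_correlation(fc, cat, "all4", min_proteins = 3)
  expect_equal(acm$r["A|iN", "B|iN"], 0.6, tolerance = 1e-12)
  expect_equal(diag(acm$r), c(1, 1), ignore_attr = TRUE)
  expect_true(isSymmetric(acm$r))

  # perfect anticorrelation
  fc2 <- fc_from_vectors(list("A|iN" = c(1, -2, 3, 0.5),
                              "B|iN" = -c(1, -2, 3, 0.5)), proteins)
  acm2 <- annotation_correlation(fc2, cat, "all4", min_proteins = 3)
  expect_equal(acm2$r["A|iN", "B|iN"], -1, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    ids <- sprintf("Q%d", seq_len(n))
    v1 <- rnorm(n); v2 <- rnorm(n)
    v1[sample(n, 1)] <- NA
    fcr <- fc_from_vectors(list("A|iN" = v1, "B|iN" = v2), ids)
    acmr <- annotation_correlation(fcr, annotation_catalog(list(s = ids)),
                                   "s", min_proteins = 2)
    expect_equal(acmr$r["A|iN", "B|iN"], oracle_pearson(v1, v2),
                 tolerance = 1e-12)
  }
})

test_that("cells below min_proteins are missing; small annotations flag empty", {
  proteins <- sprintf("P%d", 1:4)
  fc <- fc_from_vectors(list("A|iN" = c(1, 2, NA, NA), "B|iN" = c(2, 1, 4, 3)),
                        proteins)
  cat <- annotation_catalog(list(all4 = proteins, tiny = proteins[1:2]))
  acm <- annotation_correlation(fc, cat, "all4", min_proteins = 3)
  expect_true(is.na(acm$r["A|iN", "B|iN"]))  # only 2 complete pairs
  expect_equal(acm$n_pairs["A|iN", "B|iN"], 2, ignore_attr = TRUE)
  empty <- annotation_correlation(fc, cat, "tiny", min_proteins = 10)
  expect_true(attr(empty, "empty"))
  expect_true(all(is.na(empty$r)))
})

test_that("organelle correlation is the mean of pairwise peer correlations", {
  set.seed(31)
  proteins <- sprintf("P%d", 1:30)
  vecs <- list("A|iN" = rnorm(30), "B|iN" = rnorm(30), "C|iN" = rnorm(30),
               "D|iDA" = rnorm(30))
  fc <- fc_from_vectors(vecs, proteins)
  cat <- annotation_catalog(list(s = proteins))
  oc <- organelle_correlation(fc, cat, "s", "A", "iN")
  expected <- mean(c(oracle_pearson(vecs[["A|iN"]], vecs[["B|iN"]]),
                     oracle_pearson(vecs[["A|iN"]], vecs[["C|iN"]])))
  expect_equal(oc, expected, tolerance = 1e-12)
  # peers stay within the cell type and exclude the condition itself
  peers <- data.frame(genotype = c("C", "B"), cell_type = "iN")
  oc_rev <- organelle_correlation(fc, cat, "s", "A", "iN", peers = peers)
  expect_equal(oc, oc_rev, tolerance = 1e-12)
  expect_error(organelle_correlation(
    fc, cat, "s", "A", "iN",
    peers = data.frame(genotype = c("A", "B"), cell_type = "iN")), "itself")

  ident <- fc_from_vectors(list("A|iN" = vecs[[1]], "B|iN" = vecs[[1]]),
                           proteins)
  expect_equal(organelle_correlation(ident, cat, "s", "A", "iN"), 1,
               tolerance = 1e-12)
})

test_that("cross-cell-type correlation pairs the same genotype's conditions", {
  set.seed(77)
  proteins <- sprintf("P%d", 1:20)
  v_in <- rnorm(20); v_ida <- v_in + rnorm(20, 0, 0.3)
  fc <- fc_from_vectors(list("G|iN" = v_in, "G|iDA" = v_ida,
                             "H|iN" = rnorm(20)), proteins)
  cat <- annotation_catalog(list(s = proteins))
  expect_equal(cross_celltype_correlation(fc, cat, "s", "G"),
               oracle_pearson(v_in, v_ida), tolerance = 1e-12)
})

test_that("composite map matches entry-by-entry brute force and is order-invariant", {
  set.seed(41)
  proteins <- sprintf("P%d", 1:40)
  vecs <- list("A|iN" = rnorm(40), "B|iN" = rnorm(40), "C|iN" = rnorm(40))
  fc <- fc_from_vectors(vecs, proteins)
  cat <- annotation_catalog(list(s1 = proteins[1:25], s2 = proteins[16:40]))
  cm <- composite_map(fc, cat)
  for (cond in names(vecs)) {
    for (ann in c("s1", "s2")) {
      members <- match(cat$sets[[ann]], proteins)
      peers <- setdiff(names(vecs), cond)
      expected <- mean(vapply(peers, function(p) {
        oracle_pearson(vecs[[cond]][members], vecs[[p]][members])
      }, 0))
      expect_equal(cm$matrix[cond, ann], expected, tolerance = 1e-12)
    }
  }
  expect_true(all(cm$matrix >= -1 & cm$matrix <= 1, na.rm = TRUE))

  # permuting the input rows leaves every entry unchanged
  fc_perm <- fc[sample(nrow(fc)), , drop = FALSE]
  cm2 <- composite_map(fc_perm, cat)
  expect_equal(cm2$matrix[rownames(cm$matrix), colnames(cm$matrix)],
               cm$matrix)

  ident <- fc_from_vectors(list("A|iN" = vecs[[1]], "B|iN" = vecs[[1]]),
                           proteins)
  cmi <- composite_map(ident, annotation_catalog(list(s1 = proteins)))
  expect_equal(unname(cmi$matrix[, 1]), c(1, 1), tolerance = 1e-12)
})

test_that("class summaries recombine to the grand mean", {
  set.seed(51)
  proteins <- sprintf("P%d", 1:30)
  vecs <- setNames(lapply(1:5, function(i) rnorm(30)),
                   paste0(c("A", "B", "C", "D", "E"), "|iN"))
  fc <- fc_from_vectors(vecs, proteins)
  cat <- annotation_catalog(list(s = proteins))
  cm <- composite_map(fc, cat)
  classes <- c(A = "X", B = "X", C = "Y", D = "Y", E = "Z")
  cs <- class_variance(cm, classes)
  # two-member class: sample sd
  x <- cm$matrix[c("C|iN", "D|iN"), "s"]
  row_y <- cs[cs$class == "Y", ]
  expect_equal(row_y$mean, mean(x))
  expect_equal(row_y$sd, sd(x))
  expect_equal(cs$sd[cs$class == "Z"], 0)
  expect_equal(cs$n[cs$class == "Z"], 1L, ignore_attr = TRUE)
  grand <- sum(cs$mean * cs$n) / sum(cs$n)
  expect_equal(grand, mean(cm$matrix[, "s"]), tolerance = 1e-12)
  expect_equal(sum(cs$n), 5L)
  expect_error(class_variance(cm, classes[-1]), "A")
})

test_that("link filtering applies the circos thresholds to the upper triangle", {
  conds <- data.frame(genotype = c("A", "B", "C"), cell_type = "iN")
  conds$id <- condition_id(conds$genotype, conds$cell_type)
  r <- matrix(c(1, -0.3, 0.5,
                -0.3, 1, 0.8,
                0.5, 0.8, 1), 3, 3, dimnames = list(conds$id, conds$id))
  acm <- structure(list(annotation = "mito", conditions = conds, r = r,
                        n_pairs = r * 0 + 50),
                   class = "annotation_correlation")
  links <- filter_links(acm)
  expect_equal(sort(links$r), c(-0.3, 0.8))
  expect_false(any(links$condition_a == links$condition_b))

  origin <- filter_links(acm, origin = "A")
  expect_equal(origin$r, -0.3)

  zero <- acm
  zero$r[] <- 0; diag(zero$r) <- 1
  expect_equal(nrow(filter_links(zero)), 0)
  expect_error(filter_links(acm, neg_max = 0.8, pos_min = 0.7), "below")
})

test_that("impact score ranks the dominant condition first, deterministically", {
  proteins <- sprintf("P%d", 1:40)
  cat <- annotation_catalog(list(a1 = proteins[1:20], a2 = proteins[21:40]),
                            groups = list(g = c("a1", "a2")))
  vec_hit <- c(rep(1, 20), rep(-1, 20))
  vec_null <- rep(0, 40)
  fc <- fc_from_vectors(list("HIT|iN" = vec_hit, "Z1|iN" = vec_null,
                             "Z2|iN" = vec_null), proteins)
  imp <- impact_score(fc, cat, "g", "iN")
  expect_equal(imp$genotype[imp$rank == 1], "HIT")
  expect_equal(sort(imp$rank), 1:3)
  # ties broken by genotype label
  expect_equal(imp$genotype[imp$rank == 2], "Z1")

  # all conditions identical -> all impacts 0, ranks by label
  fc_eq <- fc_from_vectors(list("B|iN" = vec_hit, "A|iN" = vec_hit),
                           proteins)
  imp_eq <- impact_score(fc_eq, cat, "g", "iN")
  expect_equal(imp_eq$impact, c(0, 0))
  expect_equal(imp_eq$genotype, c("A", "B"))

  # depends only on |log2fc|: flipping one condition's signs changes nothing
  fc_flip <- fc_from_vectors(list("HIT|iN" = -vec_hit, "Z1|iN" = vec_null,
                                  "Z2|iN" = vec_null), proteins)
  imp_flip <- impact_score(fc_flip, cat, "g", "iN")
  expect_equal(imp_flip$impact, imp$impact)
  expect_equal(imp_flip$rank, imp$rank)
})

test_that("hierarchical clustering reproduces hand agglomeration", {
  prof2 <- rbind(a = c(1, 2, 3, 5), b = c(2, 1, 4, 3))
  hc2 <- hcluster_correlations(prof2)
  expect_equal(length(hc2$height), 1)
  expect_equal(hc2$height, 1 - oracle_pearson(prof2["a", ], prof2["b", ]),
               tolerance = 1e-12)

  set.seed(61)
  prof3 <- rbind(x = rnorm(6), y = rnorm(6), z = rnorm(6))
  d <- matrix(0, 3, 3, dimnames = list(rownames(prof3), rownames(prof3)))
  for (i in 1:3) for (j in 1:3) {
    d[i, j] <- 1 - oracle_pearson(prof3[i, ], prof3[j, ])
  }
  # hand agglomeration, average linkage: merge the closest pair, then the
  # remaining row at the mean of its two distances
  pairs <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
  rest <- setdiff(1:3, pairs)
  h1 <- d[pairs[1], pairs[2]]
  h2 <- mean(d[rest, pairs])
  hc3 <- hcluster_correlations(prof3, linkage = "average")
  expect_equal(sort(hc3$height), sort(c(h1, h2)), tolerance = 1e-12)

  # relabeling permutes leaves but preserves merge heights
  perm <- c(3, 1, 2)
  hc_perm <- hcluster_correlations(prof3[perm, ], linkage = "average")
  expect_equal(sort(hc_perm$height), sort(hc3$height), tolerance = 1e-12)

  sparse <- rbind(u = c(1, NA, NA, NA, NA, NA), prof3)
  expect_warning(hcu <- hcluster_correlations(sparse), "u")
  expect_equal(length(hcu$order), 3)
})
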