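#' Two-sample Wilcoxon / Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test on the Mann-Whitney U statistic. For combined
#' sample sizes up to `exact_max_n` the p-value is exact by full enumeration
#' of all group assignments (midranks, so ties are handled exactly); beyond
#' that a normal approximation with tie and continuity correction is used.
#' All values tied yields p = 1.
#'
#' @param x,y numeric vectors (NA dropped).
#' @param exact_max_n combined-n crossover from enumeration to the normal
#'   approximation (default 12).
#' @return list with `statistic` (U for the first sample), `p`, and `exact`
#'   (logical).
#' @export
rank_sum_test <- function(x, y, exact_max_n = 12) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("rank_sum_test needs >= 1 value per group")
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_stat <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max_n) {
    # full enumeration of which pooled positions belong to group 1
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) {
      sum(rk[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(us - mu) >= abs(u_stat - mu) - 1e-12)
    return(list(statistic = u_stat, p = p, exact = TRUE))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = u_stat, p = 1, exact = FALSE))
  z <- (abs(u_stat - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(statistic = u_stat, p = min(1, 2 * pnorm(-z)), exact = FALSE)
}

#' LysoIP enrichment over the untagged background
#'
#' Per-protein log2 enrichment of a tagged immunoprecipitation group over the
#' untagged background cells, with Student-t p-values and BH q-values
#' (delegates to [compute_contrast] on the `lysoip` fraction).
#'
#' @param m an [abundance_matrix] on the `log2` scale (normalised).
#' @param design a [study_design] containing `lysoip` samples with tagged and
#'   untagged groups.
#' @param tagged_genotype genotype of the tagged group.
#' @param untagged_genotype genotype label of the untagged background
#'   (defaults to the design's control genotype).
#' @param cell_type cell type (default: the lysoip samples' cell type).
#' @param test_kind `"student"` or `"welch"`.
#' @return a fold-change table; `log2fc` is the enrichment over untagged.
#' @export
enrichment_vs_untagged <- function(m, design, tagged_genotype,
                                   untagged_genotype = NULL,
                                   cell_type = NULL,
                                   test_kind = c("student", "welch")) {
  test_kind <- match.arg(test_kind)
  lyso <- design[design$fraction == "lysoip", , drop = FALSE]
  if (nrow(lyso) == 0) stopf("design has no lysoip samples")
  if (!any(lyso$tag_status == "untagged")) {
    stopf("LysoIP analysis requires an untagged background group")
  }
  untagged_genotype <- untagged_genotype %||%
    unique(lyso$genotype[lyso$tag_status == "untagged"])[1]
  cell_type <- cell_type %||% unique(lyso$cell_type)[1]
  ids_test <- select_samples(design, tagged_genotype, cell_type, "lysoip",
                             tag_status = "tagged")
  ids_ref <- select_samples(design, untagged_genotype, cell_type, "lysoip",
                            tag_status = "untagged")
  if (length(ids_test) < 2 || length(ids_ref) < 2) {
    stopf("both the tagged and untagged group need >= 2 replicates")
  }
  res <- row_t_test(m$values[, ids_test, drop = FALSE],
                    m$values[, ids_ref, drop = FALSE], test_kind)
  keep <- res$n_test >= 1 | res$n_ref >= 1
  out <- data.frame(
    protein_id = rownames(m$values),
    genotype = tagged_genotype, cell_type = cell_type, fraction = "lysoip",
    log2fc = ifelse(res$n_test >= 1 & res$n_ref >= 1, res$log2fc, NA_real_),
    p = res$p, q = bh_adjust(res$p),
    n_test = res$n_test, n_ref = res$n_ref,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$neglog10p <- -log10(out$p)
  out$neglog10q <- -log10(out$q)
  rownames(out) <- NULL
  out
}

#' Co-enrichment relative to the mean lysosomal enrichment
#'
#' The co-enrichment threshold of a tagged group is the mean enrichment of
#' its quantified lysosome-annotated proteins; a protein is co-enriched when
#' its enrichment is at or above that threshold (inclusive boundary). Counts
#' per annotation ask which other compartments co-purify with lysosomes.
#'
#' @param e an enrichment table from [enrichment_vs_untagged] (one tagged
#'   group).
#' @param catalog an [annotation_catalog].
#' @param lysosome_label label of the lysosome annotation (default
#'   `"lysosome"`).
#' @return object of class `coenrichment_result`: list with `threshold`,
#'   `proteins` (data.frame `protein_id`, `log2fc`, `co_enriched`) and
#'   `counts` (data.frame `annotation`, `n_co_enriched`, `n_quantified`).
#' @export
coenrichment_flags <- function(e, catalog, lysosome_label = "lysosome") {
  stopifnot(inherits(catalog, "annotation_catalog"))
  members <- catalog$sets[[lysosome_label]]
  if (is.null(members)) stopf("unknown lysosome annotation '%s'", lysosome_label)
  quantified <- e[!is.na(e$log2fc), , drop = FALSE]
  lyso_vals <- quantified$log2fc[quantified$protein_id %in% members]
  if (length(lyso_vals) == 0) {
    stopf("no quantified protein carries the '%s' annotation", lysosome_label)
  }
  threshold <- mean(lyso_vals)
  proteins <- data.frame(protein_id = quantified$protein_id,
                         log2fc = quantified$log2fc,
                         co_enriched = quantified$log2fc >= threshold,
                         stringsAsFactors = FALSE)
  co_ids <- proteins$protein_id[proteins$co_enriched]
  counts <- data.frame(
    annotation = names(catalog$sets),
    n_co_enriched = vapply(catalog$sets, function(s) sum(co_ids %in% s), 1L),
    n_quantified = vapply(catalog$sets,
                          function(s) sum(proteins$protein_id %in% s), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(threshold = threshold, proteins = proteins, counts = counts,
                 lysosome_label = lysosome_label),
            class = "coenrichment_result")
}

#' @export
print.coenrichment_result <- function(x, ...) {
  cat(sprintf("coenrichment_result: threshold %.4f, %d / %d proteins co-enriched\n",
              x$threshold, sum(x$proteins$co_enriched), nrow(x$proteins)))
  invisible(x)
}

#' Per-annotation organelle shift test between two LysoIP groups
#'
#' For each annotation, a two-sided rank-sum test comparing the annotation's
#' protein enrichments between the KO and control tagged groups (shared
#' protein universe), with BH correction across annotations. Annotations with
#' fewer than `min_members` shared quantified proteins are skipped with a
#' warning.
#'
#' @param e_control,e_ko enrichment tables from [enrichment_vs_untagged].
#' @param catalog an [annotation_catalog].
#' @param min_members minimum shared quantified proteins (default 3).
#' @param exact_max_n see [rank_sum_test].
#' @return data.frame with columns `annotation`, `n`, `statistic` (U of the
#'   KO sample), `delta_mean` (KO - control mean enrichment), `p`, `q`.
#' @export
organelle_shift_test <- function(e_control, e_ko, catalog, min_members = 3,
                                 exact_max_n = 12) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  shared <- intersect(e_control$protein_id[!is.na(e_control$log2fc)],
                      e_ko$protein_id[!is.na(e_ko$log2fc)])
  ctrl <- setNames(e_control$log2fc[match(shared, e_control$protein_id)], shared)
  ko <- setNames(e_ko$log2fc[match(shared, e_ko$protein_id)], shared)
  rows <- list()
  skipped <- character()
  for (ann in names(catalog$sets)) {
    members <- intersect(catalog$sets[[ann]], shared)
    if (length(members) < min_members) {
      skipped <- c(skipped, ann)
      next
    }
    rs <- rank_sum_test(ko[members], ctrl[members], exact_max_n = exact_max_n)
    rows[[ann]] <- data.frame(
      annotation = ann, n = length(members), statistic = rs$statistic,
      delta_mean = mean(ko[members]) - mean(ctrl[members]),
      p = rs$p, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warnf("annotation(s) skipped (< %d shared proteins): %s", min_members,
          paste(skipped, collapse = ", "))
  }
  if (length(rows) == 0) stopf("no annotation passes min_members")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Significance counts per organelle for a KO-vs-control LysoIP contrast
#'
#' Delegates to [count_significant] on a KO-vs-control fold-change table
#' computed on the `lysoip` fraction (the up/down bar-plot numbers).
#'
#' @param fc fold-change table of the KO-vs-control LysoIP contrast.
#' @param catalog an [annotation_catalog].
#' @param q_max,min_abs_log2fc significance thresholds.
#' @return data.frame with columns `annotation`, `up`, `down`.
#' @export
per_organelle_significance <- function(fc, catalog, q_max = 0.05,
                                       min_abs_log2fc = 0) {
  count_significant(fc, catalog, q_max = q_max,
                    min_abs_log2fc = min_abs_log2fc)
}
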