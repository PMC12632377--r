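#' Within-genotype fraction log-ratio
#'
#' Per protein, the mean log2 abundance of the numerator fraction minus the
#' mean of the denominator fraction for one genotype (e.g. projection minus
#' whole-cell). Replicate-level ratios are retained, paired by replicate
#' index, for the downstream ratio-of-ratios t-test.
#'
#' @param m an [abundance_matrix] on the `log2` scale.
#' @param design a [study_design].
#' @param genotype genotype label.
#' @param num_fraction,den_fraction fraction labels (default
#'   projection / whole_cell).
#' @param cell_type optional cell-type filter.
#' @return object of class `fraction_ratio_table`: list with `genotype`,
#'   `ratio_log2` (named vector) and `replicate_ratios` (proteins x paired
#'   replicates).
#' @export
fraction_log_ratio <- function(m, design, genotype,
                               num_fraction = "projection",
                               den_fraction = "whole_cell",
                               cell_type = NULL) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(design, "study_design"))
  if (m$scale != "log2") stopf("fraction_log_ratio expects a log2 matrix")
  cell_type <- cell_type %||%
    unique(design$cell_type[design$genotype == genotype])[1]
  pick <- function(fraction) {
    sub <- design[design$genotype == genotype &
                    design$cell_type == cell_type &
                    design$fraction == fraction, , drop = FALSE]
    if (nrow(sub) < 2) {
      stopf("genotype '%s' needs >= 2 replicates in fraction '%s'",
            genotype, fraction)
    }
    setNames(sub$sample_id, sub$replicate)[order(sub$replicate)]
  }
  num_ids <- pick(num_fraction)
  den_ids <- pick(den_fraction)
  num <- m$values[, num_ids, drop = FALSE]
  den <- m$values[, den_ids, drop = FALSE]
  sn <- row_group_stats(num)
  sdn <- row_group_stats(den)
  ratio <- ifelse(sn$n >= 1 & sdn$n >= 1, sn$mean - sdn$mean, NA_real_)
  shared_reps <- intersect(names(num_ids), names(den_ids))
  rep_ratios <- num[, num_ids[shared_reps], drop = FALSE] -
    den[, den_ids[shared_reps], drop = FALSE]
  colnames(rep_ratios) <- paste0("r", shared_reps)
  structure(list(genotype = genotype, cell_type = cell_type,
                 num_fraction = num_fraction, den_fraction = den_fraction,
                 ratio_log2 = setNames(ratio, rownames(m$values)),
                 replicate_ratios = rep_ratios),
            class = "fraction_ratio_table")
}

#' Ratio-of-ratios between KO and control fraction ratios
#'
#' Per protein: log2 RoR = KO fraction ratio minus control fraction ratio,
#' isolating genotype-specific spatial redistribution from genotype-shared
#' compartment composition (shared deltas cancel). The p-value is a Student
#' t-test on the paired replicate-level ratios (KO vs control replicates);
#' q by BH; class `up`/`down`/`ns` by `q <= q_max` and `|log2_ror| >=
#' min_abs`.
#'
#' @param ko,ctrl [fraction_log_ratio] tables over a shared protein universe.
#' @param q_max,min_abs classification thresholds (defaults 0.05 and 0).
#' @return data.frame with columns `protein_id`, `log2_ror`, `p`, `q`,
#'   `class`.
#' @export
ratio_of_ratios <- function(ko, ctrl, q_max = 0.05, min_abs = 0) {
  stopifnot(inherits(ko, "fraction_ratio_table"),
            inherits(ctrl, "fraction_ratio_table"))
  shared <- intersect(names(ko$ratio_log2)[!is.na(ko$ratio_log2)],
                      names(ctrl$ratio_log2)[!is.na(ctrl$ratio_log2)])
  if (length(shared) == 0) stopf("no shared quantified proteins")
  ror <- ko$ratio_log2[shared] - ctrl$ratio_log2[shared]
  res <- row_t_test(ko$replicate_ratios[shared, , drop = FALSE],
                    ctrl$replicate_ratios[shared, , drop = FALSE],
                    "student")
  p <- res$p
  q <- bh_adjust(p)
  cls <- rep("ns", length(shared))
  sig <- !is.na(q) & q <= q_max & abs(ror) >= min_abs
  cls[sig & ror > 0] <- "up"
  cls[sig & ror < 0] <- "down"
  out <- data.frame(protein_id = shared, log2_ror = unname(ror),
                    p = p, q = q, class = cls, stringsAsFactors = FALSE)
  attr(out, "q_max") <- q_max
  attr(out, "min_abs") <- min_abs
  out
}

#' Annotation-level effect ranking of a ratio-of-ratios table
#'
#' Per annotation: the delta mean (mean log2 RoR over the annotation minus
#' the mean over its complement among quantified proteins), Cohen's d of the
#' same comparison, and the mean absolute log2 RoR over the annotation. The
#' overall rank is the ascending order of the mean of the three per-metric
#' descending ranks (|delta mean|, |Cohen's d|, RoR magnitude); ties broken
#' by label. Each annotation is additionally tested against its complement by
#' a two-sided rank-sum test with BH correction.
#'
#' @param ror a [ratio_of_ratios] table.
#' @param catalog an [annotation_catalog].
#' @param min_proteins annotations with fewer quantified members are
#'   excluded.
#' @param exact_max_n see [rank_sum_test].
#' @return data.frame with columns `annotation`, `n`, `delta_mean`,
#'   `cohens_d`, `mean_abs_ror`, `wilcoxon_p`, `wilcoxon_q`, `rank`.
#' @export
annotation_effect_ranking <- function(ror, catalog, min_proteins = 10,
                                      exact_max_n = 12) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  vals <- setNames(ror$log2_ror, ror$protein_id)
  rows <- list()
  for (ann in names(catalog$sets)) {
    members <- intersect(catalog$sets[[ann]], names(vals))
    if (length(members) < min_proteins) next
    complement <- setdiff(names(vals), members)
    if (length(complement) < 2) next
    a <- vals[members]
    b <- vals[complement]
    es <- cohens_d(a, b)
    rs <- rank_sum_test(a, b, exact_max_n = exact_max_n)
    rows[[ann]] <- data.frame(
      annotation = ann, n = length(members),
      delta_mean = es$delta_mean, cohens_d = es$cohens_d,
      mean_abs_ror = mean(abs(a)), wilcoxon_p = rs$p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stopf("no annotation passes min_proteins")
  out <- do.call(rbind, rows)
  out$wilcoxon_q <- bh_adjust(out$wilcoxon_p)
  rank_desc <- function(v) rank(-v, ties.method = "average")
  mean_rank <- (rank_desc(abs(out$delta_mean)) +
                  rank_desc(abs(out$cohens_d)) +
                  rank_desc(out$mean_abs_ror)) / 3
  ord <- order(mean_rank, out$annotation)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "mean of descending ranks of |delta_mean|, |cohens_d|, mean_abs_ror"
  out
}
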