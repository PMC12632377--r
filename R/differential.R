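#' Specify a contrast
#'
#' A contrast compares a test genotype against a reference genotype within
#' one cell type and fraction.
#'
#' @param test_genotype,reference_genotype genotype labels (must differ).
#' @param cell_type cell-type label.
#' @param fraction fraction label (default `whole_cell`).
#' @param tag_status optional tag-status filter for LysoIP designs.
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(test_genotype, reference_genotype, cell_type,
                          fraction = "whole_cell", tag_status = NULL) {
  if (identical(test_genotype, reference_genotype)) {
    stopf("test and reference genotype must differ")
  }
  structure(list(test_genotype = test_genotype,
                 reference_genotype = reference_genotype,
                 cell_type = cell_type, fraction = fraction,
                 tag_status = tag_status),
            class = "contrast_spec")
}

select_samples <- function(design, genotype, cell_type, fraction,
                           tag_status = NULL) {
  keep <- design$genotype == genotype & design$cell_type == cell_type &
    design$fraction == fraction
  if (!is.null(tag_status)) keep <- keep & design$tag_status == tag_status
  design$sample_id[keep]
}

# Vectorised two-sample t over matrix rows. Student (pooled) by default;
# Welch-Satterthwaite behind test_kind = "welch". Zero-variance sentinel:
# both groups constant and equal -> p = 1; constant and unequal -> p = 0.
row_t_test <- function(x_test, x_ref, test_kind = c("student", "welch")) {
  test_kind <- match.arg(test_kind)
  st <- row_group_stats(x_test)
  sr <- row_group_stats(x_ref)
  diff <- st$mean - sr$mean
  n1 <- st$n; n2 <- sr$n
  p <- rep(NA_real_, length(diff))
  ok <- n1 >= 2 & n2 >= 2
  if (test_kind == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * st$var + (n2 - 1) * sr$var) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- st$var / n1; b <- sr$var / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tt <- diff / se
  p[ok] <- 2 * pt(-abs(tt[ok]), df[ok])
  zero_se <- ok & !is.na(se) & se == 0
  p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0
  list(log2fc = diff, p = p, n_test = n1, n_ref = n2, t = tt)
}

#' Compute a per-protein fold-change contrast
#'
#' Per protein: log2 fold change as the difference of group means over
#' present values, a two-sided t-test p-value (Student pooled-variance by
#' default, matching the standard TMT workflow; Welch behind a flag) and
#' Benjamini-Hochberg q-values over the contrast's non-missing p-values.
#' Proteins with fewer than 2 replicates in either group get a missing
#' p-value but a reported log2fc whenever both means are computable; proteins
#' entirely missing in both groups are omitted (with a message).
#'
#' @param m an [abundance_matrix] on the `log2` scale.
#' @param design a [study_design].
#' @param spec a [contrast_spec].
#' @param test_kind `"student"` (default) or `"welch"`.
#' @return a fold-change table: data.frame with columns `protein_id`,
#'   `genotype`, `cell_type`, `fraction`, `log2fc`, `p`, `q`, `n_test`,
#'   `n_ref`, `neglog10p`, `neglog10q`.
#' @export
compute_contrast <- function(m, design, spec,
                             test_kind = c("student", "welch")) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(design, "study_design"),
            inherits(spec, "contrast_spec"))
  test_kind <- match.arg(test_kind)
  if (m$scale != "log2") stopf("compute_contrast expects a log2 matrix")
  ids_test <- select_samples(design, spec$test_genotype, spec$cell_type,
                             spec$fraction, spec$tag_status)
  ids_ref <- select_samples(design, spec$reference_genotype, spec$cell_type,
                            spec$fraction, spec$tag_status)
  if (length(ids_test) == 0) {
    stopf("no samples for test group %s/%s/%s", spec$test_genotype,
          spec$cell_type, spec$fraction)
  }
  if (length(ids_ref) == 0) {
    stopf("no samples for reference group %s/%s/%s", spec$reference_genotype,
          spec$cell_type, spec$fraction)
  }
  ids_test <- intersect(ids_test, colnames(m$values))
  ids_ref <- intersect(ids_ref, colnames(m$values))
  res <- row_t_test(m$values[, ids_test, drop = FALSE],
                    m$values[, ids_ref, drop = FALSE], test_kind)
  keep <- res$n_test >= 1 | res$n_ref >= 1
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("compute_contrast: %d protein(s) missing in both groups omitted",
                    n_drop))
  }
  # log2fc only where both means exist
  log2fc <- ifelse(res$n_test >= 1 & res$n_ref >= 1, res$log2fc, NA_real_)
  out <- data.frame(
    protein_id = rownames(m$values),
    genotype = spec$test_genotype,
    cell_type = spec$cell_type,
    fraction = spec$fraction,
    log2fc = log2fc,
    p = res$p,
    q = bh_adjust(res$p),
    n_test = res$n_test,
    n_ref = res$n_ref,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$neglog10p <- -log10(out$p)
  out$neglog10q <- -log10(out$q)
  rownames(out) <- NULL
  out
}

#' All KO-vs-control contrasts of a design
#'
#' Convenience wrapper running [compute_contrast] for every non-control
#' genotype in each requested cell type, row-binding the results into one
#' long fold-change table (the substrate of the landscape module).
#'
#' @inheritParams compute_contrast
#' @param cell_types cell types to process (default: all in the design).
#' @param fraction fraction to use.
#' @return long fold-change data.frame (one block per condition).
#' @export
compute_all_contrasts <- function(m, design, cell_types = NULL,
                                  fraction = "whole_cell",
                                  test_kind = c("student", "welch")) {
  test_kind <- match.arg(test_kind)
  control <- attr(design, "control_genotype")
  in_fraction <- design$fraction == fraction
  cell_types <- cell_types %||% unique(design$cell_type[in_fraction])
  blocks <- list()
  for (ct in cell_types) {
    genos <- setdiff(unique(design$genotype[in_fraction &
                                              design$cell_type == ct]),
                     control)
    for (g in genos) {
      blocks[[condition_id(g, ct)]] <- compute_contrast(
        m, design, contrast_spec(g, control, ct, fraction), test_kind)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment over the non-missing
#' p-values; missing entries pass through as missing and do not count toward
#' the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Cohen's d and delta mean
#'
#' Standardised mean difference with a pooled, Bessel-corrected standard
#' deviation. A zero pooled SD yields a signed infinite sentinel (or 0 when
#' the means agree).
#'
#' @param test,ref numeric vectors (each of length >= 2; NA dropped).
#' @return list with `delta_mean` and `cohens_d`.
#' @export
cohens_d <- function(test, ref) {
  test <- test[!is.na(test)]
  ref <- ref[!is.na(ref)]
  if (length(test) < 2 || length(ref) < 2) {
    stopf("cohens_d needs >= 2 values per group")
  }
  delta <- mean(test) - mean(ref)
  sp <- sqrt(((length(test) - 1) * var(test) + (length(ref) - 1) * var(ref)) /
               (length(test) + length(ref) - 2))
  d <- if (sp > 0) delta / sp else if (delta == 0) 0 else sign(delta) * Inf
  list(delta_mean = delta, cohens_d = d)
}

#' Count significant proteins per annotation and direction
#'
#' Per annotation: `up` counts proteins with `q <= q_max` and
#' `log2fc >= min_abs_log2fc`; `down` analogously with
#' `log2fc <= -min_abs_log2fc`. A protein in k annotations contributes to all
#' k.
#'
#' @param fc a fold-change table (one contrast).
#' @param catalog an [annotation_catalog].
#' @param q_max q-value cutoff.
#' @param min_abs_log2fc absolute fold-change floor (default 0).
#' @return data.frame with columns `annotation`, `up`, `down`.
#' @export
count_significant <- function(fc, catalog, q_max = 0.05, min_abs_log2fc = 0) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  sig <- !is.na(fc$q) & !is.na(fc$log2fc) & fc$q <= q_max
  up_ids <- fc$protein_id[sig & fc$log2fc >= min_abs_log2fc]
  dn_ids <- fc$protein_id[sig & fc$log2fc <= -min_abs_log2fc]
  data.frame(
    annotation = names(catalog$sets),
    up = vapply(catalog$sets, function(s) sum(up_ids %in% s), 1L),
    down = vapply(catalog$sets, function(s) sum(dn_ids %in% s), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}
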