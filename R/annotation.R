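#' Threshold-defined protein membership
#'
#' Returns the proteins of one contrast whose log2 fold change passes a
#' strict threshold rule, e.g. `log2fc > -0.75` for the Euler-overlap
#' analyses. Boundary values are excluded (strict inequality) and missing
#' fold changes never qualify.
#'
#' @param fc a long fold-change table.
#' @param genotype,cell_type identify the contrast; `fraction` optionally.
#' @param direction `"greater"` or `"less"`.
#' @param cutoff numeric threshold.
#' @param fraction optional fraction filter.
#' @return character vector of protein ids.
#' @export
threshold_membership <- function(fc, genotype, cell_type,
                                 direction = c("greater", "less"), cutoff,
                                 fraction = NULL) {
  direction <- match.arg(direction)
  keep <- fc$genotype == genotype & fc$cell_type == cell_type
  if (!is.null(fraction)) keep <- keep & fc$fraction == fraction
  if (!any(keep)) {
    stopf("no contrast for genotype '%s', cell type '%s' in table",
          genotype, cell_type)
  }
  sub <- fc[keep & !is.na(fc$log2fc), , drop = FALSE]
  pass <- if (direction == "greater") sub$log2fc > cutoff else sub$log2fc < cutoff
  sub$protein_id[pass]
}

#' Exact Venn-region counts for up to six sets
#'
#' Computes the exact count of every non-empty region of the Venn partition
#' over the input sets (the numbers behind Euler diagrams; layout geometry is
#' presentation and not computed).
#'
#' @param sets named list of 1-6 character vectors.
#' @return data.frame with columns `signature` (one character of "0"/"1" per
#'   set, "1" = member of that set) and `count`; only regions with
#'   `count > 0` could be non-trivial but all 2^k - 1 regions are reported.
#' @export
overlap_counts <- function(sets) {
  k <- length(sets)
  if (k < 1 || k > 6) stopf("overlap_counts supports 1 to 6 sets (got %d)", k)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe), ncol = k)
  sig <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  all_sigs <- vapply(seq_len(2^k - 1), function(i) {
    paste(as.integer(rev(intToBits(i)[seq_len(k)]) == 1), collapse = "")
  }, "")
  counts <- vapply(all_sigs, function(s) sum(sig == s), 1L)
  structure(data.frame(signature = all_sigs, count = counts,
                       row.names = NULL, stringsAsFactors = FALSE),
            set_names = names(sets), class = c("overlap_table", "data.frame"))
}

#' Hypergeometric over-representation test
#'
#' Minimal over-representation analysis: for each annotation, the right-tail
#' hypergeometric probability of drawing at least the observed overlap when
#' sampling `|query|` proteins from the background without replacement.
#' Annotations are intersected with the background first; q-values by
#' Benjamini-Hochberg across annotations.
#'
#' @param query character vector of protein ids (must be a subset of
#'   `background`).
#' @param catalog an [annotation_catalog].
#' @param background character vector of protein ids; defaults in callers to
#'   the proteins quantified in the contrast.
#' @return data.frame with columns `annotation`, `set_size` (within
#'   background), `overlap`, `expected`, `fold`, `p`, `q`.
#' @export
ora_hypergeometric <- function(query, catalog, background) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    stopf("query protein(s) outside the background: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(catalog$sets), function(lbl) {
    s <- intersect(catalog$sets[[lbl]], background)
    k <- length(intersect(s, query))
    m <- length(s)
    p <- phyper(k - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    expected <- n_q * m / n_bg
    data.frame(annotation = lbl, set_size = m, overlap = k,
               expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
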