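#' Conditions of a fold-change table
#'
#' @param fc a long fold-change table (see [compute_all_contrasts]).
#' @return data.frame with columns `genotype`, `cell_type`, `id`.
#' @export
fc_conditions <- function(fc) {
  u <- unique(data.frame(genotype = fc$genotype, cell_type = fc$cell_type,
                         stringsAsFactors = FALSE))
  u$id <- condition_id(u$genotype, u$cell_type)
  rownames(u) <- NULL
  u
}

# proteins x conditions matrix of log2fc restricted to the given protein ids
fc_matrix <- function(fc, proteins = NULL, conditions = NULL) {
  conds <- conditions %||% fc_conditions(fc)
  proteins <- proteins %||% unique(fc$protein_id)
  m <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(conds),
              dimnames = list(proteins, conds$id))
  key <- condition_id(fc$genotype, fc$cell_type)
  for (j in seq_len(nrow(conds))) {
    sub <- fc[key == conds$id[j], c("protein_id", "log2fc")]
    sub <- sub[sub$protein_id %in% proteins, , drop = FALSE]
    m[sub$protein_id, j] <- sub$log2fc
  }
  m
}

#' Mean log2 fold change of an annotation in one condition
#'
#' @param fc long fold-change table.
#' @param catalog an [annotation_catalog].
#' @param annotation annotation label.
#' @param genotype,cell_type the condition.
#' @return mean of non-missing log2fc over the annotation's proteins.
#' @export
annotation_mean_log2fc <- function(fc, catalog, annotation, genotype,
                                   cell_type) {
  members <- catalog$sets[[annotation]]
  if (is.null(members)) stopf("unknown annotation '%s'", annotation)
  sub <- fc[fc$genotype == genotype & fc$cell_type == cell_type &
              fc$protein_id %in% members, "log2fc"]
  mean(sub, na.rm = TRUE)
}

#' Annotation-restricted pairwise correlation matrix
#'
#' Pearson correlation of each pair of conditions' log2 fold-change vectors,
#' restricted to the annotation's proteins with both values present
#' (pairwise-complete). Cells resting on fewer than `min_proteins` proteins
#' are missing; an annotation with fewer than `min_proteins` quantified
#' proteins overall yields an empty (all-missing) matrix, flagged via the
#' `empty` attribute rather than an error.
#'
#' @param fc long fold-change table (conditions never include the control).
#' @param catalog an [annotation_catalog].
#' @param annotation annotation label.
#' @param conditions optional condition data.frame (`genotype`, `cell_type`);
#'   defaults to every condition in `fc`.
#' @param min_proteins minimum pairwise-complete proteins per cell
#'   (default 10).
#' @return object of class `annotation_correlation`: list with `annotation`,
#'   `conditions`, `r` (symmetric, unit diagonal where defined) and `n_pairs`.
#' @export
annotation_correlation <- function(fc, catalog, annotation, conditions = NULL,
                                   min_proteins = 10) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  members <- catalog$sets[[annotation]]
  if (is.null(members)) stopf("unknown annotation '%s'", annotation)
  conds <- conditions %||% fc_conditions(fc)
  x <- fc_matrix(fc, proteins = intersect(unique(fc$protein_id), members),
                 conditions = conds)
  present <- !is.na(x)
  n_pairs <- crossprod(present)
  empty <- nrow(x) < min_proteins
  if (empty || nrow(x) < 2) {
    r <- matrix(NA_real_, nrow(conds), nrow(conds),
                dimnames = dimnames(n_pairs))
  } else {
    r <- suppressWarnings(cor(x, use = "pairwise.complete.obs",
                              method = "pearson"))
    r[n_pairs < min_proteins] <- NA_real_
    diag(r)[diag(n_pairs) >= min_proteins] <- 1
  }
  structure(list(annotation = annotation, conditions = conds, r = r,
                 n_pairs = n_pairs),
            empty = empty, class = "annotation_correlation")
}

#' @export
print.annotation_correlation <- function(x, ...) {
  cat(sprintf("annotation_correlation '%s': %d conditions%s\n", x$annotation,
              nrow(x$r), if (isTRUE(attr(x, "empty"))) " (empty)" else ""))
  invisible(x)
}

#' Organelle correlation of one condition against its peers
#'
#' The scalar summarising how similarly a condition's annotation-restricted
#' fold-change profile behaves relative to other conditions: the mean of its
#' pairwise-complete Pearson correlations to each peer (cells failing
#' `min_proteins` are skipped). Peers default to all other conditions of the
#' same cell type.
#'
#' @inheritParams annotation_correlation
#' @param genotype,cell_type the condition summarised.
#' @param peers optional condition data.frame of peers (never including the
#'   condition itself).
#' @return mean pairwise correlation, or `NA` when no valid peer cell exists.
#' @export
organelle_correlation <- function(fc, catalog, annotation, genotype,
                                  cell_type, peers = NULL,
                                  min_proteins = 10) {
  self_id <- condition_id(genotype, cell_type)
  if (is.null(peers)) {
    peers <- fc_conditions(fc)
    peers <- peers[peers$cell_type == cell_type & peers$id != self_id, ,
                   drop = FALSE]
  } else {
    peers$id <- condition_id(peers$genotype, peers$cell_type)
    if (self_id %in% peers$id) stopf("peers must exclude the condition itself")
  }
  if (nrow(peers) == 0) return(NA_real_)
  conds <- rbind(data.frame(genotype = genotype, cell_type = cell_type,
                            id = self_id, stringsAsFactors = FALSE),
                 peers[, c("genotype", "cell_type", "id")])
  acm <- annotation_correlation(fc, catalog, annotation, conditions = conds,
                                min_proteins = min_proteins)
  rs <- acm$r[self_id, peers$id]
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}

#' Cross-cell-type organelle correlation of one genotype
#'
#' Pairs the same genotype's two cell-type conditions and returns the
#' pairwise-complete Pearson correlation of their annotation-restricted
#' fold-change vectors (the iN-vs-iDA scatter statistic).
#'
#' @inheritParams annotation_correlation
#' @param genotype genotype label.
#' @param cell_types length-2 character vector.
#' @return correlation, or `NA` below `min_proteins`.
#' @export
cross_celltype_correlation <- function(fc, catalog, annotation, genotype,
                                       cell_types = c("iN", "iDA"),
                                       min_proteins = 10) {
  stopifnot(length(cell_types) == 2)
  conds <- data.frame(genotype = genotype, cell_type = cell_types,
                      stringsAsFactors = FALSE)
  conds$id <- condition_id(conds$genotype, conds$cell_type)
  acm <- annotation_correlation(fc, catalog, annotation, conditions = conds,
                                min_proteins = min_proteins)
  acm$r[1, 2]
}

#' Composite organelle correlation map
#'
#' The condition-by-annotation matrix of organelle correlation factors: each
#' entry is [organelle_correlation] of that condition against all other
#' conditions of the same cell type, for that annotation. Integrates the
#' direction and strength of fold-change relationships across the landscape.
#'
#' @inheritParams annotation_correlation
#' @param annotations annotation labels (default: all catalog sets).
#' @return object of class `composite_map`: list with `matrix` (conditions x
#'   annotations), `conditions` and `method`.
#' @export
composite_map <- function(fc, catalog, conditions = NULL, annotations = NULL,
                          min_proteins = 10) {
  conds <- conditions %||% fc_conditions(fc)
  if (is.null(conds$id)) conds$id <- condition_id(conds$genotype, conds$cell_type)
  annotations <- annotations %||% names(catalog$sets)
  out <- matrix(NA_real_, nrow = nrow(conds), ncol = length(annotations),
                dimnames = list(conds$id, annotations))
  for (ann in annotations) {
    acm <- annotation_correlation(fc, catalog, ann, conditions = conds,
                                  min_proteins = min_proteins)
    for (i in seq_len(nrow(conds))) {
      peer_ids <- conds$id[conds$cell_type == conds$cell_type[i] &
                             conds$id != conds$id[i]]
      if (length(peer_ids) == 0) next
      rs <- acm$r[conds$id[i], peer_ids]
      if (!all(is.na(rs))) out[i, ann] <- mean(rs, na.rm = TRUE)
    }
  }
  structure(list(matrix = out, conditions = conds,
                 method = "mean-pairwise-within-celltype",
                 min_proteins = min_proteins),
            class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  cat(sprintf("composite_map [%s]: %d conditions x %d annotations\n",
              x$method, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Disease-class summaries of the composite map
#'
#' Per (disease class, annotation, cell type): mean and sample SD of the
#' composite-map entries over the class's member conditions (the mean +/- SD
#' organelle correlation panels).
#'
#' @param cm a [composite_map].
#' @param disease_class named character vector mapping genotype to class.
#' @return data.frame with columns `class`, `cell_type`, `annotation`,
#'   `mean`, `sd`, `n` (`sd` = 0 when `n` = 1).
#' @export
class_variance <- function(cm, disease_class) {
  stopifnot(inherits(cm, "composite_map"))
  conds <- cm$conditions
  missing_class <- setdiff(unique(conds$genotype), names(disease_class))
  if (length(missing_class) > 0) {
    stopf("no disease class for genotype(s): %s",
          paste(missing_class, collapse = ", "))
  }
  cls <- disease_class[conds$genotype]
  rows <- list()
  for (ct in unique(conds$cell_type)) {
    for (cl in unique(cls[conds$cell_type == ct])) {
      sel <- conds$cell_type == ct & cls == cl
      sub <- cm$matrix[conds$id[sel], , drop = FALSE]
      for (ann in colnames(sub)) {
        v <- sub[, ann]
        v <- v[!is.na(v)]
        if (length(v) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, cell_type = ct, annotation = ann,
          mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
          n = length(v), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter correlation links for circos-style display
#'
#' Scans the upper triangle of one or more annotation correlation matrices
#' and retains pairs with `r < neg_max` or `r > pos_min` (the printed circos
#' thresholds are -0.2 and 0.7). Self-links are never emitted. An `origin`
#' filter keeps only links touching the named genotypes or condition ids.
#'
#' @param x an `annotation_correlation` or a list of them.
#' @param neg_max retain links with correlation below this (default -0.2).
#' @param pos_min retain links with correlation above this (default 0.7).
#' @param origin optional character vector of genotypes or condition ids.
#' @return data.frame with columns `annotation`, `condition_a`,
#'   `condition_b`, `r`; thresholds recorded as attributes.
#' @export
filter_links <- function(x, neg_max = -0.2, pos_min = 0.7, origin = NULL) {
  if (neg_max >= pos_min) stopf("neg_max must be below pos_min")
  acms <- if (inherits(x, "annotation_correlation")) list(x) else x
  rows <- list()
  for (acm in acms) {
    r <- acm$r
    ids <- rownames(r)
    genos <- acm$conditions$genotype[match(ids, acm$conditions$id)]
    n <- nrow(r)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        v <- r[i, j]
        if (is.na(v) || !(v < neg_max || v > pos_min)) next
        if (!is.null(origin) &&
            !any(c(ids[i], ids[j], genos[i], genos[j]) %in% origin)) next
        rows[[length(rows) + 1]] <- data.frame(
          annotation = acm$annotation, condition_a = ids[i],
          condition_b = ids[j], r = v, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(annotation = character(), condition_a = character(),
               condition_b = character(), r = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "neg_max") <- neg_max
  attr(out, "pos_min") <- pos_min
  out
}

#' Ranked organelle impact score
#'
#' Scores how strongly each condition of a cell type perturbs a group of
#' annotations: for each annotation, the mean absolute log2 fold change over
#' its proteins is z-scored across the cell type's conditions; a condition's
#' impact is the mean z over the group's annotations, ranked descending
#' (rank 1 = highest impact; ties broken by genotype label).
#'
#' @param fc long fold-change table.
#' @param catalog an [annotation_catalog].
#' @param group a group label from the catalog, or a character vector of
#'   annotation labels.
#' @param cell_type cell type analysed.
#' @param conditions optional condition data.frame (defaults to the table's
#'   conditions of that cell type).
#' @param min_proteins annotations with fewer quantified proteins are dropped
#'   with a warning.
#' @return data.frame with columns `genotype`, `cell_type`, `impact`, `rank`;
#'   per-annotation z contributions in the `components` attribute and the
#'   scoring convention in the `method` attribute.
#' @export
impact_score <- function(fc, catalog, group, cell_type, conditions = NULL,
                         min_proteins = 10) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  annotations <- if (length(group) == 1 && group %in% names(catalog$groups)) {
    catalog$groups[[group]]
  } else {
    group
  }
  unknown <- setdiff(annotations, names(catalog$sets))
  if (length(unknown) > 0) {
    stopf("unknown annotation(s) in group: %s", paste(unknown, collapse = ", "))
  }
  conds <- conditions %||% fc_conditions(fc)
  conds <- conds[conds$cell_type == cell_type, , drop = FALSE]
  if (nrow(conds) < 2) stopf("impact_score needs >= 2 conditions in '%s'", cell_type)
  x <- fc_matrix(fc, conditions = conds)
  m <- matrix(NA_real_, nrow = nrow(conds), ncol = length(annotations),
              dimnames = list(conds$id, annotations))
  dropped <- character()
  for (ann in annotations) {
    members <- intersect(rownames(x), catalog$sets[[ann]])
    sub <- abs(x[members, , drop = FALSE])
    n_ok <- colSums(!is.na(sub))
    if (all(n_ok < min_proteins)) {
      dropped <- c(dropped, ann)
      next
    }
    m[, ann] <- ifelse(n_ok >= min_proteins, colMeans(sub, na.rm = TRUE),
                       NA_real_)
  }
  if (length(dropped) > 0) {
    warnf("annotation(s) below min_proteins dropped from impact score: %s",
          paste(dropped, collapse = ", "))
    m <- m[, setdiff(annotations, dropped), drop = FALSE]
  }
  if (ncol(m) == 0) stopf("no annotation in the group passes min_proteins")
  z <- apply(m, 2, function(v) {
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) ifelse(is.na(v), NA_real_, 0) else (v - mu) / s
  })
  z <- matrix(z, nrow = nrow(conds), dimnames = list(conds$id, colnames(m)))
  impact <- rowMeans(z, na.rm = TRUE)
  ord <- order(-impact, conds$genotype)
  rank <- integer(length(impact))
  rank[ord] <- seq_along(ord)
  out <- data.frame(genotype = conds$genotype, cell_type = cell_type,
                    impact = unname(impact), rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "components") <- z
  attr(out, "method") <- "z-scored mean |log2fc| averaged over annotation group"
  out
}

#' Hierarchical clustering of correlation profiles
#'
#' Agglomerative clustering of profile rows (e.g. conditions by annotation
#' correlation factors) under the distance 1 - Pearson r between rows
#' (pairwise-complete). Rows with fewer than 3 non-missing entries are
#' excluded with a warning.
#'
#' @param profile numeric matrix with named rows.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return an [stats::hclust] tree (deterministic leaf order).
#' @export
hcluster_correlations <- function(profile, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  profile <- as.matrix(profile)
  ok <- rowSums(!is.na(profile)) >= 3
  if (any(!ok)) {
    warnf("excluding %d row(s) with < 3 non-missing entries: %s", sum(!ok),
          paste(rownames(profile)[!ok], collapse = ", "))
    profile <- profile[ok, , drop = FALSE]
  }
  if (nrow(profile) < 2) stopf("need >= 2 usable rows to cluster")
  r <- suppressWarnings(cor(t(profile), use = "pairwise.complete.obs"))
  if (any(is.na(r))) {
    stopf("undefined row-row correlation (insufficient pairwise overlap)")
  }
  d <- as.dist(1 - r)
  hclust(d, method = linkage)
}
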