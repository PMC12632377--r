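#' Log2-transform a raw intensity matrix
#'
#' @param m an [abundance_matrix] on the `raw_intensity` scale with all
#'   present values strictly positive.
#' @return the matrix on the `log2` scale; missing entries preserved.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "raw_intensity") {
    stopf("log2_transform expects a raw_intensity matrix (got scale '%s')",
          m$scale)
  }
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-positive intensity at protein '%s', sample '%s'",
          rownames(m$values)[bad[1, 1]], colnames(m$values)[bad[1, 2]])
  }
  abundance_matrix(log2(m$values), scale = "log2")
}

#' Median-centre each sample column
#'
#' Per sample, subtracts the median of present log2 values so every column
#' has median 0. This is the single supported normalisation; total-intensity
#' scaling reduces to it after summation in log space.
#'
#' @param m an [abundance_matrix] on the `log2` scale.
#' @return the centred matrix (idempotent: applying twice equals once).
#' @export
normalize_median <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "log2") stopf("normalize_median expects a log2 matrix")
  n_present <- colSums(!is.na(m$values))
  if (any(n_present == 0)) {
    stopf("sample(s) with no present values: %s",
          paste(colnames(m$values)[n_present == 0], collapse = ", "))
  }
  med <- apply(m$values, 2, median, na.rm = TRUE)
  abundance_matrix(sweep(m$values, 2, med, "-"), scale = "log2")
}

#' Row z-score a log2 matrix
#'
#' Centres each row to mean 0 and scales to sample standard deviation 1 over
#' present values. Zero-variance rows map to all-zeros so heatmaps stay
#' dense; rows with fewer than 2 present values are emitted as all-missing
#' with a warning.
#'
#' @param m an [abundance_matrix] on the `log2` scale.
#' @return the z-scored matrix.
#' @export
row_z <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "log2") stopf("row_z expects a log2 matrix")
  st <- row_group_stats(m$values)
  out <- m$values
  degenerate <- st$n < 2
  if (any(degenerate)) {
    warnf("%d row(s) with < 2 present values emitted as all-missing",
          sum(degenerate))
    out[degenerate, ] <- NA_real_
  }
  sds <- sqrt(st$var)
  zerovar <- !degenerate & sds == 0
  scale_by <- ifelse(!degenerate & sds > 0, sds, 1)
  out <- (out - st$mean) / scale_by
  # zero-variance rows: present entries become 0, missing stay missing
  out[zerovar, ][!is.na(out[zerovar, , drop = FALSE])] <- 0
  abundance_matrix(out, scale = "log2")
}

#' Quality-control metrics per genotype and cell type
#'
#' For each (genotype, cell type) group: the number of proteins with at least
#' one present value, and the median relative standard deviation (RSD, in
#' percent, computed on linear intensities) over proteins quantified in all of
#' the group's replicates. Groups with a single sample have undefined RSD
#' (reported missing). Per-sample present counts are attached.
#'
#' @param m an [abundance_matrix] on the `raw_intensity` scale.
#' @param design a [study_design].
#' @return list with `groups` (data.frame: genotype, cell_type, n_samples,
#'   protein_count, median_rsd) and `samples` (data.frame: sample_id,
#'   n_present), class `qc_report`.
#' @export
qc_metrics <- function(m, design) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(design, "study_design"))
  if (m$scale != "raw_intensity") {
    stopf("qc_metrics computes RSD on linear intensities; pass a raw_intensity matrix")
  }
  design <- design[design$sample_id %in% colnames(m$values), , drop = FALSE]
  key <- paste(design$genotype, design$cell_type, sep = "\r")
  groups <- unique(data.frame(genotype = design$genotype,
                              cell_type = design$cell_type,
                              key = key, stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(groups)), function(i) {
    ids <- design$sample_id[key == groups$key[i]]
    x <- m$values[, ids, drop = FALSE]
    pc <- sum(rowSums(!is.na(x)) >= 1)
    if (length(ids) < 2) {
      mrsd <- NA_real_
    } else {
      full <- rowSums(!is.na(x)) == length(ids)
      if (!any(full)) {
        mrsd <- NA_real_
      } else {
        xf <- x[full, , drop = FALSE]
        mu <- rowMeans(xf)
        sdv <- apply(xf, 1, sd)
        mrsd <- median(100 * sdv / mu)
      }
    }
    data.frame(genotype = groups$genotype[i], cell_type = groups$cell_type[i],
               n_samples = length(ids), protein_count = pc,
               median_rsd = mrsd, stringsAsFactors = FALSE)
  })
  out <- list(groups = do.call(rbind, res),
              samples = data.frame(sample_id = colnames(m$values),
                                   n_present = colSums(!is.na(m$values)),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE))
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  print(x$groups, ...)
  invisible(x)
}
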