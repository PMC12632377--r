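#' Construct a study design
#'
#' A study design is a per-sample metadata table: sample identifier, genotype,
#' cell type (`iN`, `iDA`, `HeLa`), fraction (`whole_cell`, `soma`,
#' `projection`, `lysoip`), replicate index and tag status (`tagged`,
#' `untagged`, `not_applicable`). Tag status is only meaningful for LysoIP
#' samples; all other fractions must carry `not_applicable`.
#'
#' @param samples data.frame with columns `sample_id`, `genotype`,
#'   `cell_type`, `fraction`, `replicate`, `tag_status`; extra columns are
#'   preserved as opaque metadata.
#' @param control_genotype genotype label serving as the reference in all
#'   contrasts; must appear among the samples.
#' @return an object of class `study_design` (a validated data.frame with a
#'   `control_genotype` attribute).
#' @export
study_design <- function(samples, control_genotype = "Control") {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "genotype", "cell_type", "fraction",
                "replicate", "tag_status")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stopf("design is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$genotype <- as.character(samples$genotype)
  samples$replicate <- as.integer(samples$replicate)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0) {
    stopf("duplicate sample_id: %s", paste(unique(dup), collapse = ", "))
  }
  check_enum <- function(col, allowed) {
    vals <- as.character(samples[[col]])
    bad <- which(!vals %in% allowed)
    if (length(bad) > 0) {
      stopf("unknown %s value '%s' in design row %d", col, vals[bad[1]], bad[1])
    }
    vals
  }
  samples$cell_type <- check_enum("cell_type", .cell_types)
  samples$fraction <- check_enum("fraction", .fractions)
  samples$tag_status <- check_enum("tag_status", .tag_status)
  if (any(is.na(samples$replicate) | samples$replicate < 1)) {
    stopf("replicate must be a positive integer for every sample")
  }
  bad_tag <- samples$fraction != "lysoip" & samples$tag_status != "not_applicable"
  if (any(bad_tag)) {
    stopf("tag_status must be 'not_applicable' for non-lysoip sample(s): %s",
          paste(samples$sample_id[bad_tag], collapse = ", "))
  }
  if (!control_genotype %in% samples$genotype) {
    stopf("control genotype '%s' does not appear among the samples",
          control_genotype)
  }
  rownames(samples) <- NULL
  structure(samples, control_genotype = control_genotype,
            class = c("study_design", "data.frame"))
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d samples, %d genotypes, control = '%s'\n",
              nrow(x), length(unique(x$genotype)),
              attr(x, "control_genotype")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read / write a study design TSV
#'
#' The file is tab-separated with a header containing at least `sample_id`,
#' `genotype`, `cell_type`, `fraction`, `replicate` and `tag_status`; column
#' order is irrelevant and unknown extra columns are preserved.
#'
#' @param path file path.
#' @param control_genotype control genotype label; defaults to `"Control"`
#'   when present in the file, otherwise the first genotype.
#' @return `read_design` returns a [study_design]; `write_design` returns
#'   `path` invisibly.
#' @export
read_design <- function(path, control_genotype = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if (is.null(control_genotype)) {
    control_genotype <- if ("Control" %in% df$genotype) "Control" else df$genotype[1]
  }
  study_design(df, control_genotype = control_genotype)
}

#' @rdname read_design
#' @param design a [study_design].
#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Construct an abundance matrix
#'
#' Proteins-by-samples intensity table with an explicit scale flag. Missing
#' entries are allowed and are never imputed; all downstream statistics use
#' pairwise-complete observations.
#'
#' @param values numeric matrix; rownames are protein identifiers, colnames
#'   sample identifiers.
#' @param scale `"raw_intensity"` (linear, strictly positive) or `"log2"`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, scale = c("raw_intensity", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("abundance values must carry protein rownames and sample colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stopf("duplicate protein id: %s", paste(unique(dup), collapse = ", "))
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0) {
    stopf("duplicate sample id: %s", paste(unique(dup), collapse = ", "))
  }
  if (scale == "raw_intensity" && any(values <= 0, na.rm = TRUE)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stopf("raw intensity must be > 0; offending value at protein '%s', sample '%s'",
          rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  structure(list(values = values, scale = scale), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples [%s], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Read / write an abundance matrix
#'
#' Wide TSV/CSV: first column `protein_id`, remaining columns one per sample.
#' Empty cells are read as missing; missing values are written back as empty
#' cells. The separator follows the file extension (`.csv` is
#' comma-separated, anything else tab-separated).
#'
#' @param path file path.
#' @param scale declared scale of the stored values.
#' @param design optional [study_design]; when given, sample columns are
#'   cross-validated against it.
#' @return `read_abundance` returns an [abundance_matrix]; `write_abundance`
#'   returns `path` invisibly.
#' @export
read_abundance <- function(path, scale = c("raw_intensity", "log2"),
                           design = NULL) {
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2) stopf("abundance table needs a protein_id column plus samples")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      col[col == ""] <- NA
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        stopf("non-numeric cell '%s' at protein '%s', sample '%s'",
              col[bad[1]], ids[bad[1]], names(vals)[j])
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!is.null(design)) {
    extra <- setdiff(colnames(m), design$sample_id)
    if (length(extra) > 0) {
      stopf("sample column(s) absent from design: %s",
            paste(extra, collapse = ", "))
    }
  }
  abundance_matrix(m, scale = scale)
}

#' @rdname read_abundance
#' @param m an [abundance_matrix].
#' @export
write_abundance <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values))
  chr[is.na(m$values)] <- ""
  df <- data.frame(protein_id = rownames(m$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- colnames(m$values)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an annotation catalog
#'
#' Named, possibly overlapping protein sets for subcellular compartments and
#' functions (lysosome, mitochondria, OXPHOS, SynapseSV, ...), optional
#' annotation groups (e.g. "mitochondrial" spanning several annotations) and
#' an optional genotype-to-disease-class map.
#'
#' @param sets named list of non-empty character vectors (annotation label ->
#'   protein ids).
#' @param groups named list of character vectors (group label -> annotation
#'   labels); every referenced label must exist in `sets`.
#' @param disease_class named character vector (genotype -> class label).
#' @return an object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(sets, groups = list(),
                               disease_class = character()) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stopf("annotation sets must be named")
  }
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup) > 0) {
    stopf("duplicate annotation label: %s", paste(unique(dup), collapse = ", "))
  }
  empty <- names(sets)[vapply(sets, length, 1L) == 0]
  if (length(empty) > 0) {
    stopf("empty annotation set: %s", paste(empty, collapse = ", "))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  for (g in names(groups)) {
    unknown <- setdiff(groups[[g]], names(sets))
    if (length(unknown) > 0) {
      stopf("group '%s' references unknown annotation(s): %s",
            g, paste(unknown, collapse = ", "))
    }
  }
  structure(list(sets = sets, groups = groups,
                 disease_class = disease_class),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog: %d sets (%d-%d members), %d groups, %d classed genotypes\n",
              length(x$sets), min(vapply(x$sets, length, 1L)),
              max(vapply(x$sets, length, 1L)), length(x$groups),
              length(x$disease_class)))
  invisible(x)
}

#' Read / write an annotation catalog
#'
#' GMT format: one line per set, tab-separated fields `label`, `description`,
#' then member protein ids. Groups and disease classes live in optional
#' two-column sidecar TSVs (`group<TAB>annotation`, header included, and
#' `genotype<TAB>class`).
#'
#' @param path GMT file path.
#' @param groups_path,classes_path optional sidecar TSV paths.
#' @return `read_catalog` returns an [annotation_catalog]; `write_catalog`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path, groups_path = NULL, classes_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("GMT line %d ('%s') has no members", i, fields[1])
    }
    label <- fields[1]
    if (label %in% names(sets)) stopf("duplicate annotation label: %s", label)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) stopf("GMT line %d ('%s') has no members", i, label)
    sets[[label]] <- members
  }
  groups <- list()
  if (!is.null(groups_path)) {
    gt <- read.delim(groups_path, sep = "\t", stringsAsFactors = FALSE)
    groups <- split(as.character(gt[[2]]), as.character(gt[[1]]))
  }
  classes <- character()
  if (!is.null(classes_path)) {
    ct <- read.delim(classes_path, sep = "\t", stringsAsFactors = FALSE)
    classes <- setNames(as.character(ct[[2]]), as.character(ct[[1]]))
  }
  annotation_catalog(sets, groups = groups, disease_class = classes)
}

#' @rdname read_catalog
#' @param catalog an [annotation_catalog].
#' @export
write_catalog <- function(catalog, path, groups_path = NULL,
                          classes_path = NULL) {
  lines <- vapply(names(catalog$sets), function(lbl) {
    paste(c(lbl, "na", catalog$sets[[lbl]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  if (!is.null(groups_path)) {
    gt <- data.frame(
      group = rep(names(catalog$groups),
                  vapply(catalog$groups, length, 1L)),
      annotation = unlist(catalog$groups, use.names = FALSE))
    write.table(gt, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(classes_path)) {
    ct <- data.frame(genotype = names(catalog$disease_class),
                     class = unname(catalog$disease_class))
    write.table(ct, classes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
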