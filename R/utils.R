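`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition identifier
#'
#' A condition is a (genotype, cell type) pair; correlation analyses never
#' include the control genotype as a condition because fold changes are taken
#' relative to it.
#'
#' @param genotype character vector of genotype labels.
#' @param cell_type character vector of cell-type labels.
#' @return character vector of `"genotype|cell_type"` identifiers.
#' @export
condition_id <- function(genotype, cell_type) {
  paste(genotype, cell_type, sep = "|")
}

# stable small-integer sub-stream seed derived from (purpose, seed);
# kept below 2^31 - 1 so set.seed() accepts it
seed_stream <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * ((seq_len(nchar(purpose)) - 1L) %% 31L + 1L))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# row-wise n / mean / sample variance over present values of a numeric matrix
row_group_stats <- function(x) {
  present <- !is.na(x)
  n <- rowSums(present)
  x0 <- x
  x0[!present] <- 0
  s1 <- rowSums(x0)
  m <- ifelse(n > 0, s1 / n, NA_real_)
  s2 <- rowSums(x0^2)
  v <- ifelse(n > 1, (s2 - n * m^2) / (n - 1), NA_real_)
  # guard tiny negative values from cancellation
  v <- ifelse(!is.na(v) & v < 0, 0, v)
  list(n = n, mean = m, var = v)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
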