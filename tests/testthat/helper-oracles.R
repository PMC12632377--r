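# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# textbook sum-of-products Pearson correlation, pairwise-complete
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# direct step-up Benjamini-Hochberg: q_(i) = min over j >= i of p_(j)*n/j
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# exhaustive two-sided rank-sum p over all group assignments (midranks)
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  ws <- apply(combos, 2, function(idx) sum(rk[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# exact right-tail hypergeometric by summing binomial-coefficient ratios
oracle_hyper_right <- function(overlap, set_size, bg_size, draws) {
  ks <- overlap:min(set_size, draws)
  sum(choose(set_size, ks) * choose(bg_size - set_size, draws - ks)) /
    choose(bg_size, draws)
}

# all permutations of 1..n (n small)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos - 1)
    }
  }
  out
}

# small abundance matrix + design fixture: g genotypes x r replicates
tiny_dataset <- function(values, genotypes, n_rep, cell_type = "iN",
                         control = "Control") {
  n_samp <- length(genotypes) * n_rep
  stopifnot(ncol(values) == n_samp)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%d", seq_len(nrow(values)))
  }
  grid <- expand.grid(replicate = seq_len(n_rep), genotype = genotypes,
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_r%d", grid$genotype, grid$replicate)
  colnames(values) <- ids
  design <- study_design(data.frame(
    sample_id = ids, genotype = grid$genotype, cell_type = cell_type,
    fraction = "whole_cell", replicate = grid$replicate,
    tag_status = "not_applicable", stringsAsFactors = FALSE),
    control_genotype = control)
  list(abundance = abundance_matrix(values, scale = "log2"), design = design)
}

# long fold-change table built directly from stated values
toy_fc <- function(protein_id, log2fc, genotype = "KO", cell_type = "iN",
                   q = NA_real_, p = NA_real_) {
  data.frame(protein_id = protein_id, genotype = genotype,
             cell_type = cell_type, fraction = "whole_cell",
             log2fc = log2fc, p = p, q = q,
             n_test = 3L, n_ref = 3L, stringsAsFactors = FALSE)
}
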