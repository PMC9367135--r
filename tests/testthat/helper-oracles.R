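# Independent brute-force oracles for the overlap and rank tests.
# These enumerate outcomes directly and never touch the package's code
# paths (phyper / fisher.test / wilcox.test).

# Upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws of
# n items from a universe of N in which items 1..K form the category.
oracle_hyper_upper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# One-sided Fisher p ("greater" for cell a) on the 2x2 table
# [[a, b], [c, d]]: hypergeometric upper tail at the observed margins.
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_upper(a + b + c + d, a + b, a + c, a)
}

# Exact one-sided Wilcoxon rank-sum P(W_x <= w_obs) by enumerating all
# rank assignments (no ties allowed).
oracle_wilcox_less <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  sets <- utils::combn(n + m, n)
  mean(colSums(matrix(seq_len(n + m)[sets], nrow = n)) <= w_obs)
}

# Classical balanced two-way ANOVA F for the cell effect from the direct
# sum-of-squares formulas (complete designs only).
oracle_balanced_anova_F <- function(y, cell, animal) {
  cells <- unique(cell); animals <- unique(animal)
  a <- length(cells); b <- length(animals)
  stopifnot(length(y) == a * b)
  gm <- mean(y)
  ss_cell <- b * sum((tapply(y, cell, mean) - gm)^2)
  ss_animal <- a * sum((tapply(y, animal, mean) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  sse <- ss_tot - ss_cell - ss_animal
  df_num <- a - 1; df_den <- (a - 1) * (b - 1)
  (ss_cell / df_num) / (sse / df_den)
}

# Step-up BH from the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 1L, chrom_length_bp = 200000L, n_genes = 6L,
         n_dmr_planted = 4L, n_cgis_per_chrom = 3L, n_snps = 40L,
         seed = 42L),
    list(...))
  do.call(sim_config, args)
}
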