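# Small programmatic fixtures shared across test files.

# Dense toy matrix with known structure: 5 genes x 4 observations.
toy_matrix <- function(layer = "raw_counts") {
  m <- matrix(c(3, 0, 1, 0, 2,
                0, 0, 0, 0, 1,
                5, 4, 3, 2, 1,
                0, 2, 0, 2, 0),
              nrow = 5,
              dimnames = list(paste0("G", 1:5), paste0("c", 1:4)))
  expression_matrix(m, layer = layer)
}

# Random sparse integer count matrix with unique dimnames.
random_counts <- function(n_genes, n_obs, seed, lambda = 0.6) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_obs, lambda), n_genes, n_obs,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("b%04d", seq_len(n_obs))))
  m
}

# Independent brute-force recovery AUC: builds the step curve c(i) literally.
brute_force_auc <- function(ranking, sig_genes, top_fraction, n_universe) {
  m <- length(sig_genes)
  T <- max(1, floor(top_fraction * n_universe))
  c_i <- vapply(seq_len(T),
                function(i) sum(sig_genes %in% ranking[seq_len(min(i, length(ranking)))]),
                numeric(1))
  denom <- sum(vapply(seq_len(T), function(i) min(i, m), numeric(1)))
  sum(c_i) / denom
}

# Textbook BH step-down: q_(i) = min_{j >= i} (m * p_(j) / j), capped at 1,
# mapped back to input order.
textbook_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(m * p[ord][js] / js))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
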