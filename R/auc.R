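#' Rank the expressed genes of one observation
#'
#' Orders the genes of a single observation by decreasing expression value.
#' Zero-count genes are discarded from the ranking entirely (they are treated
#' as missing, never as bottom-ranked), mirroring the
#' \code{keepZeroesAsNA} convention of AUCell-style scoring.  Ties are broken
#' by a seeded uniform random permutation within each tie group, so rankings
#' are reproducible given the seed but carry no systematic ordering bias.
#'
#' @param expr numeric vector of expression values for one observation,
#'   named by gene.
#' @param seed integer seed for tie-breaking.
#' @return character vector of gene names, best rank first; its length is
#'   the number of nonzero genes.
#' @export
rank_observation <- function(expr, seed = 1L) {
  if (is.null(names(expr))) stop("'expr' must be named by gene")
  nz <- which(expr > 0)
  if (!length(nz))
    stop("all-zero observation cannot be ranked; filter such observations first")
  u <- with_seed(seed, runif(length(nz)))
  ord <- order(-expr[nz], u)
  names(expr)[nz[ord]]
}

#' Signature recovery AUC from a ranking
#'
#' Builds the step recovery curve \eqn{c(i)} = number of signature genes found
#' at ranking positions \eqn{\le i}, for \eqn{i = 1..T} with
#' \eqn{T = \max(1, \lfloor \code{top_fraction} \cdot |U| \rfloor)} over the
#' gene universe \eqn{U}, and returns the area under it normalized by the
#' maximum achievable area \eqn{\sum_{i=1}^{T} \min(i, m)}, where \eqn{m} is
#' the number of signature genes in the universe.  Signature genes with zero
#' counts are absent from the ranking and are never recovered.  The score is
#' 1 when the m signature genes occupy the top m ranks, 0 when none appears
#' in the top T.
#'
#' @param ranking character vector from [rank_observation()].
#' @param sig_genes character vector of signature genes.
#' @param top_fraction fraction of the gene universe defining the top of the
#'   ranking considered; default 0.05.
#' @param n_universe number of genes in the matrix universe.
#' @param m number of signature genes present in the universe; defaults to
#'   \code{length(sig_genes)}.
#' @return AUC in [0, 1].
#' @export
recovery_auc <- function(ranking, sig_genes, top_fraction = 0.05, n_universe,
                         m = length(sig_genes)) {
  if (m < 1) stop("no signature gene in the universe (m = 0)")
  T <- floor(top_fraction * n_universe)
  if (T < 1) {
    if (top_fraction <= 0) stop("top_fraction must be positive (T < 1)")
    T <- 1L
  }
  pos <- match(sig_genes, ranking)
  hits <- pos[!is.na(pos) & pos <= T]
  sum(T - hits + 1) / sum(pmin(seq_len(T), m))
}

## Positions of every gene in every observation's tie-broken ranking.
## Returns an integer matrix (genes x observations); 0 marks a zero-count
## gene absent from that observation's ranking.  Tie seeds are derived from
## (seed, observation index) so rankings are reproducible per observation
## and shared by the true-signature scoring and the permutation null.
rank_positions <- function(x, seed = 1L) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- x$values
  n_genes <- nrow(m)
  n_obs <- ncol(m)
  P <- matrix(0L, n_genes, n_obs, dimnames = dimnames(m))
  p <- m@p; i <- m@i; v <- m@x
  for (j in seq_len(n_obs)) {
    idx <- if (p[j + 1] > p[j]) seq.int(p[j] + 1L, p[j + 1]) else integer(0)
    if (!length(idx))
      stop("all-zero observation '", colnames(m)[j],
           "' cannot be ranked; run filter_observations() first")
    rows <- i[idx] + 1L
    vals <- v[idx]
    u <- with_seed(derive_seed(seed, j), runif(length(vals)))
    ord <- order(-vals, u)
    P[rows[ord], j] <- seq_along(ord)
  }
  P
}

## Recovery AUC of one gene set across all observations, from a position
## matrix.  Vectorized form of recovery_auc: numerator per observation is
## sum over signature genes of (T - position + 1) for positions within 1..T.
score_positions <- function(P, sig_rows, T, m) {
  S <- P[sig_rows, , drop = FALSE]
  contrib <- (S > 0L & S <= T) * (T - S + 1L)
  colSums(contrib) / sum(pmin(seq_len(T), m))
}

#' Score a signature across all observations
#'
#' Computes the recovery AUC of one signature for every observation of a
#' matrix.  Rankings are built once per observation (zero-count genes
#' excluded, seeded tie-breaking) and are identical to those used by
#' [build_null()] at the same seed, so signature scores and the background
#' null are directly comparable.
#'
#' @param x an \code{\link{expression_matrix}} with no all-zero observation.
#' @param sig_genes character vector of signature genes (or a
#'   \code{\link{gene_signature}}).
#' @param top_fraction see [recovery_auc()].
#' @param seed integer seed controlling tie-breaking.
#' @return data.frame (\code{score_table}) with columns \code{obs_id},
#'   \code{auc}.
#' @export
score_signature <- function(x, sig_genes, top_fraction = 0.05, seed = 1L) {
  if (inherits(sig_genes, "gene_signature")) sig_genes <- sig_genes$genes
  sig_genes <- toupper(sig_genes)
  universe <- toupper(gene_ids(x))
  sig_rows <- which(universe %in% sig_genes)
  if (!length(sig_rows))
    stop("no signature gene present in the matrix universe")
  T <- max(1L, floor(top_fraction * length(universe)))
  if (top_fraction <= 0) stop("top_fraction must be positive")
  P <- rank_positions(x, seed = seed)
  auc <- score_positions(P, sig_rows, T, length(sig_rows))
  structure(data.frame(obs_id = obs_ids(x), auc = as.numeric(auc),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}

#' Permutation background null for recovery-AUC scores
#'
#' Estimates the background distribution of recovery-AUC scores by rescoring
#' every observation with \code{n_perm} random gene sets of length \code{m}
#' sampled uniformly without replacement from the matrix gene universe
#' (default 10000 sets, matching the published procedure).  Scores are pooled
#' over observations and permutations and the empirical
#' \code{quantile_q} quantile is the data-driven confidence threshold above
#' which a signature score is called non-background.
#'
#' @param x an \code{\link{expression_matrix}} (filtered; no all-zero
#'   observations).
#' @param m length of the random gene sets (the signature length).
#' @param n_perm number of random gene sets; default 10000.
#' @param quantile_q quantile of the pooled null defining the threshold;
#'   default 0.95.
#' @param top_fraction see [recovery_auc()].
#' @param seed integer seed; rankings and gene-set sampling both derive from
#'   it.
#' @param keep_scores keep the pooled score vector (length
#'   \code{n_perm * n_obs}) in the result; set \code{FALSE} to save memory.
#' @return an object of class \code{null_distribution} with elements
#'   \code{scores}, \code{n_perm}, \code{sig_length}, \code{quantile_q},
#'   \code{threshold}, \code{seed}.
#' @export
build_null <- function(x, m, n_perm = 10000L, quantile_q = 0.95,
                       top_fraction = 0.05, seed = 1L, keep_scores = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- assert_count(m, "m", lower = 1L)
  n_perm <- assert_count(n_perm, "n_perm", lower = 1L)
  assert_scalar_number(quantile_q, "quantile_q", lower = 1e-12, upper = 1 - 1e-12)
  universe <- gene_ids(x)
  if (m >= length(universe))
    stop(sprintf("signature length m (%d) must be smaller than the universe (%d)",
                 m, length(universe)))
  T <- max(1L, floor(top_fraction * length(universe)))
  if (top_fraction <= 0) stop("top_fraction must be positive")
  P <- rank_positions(x, seed = seed)
  sets <- with_seed(seed, {
    matrix(replicate(n_perm, sample.int(length(universe), m)), nrow = m)
  })
  n_obs <- ncol(P)
  pooled <- numeric(n_obs * n_perm)
  for (b in seq_len(n_perm))
    pooled[((b - 1L) * n_obs + 1L):(b * n_obs)] <-
      score_positions(P, sets[, b], T, m)
  threshold <- as.numeric(quantile(pooled, quantile_q, type = 7))
  structure(
    list(scores = if (keep_scores) pooled else NULL,
         n_perm = n_perm, sig_length = m, quantile_q = quantile_q,
         threshold = threshold, top_fraction = top_fraction,
         n_obs = n_obs, seed = as.integer(seed)),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(paste0("null_distribution: %d random %d-gene sets x %d observations\n",
                     "  threshold (q = %.3f): %.6f\n"),
              x$n_perm, x$sig_length, x$n_obs, x$quantile_q, x$threshold))
  invisible(x)
}

#' Serialize a null distribution to JSON
#'
#' Writes the summary (n_perm, signature length, quantile, threshold, seed)
#' as JSON; the pooled raw scores can optionally go to a CSV alongside.
#'
#' @param null a \code{null_distribution}.
#' @param path output JSON path.
#' @param scores_path optional CSV path for the pooled raw scores.
#' @return invisibly, \code{path}.
#' @export
write_null <- function(null, path, scores_path = NULL) {
  jsonlite::write_json(
    list(n_perm = null$n_perm, sig_length = null$sig_length,
         quantile_q = null$quantile_q, threshold = null$threshold,
         top_fraction = null$top_fraction, seed = null$seed),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(scores_path) && !is.null(null$scores))
    write.csv(data.frame(auc = null$scores), scores_path, row.names = FALSE)
  invisible(path)
}
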