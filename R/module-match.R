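#' Size-penalized overlap score between two gene modules
#'
#' Fraction of shared genes scaled by module size so that larger modules are
#' penalized more than smaller ones.  The default is the Ochiai (cosine /
#' geometric-mean) coefficient \eqn{|A \cap B| / \sqrt{|A| |B|}}, which is
#' symmetric and equals 1 only for identical modules; a containment variant
#' \eqn{|A \cap B| / \max(|A|, |B|)} is available.
#'
#' @param a,b character vectors of gene symbols (non-empty).
#' @param scaling \code{"ochiai"} or \code{"containment"}.
#' @return score in [0, 1].
#' @export
scaled_overlap <- function(a, b, scaling = c("ochiai", "containment")) {
  scaling <- match.arg(scaling)
  a <- unique(toupper(a)); b <- unique(toupper(b))
  if (!length(a) || !length(b)) stop("modules must be non-empty")
  ov <- length(intersect(a, b))
  switch(scaling,
         ochiai = ov / sqrt(length(a) * length(b)),
         containment = ov / max(length(a), length(b)))
}

#' Fisher exact test of gene-module overlap
#'
#' Tests the overlap of two modules against a gene universe with the
#' hypergeometric 2x2 exact test.  The two-sided p-value sums the
#' probabilities of all tables (margins fixed) whose probability does not
#' exceed that of the observed table.  The odds ratio is the sample ratio
#' \eqn{(ad)/(bc)}; division by zero is reported as infinite.
#'
#' @param a,b character vectors of gene symbols, both subsets of
#'   \code{universe}.
#' @param universe character vector, the gene universe U.
#' @return list with \code{table} (named counts a, b, c, d),
#'   \code{p_two_sided}, \code{odds_ratio}, \code{overlap}.
#' @export
fisher_overlap <- function(a, b, universe) {
  a <- unique(toupper(a)); b <- unique(toupper(b))
  universe <- unique(toupper(universe))
  if (!all(a %in% universe)) stop("module A is not contained in the universe")
  if (!all(b %in% universe)) stop("module B is not contained in the universe")
  n_u <- length(universe)
  ov <- length(intersect(a, b))
  tab <- c(a = ov, b = length(a) - ov, c = length(b) - ov,
           d = n_u - length(a) - length(b) + ov)
  p <- hyper_test_p(ov, length(a), length(b), n_u)
  or <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
  if (is.nan(or)) or <- if (tab["a"] > 0) Inf else NaN
  list(table = tab, p_two_sided = p, odds_ratio = unname(or), overlap = ov)
}

## Two-sided hypergeometric exact p-value for overlap a between a set of
## size ka and a set of size kb in a universe of size n: sums dhyper
## probabilities over the support that are <= the observed probability, with
## a small relative tolerance absorbing floating-point noise among
## mathematically tied tables.  Vectorized over `a`.
hyper_test_p <- function(a, ka, kb, n) {
  support <- max(0L, ka + kb - n):min(ka, kb)
  dens <- dhyper(support, ka, n - ka, kb)
  vapply(a, function(obs) {
    d_obs <- dens[match(obs, support)]
    if (is.na(d_obs)) stop("observed overlap outside hypergeometric support")
    min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-down false-discovery-rate adjustment: the adjusted value of the
#' i-th order statistic is \eqn{\min_{j \ge i} (m \, p_{(j)} / j)}, capped at
#' 1.  Wraps [stats::p.adjust()] after validating the inputs.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Match gene modules between two collections
#'
#' Scores every (baseline, query) module pair with the size-penalized
#' overlap and the Fisher exact test, applies Benjamini-Hochberg correction
#' jointly across all pairs, and assigns each baseline module its best match:
#' the significant pair (q below \code{alpha}) with the highest scaled
#' score, ties broken by smaller p, then by lexicographic query id.  A
#' baseline module with no significant pair is reported unmatched (NA).
#'
#' @param baseline,query named lists of character vectors (gene modules);
#'   the baseline comparator is typically the in vitro collection.
#' @param universe gene universe U covering all module genes; default the
#'   union of all genes in both collections.
#' @param alpha significance level on the adjusted q-values, default 0.05.
#' @param scaling passed to [scaled_overlap()].
#' @return object of class \code{module_match} with \code{pairs} (long
#'   data.frame: baseline_id, query_id, overlap, scaled_score, p, q_bh,
#'   odds_ratio) and \code{best} (data.frame: baseline_id, query_id,
#'   scaled_score, q_bh; query_id NA when unmatched), plus the recorded
#'   \code{universe_size}.
#' @export
match_modules <- function(baseline, query, universe = NULL, alpha = 0.05,
                          scaling = c("ochiai", "containment")) {
  scaling <- match.arg(scaling)
  if (!length(baseline) || !length(query))
    stop("module collections must be non-empty")
  if (is.null(names(baseline)) || is.null(names(query)))
    stop("module collections must be named")
  baseline <- lapply(baseline, function(g) unique(toupper(g)))
  query <- lapply(query, function(g) unique(toupper(g)))
  if (is.null(universe))
    universe <- unique(c(unlist(baseline), unlist(query)))
  else
    universe <- unique(toupper(universe))
  pairs <- expand.grid(baseline_id = names(baseline), query_id = names(query),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    A <- baseline[[pairs$baseline_id[i]]]
    B <- query[[pairs$query_id[i]]]
    f <- fisher_overlap(A, B, universe)
    data.frame(baseline_id = pairs$baseline_id[i],
               query_id = pairs$query_id[i],
               overlap = f$overlap,
               scaled_score = scaled_overlap(A, B, scaling),
               p = f$p_two_sided, odds_ratio = f$odds_ratio,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_bh <- bh_adjust(res$p)
  res <- res[, c("baseline_id", "query_id", "overlap", "scaled_score",
                 "p", "q_bh", "odds_ratio")]
  best <- do.call(rbind, lapply(names(baseline), function(bid) {
    cand <- res[res$baseline_id == bid & res$q_bh < alpha, , drop = FALSE]
    if (!nrow(cand))
      return(data.frame(baseline_id = bid, query_id = NA_character_,
                        scaled_score = NA_real_, q_bh = NA_real_,
                        stringsAsFactors = FALSE))
    cand <- cand[order(-cand$scaled_score, cand$p, cand$query_id), ]
    data.frame(baseline_id = bid, query_id = cand$query_id[1],
               scaled_score = cand$scaled_score[1], q_bh = cand$q_bh[1],
               stringsAsFactors = FALSE)
  }))
  structure(list(pairs = res, best = best,
                 universe_size = length(universe), alpha = alpha,
                 scaling = scaling),
            class = "module_match")
}

#' @export
print.module_match <- function(x, ...) {
  cat(sprintf("module_match: %d baseline x %d query modules (|U| = %d, %s scaling)\n",
              length(unique(x$pairs$baseline_id)),
              length(unique(x$pairs$query_id)),
              x$universe_size, x$scaling))
  matched <- !is.na(x$best$query_id)
  cat(sprintf("  %d of %d baseline modules matched at q < %g\n",
              sum(matched), nrow(x$best), x$alpha))
  print(x$best, row.names = FALSE)
  invisible(x)
}
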