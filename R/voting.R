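#' k-of-n signature voting over observations
#'
#' For each observation, counts how many signature genes vote — value >=
#' theta in threshold mode, value > 0 in presence mode — and calls the
#' observation positive when at least k genes vote.  Signature genes absent
#' from the matrix are kept in the rule (they simply never vote), so the
#' k-of-n semantics are stable across datasets; a warning lists them.  An
#' optional \code{average} mode instead requires the mean expression of the
#' signature genes to reach theta.
#'
#' @param x an \code{\link{expression_matrix}} (normalized layer expected for
#'   threshold voting; presence voting is layer-independent).
#' @param sig a \code{\link{gene_signature}}.
#' @param mode override of the signature's voting mode; one of
#'   \code{"threshold"}, \code{"presence"}, \code{"average"}.
#' @return data.frame with columns \code{obs_id}, \code{signature},
#'   \code{vote_count}, \code{call}.
#' @examples
#' m <- expression_matrix(matrix(c(2, 0, 1, 0, 3, 2), nrow = 3,
#'        dimnames = list(c("A", "B", "C"), c("c1", "c2"))), "raw_counts")
#' vote(m, gene_signature("s", c("A", "B", "C"), min_genes = 2,
#'                        expr_threshold = 1))
#' @export
vote <- function(x, sig, mode = NULL) {
  stopifnot(inherits(x, "expression_matrix"), inherits(sig, "gene_signature"))
  mode <- mode %||% sig$mode
  mode <- match.arg(mode, c("threshold", "presence", "average"))
  rows <- match(sig$genes, toupper(gene_ids(x)))   # symbols match case-insensitively
  present <- !is.na(rows)
  if (!any(present))
    stop("no signature gene of '", sig$name, "' is present in the matrix: ",
         paste(sig$genes, collapse = ", "))
  if (!all(present))
    warning(sprintf("signature '%s': %d gene(s) absent from matrix (never vote): %s",
                    sig$name, sum(!present),
                    paste(sig$genes[!present], collapse = ", ")))
  sub <- x$values[rows[present], , drop = FALSE]
  if (mode == "average") {
    avg <- Matrix::colSums(sub) / length(sig$genes)
    counts <- as.integer(Matrix::colSums(sub > 0))
    calls <- avg >= sig$expr_threshold
  } else {
    voting <- if (mode == "presence") sub > 0 else sub >= sig$expr_threshold
    counts <- as.integer(Matrix::colSums(voting))
    calls <- counts >= sig$min_genes
  }
  data.frame(obs_id = obs_ids(x), signature = sig$name,
             vote_count = counts, call = as.logical(calls),
             stringsAsFactors = FALSE)
}

#' Select anchor observations by tolerant gene-set voting
#'
#' Pseudotime start/end regions are anchored on observations expressing a
#' small curated gene set, allowing up to \code{tolerance} genes to be
#' missing: an observation is selected when at least \eqn{n - t} of the
#' \eqn{n} genes reach \code{expr_threshold}.  Equivalent to [vote()] with
#' \eqn{k = n - t}.  Genes absent from the matrix count toward the tolerance.
#'
#' @param x normalized \code{\link{expression_matrix}}.
#' @param genes character vector of anchor genes.
#' @param expr_threshold per-gene threshold theta.
#' @param tolerance number of genes allowed to miss (t < n).
#' @return character vector of selected observation barcodes.
#' @export
select_anchor_cells <- function(x, genes, expr_threshold, tolerance = 0L) {
  genes <- toupper(genes)
  n <- length(genes)
  tolerance <- assert_count(tolerance, "tolerance")
  if (tolerance >= n)
    stop(sprintf("tolerance (%d) must be smaller than the gene-set size (%d)",
                 tolerance, n))
  sig <- gene_signature("anchor", genes, tolerance = tolerance,
                        expr_threshold = expr_threshold)
  v <- vote(x, sig)
  v$obs_id[v$call]
}

#' Positive fraction per group
#'
#' Summarizes boolean calls over a labelling of the observations (sample,
#' area, cluster, ...): for each label, the number of positive observations,
#' the group size, and their ratio.  This is the summary behind frequency
#' histograms of RG-like cells per sample and fractions of cells with
#' non-zero senescence-panel expression.
#'
#' @param calls logical vector of per-observation calls.
#' @param labels vector of group labels aligned with \code{calls}; missing
#'   (NA) labels are an error.
#' @return data.frame with columns \code{label}, \code{n_positive},
#'   \code{n_total}, \code{fraction}.
#' @export
positive_fraction <- function(calls, labels) {
  if (length(calls) != length(labels))
    stop("'calls' and 'labels' must have equal length")
  if (anyNA(labels)) stop("every observation must carry a label")
  if (anyNA(calls)) stop("calls must not contain NA")
  tot <- table(labels)
  pos <- tapply(as.logical(calls), labels, sum)
  data.frame(label = names(tot),
             n_positive = as.integer(pos[names(tot)]),
             n_total = as.integer(tot),
             fraction = as.numeric(pos[names(tot)] / tot),
             stringsAsFactors = FALSE, row.names = NULL)
}
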