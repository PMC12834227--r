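#' Construct a gene signature with voting parameters
#'
#' A signature is an ordered set of \eqn{n} gene symbols together with the
#' parameters of the k-of-n voting rule used to call observations positive:
#' at least \code{min_genes} (k) of the n genes must be expressed at or above
#' \code{expr_threshold} (theta).  The tolerance \eqn{t = n - k} (how many
#' genes may be missing) is the equivalent parameterization used when
#' selecting pseudotime anchor regions; supply either \code{min_genes} or
#' \code{tolerance} and the other is derived.  In \code{presence} mode the
#' threshold is ignored and a gene votes whenever its value is strictly
#' positive.
#'
#' @param name signature name.
#' @param genes character vector of gene symbols (uppercased; duplicates are
#'   an error).
#' @param min_genes k, the minimum number of voting genes; default n.
#' @param expr_threshold theta, the per-gene expression threshold on the
#'   normalized layer; ignored in presence mode.
#' @param tolerance t, the number of genes allowed to be missing
#'   (\eqn{t = n - k}); alternative to \code{min_genes}.
#' @param mode \code{"threshold"} (value >= theta votes) or
#'   \code{"presence"} (value > 0 votes).
#' @return an object of class \code{gene_signature}.
#' @examples
#' gene_signature("RG", c("VIM", "HES1", "SOX2"), min_genes = 2, expr_threshold = 1)
#' @export
gene_signature <- function(name, genes, min_genes = NULL, expr_threshold = 0,
                           tolerance = NULL, mode = c("threshold", "presence")) {
  mode <- match.arg(mode)
  genes <- toupper(as.character(genes))
  if (!length(genes)) stop("signature '", name, "' has an empty gene list")
  if (anyDuplicated(genes))
    stop("signature '", name, "' contains duplicate genes")
  n <- length(genes)
  if (!is.null(min_genes) && !is.null(tolerance) &&
      as.integer(min_genes) + as.integer(tolerance) != n)
    stop("min_genes and tolerance are inconsistent: k + t must equal n")
  if (is.null(min_genes))
    min_genes <- if (is.null(tolerance)) n else n - assert_count(tolerance, "tolerance")
  min_genes <- assert_count(min_genes, "min_genes", lower = 1L)
  if (min_genes > n)
    stop(sprintf("min_genes (%d) exceeds signature size (%d)", min_genes, n))
  assert_scalar_number(expr_threshold, "expr_threshold", lower = 0)
  structure(
    list(name = as.character(name), genes = genes,
         min_genes = min_genes, expr_threshold = expr_threshold,
         tolerance = n - min_genes, mode = mode),
    class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  thr <- if (x$mode == "presence") "presence/absence"
         else sprintf("threshold %g", x$expr_threshold)
  cat(sprintf("gene_signature '%s': %d of %d genes, %s (tolerance %d)\n",
              x$name, x$min_genes, length(x$genes), thr, x$tolerance))
  cat("  ", paste(utils::head(x$genes, 12), collapse = ", "),
      if (length(x$genes) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)
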