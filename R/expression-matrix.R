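#' Construct an expression matrix
#'
#' Container for a genes x observations matrix of expression values, either
#' raw UMI counts or library-size normalized log expression.  Values are held
#' in a sparse \code{\link[Matrix]{dgCMatrix}} with gene symbols as row names
#' and observation barcodes as column names.
#'
#' @param values numeric matrix or \code{Matrix} sparse matrix, genes in rows,
#'   observations (cells or spots) in columns; must carry row and column
#'   names, all values non-negative.  The \code{raw_counts} layer must contain
#'   integers only.
#' @param layer one of \code{"raw_counts"} or \code{"normalized"}.
#' @param scale_factor,log_base for a \code{normalized} layer, the parameters
#'   the normalization was computed with (recorded as metadata so downstream
#'   thresholds are interpretable).
#' @return an object of class \code{expression_matrix}.
#' @seealso [normalize_counts()], [filter_observations()], [read_counts()]
#' @export
expression_matrix <- function(values, layer = c("raw_counts", "normalized"),
                              scale_factor = NULL, log_base = NULL) {
  layer <- match.arg(layer)
  if (is.matrix(values)) values <- Matrix::Matrix(values, sparse = TRUE)
  if (!methods::is(values, "CsparseMatrix"))
    values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  gene_ids <- rownames(values)
  obs_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(obs_ids))
    stop("'values' must have gene row names and observation column names")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers; disambiguate before construction")
  if (anyDuplicated(obs_ids))
    stop("duplicate observation barcodes; namespace them as '<sample>:<barcode>'")
  v <- values@x
  if (length(v) && min(v) < 0) stop("expression values must be non-negative")
  if (layer == "raw_counts" && length(v) && any(v != floor(v)))
    stop("raw_counts layer must contain integer values only")
  structure(
    list(values = values, layer = layer,
         scale_factor = scale_factor, log_base = log_base),
    class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
dimnames.expression_matrix <- function(x) dimnames(x$values)

#' Gene identifiers of an expression matrix
#' @param x an \code{expression_matrix}.
#' @return character vector of gene symbols.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Observation barcodes of an expression matrix
#' @param x an \code{expression_matrix}.
#' @return character vector of barcodes.
#' @export
obs_ids <- function(x) colnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  d <- dim(x$values)
  nz <- length(x$values@x)
  cat(sprintf("expression_matrix: %d genes x %d observations (%s layer, %.1f%% nonzero)\n",
              d[1], d[2], x$layer, 100 * nz / prod(pmax(d, 1))))
  if (x$layer == "normalized")
    cat(sprintf("  normalization: log%s(1 + v * %g / libsize)\n",
                format(x$log_base), x$scale_factor))
  invisible(x)
}

#' Library-size log normalization of raw counts
#'
#' Rescales each observation to a common library size and log-transforms:
#' a count \eqn{v} in an observation with total count \eqn{N} becomes
#' \eqn{\log_b(1 + v \cdot s / N)} with scale factor \eqn{s} (default 10000)
#' and log base \eqn{b} (default 2).  Zeros map to zeros, and the transform is
#' strictly monotone within each observation, so rank-based scoring is
#' unaffected by the choice of base.
#'
#' @param x an \code{expression_matrix} with layer \code{raw_counts}.
#' @param scale_factor common library size, default 10000.
#' @param log_base logarithm base, default 2 (set \code{exp(1)} for the
#'   natural-log convention).
#' @return an \code{expression_matrix} with layer \code{normalized}.
#' @export
normalize_counts <- function(x, scale_factor = 10000, log_base = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$layer != "raw_counts")
    stop("normalize_counts() expects the raw_counts layer")
  assert_scalar_number(scale_factor, "scale_factor", lower = 1e-12)
  assert_scalar_number(log_base, "log_base", lower = 1 + 1e-12)
  totals <- Matrix::colSums(x$values)
  if (any(totals == 0))
    stop("observations with zero total counts present; run filter_observations() first: ",
         paste(utils::head(colnames(x$values)[totals == 0], 5), collapse = ", "))
  m <- x$values
  ## operate on the sparse slots directly: zero stays zero exactly
  per_obs <- rep.int(scale_factor / totals, diff(m@p))
  m@x <- log1p(m@x * per_obs) / log(log_base)
  expression_matrix(m, layer = "normalized",
                    scale_factor = scale_factor, log_base = log_base)
}

#' Filter observations by number of detected genes
#'
#' Keeps observations (spots or cells) detecting strictly more than
#' \code{min_unique_genes} genes with a count above zero; the default of 100
#' reproduces the usual spatial spot-quality rule "spots containing >100
#' unique genes were kept".  Observation order is preserved.
#'
#' @param x an \code{expression_matrix} (raw counts).
#' @param min_unique_genes integer; observations must exceed this number of
#'   nonzero genes to be retained.
#' @return filtered \code{expression_matrix}.
#' @export
filter_observations <- function(x, min_unique_genes = 100) {
  stopifnot(inherits(x, "expression_matrix"))
  min_unique_genes <- assert_count(min_unique_genes, "min_unique_genes")
  nnz <- diff(x$values@p)
  keep <- nnz > min_unique_genes
  if (!any(keep))
    stop(sprintf("no observation exceeds %d detected genes; nothing retained",
                 min_unique_genes))
  out <- x
  out$values <- x$values[, keep, drop = FALSE]
  out
}
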