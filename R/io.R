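#' Read a count matrix from an MTX triplet
#'
#' Reads the standard single-cell triplet layout: a MatrixMarket coordinate
#' file plus one-record-per-line TSV companions for features (genes) and
#' barcodes.  Indices in the file are 1-based.  Duplicate gene symbols are
#' disambiguated deterministically in file order by suffixing \code{".1"},
#' \code{".2"}, ...; duplicate barcodes are an error (namespace them as
#' \code{"<sample>:<barcode>"} upstream).
#'
#' @param matrix_path path to the MatrixMarket \code{.mtx} file.
#' @param features_path path to the features TSV (first column = gene symbol).
#' @param barcodes_path path to the barcodes TSV (first column = barcode).
#' @return an \code{\link{expression_matrix}} with layer \code{raw_counts}.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop(sprintf("format error: %d features but matrix header declares %d rows",
                 nrow(feats), nrow(m)))
  if (nrow(bcs) != ncol(m))
    stop(sprintf("format error: %d barcodes but matrix header declares %d columns",
                 nrow(bcs), ncol(m)))
  if (length(m@x) && any(m@x != floor(m@x)))
    stop("format error: non-integer values in count matrix")
  genes <- disambiguate_symbols(as.character(feats[[1]]))
  rownames(m) <- genes
  colnames(m) <- as.character(bcs[[1]])
  expression_matrix(m, layer = "raw_counts")
}

disambiguate_symbols <- function(symbols) {
  dup <- duplicated(symbols) | duplicated(symbols, fromLast = TRUE)
  if (!any(dup)) return(symbols)
  out <- symbols
  for (s in unique(symbols[dup])) {
    idx <- which(symbols == s)
    out[idx[-1]] <- paste0(s, ".", seq_len(length(idx) - 1L))
  }
  out
}

#' Write a count matrix as an MTX triplet
#'
#' Inverse of [read_counts()]; writes \code{matrix.mtx}, \code{features.tsv}
#' and \code{barcodes.tsv} into \code{dir}.
#'
#' @param x an \code{expression_matrix} with layer \code{raw_counts}.
#' @param dir output directory, created if missing.
#' @return invisibly, the three file paths.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$layer != "raw_counts") stop("write_counts() expects raw counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(x$values, paths[1])
  write.table(data.frame(gene = gene_ids(x)), paths[2], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(barcode = obs_ids(x)), paths[3], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read gene signatures
#'
#' Reads gene sets either from a GMT file (one signature per line:
#' name, description, then genes, tab-separated) or from a plain text file
#' with one gene per line (a single signature named after the file).  Gene
#' symbols are uppercased so matching against expression matrices is
#' case-insensitive; duplicates within a signature are dropped with a
#' warning.  Voting parameters (k, threshold, tolerance, mode) are not part
#' of either format and are attached afterwards via [gene_signature()] or
#' supplied through \code{params}.
#'
#' @param path input file.
#' @param format \code{"gmt"} or \code{"list"} (one gene per line).
#' @param params optional named list of per-signature voting parameters; each
#'   element is a list with any of \code{min_genes}, \code{expr_threshold},
#'   \code{tolerance}, \code{mode} and is matched to signatures by name.
#' @return a named list of \code{\link{gene_signature}} objects.
#' @export
read_signatures <- function(path, format = c("gmt", "list"), params = list()) {
  format <- match.arg(format)
  if (format == "list") {
    genes <- readLines(path)
    genes <- trimws(genes)
    genes <- genes[nzchar(genes)]
    name <- sub("\\.[^.]*$", "", basename(path))
    sets <- stats::setNames(list(genes), name)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    sets <- list()
    for (i in seq_along(lines)) {
      fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3)
        stop(sprintf("malformed GMT line %d in %s: expected name, description and >=1 gene",
                     i, path))
      sets[[fields[1]]] <- fields[-(1:2)]
    }
  }
  out <- lapply(names(sets), function(name) {
    genes <- toupper(sets[[name]])
    if (anyDuplicated(genes)) {
      warning(sprintf("signature '%s': %d duplicate gene(s) removed",
                      name, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    p <- params[[name]] %||% list()
    gene_signature(name, genes,
                   min_genes = p$min_genes %||% length(genes),
                   expr_threshold = p$expr_threshold %||% 0,
                   mode = p$mode %||% "threshold")
  })
  stats::setNames(out, names(sets))
}

#' Write gene signatures as GMT
#'
#' @param signatures a list of \code{\link{gene_signature}} objects or named
#'   character vectors.
#' @param path output GMT file.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    if (inherits(s, "gene_signature"))
      paste(c(s$name, "na", s$genes), collapse = "\t")
    else
      paste(c(names(signatures)[i], "na", s), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spot metadata table
#'
#' CSV with columns \code{obs_id, x, y, tissue, niche, sample_id, group}.
#' Coordinates are 0-based integers on a rectangular grid; \code{tissue} must
#' be \code{WM} or \code{GM}; niche labels are validated against
#' \code{niche_vocabulary} when given.
#'
#' @param path CSV file.
#' @param niche_vocabulary optional character vector of allowed niche labels.
#' @return a \code{data.frame} (class \code{spot_table}).
#' @export
read_spot_table <- function(path, niche_vocabulary = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_spot_table(df, niche_vocabulary = niche_vocabulary)
}

#' Validate a spot metadata data.frame
#'
#' @param df data.frame with columns \code{obs_id, x, y, tissue, niche,
#'   sample_id, group}.
#' @inheritParams read_spot_table
#' @return the validated \code{data.frame} with class \code{spot_table}.
#' @export
as_spot_table <- function(df, niche_vocabulary = NULL) {
  required <- c("obs_id", "x", "y", "tissue", "niche", "sample_id", "group")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("spot table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$obs_id))
    stop("duplicate obs_id in spot table")
  if (anyDuplicated(df[, c("sample_id", "x", "y")]))
    stop("duplicate (sample_id, x, y) coordinates in spot table")
  if (any(df$x != floor(df$x)) || any(df$y != floor(df$y)) ||
      any(df$x < 0) || any(df$y < 0))
    stop("x and y must be non-negative integer grid coordinates")
  if (!all(df$tissue %in% c("WM", "GM")))
    stop("tissue must be 'WM' or 'GM'")
  if (!is.null(niche_vocabulary) && !all(df$niche %in% niche_vocabulary))
    stop("unknown niche label(s): ",
         paste(setdiff(unique(df$niche), niche_vocabulary), collapse = ", "))
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Read a flat key-value configuration file
#'
#' Configuration is a flat YAML mapping with namespaced keys such as
#' \code{voting.rg.k} or \code{null.n_perm}; unknown keys raise an error
#' listing the accepted ones.  [default_config()] documents every key and its
#' default.
#'
#' @param path YAML file (flat mapping).
#' @return named list merging the file over [default_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\naccepted keys: ", paste(names(defaults), collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' Default pipeline configuration
#'
#' Mirrors the published analysis parameters: log2 normalization with scale
#' factor 10000; spot filter at >100 detected genes; radial-glia voting 6 of
#' 9 at threshold 1, astroglial 7 of 10 at 0.5, NPC 5 of 7 at 0.5, interferon
#' 3 of 6 at 0.5, NOTCH1 13 of 16 in presence/absence mode; 10000 random gene
#' sets for the AUC background null; DARG-high gene-count gates of >6 (WM)
#' and >4 (GM).  The background confidence quantile is not stated in the
#' published analysis; the default here is a conservative 0.99.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    norm.scale_factor = 10000,
    norm.log_base = 2,
    filter.min_unique_genes = 100L,
    voting.rg.k = 6L, voting.rg.theta = 1,
    voting.astro.k = 7L, voting.astro.theta = 0.5,
    voting.npc.k = 5L, voting.npc.theta = 0.5,
    voting.ifn.k = 3L, voting.ifn.theta = 0.5,
    voting.notch1.k = 13L, voting.notch1.mode = "presence",
    auc.top_fraction = 0.05,
    null.n_perm = 10000L,
    null.quantile = 0.99,
    darg.wm_gene_threshold = 6L,
    darg.gm_gene_threshold = 4L,
    darg.vote_mode = "presence",
    test.n_bins = 20L,
    match.alpha = 0.05,
    match.scaling = "ochiai"
  )
}
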