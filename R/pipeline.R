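#' End-to-end DARG spot analysis
#'
#' Chains the full calling pipeline on in-memory objects: spot filtering
#' (>\code{filter.min_unique_genes} detected genes), library-size log
#' normalization, presence-mode voting on the radial-glia and inflammatory
#' signature subsets, recovery-AUC scoring of the combined DARG signature,
#' the random-gene-set permutation null, dual-criterion DARG-high calling,
#' and niche plus patient-level summaries.  All randomness (ranking
#' tie-breaks, null gene sets) derives from the single configured seed.
#'
#' @param counts an \code{\link{expression_matrix}} of raw counts.
#' @param spots a \code{spot_table} covering (at least) the retained spots.
#' @param rg_genes,infl_genes character vectors: the radial-glia and
#'   inflammatory DARG signature subsets.
#' @param config named list as from [default_config()] / [read_config()];
#'   individual entries may be overridden.
#' @param keep_null_scores keep the pooled null scores in the result.
#' @return object of class \code{darg_result} with elements \code{calls},
#'   \code{scores}, \code{null}, \code{niche}, \code{patient} (NULL when
#'   only one group is present), \code{rg_votes}, \code{infl_votes},
#'   \code{config}, \code{n_spots_in}, \code{n_spots_kept}.
#' @export
darg_analysis <- function(counts, spots, rg_genes, infl_genes,
                          config = default_config(),
                          keep_null_scores = FALSE) {
  cfg <- utils::modifyList(default_config(), config)
  assert_count(cfg$null.n_perm, "null.n_perm", lower = 1L)
  assert_scalar_number(cfg$null.quantile, "null.quantile",
                       lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(cfg$auc.top_fraction, "auc.top_fraction", lower = 1e-12)
  seed <- as.integer(cfg$seed)
  n_in <- ncol(counts$values)
  filtered <- filter_observations(counts, cfg$filter.min_unique_genes)
  norm <- normalize_counts(filtered, scale_factor = cfg$norm.scale_factor,
                           log_base = cfg$norm.log_base)
  rg_sig <- gene_signature("RG", rg_genes, min_genes = 1,
                           mode = cfg$darg.vote_mode)
  infl_sig <- gene_signature("INFL", infl_genes, min_genes = 1,
                             mode = cfg$darg.vote_mode)
  rg_votes <- vote(norm, rg_sig)
  infl_votes <- vote(norm, infl_sig)
  darg_genes <- unique(c(toupper(rg_genes), toupper(infl_genes)))
  scores <- score_signature(norm, darg_genes,
                            top_fraction = cfg$auc.top_fraction, seed = seed)
  m <- sum(darg_genes %in% gene_ids(norm))
  null <- build_null(norm, m = m, n_perm = cfg$null.n_perm,
                     quantile_q = cfg$null.quantile,
                     top_fraction = cfg$auc.top_fraction, seed = seed,
                     keep_scores = keep_null_scores)
  spots_kept <- spots[match(obs_ids(norm), spots$obs_id), , drop = FALSE]
  if (anyNA(spots_kept$obs_id))
    stop("alignment error: retained spots missing from the spot table")
  calls <- call_darg_high(scores, null, rg_votes, infl_votes, spots_kept,
                          wm_gene_threshold = cfg$darg.wm_gene_threshold,
                          gm_gene_threshold = cfg$darg.gm_gene_threshold)
  niche <- niche_summary(calls, spots_kept)
  patient <- if (length(unique(spots_kept$group)) == 2)
    patient_summary(scores, spots_kept)
  else NULL
  structure(
    list(calls = calls, scores = scores, null = null, niche = niche,
         patient = patient, rg_votes = rg_votes, infl_votes = infl_votes,
         config = cfg, n_spots_in = n_in, n_spots_kept = ncol(norm$values)),
    class = "darg_result")
}

#' @export
print.darg_result <- function(x, ...) {
  n_high <- sum(x$calls$darg_high)
  cat(sprintf(paste0("darg_result: %d/%d spots kept, %d DARG-high (%.2f%%)\n",
                     "  AUC threshold %.6f (q = %.3f, %d permutations)\n"),
              x$n_spots_kept, x$n_spots_in, n_high,
              100 * n_high / x$n_spots_kept,
              x$null$threshold, x$null$quantile_q, x$null$n_perm))
  invisible(x)
}

#' @export
summary.darg_result <- function(object, ...) {
  cat("DARG-high calls by niche:\n")
  print(object$niche, row.names = FALSE)
  if (!is.null(object$patient)) {
    cat("\nPatient-level mean AUC by group:\n")
    print(object$patient$samples, row.names = FALSE)
    cat(sprintf("\nRank test: W = %g, p = %.4g\n",
                unname(object$patient$test$statistic),
                object$patient$test$p.value))
  }
  invisible(object)
}

#' Simulate a spatial dataset to disk
#'
#' Runs [simulate_spatial()] and writes the standard artifact layout into
#' \code{out_dir}: the MTX triplet (\code{matrix.mtx}, \code{features.tsv},
#' \code{barcodes.tsv}), \code{spots.csv}, \code{truth.csv},
#' \code{signatures.gmt} (RG and INFL subsets) and \code{manifest.json}
#' recording every simulation parameter and the seed, so simulated data flow
#' through the same readers as real data.
#'
#' @param out_dir output directory (parent must exist).
#' @param ... passed to [simulate_spatial()].
#' @param seed integer seed recorded in the manifest.
#' @return invisibly, the simulation list from [simulate_spatial()].
#' @export
simulate_dataset <- function(out_dir, ..., seed = 1L) {
  if (!dir.exists(dirname(out_dir)))
    stop("parent directory does not exist: ", dirname(out_dir))
  dir.create(out_dir, showWarnings = FALSE)
  sim <- simulate_spatial(..., seed = seed)
  write_counts(sim$matrix, out_dir)
  write.csv(sim$spots, file.path(out_dir, "spots.csv"), row.names = FALSE)
  write.csv(data.frame(obs_id = names(sim$truth$darg_truth),
                       darg_truth = unname(sim$truth$darg_truth)),
            file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_gmt(list(RG = sim$rg_genes, INFL = sim$infl_genes),
            file.path(out_dir, "signatures.gmt"))
  jsonlite::write_json(
    list(artifact = "dargspot", version = as.character(utils::packageVersion("dargspot")),
         seed = seed, parameters = sim$truth$parameters),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Run the DARG pipeline on a dataset directory
#'
#' File-level driver: reads the MTX triplet, \code{spots.csv} and
#' \code{signatures.gmt} (signatures named \code{RG} and \code{INFL}) from
#' \code{data_dir}, runs [darg_analysis()] under \code{config}, and writes
#' \code{darg_calls.csv}, \code{niche_summary.csv},
#' \code{patient_summary.csv} (when two groups are present),
#' \code{null.json} and \code{report.json} into \code{out_dir}.
#'
#' @param data_dir directory with the dataset files.
#' @param out_dir output directory (created).
#' @param config named list (see [read_config()]), or a path to a config
#'   file.
#' @return invisibly, the \code{darg_result}.
#' @export
run_darg_pipeline <- function(data_dir, out_dir, config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  counts <- read_counts(file.path(data_dir, "matrix.mtx"),
                        file.path(data_dir, "features.tsv"),
                        file.path(data_dir, "barcodes.tsv"))
  spots <- read_spot_table(file.path(data_dir, "spots.csv"))
  sigs <- read_signatures(file.path(data_dir, "signatures.gmt"), "gmt")
  if (!all(c("RG", "INFL") %in% names(sigs)))
    stop("signatures.gmt must define signatures named 'RG' and 'INFL'")
  res <- darg_analysis(counts, spots, sigs$RG$genes, sigs$INFL$genes, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$calls, file.path(out_dir, "darg_calls.csv"), row.names = FALSE)
  write.csv(res$niche, file.path(out_dir, "niche_summary.csv"),
            row.names = FALSE)
  if (!is.null(res$patient))
    write.csv(res$patient$samples, file.path(out_dir, "patient_summary.csv"),
              row.names = FALSE)
  write_null(res$null, file.path(out_dir, "null.json"))
  report <- list(
    seed = cfg$seed,
    n_spots_in = res$n_spots_in, n_spots_kept = res$n_spots_kept,
    auc_threshold = res$null$threshold,
    n_darg_high = sum(res$calls$darg_high),
    pct_darg_high = 100 * mean(res$calls$darg_high),
    niche = res$niche,
    patient_p = if (!is.null(res$patient)) res$patient$test$p.value,
    config = cfg)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Match module GMT files on disk
#'
#' Reads baseline and query module collections from GMT files, runs
#' [match_modules()], and writes the long-format pair table and the
#' best-match table as CSV.
#'
#' @param baseline_gmt,query_gmt GMT files.
#' @param out_prefix path prefix; writes \code{<prefix>_pairs.csv} and
#'   \code{<prefix>_best.csv}.
#' @param universe_file optional one-gene-per-line universe file; default is
#'   the union of all module genes.
#' @param alpha,scaling passed to [match_modules()].
#' @return invisibly, the \code{module_match} result.
#' @export
run_module_matching <- function(baseline_gmt, query_gmt, out_prefix,
                                universe_file = NULL, alpha = 0.05,
                                scaling = "ochiai") {
  baseline <- lapply(read_signatures(baseline_gmt, "gmt"), `[[`, "genes")
  query <- lapply(read_signatures(query_gmt, "gmt"), `[[`, "genes")
  universe <- if (!is.null(universe_file))
    toupper(trimws(readLines(universe_file)))
  else NULL
  mm <- match_modules(baseline, query, universe = universe, alpha = alpha,
                      scaling = scaling)
  write.csv(mm$pairs, paste0(out_prefix, "_pairs.csv"), row.names = FALSE)
  write.csv(mm$best, paste0(out_prefix, "_best.csv"), row.names = FALSE)
  invisible(mm)
}
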