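#' Call DARG-high spots from AUC and voting criteria
#'
#' A spot is DARG-high when (1) its signature recovery AUC exceeds the
#' permutation-null confidence threshold and (2) it expresses strictly more
#' than a tissue-specific number of genes from \emph{both} the radial-glia
#' and the inflammatory DARG signature subsets: more than
#' \code{wm_gene_threshold} (default 6) genes in white-matter spots, more
#' than \code{gm_gene_threshold} (default 4) in gray-matter spots.  All
#' inequalities are strict.  Vote counts are expected in presence mode
#' (number of signature genes with value > 0).
#'
#' @param scores a \code{score_table} from [score_signature()] (columns
#'   \code{obs_id}, \code{auc}).
#' @param null a \code{null_distribution} from [build_null()], or a single
#'   numeric threshold.
#' @param rg_votes,infl_votes vote data.frames from [vote()] for the
#'   radial-glia and inflammatory subsets (columns \code{obs_id},
#'   \code{vote_count}).
#' @param spot_table a \code{spot_table} supplying \code{tissue} per spot.
#' @param wm_gene_threshold,gm_gene_threshold strict lower bounds on the
#'   per-subset vote counts for WM and GM spots.
#' @return data.frame (\code{darg_calls}) with columns \code{obs_id},
#'   \code{auc}, \code{passed_auc}, \code{rg_vote_count},
#'   \code{infl_vote_count}, \code{tissue}, \code{darg_high}.
#' @export
call_darg_high <- function(scores, null, rg_votes, infl_votes, spot_table,
                           wm_gene_threshold = 6L, gm_gene_threshold = 4L) {
  threshold <- if (inherits(null, "null_distribution")) null$threshold else
    assert_scalar_number(null, "null")
  obs <- scores$obs_id
  align <- function(df, what) {
    i <- match(obs, df$obs_id)
    if (anyNA(i))
      stop("alignment error: ", sum(is.na(i)), " observation(s) missing from ",
           what, ": ", paste(utils::head(obs[is.na(i)], 5), collapse = ", "))
    df[i, , drop = FALSE]
  }
  rg <- align(rg_votes, "rg_votes")
  infl <- align(infl_votes, "infl_votes")
  spots <- align(spot_table, "spot_table")
  g <- ifelse(spots$tissue == "WM", wm_gene_threshold, gm_gene_threshold)
  passed_auc <- scores$auc > threshold
  darg_high <- passed_auc & rg$vote_count > g & infl$vote_count > g
  structure(
    data.frame(obs_id = obs, auc = scores$auc, passed_auc = passed_auc,
               rg_vote_count = rg$vote_count,
               infl_vote_count = infl$vote_count,
               tissue = spots$tissue, darg_high = darg_high,
               stringsAsFactors = FALSE),
    class = c("darg_calls", "data.frame"))
}

#' Per-niche summary of DARG-high calls
#'
#' Counts DARG-high spots and averages AUC per spatial niche (lesion core,
#' lesion rim, perilesional WM, ...).
#'
#' @param calls a \code{darg_calls} data.frame from [call_darg_high()].
#' @param spot_table a \code{spot_table} with \code{niche} per spot.
#' @return data.frame with columns \code{niche}, \code{n_spots},
#'   \code{n_darg_high}, \code{fraction}, \code{mean_auc}.
#' @export
niche_summary <- function(calls, spot_table) {
  i <- match(calls$obs_id, spot_table$obs_id)
  if (anyNA(i)) stop("alignment error: spots missing from spot_table")
  niche <- spot_table$niche[i]
  if (anyNA(niche)) stop("every spot must carry a niche label")
  tot <- table(niche)
  n_high <- tapply(calls$darg_high, niche, sum)
  mean_auc <- tapply(calls$auc, niche, mean)
  nm <- names(tot)
  data.frame(niche = nm,
             n_spots = as.integer(tot),
             n_darg_high = as.integer(n_high[nm]),
             fraction = as.numeric(n_high[nm] / tot),
             mean_auc = as.numeric(mean_auc[nm]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Patient-level enrichment summary and group comparison
#'
#' Averages spot-level AUC scores per sample and compares the two groups
#' (e.g. Ctrl vs MS) with a two-sided rank test: an unpaired Wilcoxon
#' rank-sum test by default (exact when sample sizes permit and there are no
#' ties, normal approximation otherwise), or a paired signed-rank test when
#' \code{paired = TRUE} and the groups are matched by order.
#'
#' @param scores a \code{score_table} (columns \code{obs_id}, \code{auc}).
#' @param spot_table a \code{spot_table} with \code{sample_id} and
#'   \code{group} per spot.
#' @param paired use a paired signed-rank test instead of the rank-sum test.
#' @return list with \code{samples} (data.frame \code{sample_id},
#'   \code{group}, \code{n_spots}, \code{mean_auc}) and \code{test}
#'   (\code{htest} from [stats::wilcox.test()]).
#' @export
patient_summary <- function(scores, spot_table, paired = FALSE) {
  i <- match(scores$obs_id, spot_table$obs_id)
  if (anyNA(i)) stop("alignment error: spots missing from spot_table")
  sample_id <- spot_table$sample_id[i]
  group <- spot_table$group[i]
  per <- aggregate(list(mean_auc = scores$auc),
                   by = list(sample_id = sample_id), FUN = mean)
  per$group <- spot_table$group[match(per$sample_id, spot_table$sample_id)]
  per$n_spots <- as.integer(table(sample_id)[per$sample_id])
  per <- per[, c("sample_id", "group", "n_spots", "mean_auc")]
  groups <- unique(per$group)
  if (length(groups) != 2)
    stop("exactly two groups are required, found: ",
         paste(groups, collapse = ", "))
  a <- per$mean_auc[per$group == groups[1]]
  b <- per$mean_auc[per$group == groups[2]]
  if (!length(a) || !length(b)) stop("each group needs at least one sample")
  test <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", paired = paired,
                correct = FALSE))
  list(samples = per, test = test)
}

#' Quantile-binned Welch t-test
#'
#' Compares two sets of enrichment scores while mitigating the inflated
#' degrees of freedom of spot-level testing: within each group the values
#' are sorted and split into \code{n_bins} quantile bins whose sizes differ
#' by at most one, each bin is averaged, and the two vectors of bin means
#' are compared with an unpaired two-sided t-test (Welch by default).  When
#' \code{n_bins} equals the group size the procedure reduces exactly to a
#' t-test on the raw values.
#'
#' @param values_a,values_b numeric vectors, each of length >= \code{n_bins}.
#' @param n_bins number of quantile bins (>= 2), default 20.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with \code{t_statistic}, \code{df}, \code{p_two_sided},
#'   \code{bin_means_a}, \code{bin_means_b}.
#' @export
quantile_bin_test <- function(values_a, values_b, n_bins = 20L,
                              var_equal = FALSE) {
  n_bins <- assert_count(n_bins, "n_bins", lower = 2L)
  if (length(values_a) < n_bins || length(values_b) < n_bins)
    stop(sprintf("each group needs at least n_bins = %d values", n_bins))
  ma <- quantile_bin_means(values_a, n_bins)
  mb <- quantile_bin_means(values_b, n_bins)
  tt <- t.test(ma, mb, alternative = "two.sided", var.equal = var_equal)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, bin_means_a = ma, bin_means_b = mb)
}

## Sort, split into n_bins contiguous quantile bins with sizes differing by
## <= 1, and average each bin.
quantile_bin_means <- function(values, n_bins) {
  v <- sort(values)
  bounds <- round(seq(0, length(v), length.out = n_bins + 1))
  vapply(seq_len(n_bins),
         function(b) mean(v[(bounds[b] + 1):bounds[b + 1]]),
         numeric(1))
}

#' Correlate unit-level enrichment with a covariate
#'
#' Association between per-unit mean enrichment (e.g. niche-by-patient mean
#' AUC) and a covariate such as a deconvolved cell-type proportion.
#'
#' @param scores_by_unit,covariate_by_unit aligned numeric vectors, length
#'   >= 3.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{coefficient}, \code{p}, \code{method}, \code{n}.
#' @export
associate_covariate <- function(scores_by_unit, covariate_by_unit,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(scores_by_unit) != length(covariate_by_unit))
    stop("unit vectors must be aligned (equal length)")
  if (length(scores_by_unit) < 3) stop("at least 3 units are required")
  if (stats::sd(scores_by_unit) == 0 || stats::sd(covariate_by_unit) == 0)
    stop("undefined correlation: zero variance in one of the variables")
  ct <- suppressWarnings(
    cor.test(scores_by_unit, covariate_by_unit, method = method,
             alternative = "two.sided"))
  list(coefficient = unname(ct$estimate), p = ct$p.value,
       method = method, n = length(scores_by_unit))
}
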