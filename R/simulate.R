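#' Simulate a sparse single-cell count matrix with planted populations
#'
#' Draws negative-binomial UMI counts (variance \eqn{\mu + \mu^2 \phi},
#' dispersion \eqn{\phi}) over lognormally distributed per-gene base means
#' and a per-observation multiplicative lognormal library-size factor,
#' reproducing the empirical mean-variance structure of UMI data that the
#' library-size normalization assumes.  Planted populations occupy stated
#' fractions of the observations (remainder = background) and have the mean
#' of their signature genes multiplied by \eqn{2^{LFC}}.  Optional Bernoulli
#' dropout zeroes each count independently.  Deterministic given
#' \code{seed}.
#'
#' @param n_genes,n_obs dimensions of the matrix.
#' @param gene_mean_meanlog,gene_mean_sdlog lognormal parameters of the
#'   per-gene base mean; defaults log(0.28) and 0.15 emulate a curated gene
#'   panel on sparse spatial spots detecting roughly a quarter of the panel.
#' @param dispersion NB dispersion \eqn{\phi} (variance
#'   \eqn{\mu + \mu^2 \phi}); 0 gives Poisson counts.  Default 0.5.
#' @param libsize_meanlog,libsize_sdlog lognormal parameters of the
#'   per-observation library factor.
#' @param populations list of planted populations, each a list with
#'   \code{fraction} (of observations), \code{signature_genes} (character)
#'   and \code{log2_fold_change} (>= 0).  Fractions must sum to at most 1.
#' @param dropout_rate probability of zeroing any count, default 0.
#' @param seed integer seed.
#' @return list with \code{matrix} (an \code{\link{expression_matrix}},
#'   raw counts) and \code{truth} (list: \code{obs_labels} — planted
#'   population per observation, \code{"background"} otherwise — and
#'   \code{parameters}).
#' @export
simulate_counts <- function(n_genes, n_obs,
                            gene_mean_meanlog = log(0.28),
                            gene_mean_sdlog = 0.15,
                            dispersion = 0.5,
                            libsize_meanlog = 0, libsize_sdlog = 0.15,
                            populations = list(),
                            dropout_rate = 0, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", lower = 1L)
  n_obs <- assert_count(n_obs, "n_obs", lower = 1L)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  fracs <- vapply(populations, function(p) p$fraction, numeric(1))
  if (length(fracs) && (any(fracs < 0) || sum(fracs) > 1 + 1e-9))
    stop("population fractions must be non-negative and sum to at most 1")
  for (p in populations)
    if ((p$log2_fold_change %||% 0) < 0)
      stop("log2_fold_change must be non-negative")
  genes <- sprintf("G%05d", seq_len(n_genes))
  obs <- sprintf("OBS%06d", seq_len(n_obs))

  ## contiguous block assignment keeps planted fractions exact up to rounding
  labels <- rep("background", n_obs)
  at <- 0L
  for (pi in seq_along(populations)) {
    size <- floor(populations[[pi]]$fraction * n_obs)
    if (size > 0) labels[(at + 1L):(at + size)] <- paste0("pop", pi)
    at <- at + size
  }

  counts <- with_seed(seed, {
    mu_g <- rlnorm(n_genes, gene_mean_meanlog, gene_mean_sdlog)
    lib <- rlnorm(n_obs, libsize_meanlog, libsize_sdlog)
    mu <- outer(mu_g, lib)
    for (pi in seq_along(populations)) {
      p <- populations[[pi]]
      rows <- match(toupper(p$signature_genes), genes)
      if (anyNA(rows)) stop("population signature gene(s) outside the panel")
      cols <- which(labels == paste0("pop", pi))
      if (length(cols))
        mu[rows, cols] <- mu[rows, cols] * 2^(p$log2_fold_change %||% 0)
    }
    cnt <- if (dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else
      stats::rpois(length(mu), mu)
    if (dropout_rate > 0)
      cnt <- cnt * (rbinom(length(cnt), 1L, 1 - dropout_rate))
    matrix(cnt, n_genes, n_obs, dimnames = list(genes, obs))
  })
  list(matrix = expression_matrix(counts, layer = "raw_counts"),
       truth = list(obs_labels = stats::setNames(labels, obs),
                    parameters = list(
                      n_genes = n_genes, n_obs = n_obs,
                      gene_mean_meanlog = gene_mean_meanlog,
                      gene_mean_sdlog = gene_mean_sdlog,
                      dispersion = dispersion,
                      libsize_meanlog = libsize_meanlog,
                      libsize_sdlog = libsize_sdlog,
                      populations = populations,
                      dropout_rate = dropout_rate, seed = seed)))
}

## Niche of every grid spot for the concentric lesion layout: Euclidean
## distance from the grid center defines lesion core (LC), lesion rim (LR),
## perilesional (PLWM) and normal-appearing (NAWM) white matter.
concentric_niches <- function(grid_w, grid_h, lc_radius, lr_width, plwm_width) {
  if (lc_radius + lr_width + plwm_width > min(grid_w - 1, grid_h - 1) / 2)
    stop("layout exceeds grid: lc_radius + lr_width + plwm_width must fit ",
         "within half the grid extent")
  xy <- expand.grid(x = 0:(grid_w - 1), y = 0:(grid_h - 1))
  d <- sqrt((xy$x - (grid_w - 1) / 2)^2 + (xy$y - (grid_h - 1) / 2)^2)
  niche <- rep("NAWM", nrow(xy))
  niche[d <= lc_radius + lr_width + plwm_width] <- "PLWM"
  niche[d <= lc_radius + lr_width] <- "LR"
  niche[d <= lc_radius] <- "LC"
  cbind(xy, niche = niche, stringsAsFactors = FALSE)
}

## Gray-matter layout: stacked horizontal zones (neuronal-enrichment bands).
band_niches <- function(grid_w, grid_h, n_bands) {
  if (n_bands < 1 || n_bands > grid_h)
    stop("layout exceeds grid: n_bands must be between 1 and grid_h")
  xy <- expand.grid(x = 0:(grid_w - 1), y = 0:(grid_h - 1))
  band <- 1L + floor(xy$y * n_bands / grid_h)
  cbind(xy, niche = paste0("GMZ", band), stringsAsFactors = FALSE)
}

#' Simulate a spatial dataset with a planted lesion layout
#'
#' Lays a rectangular spot grid over a concentric white-matter lesion
#' (lesion core / rim / perilesional / normal-appearing WM, assigned by
#' Euclidean distance from the grid center) or stacked gray-matter zones,
#' plants DARG-truth spots per niche at the stated Bernoulli rates, and
#' up-shifts the radial-glia and inflammatory signature genes of those spots
#' by \code{log2_fold_change}.  Counts follow the [simulate_counts()]
#' negative-binomial model.  The default rates put most DARG spots at the
#' lesion rim, the enrichment pattern the calling pipeline is expected to
#' recover.
#'
#' @param grid_w,grid_h grid dimensions in spots; default 60 x 60.
#' @param layout \code{"concentric"} (WM lesion) or \code{"bands"} (GM
#'   zones).
#' @param lc_radius,lr_width,plwm_width concentric layout geometry in grid
#'   units; must fit within half the grid extent.
#' @param n_bands number of zones for the \code{bands} layout.
#' @param darg_rates named vector of per-niche DARG-truth rates; names must
#'   cover the layout's niches.  Default
#'   \code{c(LC = 0.01, LR = 0.06, PLWM = 0.03, NAWM = 0.005)}.
#' @param n_genes size of the gene panel, default 1000.
#' @param n_rg_genes,n_infl_genes sizes of the planted radial-glia and
#'   inflammatory signature subsets (the first genes of the panel), default
#'   20 each.
#' @param log2_fold_change mean shift of signature genes in DARG spots,
#'   default 2.
#' @param tissue \code{"WM"} or \code{"GM"} recorded in the spot table.
#' @param sample_id,group sample annotation for the spot table.
#' @param dropout_rate,dispersion,gene_mean_meanlog,gene_mean_sdlog,libsize_meanlog,libsize_sdlog
#'   count-model parameters, see [simulate_counts()].
#' @param seed integer seed.
#' @return list with \code{matrix} (raw counts), \code{spots} (a
#'   \code{spot_table}), \code{rg_genes}, \code{infl_genes}, and
#'   \code{truth} (list: \code{darg_truth} named logical per spot,
#'   \code{parameters}).
#' @export
simulate_spatial <- function(grid_w = 60, grid_h = 60,
                             layout = c("concentric", "bands"),
                             lc_radius = 10, lr_width = 8, plwm_width = 10,
                             n_bands = 4,
                             darg_rates = c(LC = 0.01, LR = 0.06,
                                            PLWM = 0.03, NAWM = 0.005),
                             n_genes = 1000,
                             n_rg_genes = 20, n_infl_genes = 20,
                             log2_fold_change = 2,
                             tissue = c("WM", "GM"),
                             sample_id = "S1", group = "MS",
                             gene_mean_meanlog = log(0.28),
                             gene_mean_sdlog = 0.15,
                             dispersion = 0.5,
                             libsize_meanlog = 0, libsize_sdlog = 0.15,
                             dropout_rate = 0, seed = 1L) {
  layout <- match.arg(layout)
  tissue <- match.arg(tissue)
  grid_w <- assert_count(grid_w, "grid_w", lower = 1L)
  grid_h <- assert_count(grid_h, "grid_h", lower = 1L)
  if (any(darg_rates < 0 | darg_rates > 1))
    stop("darg_rates must lie in [0, 1]")
  grid <- if (layout == "concentric")
    concentric_niches(grid_w, grid_h, lc_radius, lr_width, plwm_width)
  else band_niches(grid_w, grid_h, n_bands)
  missing_rates <- setdiff(unique(grid$niche), names(darg_rates))
  if (length(missing_rates))
    stop("darg_rates missing for niche(s): ",
         paste(missing_rates, collapse = ", "))
  n_obs <- nrow(grid)
  genes <- sprintf("G%05d", seq_len(n_genes))
  if (n_rg_genes + n_infl_genes > n_genes)
    stop("signature subsets exceed the gene panel")
  rg_genes <- genes[seq_len(n_rg_genes)]
  infl_genes <- genes[n_rg_genes + seq_len(n_infl_genes)]
  obs <- paste0(sample_id, ":", grid$x, "x", grid$y)

  sim <- with_seed(seed, {
    darg_truth <- runif(n_obs) < darg_rates[grid$niche]
    mu_g <- rlnorm(n_genes, gene_mean_meanlog, gene_mean_sdlog)
    lib <- rlnorm(n_obs, libsize_meanlog, libsize_sdlog)
    mu <- outer(mu_g, lib)
    sig_rows <- seq_len(n_rg_genes + n_infl_genes)
    mu[sig_rows, darg_truth] <- mu[sig_rows, darg_truth] * 2^log2_fold_change
    cnt <- if (dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else
      stats::rpois(length(mu), mu)
    if (dropout_rate > 0)
      cnt <- cnt * rbinom(length(cnt), 1L, 1 - dropout_rate)
    list(counts = matrix(cnt, n_genes, n_obs,
                         dimnames = list(genes, obs)),
         darg_truth = stats::setNames(as.logical(darg_truth), obs))
  })
  spots <- as_spot_table(data.frame(
    obs_id = obs, x = grid$x, y = grid$y, tissue = tissue,
    niche = grid$niche, sample_id = sample_id, group = group,
    stringsAsFactors = FALSE))
  list(matrix = expression_matrix(sim$counts, layer = "raw_counts"),
       spots = spots, rg_genes = rg_genes, infl_genes = infl_genes,
       truth = list(darg_truth = sim$darg_truth,
                    parameters = list(
                      grid_w = grid_w, grid_h = grid_h, layout = layout,
                      lc_radius = lc_radius, lr_width = lr_width,
                      plwm_width = plwm_width, n_bands = n_bands,
                      darg_rates = as.list(darg_rates), n_genes = n_genes,
                      n_rg_genes = n_rg_genes, n_infl_genes = n_infl_genes,
                      log2_fold_change = log2_fold_change, tissue = tissue,
                      gene_mean_meanlog = gene_mean_meanlog,
                      gene_mean_sdlog = gene_mean_sdlog,
                      dispersion = dispersion,
                      libsize_meanlog = libsize_meanlog,
                      libsize_sdlog = libsize_sdlog,
                      dropout_rate = dropout_rate, seed = seed)))
}

#' Simulate paired gene-module collections with a planted mapping
#'
#' Builds a baseline collection of gene modules and a query collection in
#' which each query module shares genes with exactly one planted baseline
#' partner at the requested Jaccard overlap (plus hypergeometric background
#' overlap with non-partners from random fill genes).  Used to validate
#' [match_modules()]: the recovered best-match mapping should equal the
#' planted one.
#'
#' @param universe_size size of the gene universe.
#' @param n_modules number of modules per collection.
#' @param module_size_range integer range the module sizes are drawn from.
#' @param planted_jaccard target Jaccard index between a query module and
#'   its baseline partner, in (0, 1].
#' @param noise_genes number of extra genes per query module sampled from
#'   other baseline modules (cross-contamination), default 0.
#' @param seed integer seed.
#' @return list with \code{baseline}, \code{query} (named lists of gene
#'   vectors), \code{mapping} (data.frame baseline_id, query_id) and
#'   \code{parameters}.
#' @export
simulate_module_sets <- function(universe_size, n_modules = 5,
                                 module_size_range = c(40, 60),
                                 planted_jaccard = 0.5, noise_genes = 0,
                                 seed = 1L) {
  universe_size <- assert_count(universe_size, "universe_size", lower = 2L)
  n_modules <- assert_count(n_modules, "n_modules", lower = 1L)
  assert_scalar_number(planted_jaccard, "planted_jaccard",
                       lower = 1e-12, upper = 1)
  noise_genes <- assert_count(noise_genes, "noise_genes")
  if (max(module_size_range) + noise_genes > universe_size)
    stop("infeasible module sizes for this universe")
  universe <- sprintf("U%05d", seq_len(universe_size))
  out <- with_seed(seed, {
    baseline <- list(); query <- list()
    sizes <- seq(module_size_range[1], module_size_range[2])
    for (i in seq_len(n_modules)) {
      sA <- sizes[sample.int(length(sizes), 1)]
      sB <- sizes[sample.int(length(sizes), 1)]
      A <- sample(universe, sA)
      a <- round(planted_jaccard * (sA + sB) / (1 + planted_jaccard))
      a <- max(1L, min(a, sA, sB))
      B <- c(sample(A, a), sample(setdiff(universe, A), sB - a))
      baseline[[paste0("M", i)]] <- A
      query[[paste0("Q", i)]] <- B
    }
    if (noise_genes > 0)
      for (i in seq_len(n_modules)) {
        others <- unique(unlist(baseline[-i]))
        extra <- sample(setdiff(others, query[[i]]),
                        min(noise_genes, length(setdiff(others, query[[i]]))))
        query[[i]] <- unique(c(query[[i]], extra))
      }
    list(baseline = baseline, query = query)
  })
  list(baseline = out$baseline, query = out$query,
       mapping = data.frame(baseline_id = paste0("M", seq_len(n_modules)),
                            query_id = paste0("Q", seq_len(n_modules)),
                            stringsAsFactors = FALSE),
       parameters = list(universe_size = universe_size,
                         n_modules = n_modules,
                         module_size_range = module_size_range,
                         planted_jaccard = planted_jaccard,
                         noise_genes = noise_genes, seed = seed),
       universe = universe)
}
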