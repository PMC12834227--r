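make_calls_input <- function(df) {
  spot <- as_spot_table(data.frame(
    obs_id = df$obs_id, x = seq_len(nrow(df)) - 1, y = 0,
    tissue = df$tissue, niche = df$niche %||% "LR",
    sample_id = df$sample_id %||% "S1", group = df$group %||% "MS",
    stringsAsFactors = FALSE))
  scores <- data.frame(obs_id = df$obs_id, auc = df$auc)
  rg <- data.frame(obs_id = df$obs_id, vote_count = df$rg)
  infl <- data.frame(obs_id = df$obs_id, vote_count = df$infl)
  list(scores = scores, rg = rg, infl = infl, spots = spot)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("DARG-high calling applies strict dual criteria per tissue", {
  df <- data.frame(
    obs_id = c("wm_hi", "wm_rg_at_gate", "gm_auc_low", "gm_hi", "wm_auc_low"),
    tissue = c("WM", "WM", "GM", "GM", "WM"),
    auc    = c(0.30, 0.30, 0.10, 0.30, 0.10),
    rg     = c(7L, 6L, 10L, 5L, 9L),
    infl   = c(7L, 9L, 10L, 5L, 9L))
  inp <- make_calls_input(df)
  calls <- call_darg_high(inp$scores, 0.2, inp$rg, inp$infl, inp$spots)
  expect_equal(calls$darg_high,
               c(TRUE,   # WM: auc above, rg 7 > 6 and infl 7 > 6
                 FALSE,  # WM boundary: rg exactly 6 fails the strict > 6
                 FALSE,  # GM: counts high but AUC gate fails
                 TRUE,   # GM: 5 > 4 on both subsets, AUC above
                 FALSE)) # WM: AUC gate fails
  expect_true(all(calls$darg_high <= calls$passed_auc))
  expect_error(call_darg_high(inp$scores, 0.2, inp$rg[-1, ], inp$infl,
                              inp$spots), "alignment")
})

test_that("DARG-high set shrinks monotonically as thresholds rise", {
  set.seed(31)
  n <- 200
  df <- data.frame(obs_id = sprintf("s%03d", 1:n),
                   tissue = sample(c("WM", "GM"), n, TRUE),
                   auc = runif(n), rg = rpois(n, 6), infl = rpois(n, 6))
  inp <- make_calls_input(df)
  base <- call_darg_high(inp$scores, 0.3, inp$rg, inp$infl, inp$spots,
                         wm_gene_threshold = 5, gm_gene_threshold = 3)
  for (thr in c(0.4, 0.6)) {
    higher <- call_darg_high(inp$scores, thr, inp$rg, inp$infl, inp$spots,
                             wm_gene_threshold = 5, gm_gene_threshold = 3)
    expect_true(all(higher$darg_high <= base$darg_high))
  }
  for (g in c(6, 8)) {
    stricter <- call_darg_high(inp$scores, 0.3, inp$rg, inp$infl, inp$spots,
                               wm_gene_threshold = g, gm_gene_threshold = g - 2)
    expect_true(all(stricter$darg_high <= base$darg_high))
  }
})

test_that("niche summaries are exact aggregations", {
  set.seed(12)
  n <- 120
  niches <- sample(c("LC", "LR", "PLWM", "NAWM"), n, TRUE)
  df <- data.frame(obs_id = sprintf("s%03d", 1:n), tissue = "WM",
                   auc = runif(n), rg = rpois(n, 8), infl = rpois(n, 8),
                   niche = niches)
  inp <- make_calls_input(df)
  calls <- call_darg_high(inp$scores, 0.5, inp$rg, inp$infl, inp$spots)
  ns <- niche_summary(calls, inp$spots)
  expect_equal(sum(ns$n_spots), n)
  for (k in seq_len(nrow(ns))) {
    idx <- niches == ns$niche[k]
    expect_equal(ns$n_darg_high[k], sum(calls$darg_high[idx]))
    expect_equal(ns$mean_auc[k], mean(calls$auc[idx]))
    expect_equal(ns$fraction[k], mean(calls$darg_high[idx]))
  }
  # no positive spots -> all fractions zero; single niche -> one row
  none <- call_darg_high(inp$scores, 2, inp$rg, inp$infl, inp$spots)
  expect_true(all(niche_summary(none, inp$spots)$fraction == 0))
  one <- inp$spots; one$niche <- "LR"
  expect_equal(nrow(niche_summary(calls, one)), 1L)
})

test_that("patient summaries average per sample and rank-test the groups", {
  mk <- function(mean_auc_by_sample, groups) {
    spots <- do.call(rbind, lapply(names(mean_auc_by_sample), function(s)
      data.frame(obs_id = paste0(s, "_", 1:4), x = 1:4,
                 y = match(s, names(mean_auc_by_sample)), tissue = "WM",
                 niche = "LR", sample_id = s, group = groups[[s]])))
    scores <- data.frame(
      obs_id = spots$obs_id,
      auc = unlist(lapply(mean_auc_by_sample, function(mu) mu + c(-0.02, -0.01, 0.01, 0.02))))
    list(scores = scores, spots = as_spot_table(spots))
  }
  # fully separated two-vs-two: exact rank-sum p = 2 / choose(4,2) = 1/3
  inp <- mk(c(a = 0.1, b = 0.2, c = 0.7, d = 0.8),
            c(a = "Ctrl", b = "Ctrl", c = "MS", d = "MS"))
  ps <- patient_summary(inp$scores, inp$spots)
  expect_equal(sort(ps$samples$mean_auc), c(0.1, 0.2, 0.7, 0.8))
  expect_equal(ps$test$p.value, 1 / 3, tolerance = 1e-12)
  # identical groups -> p = 1
  inp2 <- mk(c(a = 0.1, b = 0.2, c = 0.1, d = 0.2),
             c(a = "Ctrl", b = "Ctrl", c = "MS", d = "MS"))
  expect_equal(patient_summary(inp2$scores, inp2$spots)$test$p.value, 1)
  # rank invariance under a constant shift
  inp3 <- inp
  inp3$scores$auc <- inp3$scores$auc + 0.05
  expect_equal(patient_summary(inp3$scores, inp3$spots)$test$p.value,
               ps$test$p.value)
  # a single group is an error
  expect_error(patient_summary(inp$scores,
    transform(inp$spots, group = "MS")), "two groups")
})

test_that("quantile-binned t-test reduces, conserves means, and matches an oracle", {
  set.seed(77)
  a <- rnorm(1000, 0, 1)
  b <- rnorm(1000, 0.1, 1)
  res <- quantile_bin_test(a, b, n_bins = 20)
  # oracle: sort, split into equal bins, average, textbook Welch formula
  bm <- function(v, B) {
    v <- sort(v); n <- length(v)
    sapply(split(v, rep(1:B, each = n / B)), mean)
  }
  ma <- bm(a, 20); mb <- bm(b, 20)
  se <- sqrt(var(ma) / 20 + var(mb) / 20)
  t_oracle <- (mean(ma) - mean(mb)) / se
  df_oracle <- se^4 / ((var(ma) / 20)^2 / 19 + (var(mb) / 20)^2 / 19)
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, df_oracle, tolerance = 1e-10)
  expect_equal(res$p_two_sided, p_oracle, tolerance = 1e-10)
  # conservation: mean of bin means equals the group mean when divisible
  expect_equal(mean(res$bin_means_a), mean(a), tolerance = 1e-12)
  # identical groups -> t = 0, p = 1
  eq <- quantile_bin_test(a, a, n_bins = 10)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_two_sided, 1)
  # n_bins equal to group sizes reduces to a plain Welch t-test on raw values
  sa <- rnorm(30); sb <- rnorm(30, 0.5)
  red <- quantile_bin_test(sa, sb, n_bins = 30)
  plain <- t.test(sa, sb)
  expect_equal(red$t_statistic, unname(plain$statistic), tolerance = 1e-12)
  expect_equal(red$p_two_sided, plain$p.value, tolerance = 1e-12)
  expect_error(quantile_bin_test(a, b, n_bins = 1), "n_bins")
  expect_error(quantile_bin_test(rnorm(5), b, n_bins = 10), "at least")
})

test_that("uneven quantile bins differ in size by at most one", {
  v <- rnorm(47)
  ms <- dargspot:::quantile_bin_means(v, 10)
  bounds <- round(seq(0, 47, length.out = 11))
  sizes <- diff(bounds)
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_equal(sum(sizes), 47)
  expect_length(ms, 10)
})

test_that("covariate association recovers exact and random correlations", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  expect_equal(associate_covariate(x, x)$coefficient, 1)
  expect_equal(associate_covariate(x, -x)$coefficient, -1)
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  res <- associate_covariate(a, b, "pearson")
  r_closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$coefficient, r_closed, tolerance = 1e-12)
  expect_equal(res$p, cor.test(a, b)$p.value)
  sp <- associate_covariate(a, b, "spearman")
  expect_equal(sp$coefficient, cor(a, b, method = "spearman"))
  expect_error(associate_covariate(rep(1, 5), x), "zero variance")
  expect_error(associate_covariate(a[1:2], b[1:2]), "3 units")
})
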