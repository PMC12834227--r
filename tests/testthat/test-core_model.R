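test_that("MTX triplet round-trips losslessly for random sparse count matrices", {
  dir <- withr::local_tempdir()
  for (seed in 1:20) {
    m <- random_counts(30, 12, seed)
    em <- expression_matrix(m, "raw_counts")
    write_counts(em, dir)
    back <- read_counts(file.path(dir, "matrix.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"))
    expect_identical(dim(back), dim(em))
    expect_equal(as.matrix(back$values), as.matrix(em$values))
    expect_identical(gene_ids(back), gene_ids(em))
    expect_identical(obs_ids(back), obs_ids(em))
  }
})

test_that("read_counts handles toy, empty and malformed triplets", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 4", "1 1 5", "2 1 1", "3 2 2", "1 2 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("GeneA", "GeneB", "GeneC"), file.path(dir, "features.tsv"))
  writeLines(c("BC1", "BC2"), file.path(dir, "barcodes.tsv"))
  em <- read_counts(file.path(dir, "matrix.mtx"),
                    file.path(dir, "features.tsv"),
                    file.path(dir, "barcodes.tsv"))
  expect_equal(length(em$values@x), 4)
  expect_equal(unname(as.matrix(em$values)["GeneA", "BC2"]), 7)

  # header-only triplet -> all-zero matrix with stated dimensions
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "matrix.mtx"))
  empty <- read_counts(file.path(dir, "matrix.mtx"),
                       file.path(dir, "features.tsv"),
                       file.path(dir, "barcodes.tsv"))
  expect_identical(dim(empty), c(3L, 2L))
  expect_true(all(as.matrix(empty$values) == 0))

  # features/dimension mismatch
  writeLines(c("GeneA", "GeneB"), file.path(dir, "features.tsv"))
  expect_error(read_counts(file.path(dir, "matrix.mtx"),
                           file.path(dir, "features.tsv"),
                           file.path(dir, "barcodes.tsv")),
               "format error")
})

test_that("duplicate gene symbols are disambiguated deterministically in file order", {
  expect_identical(disambiguate_symbols(c("A", "B", "A", "A", "C")),
                   c("A", "B", "A.1", "A.2", "C"))
})

test_that("normalization matches the closed form and preserves zeros and order", {
  m <- random_counts(50, 20, seed = 3, lambda = 2)
  m <- m[, colSums(m) > 0]
  em <- expression_matrix(m, "raw_counts")
  for (base in c(2, exp(1))) {
    norm <- normalize_counts(em, scale_factor = 10000, log_base = base)
    expected <- log(1 + t(t(m) / colSums(m)) * 10000, base = base)
    expect_equal(as.matrix(norm$values), expected, tolerance = 1e-12)
    expect_identical(norm$layer, "normalized")
  }
  # zero preservation and single-gene closed form
  single <- expression_matrix(matrix(c(7L, 0L), 2, 1,
    dimnames = list(c("A", "B"), "c")), "raw_counts")
  n <- normalize_counts(single, scale_factor = 10000, log_base = 2)
  expect_equal(unname(as.matrix(n$values)[, 1]), c(log2(1 + 10000), 0))
})

test_that("normalization is monotone within each observation", {
  m <- random_counts(80, 10, seed = 11, lambda = 3)
  m <- m[, colSums(m) > 0]
  norm <- normalize_counts(expression_matrix(m, "raw_counts"))
  nm <- as.matrix(norm$values)
  for (j in seq_len(ncol(m))) {
    ord <- order(m[, j])
    expect_true(all(diff(nm[ord, j]) * (diff(m[ord, j]) > 0) >= 0))
    expect_true(all(diff(nm[ord, j])[diff(m[ord, j]) > 0] > 0))
  }
})

test_that("normalize refuses zero-total observations and non-raw layers", {
  m <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("A", "B"), c("c1", "c2")))
  expect_error(normalize_counts(expression_matrix(m, "raw_counts")),
               "filter_observations")
  norm <- normalize_counts(expression_matrix(m[, 1, drop = FALSE], "raw_counts"))
  expect_error(normalize_counts(norm), "raw_counts")
})

test_that("observation filter applies a strict threshold and matches brute-force counting", {
  set.seed(42)
  m <- random_counts(300, 30, seed = 42, lambda = 0.5)
  em <- expression_matrix(m, "raw_counts")
  thr <- 100L
  kept <- filter_observations(em, thr)
  brute <- colnames(m)[colSums(m > 0) > thr]
  expect_identical(obs_ids(kept), brute)

  # boundary: exactly thr detected genes -> removed; thr+1 -> kept
  mb <- matrix(0L, 150, 2, dimnames = list(sprintf("g%03d", 1:150), c("at", "above")))
  mb[1:100, "at"] <- 1L
  mb[1:101, "above"] <- 1L
  fb <- filter_observations(expression_matrix(mb, "raw_counts"), 100)
  expect_identical(obs_ids(fb), "above")

  # idempotence and subset property
  expect_identical(obs_ids(filter_observations(kept, thr)), obs_ids(kept))
  expect_true(all(obs_ids(kept) %in% obs_ids(em)))
  expect_error(filter_observations(em, 10000), "nothing retained")
})

test_that("expression_matrix enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "A"), c("c1", "c2")))
  expect_error(expression_matrix(m, "raw_counts"), "duplicate gene")
  m2 <- matrix(c(0.5, 1, 1, 1), 2, 2,
               dimnames = list(c("A", "B"), c("c1", "c2")))
  expect_error(expression_matrix(m2, "raw_counts"), "integer")
  expect_s3_class(expression_matrix(m2, "normalized"), "expression_matrix")
  m3 <- matrix(c(-1, 1, 1, 1), 2, 2,
               dimnames = list(c("A", "B"), c("c1", "c2")))
  expect_error(expression_matrix(m3, "normalized"), "non-negative")
})

test_that("signature reading parses GMT, dedups, and validates voting parameters", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(paste(c("RG", "desc", paste0("g", 1:9)), collapse = "\t"),
               paste(c("DUP", "desc", "a", "b", "a"), collapse = "\t")), gmt)
  expect_warning(sigs <- read_signatures(gmt, "gmt",
    params = list(RG = list(min_genes = 6, expr_threshold = 1))),
    "duplicate")
  expect_length(sigs$RG$genes, 9)
  expect_equal(sigs$RG$min_genes, 6L)
  expect_equal(sigs$RG$expr_threshold, 1)
  expect_length(sigs$DUP$genes, 2)

  # k > n is an invariant violation
  expect_error(read_signatures(gmt, "gmt",
    params = list(DUP = list(min_genes = 10))) |> suppressWarnings(),
    "exceeds")
  # malformed line carries its line number
  writeLines(c("ok\tdesc\tg1", "badline"), gmt)
  expect_error(read_signatures(gmt, "gmt"), "line 2")
  expect_error(gene_signature("empty", character(0)), "empty")
})

test_that("gene_signature k and tolerance parameterizations round-trip", {
  s1 <- gene_signature("s", paste0("g", 1:9), min_genes = 6)
  s2 <- gene_signature("s", paste0("g", 1:9), tolerance = 3)
  expect_equal(s1$min_genes, s2$min_genes)
  expect_equal(s1$tolerance, 3L)
  expect_error(gene_signature("s", paste0("g", 1:9), min_genes = 6, tolerance = 2),
               "inconsistent")
})

test_that("spot table validation enforces schema, coordinates and vocabulary", {
  df <- data.frame(obs_id = c("a", "b"), x = 0:1, y = c(0, 0),
                   tissue = "WM", niche = c("LC", "LR"),
                   sample_id = "S1", group = "MS")
  expect_s3_class(as_spot_table(df), "spot_table")
  expect_error(as_spot_table(df[, -3]), "missing column")
  expect_error(as_spot_table(transform(df, obs_id = "a")), "duplicate obs_id")
  expect_error(as_spot_table(transform(df, x = c(-1, 1))), "non-negative")
  expect_error(as_spot_table(transform(df, tissue = "XX")), "tissue")
  expect_error(as_spot_table(df, niche_vocabulary = c("LC")), "unknown niche")
})

test_that("config reader rejects unknown keys and merges defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "null.n_perm: 100"), f)
  cfg <- read_config(f)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$null.n_perm, 100)
  expect_equal(cfg$darg.wm_gene_threshold, default_config()$darg.wm_gene_threshold)
  writeLines("no.such.key: 1", f)
  expect_error(read_config(f), "accepted keys")
})
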