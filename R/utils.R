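#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rlnorm rnbinom runif rbinom rnorm t.test
#'   wilcox.test cor.test p.adjust dhyper aggregate setNames
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG state afterwards.  All stochastic entry points funnel through
## this so that nothing in the package perturbs (or depends on) the global
## RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

## Deterministic per-observation sub-seed derived from (seed, index), kept
## within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < lower)
    stop(sprintf("'%s' must be a single integer >= %d", name, lower), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
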