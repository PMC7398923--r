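#' @useDynLib insectseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm
#' @importFrom utils write.csv modifyList
NULL

ANATOMY_CLASSES <- c("thorax", "abdomen", "wing", "leg")

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a per-item 31-bit seed from a master seed (stable, order-independent).
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 7919 + as.double(i) * 104729) %% 2147483647)
}

msg <- function(...) message(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
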