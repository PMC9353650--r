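#' @keywords internal
"_PACKAGE"

# ---- seeded RNG streams -----------------------------------------------------
# Each stochastic component (sampler, trainer, generator) owns an independent
# RNG stream so that results depend only on (seed, call order) within that
# component, never on unrelated draws elsewhere in the session.

#' Create an independent seeded RNG stream
#'
#' Returns an environment holding a private `.Random.seed` state initialized
#' from `seed`. Draws made through [rng_eval()] advance this stream without
#' touching the session RNG.
#'
#' @param seed Integer seed.
#' @return An environment of class `"atsvit_rng"`.
#' @export
make_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "atsvit_rng"
  e
}

#' Evaluate an expression under a private RNG stream
#'
#' Swaps in the stream's state, evaluates `expr`, records the advanced state,
#' and restores the session RNG.
#'
#' @param rng An object from [make_rng()].
#' @param expr Expression performing random draws.
#' @return The value of `expr`.
#' @export
rng_eval <- function(rng, expr) {
  stopifnot(inherits(rng, "atsvit_rng"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# ---- numerics ---------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# exact GELU and its derivative; x * Phi(x)
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# numerically stable row-wise softmax (row max located via max.col, which is
# far cheaper than apply for the many small matrices seen per forward pass)
row_softmax <- function(z) {
  rmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - rmax)
  e / rowSums(e)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# log(sigmoid(x)) computed stably: -log1p(exp(-x)) for x >= 0, x - log1p(exp(x)) else
log_sigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

# one-hot matrix from 1-based integer labels
one_hot <- function(y, n_classes) {
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y)] <- 1
  m
}
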