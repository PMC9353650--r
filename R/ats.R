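# Adaptive token sampling: attention, CLS-row significance scores, score CDF,
# inverse transform sampling, and token selection. Token index 1 is always the
# CLS token; patch tokens occupy positions 2..N+1.

#' Scaled dot-product attention matrix
#'
#' Computes the row-stochastic attention matrix
#' \eqn{A = \mathrm{softmax}(Q K^\top / \sqrt{d})} of a self-attention layer.
#'
#' @param Q,K Query and key matrices, each `(N+1) x d` with the CLS token in
#'   row 1.
#' @param d Key dimensionality used in the scaling factor; defaults to
#'   `ncol(K)`.
#' @return An `(N+1) x (N+1)` matrix whose rows are probability vectors.
#' @export
compute_attention <- function(Q, K, d = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K)
  if (ncol(Q) != ncol(K)) {
    stop(sprintf("query/key dimension mismatch: ncol(Q) = %d, ncol(K) = %d",
                 ncol(Q), ncol(K)))
  }
  if (nrow(Q) != nrow(K)) {
    stop(sprintf("query/key token-count mismatch: nrow(Q) = %d, nrow(K) = %d",
                 nrow(Q), nrow(K)))
  }
  stopifnot(d >= 1)
  row_softmax(tcrossprod(Q, K) / sqrt(d))
}

#' Pre-sampling output tokens
#'
#' The block output before any token is dropped: `O = A %*% V`.
#'
#' @param A Attention matrix from [compute_attention()].
#' @param V Value matrix with `nrow(V) == ncol(A)`.
#' @return Matrix of output tokens, one row per input token.
#' @export
output_tokens <- function(A, V) {
  A <- as.matrix(A); V <- as.matrix(V)
  if (ncol(A) != nrow(V)) {
    stop(sprintf("attention/value shape mismatch: ncol(A) = %d, nrow(V) = %d",
                 ncol(A), nrow(V)))
  }
  A %*% V
}

#' Token significance scores and their CDF
#'
#' Scores patch token `j` by how strongly the CLS token attends to it, weighted
#' by the magnitude of its value row:
#' \eqn{S_j = A_{1,j}\,\lVert V_j\rVert \, / \, \sum_{i=2}^{N+1} A_{1,i}\,\lVert V_i\rVert}.
#' The CLS token itself (position 1) is excluded: it carries the classification
#' information and is never a sampling candidate. The cumulative sums of `S`
#' form the sampling CDF.
#'
#' With multi-head attention, pass the per-head matrices as an
#' `(N+1) x (N+1) x heads` array; heads are averaged before scoring, which
#' reduces exactly to the single-matrix formula when `heads == 1`.
#'
#' @param A Attention matrix, or a 3-D array of per-head attention matrices.
#' @param V Value matrix (`(N+1) x d`), rows aligned with the tokens of `A`.
#' @return An object of class `"ats_scores"`: a list with `S` (length-`N`
#'   probability vector over patch tokens) and `cdf` (its cumulative sums).
#' @export
significance_scores <- function(A, V) {
  if (is.array(A) && length(dim(A)) == 3L) A <- rowSums(A, dims = 2L) / dim(A)[3L]
  A <- as.matrix(A); V <- as.matrix(V)
  n <- nrow(A)
  if (ncol(A) != n) stop("attention matrix must be square")
  if (nrow(V) != n) {
    stop(sprintf("attention/value row mismatch: nrow(A) = %d, nrow(V) = %d",
                 n, nrow(V)))
  }
  if (n < 2L) stop("need at least one patch token besides CLS")
  vnorm <- sqrt(rowSums(V^2))
  w <- A[1L, 2:n] * vnorm[2:n]
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    stop(structure(
      class = c("atsvit_degenerate_scores", "error", "condition"),
      list(message = "all significance numerators are zero; scores are degenerate",
           call = sys.call(-1L))))
  }
  S <- w / tot
  structure(list(S = S, cdf = cumsum(S)), class = "ats_scores")
}

uniform_scores <- function(n_patch) {
  S <- rep(1 / n_patch, n_patch)
  structure(list(S = S, cdf = cumsum(S)), class = "ats_scores")
}

#' Sampler configuration
#'
#' @param K Maximum number of retained patch tokens (the sampling budget).
#' @param mode `"stochastic"` draws K uniforms from U\[0,1\] (the training
#'   default); `"deterministic-quantile"` uses the midpoint quantiles
#'   `(i - 0.5)/K` for reproducible evaluation; `"deterministic-topup"` is the
#'   quantile rule followed by topping up with the highest-score unsampled
#'   indices until exactly `min(K, N)` tokens are kept (used internally so the
#'   two consistency-training branches retain equal token counts).
#' @param seed RNG seed for the sampler's private stream.
#' @return A list of class `"sampler_config"` with an attached RNG stream.
#' @export
sampler_config <- function(K,
                           mode = c("stochastic", "deterministic-quantile",
                                    "deterministic-topup"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(K >= 1)
  structure(list(K = as.integer(K), mode = mode, seed = as.integer(seed),
                 rng = make_rng(seed)),
            class = "sampler_config")
}

# Generalized inverse of a step CDF: smallest index i with cdf[i] >= u.
# Vectorized over u; returns 1-based patch-list indices.
cdf_inverse <- function(cdf, u) findInterval(u, cdf, left.open = TRUE) + 1L

#' Inverse transform sampling of patch-token indices
#'
#' Draws token indices through the generalized inverse of the significance-score
#' CDF (the smallest index whose CDF reaches the drawn quantile), then removes
#' duplicates, yielding `K' <= K` distinct indices. When `K >= N` all patch
#' tokens are returned. Returned indices are token positions in `2..N+1`
#' (position 1, the CLS token, is never sampled), in ascending order.
#'
#' @param scores An `"ats_scores"` object from [significance_scores()].
#' @param cfg A [sampler_config()].
#' @param return_raw If `TRUE`, attach the raw pre-deduplication draws (patch
#'   list indices `1..N`) as attribute `"raw"`.
#' @return Integer vector of distinct token indices, attribute `"k_prime"`
#'   giving its length.
#' @export
inverse_transform_sample <- function(scores, cfg, return_raw = FALSE) {
  stopifnot(inherits(scores, "ats_scores"), inherits(cfg, "sampler_config"))
  n <- length(scores$S)
  K <- cfg$K
  if (K >= n) {
    idx <- seq_len(n)
    raw <- idx
  } else {
    u <- switch(cfg$mode,
      "stochastic" = rng_eval(cfg$rng, stats::runif(K)),
      (seq_len(K) - 0.5) / K)  # both deterministic modes share the quantiles
    raw <- cdf_inverse(scores$cdf, u)
    idx <- sort(unique(raw))
    if (cfg$mode == "deterministic-topup" && length(idx) < K) {
      missing <- setdiff(order(scores$S, decreasing = TRUE), idx)
      idx <- sort(c(idx, missing[seq_len(K - length(idx))]))
    }
  }
  out <- idx + 1L  # shift to token positions (CLS occupies position 1)
  attr(out, "k_prime") <- length(out)
  if (return_raw) attr(out, "raw") <- raw
  out
}

#' Select retained tokens
#'
#' Gathers the CLS row plus the sampled rows of the pre-sampling output `O`,
#' preserving ascending original order, and subsets the patch-coordinate map
#' alongside.
#'
#' @param O Token matrix with CLS in row 1.
#' @param idx Token positions from [inverse_transform_sample()] (all in
#'   `2..nrow(O)`).
#' @param patch_map Optional integer vector mapping patch tokens (rows
#'   `2..nrow(O)`) to original patch-grid indices.
#' @return List with `tokens` (`(K'+1) x d`, CLS first) and `patch_map`
#'   (length `K'`, or `NULL`).
#' @export
select_tokens <- function(O, idx, patch_map = NULL) {
  O <- as.matrix(O)
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 2L) || any(idx > nrow(O))) {
    stop(sprintf("token index out of range [2, %d]", nrow(O)))
  }
  keep <- c(1L, idx)
  list(tokens = O[keep, , drop = FALSE],
       patch_map = if (!is.null(patch_map)) patch_map[idx - 1L])
}
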