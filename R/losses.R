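# The three training losses: one-vs-all binary cross-entropy on logits,
# pseudo-label MSE on class probabilities, and an Earth Mover's distance on
# token sequences solved exactly by optimal one-to-one assignment.

#' One-vs-all binary cross-entropy with logits
#'
#' Element-wise binary cross-entropy between `sigmoid(logits)` and one-hot
#' targets, averaged over every element of the batch, computed in the
#' numerically stable logits formulation
#' `max(z,0) - z*y + log(1 + exp(-|z|))`.
#'
#' @param logits `batch x n_classes` matrix of raw scores.
#' @param targets One-hot target matrix of the same shape (entries in \[0,1\]).
#' @return Scalar loss with attribute `"grad"`, the gradient with respect to
#'   `logits`.
#' @export
bce_with_logits <- function(logits, targets) {
  logits <- as.matrix(logits); targets <- as.matrix(targets)
  if (!all(dim(logits) == dim(targets))) stop("logits/targets shape mismatch")
  if (any(targets < 0 | targets > 1)) stop("targets must lie in [0, 1]")
  z <- logits; y <- targets
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  structure(loss, grad = (sigmoid(z) - y) / length(z))
}

#' Pseudo-label consistency loss
#'
#' Mean squared error between the class-probability vectors of an unlabeled
#' image and its augmented version: `(1/m) * sum_u ||p_clean_u - p_aug_u||^2`.
#' The clean branch plays the role of a fixed pseudo-label; its gradient is
#' not propagated (the returned gradient is with respect to `p_aug` only).
#'
#' @param p_clean,p_aug `m x n_classes` probability matrices for the clean and
#'   augmented branches.
#' @return Scalar loss with attribute `"grad"` (gradient w.r.t. `p_aug`).
#' @export
pseudo_label_mse <- function(p_clean, p_aug) {
  p_clean <- as.matrix(p_clean); p_aug <- as.matrix(p_aug)
  if (!all(dim(p_clean) == dim(p_aug))) stop("clean/augmented batch shape mismatch")
  m <- nrow(p_clean)
  d <- p_aug - p_clean
  structure(sum(d^2) / m, grad = 2 * d / m)
}

# Exact linear sum assignment by shortest augmenting paths with potentials
# (O(n^3)); returns perm with perm[i] = column assigned to row i.
solve_lsap <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- logical(n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}

#' Earth Mover's distance between two token sequences
#'
#' Minimum over all permutations \eqn{\pi} of
#' \eqn{\frac{1}{m}\sum_i \lVert q_{\pi(i)} - p_i \rVert^2},
#' computed exactly in polynomial time as an optimal one-to-one assignment on
#' the `m x m` pairwise squared-Euclidean cost matrix (the assignment optimum
#' equals the permutation minimum). Zero iff the two multisets of token
#' vectors admit a perfect matching; symmetric; invariant to reordering of
#' either sequence.
#'
#' @param p,q `m x d` matrices (or length-`m` vectors) of token embeddings.
#' @return Scalar loss with attributes `"assignment"` (the optimal permutation
#'   \eqn{\pi}, i.e. `q[assignment[i], ]` pairs with `p[i, ]`) and `"grad_q"`
#'   (gradient with respect to `q`; `p` is treated as fixed).
#' @export
em_loss <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
  if (is.null(dim(q))) q <- matrix(q, ncol = 1L)
  p <- as.matrix(p); q <- as.matrix(q)
  if (ncol(p) != ncol(q)) stop("token dimension mismatch between p and q")
  if (nrow(p) != nrow(q)) stop("token count mismatch between p and q")
  m <- nrow(p)
  # cost[i, j] = ||q_j - p_i||^2, via the expanded quadratic form
  cost <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  cost[cost < 0] <- 0  # clip tiny negative round-off
  perm <- solve_lsap(cost)
  val <- sum(cost[cbind(seq_len(m), perm)]) / m
  gq <- matrix(0, m, ncol(q))
  gq[perm, ] <- 2 * (q[perm, , drop = FALSE] - p) / m
  structure(val, assignment = perm, grad_q = gq)
}

#' Combine the three loss components
#'
#' The joint objective is the weighted sum `L = w1*L_CE + w2*L_MSE + w3*L_EM`;
#' the default weights are all 1 (plain sum).
#'
#' @param l_ce,l_mse,l_em Scalar loss components (consistency terms default to
#'   0 for supervised-only steps).
#' @param weights Length-3 non-negative weights.
#' @return A list of class `"loss_bundle"` with elements `L_CE`, `L_MSE`,
#'   `L_EM`, `L`.
#' @export
total_loss <- function(l_ce, l_mse = 0, l_em = 0, weights = c(1, 1, 1)) {
  parts <- c(L_CE = as.numeric(l_ce), L_MSE = as.numeric(l_mse),
             L_EM = as.numeric(l_em))
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad)) stop("non-finite loss component: ", paste(bad, collapse = ", "))
  stopifnot(length(weights) == 3L, all(weights >= 0))
  structure(list(L_CE = parts[["L_CE"]], L_MSE = parts[["L_MSE"]],
                 L_EM = parts[["L_EM"]],
                 L = sum(weights * parts)),
            class = "loss_bundle")
}
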