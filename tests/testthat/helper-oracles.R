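# Independent oracles and small fixture builders used across the suite.

# all permutations of 1..n (factorial enumeration; for brute-force oracles only)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# brute-force EM loss: minimum over all m! permutations of mean squared
# pairwise distance
em_brute <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
  if (is.null(dim(q))) q <- matrix(q, ncol = 1L)
  m <- nrow(p)
  best <- Inf
  for (perm in all_perms(m)) {
    tot <- sum((q[perm, , drop = FALSE] - p)^2)
    best <- min(best, tot)
  }
  best / m
}

# brute-force metrics from raw label vectors (independent of confusion_counts)
metrics_brute <- function(y_true, y_pred, n_classes) {
  n <- length(y_true)
  pre <- rec <- f1 <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    pre[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (pre[k] + rec[k] > 0) 2 * pre[k] * rec[k] / (pre[k] + rec[k]) else 0
  }
  list(Acc = mean(y_true == y_pred), Pre = mean(pre), Rec = mean(rec),
       F1 = mean(f1))
}

# random valid attention inputs (returns list(Q, K, V))
random_qkv <- function(n_tokens, d) {
  list(Q = matrix(rnorm(n_tokens * d), n_tokens),
       K = matrix(rnorm(n_tokens * d), n_tokens),
       V = matrix(rnorm(n_tokens * d), n_tokens))
}

# a throwaway tiny model for trainer-mechanics tests (16x16 images, 4x4 grid)
tiny_model <- function(n_classes = 2L, token_schedule = c(8L, 4L), seed = 1L,
                       depth = 2L) {
  vit_init(vit_config(image_size = 16L, channels = 1L, patch = 4L, dim = 16L,
                      depth = depth, heads = 2L, mlp_ratio = 2L,
                      n_classes = n_classes, token_schedule = token_schedule,
                      seed = seed))
}

tiny_images <- function(n, seed = 1L, size = 16L) {
  rng <- make_rng(seed)
  rng_eval(rng, replicate(n, array(runif(size * size), c(size, size, 1L)),
                          simplify = FALSE))
}
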