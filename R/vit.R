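# Compact ViT classifier with optional adaptive token sampling per block.
# Forward and reverse passes are written directly in base R matrix algebra;
# the reverse pass accumulates exact gradients for every parameter. Token
# position 1 is the CLS token throughout; sampled-away tokens simply receive
# zero gradient (the sampled index set is a constant of the backward pass).

#' Patchify an image into row-major patch vectors
#'
#' Splits an `H x W x C` image into `N = H*W/P^2` non-overlapping `P x P x C`
#' patches in row-major grid order and flattens each to a vector. The
#' operation is lossless: [unpatchify()] reconstructs the image exactly.
#'
#' @param image Numeric array `H x W x C` (a matrix is treated as `C = 1`).
#' @param P Patch side in pixels; must divide both `H` and `W`.
#' @return `N x (P*P*C)` matrix, one patch per row.
#' @export
patchify <- function(image, P) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  if (H %% P != 0L || W %% P != 0L) {
    stop(sprintf("patch side %d does not divide image dimensions %d x %d", P, H, W))
  }
  gr <- H %/% P; gc <- W %/% P
  out <- matrix(0, gr * gc, P * P * C)
  k <- 0L
  for (r in seq_len(gr)) {
    rows <- ((r - 1L) * P + 1L):(r * P)
    for (cc in seq_len(gc)) {
      k <- k + 1L
      out[k, ] <- as.vector(image[rows, ((cc - 1L) * P + 1L):(cc * P), ])
    }
  }
  out
}

#' Reassemble an image from its patch vectors
#'
#' @param patches Matrix from [patchify()].
#' @param H,W,C Original image dimensions.
#' @param P Patch side used for patchification.
#' @return The reconstructed `H x W x C` array.
#' @export
unpatchify <- function(patches, H, W, C, P) {
  img <- array(0, c(H, W, C))
  gr <- H %/% P; gc <- W %/% P
  k <- 0L
  for (r in seq_len(gr)) {
    rows <- ((r - 1L) * P + 1L):(r * P)
    for (cc in seq_len(gc)) {
      k <- k + 1L
      img[rows, ((cc - 1L) * P + 1L):(cc * P), ] <- array(patches[k, ], c(P, P, C))
    }
  }
  img
}

#' ViT model configuration
#'
#' @param image_size Input side length in pixels (images are square).
#' @param channels Image channels (1 grayscale, 3 RGB).
#' @param patch Patch side `P`; token count is `N = (image_size/patch)^2`.
#' @param dim Embedding dimension `D`.
#' @param depth Number of encoder blocks.
#' @param heads Attention heads per block (`dim %% heads == 0`).
#' @param mlp_ratio Feed-forward hidden width as a multiple of `dim`.
#' @param n_classes Number of output classes.
#' @param token_schedule Optional non-increasing integer vector of per-block
#'   retained-token budgets (length `depth`, first entry `<= N`); `NULL`
#'   disables adaptive token sampling.
#' @param seed Seed for parameter initialization and the sampler stream.
#' @return A list of class `"vit_config"`.
#' @export
vit_config <- function(image_size, channels = 1L, patch = 16L, dim = 128L,
                       depth = 6L, heads = 4L, mlp_ratio = 4L, n_classes,
                       token_schedule = NULL, seed = 1L) {
  if (image_size %% patch != 0L) {
    stop(sprintf("patch side %d does not divide image size %d", patch, image_size))
  }
  if (dim %% heads != 0L) stop("dim must be divisible by heads")
  N <- (image_size %/% patch)^2
  if (!is.null(token_schedule)) {
    token_schedule <- as.integer(token_schedule)
    if (length(token_schedule) != depth) {
      stop(sprintf("token_schedule has length %d but depth is %d",
                   length(token_schedule), depth))
    }
    if (is.unsorted(rev(token_schedule))) stop("token_schedule must be non-increasing")
    if (token_schedule[1L] > N) {
      stop(sprintf("token_schedule starts at %d but there are only %d patch tokens",
                   token_schedule[1L], N))
    }
    if (any(token_schedule < 1L)) stop("token_schedule entries must be >= 1")
  }
  structure(list(image_size = as.integer(image_size), channels = as.integer(channels),
                 patch = as.integer(patch), dim = as.integer(dim),
                 depth = as.integer(depth), heads = as.integer(heads),
                 mlp_ratio = as.integer(mlp_ratio), n_classes = as.integer(n_classes),
                 n_tokens = as.integer(N), token_schedule = token_schedule,
                 seed = as.integer(seed)),
            class = "vit_config")
}

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize a ViT model
#'
#' Weights are drawn N(0, 0.02^2), biases start at zero, layer-norm gains at
#' one; the CLS token and the learned position encodings are also N(0, 0.02^2).
#' All draws come from the model's private stream seeded by `config$seed`.
#'
#' @param config A [vit_config()].
#' @return An object of class `"atsvit_model"` (config, parameter list, RNG
#'   stream for stochastic token sampling).
#' @export
vit_init <- function(config) {
  stopifnot(inherits(config, "vit_config"))
  D <- config$dim; N <- config$n_tokens
  pdim <- config$patch^2 * config$channels
  rng <- make_rng(config$seed)
  params <- rng_eval(rng, {
    blocks <- lapply(seq_len(config$depth), function(i) {
      list(ln1_g = rep(1, D), ln1_b = rep(0, D),
           Wq = rmat(D, D), bq = rep(0, D),
           Wk = rmat(D, D), bk = rep(0, D),
           Wv = rmat(D, D), bv = rep(0, D),
           Wo = rmat(D, D), bo = rep(0, D),
           ln2_g = rep(1, D), ln2_b = rep(0, D),
           W1 = rmat(D, D * config$mlp_ratio), b1 = rep(0, D * config$mlp_ratio),
           W2 = rmat(D * config$mlp_ratio, D), b2 = rep(0, D))
    })
    list(W_emb = rmat(pdim, D), b_emb = rep(0, D),
         cls = stats::rnorm(D, sd = 0.02),
         pos = rmat(N + 1L, D),
         blocks = blocks,
         lnf_g = rep(1, D), lnf_b = rep(0, D),
         W_head = rmat(D, config$n_classes), b_head = rep(0, config$n_classes))
  })
  structure(list(config = config, params = params, rng = rng),
            class = "atsvit_model")
}

# ---- layer norm -------------------------------------------------------------

LN_EPS <- 1e-6

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(y = t(t(xhat) * g + b), xhat = xhat, inv = inv, g = g)
}

ln_backward <- function(dy, cache) {
  dxhat <- t(t(dy) * cache$g)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

addb <- function(M, b) t(t(M) + b)

# ---- embedding --------------------------------------------------------------

embed_tokens <- function(model, patches) {
  p <- model$params
  X <- addb(patches %*% p$W_emb, p$b_emb)
  rbind(p$cls, X) + p$pos
}

#' Embed an image's patches into the token sequence
#'
#' Linear patch embedding, learned CLS token prepended at position 1, learned
#' position encoding added per position.
#'
#' @param model An [vit_init()] model.
#' @param image Image array matching the model configuration.
#' @return List with `tokens` (`(N+1) x D`, CLS first) and `patch_map`
#'   (original patch-grid indices `1..N`).
#' @export
embed_image <- function(model, image) {
  patches <- patchify(image, model$config$patch)
  if (nrow(patches) != model$config$n_tokens) {
    stop(sprintf("image yields %d patches but the model expects %d",
                 nrow(patches), model$config$n_tokens))
  }
  list(tokens = embed_tokens(model, patches),
       patch_map = seq_len(model$config$n_tokens))
}

# ---- forward ----------------------------------------------------------------

# Single-image forward pass. mode controls the token sampler; "off" bypasses
# sampling even when a schedule is configured.
vit_forward_one <- function(model, image, mode = "stochastic", keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  D <- cfg$dim; hh <- cfg$heads; dh <- D %/% hh
  ats_on <- !is.null(cfg$token_schedule) && !identical(mode, "off")

  patches <- patchify(image, cfg$patch)
  X <- embed_tokens(model, patches)
  patch_map <- seq_len(cfg$n_tokens)
  token_counts <- integer(cfg$depth)
  caches <- if (keep_cache) vector("list", cfg$depth)
  last_scores <- NULL

  for (l in seq_len(cfg$depth)) {
    bp <- p$blocks[[l]]
    n <- nrow(X)
    l1 <- ln_forward(X, bp$ln1_g, bp$ln1_b)
    Q <- addb(l1$y %*% bp$Wq, bp$bq)
    K <- addb(l1$y %*% bp$Wk, bp$bk)
    V <- addb(l1$y %*% bp$Wv, bp$bv)
    A <- array(0, c(n, n, hh))
    Ocat <- matrix(0, n, D)
    for (h in seq_len(hh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- row_softmax(tcrossprod(Q[, cols, drop = FALSE],
                                   K[, cols, drop = FALSE]) / sqrt(dh))
      A[, , h] <- Ah
      Ocat[, cols] <- Ah %*% V[, cols, drop = FALSE]
    }
    attn <- addb(Ocat %*% bp$Wo, bp$bo)
    X1 <- X + attn

    sel <- NULL
    if (ats_on) {
      scores <- tryCatch(significance_scores(A, V),
                         atsvit_degenerate_scores = function(e) uniform_scores(n - 1L))
      idx <- its_sample(scores, cfg$token_schedule[l], mode, model$rng)
      sel <- c(1L, idx)
      X1 <- X1[sel, , drop = FALSE]
      patch_map <- patch_map[idx - 1L]
      if (l == cfg$depth) last_scores <- scores$S[idx - 1L]
    } else if (l == cfg$depth) {
      sc <- tryCatch(significance_scores(A, V),
                     atsvit_degenerate_scores = function(e) uniform_scores(n - 1L))
      last_scores <- sc$S
    }
    token_counts[l] <- nrow(X1)

    l2 <- ln_forward(X1, bp$ln2_g, bp$ln2_b)
    Hpre <- addb(l2$y %*% bp$W1, bp$b1)
    Hact <- gelu(Hpre)
    ffn <- addb(Hact %*% bp$W2, bp$b2)
    Xout <- X1 + ffn

    if (keep_cache) {
      caches[[l]] <- list(l1 = l1, Q = Q, K = K, V = V, A = A, Ocat = Ocat,
                          sel = sel, n_before = n, X1 = X1, l2 = l2,
                          Hpre = Hpre, Hact = Hact)
    }
    X <- Xout
  }

  lf <- ln_forward(X, p$lnf_g, p$lnf_b)
  logits <- drop(lf$y[1L, ] %*% p$W_head) + p$b_head

  list(logits = logits, tokens = X, patch_map = patch_map,
       token_counts = token_counts, last_scores = last_scores,
       cache = if (keep_cache) list(patches = patches, blocks = caches, lf = lf,
                                    X_final = X))
}

# draw sampled token positions, sharing one RNG stream across blocks/images
its_sample <- function(scores, K, mode, rng) {
  n <- length(scores$S)
  if (K >= n) return(seq_len(n) + 1L)
  u <- if (identical(mode, "stochastic")) {
    rng_eval(rng, stats::runif(K))
  } else {
    (seq_len(K) - 0.5) / K
  }
  idx <- sort(unique(cdf_inverse(scores$cdf, u)))
  if (identical(mode, "deterministic-topup") && length(idx) < K) {
    missing <- setdiff(order(scores$S, decreasing = TRUE), idx)
    idx <- sort(c(idx, missing[seq_len(K - length(idx))]))
  }
  idx + 1L
}

#' Forward pass of the ViT classifier
#'
#' Runs the encoder stack (pre-norm multi-head self-attention + GELU
#' feed-forward, residual connections), applying adaptive token sampling with
#' the configured per-block budget when a token schedule is present, and maps
#' the final CLS embedding to class logits. The final block's full token
#' sequence is returned per image as the "intermediate" representation used by
#' the Earth Mover's distance consistency loss.
#'
#' @param model An [vit_init()] model.
#' @param images A single image array or a list of image arrays.
#' @param mode Sampling mode: `"stochastic"` (training default),
#'   `"deterministic-quantile"`, `"deterministic-topup"`, or `"off"`.
#' @param keep_cache Keep per-image activation caches for [vit_backward()].
#' @return List with `logits` (`batch x n_classes`), `probs` (sigmoid of
#'   logits), `tokens`, `patch_maps`, `last_scores`, `token_counts`
#'   (`batch x depth` post-block counts), and `caches` when requested.
#' @export
vit_forward <- function(model, images, mode = c("stochastic",
                                                "deterministic-quantile",
                                                "deterministic-topup", "off"),
                        keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (!is.list(images)) images <- list(images)
  outs <- lapply(images, function(im)
    vit_forward_one(model, im, mode = mode, keep_cache = keep_cache))
  logits <- do.call(rbind, lapply(outs, `[[`, "logits"))
  list(logits = logits,
       probs = sigmoid(logits),
       tokens = lapply(outs, `[[`, "tokens"),
       patch_maps = lapply(outs, `[[`, "patch_map"),
       last_scores = lapply(outs, `[[`, "last_scores"),
       token_counts = do.call(rbind, lapply(outs, `[[`, "token_counts")),
       caches = if (keep_cache) lapply(outs, `[[`, "cache"))
}

# ---- backward ---------------------------------------------------------------

# flat-vector view of the parameter tree; the optimizer works on the vector,
# the forward pass on the tree
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    v <- flat[(i + 1L):(i + n)]
    i <<- i + n
    dim(v) <- dim(x)
    v
  }
  rec(skeleton)
}

# Exact gradients for one image, emitted as a single flat vector laid out in
# the same order as unlist(model$params): W_emb, b_emb, cls, pos, blocks
# (ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv, Wo, bo, ln2_g, ln2_b, W1, b1, W2,
# b2), lnf_g, lnf_b, W_head, b_head. dlogits: length n_classes; dtokens:
# optional gradient injected at the final block's token sequence (EM loss).
vit_backward_one <- function(model, cache, dlogits, dtokens = NULL) {
  cfg <- model$config
  p <- model$params
  D <- cfg$dim; hh <- cfg$heads; dh <- D %/% hh

  lf <- cache$lf
  nF <- nrow(cache$X_final)
  gW_head <- outer(lf$y[1L, ], dlogits)
  dYf <- matrix(0, nF, D)
  dYf[1L, ] <- drop(p$W_head %*% dlogits)
  bl <- ln_backward(dYf, lf)
  dX <- bl$dx
  if (!is.null(dtokens)) dX <- dX + dtokens

  blk_seg <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    cb <- cache$blocks[[l]]
    bp <- p$blocks[[l]]
    # feed-forward
    dffn <- dX
    dHact <- tcrossprod(dffn, bp$W2)
    gW2 <- crossprod(cb$Hact, dffn)
    dHpre <- dHact * gelu_grad(cb$Hpre)
    dXn2 <- tcrossprod(dHpre, bp$W1)
    gW1 <- crossprod(cb$l2$y, dHpre)
    b2 <- ln_backward(dXn2, cb$l2)
    dX1s <- dX + b2$dx
    # undo token selection: dropped tokens get zero gradient
    if (!is.null(cb$sel)) {
      dX1 <- matrix(0, cb$n_before, D)
      dX1[cb$sel, ] <- dX1s
    } else {
      dX1 <- dX1s
    }
    # attention
    dOcat <- tcrossprod(dX1, bp$Wo)
    gWo <- crossprod(cb$Ocat, dX1)
    dQ <- matrix(0, cb$n_before, D)
    dK <- matrix(0, cb$n_before, D)
    dV <- matrix(0, cb$n_before, D)
    for (h in seq_len(hh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- cb$A[, , h]
      dOh <- dOcat[, cols, drop = FALSE]
      Vh <- cb$V[, cols, drop = FALSE]
      dAh <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(Ah, dOh)
      dZ <- Ah * (dAh - rowSums(dAh * Ah))
      dQ[, cols] <- dZ %*% cb$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dZ, cb$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    Xn1 <- cb$l1$y
    dXn1 <- tcrossprod(dQ, bp$Wq) + tcrossprod(dK, bp$Wk) + tcrossprod(dV, bp$Wv)
    b1 <- ln_backward(dXn1, cb$l1)
    blk_seg[[l]] <- c(b1$dg, b1$db,
                      crossprod(Xn1, dQ), colSums(dQ),
                      crossprod(Xn1, dK), colSums(dK),
                      crossprod(Xn1, dV), colSums(dV),
                      gWo, colSums(dX1),
                      b2$dg, b2$db,
                      gW1, colSums(dHpre),
                      gW2, colSums(dffn))
    dX <- dX1 + b1$dx
  }

  dpatch <- dX[-1L, , drop = FALSE]
  c(crossprod(cache$patches, dpatch), colSums(dpatch),  # W_emb, b_emb
    dX[1L, ], dX,                                       # cls, pos
    unlist(blk_seg, use.names = FALSE),
    bl$dg, bl$db, gW_head, dlogits)                     # lnf, head
}

#' Backward pass: accumulate parameter gradients over a batch
#'
#' @param model The model used in the forward pass.
#' @param caches Per-image caches from [vit_forward()] with `keep_cache = TRUE`.
#' @param dlogits `batch x n_classes` gradient of the loss w.r.t. the logits.
#' @param dtokens Optional list of per-image gradients injected at the final
#'   block's token sequence (`NULL` entries allowed).
#' @return Gradient list with the same structure as `model$params`.
#' @export
vit_backward <- function(model, caches, dlogits, dtokens = NULL) {
  unflatten_params(vit_backward_flat(model, caches, dlogits, dtokens),
                   model$params)
}

# batch gradients accumulated as a flat vector (cheap elementwise adds)
vit_backward_flat <- function(model, caches, dlogits, dtokens = NULL) {
  g <- NULL
  for (i in seq_along(caches)) {
    gi <- vit_backward_one(model, caches[[i]], dlogits[i, ],
                           if (!is.null(dtokens)) dtokens[[i]])
    g <- if (is.null(g)) gi else g + gi
  }
  g
}

# ---- Adam -------------------------------------------------------------------

# Adam on the flat parameter vector with bias correction
adam_init <- function(params) {
  n <- length(flatten_params(params))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step_flat <- function(theta, grad, state, lr = 2e-5, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

adam_step <- function(params, grads, state, lr = 2e-5, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  r <- adam_step_flat(flatten_params(params), flatten_params(grads), state,
                      lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
  list(params = unflatten_params(r$theta, params), state = r$state)
}

# ---- visualization & checkpoints -------------------------------------------

#' Most significant retained patches of an image
#'
#' Runs a deterministic forward pass and returns the `k` patch positions that
#' survive adaptive sampling into the last encoder block (ranked by their
#' last-block significance score), mapped back to original-image pixel boxes.
#'
#' @param model A model configured with a token schedule.
#' @param image Input image array.
#' @param k Number of patches to return; must not exceed the last-block token
#'   budget.
#' @return Data frame with 0-based grid coordinates (`row`, `col`), the
#'   0-based row-major patch index `patch`, and 0-based pixel box corners
#'   `x0, y0` (inclusive) / `x1, y1` (exclusive), `x` running along columns.
#' @export
top_tokens <- function(model, image, k = 8L) {
  cfg <- model$config
  if (is.null(cfg$token_schedule)) stop("adaptive token sampling is not enabled")
  if (k > cfg$token_schedule[cfg$depth]) {
    stop(sprintf("k = %d exceeds the last-block token budget %d",
                 k, cfg$token_schedule[cfg$depth]))
  }
  out <- vit_forward_one(model, image, mode = "deterministic-topup")
  pm <- out$patch_map
  ord <- order(out$last_scores, decreasing = TRUE)
  pm <- pm[ord][seq_len(min(k, length(pm)))]
  gside <- cfg$image_size %/% cfg$patch
  row <- (pm - 1L) %/% gside
  col <- (pm - 1L) %% gside
  data.frame(patch = pm - 1L, row = row, col = col,
             x0 = col * cfg$patch, y0 = row * cfg$patch,
             x1 = (col + 1L) * cfg$patch, y1 = (row + 1L) * cfg$patch)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a versioned header carrying the model
#' configuration.
#'
#' @param model An `"atsvit_model"`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "atsvit_model"))
  saveRDS(list(format = "atsvit-checkpoint", version = 1L,
               config = model$config, params = model$params,
               seed = model$config$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "atsvit-checkpoint")) stop("not an atsvit checkpoint file")
  if (x$version > 1L) stop("checkpoint version ", x$version, " is newer than this package")
  structure(list(config = x$config, params = x$params, rng = make_rng(x$seed)),
            class = "atsvit_model")
}

#' Predict class labels
#'
#' @param object An `"atsvit_model"`.
#' @param images Image array or list of arrays.
#' @param mode Sampling mode; deterministic by default for reproducible
#'   evaluation.
#' @param ... Unused.
#' @return List with `probs` (per-class sigmoid probabilities) and `class`
#'   (1-based argmax labels).
#' @export
predict.atsvit_model <- function(object, images,
                                 mode = "deterministic-quantile", ...) {
  out <- vit_forward(object, images, mode = mode)
  list(probs = out$probs, class = max.col(out$logits, ties.method = "first"))
}
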