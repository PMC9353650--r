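# Patchification, embedding, the encoder stack, and gradient correctness.

test_that("patchify produces the expected token counts and is lossless", {
  img <- array(runif(64 * 64), c(64, 64, 1))
  p <- patchify(img, 16)
  expect_equal(dim(p), c(16, 256))
  expect_equal(unpatchify(p, 64, 64, 1, 16), img)

  # single-patch degenerate case: the flattened image itself
  one <- patchify(img, 64)
  expect_equal(dim(one), c(1, 4096))
  expect_equal(drop(one), as.vector(img))

  # 256x256 grayscale with 16-pixel patches gives the full 256-token grid
  big <- array(0, c(256, 256, 1))
  expect_equal(nrow(patchify(big, 16)), 256)

  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p3 <- patchify(rgb, 8)
  expect_equal(dim(p3), c(16, 192))
  expect_equal(unpatchify(p3, 32, 32, 3, 8), rgb)

  expect_error(patchify(img, 10), "does not divide")
})

test_that("embedding prepends CLS and breaks patch-permutation symmetry", {
  m <- tiny_model()
  img <- array(runif(256), c(16, 16, 1))
  e <- embed_image(m, img)
  expect_equal(nrow(e$tokens), 16 + 1)
  expect_equal(length(e$patch_map), 16)

  # permuting patches changes the embedded sequence (position encodings)
  img2 <- unpatchify(patchify(img, 4)[c(2:16, 1), ], 16, 16, 1, 4)
  e2 <- embed_image(m, img2)
  expect_false(isTRUE(all.equal(e$tokens, e2$tokens)))

  # zero image: all patch embeddings equal bias + position term
  z <- embed_image(m, array(0, c(16, 16, 1)))
  expect_equal(z$tokens[-1, ] - m$params$pos[-1, ],
               matrix(m$params$b_emb, 16, 16, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("token counts follow the schedule and CLS survives every block", {
  m <- tiny_model(token_schedule = c(8L, 4L))
  img <- array(runif(256), c(16, 16, 1))
  out <- vit_forward(m, img, mode = "stochastic")
  expect_true(all(out$token_counts[1, ] <= c(9, 5)))
  expect_true(length(out$patch_maps[[1]]) == out$token_counts[1, 2] - 1L)

  # ATS off: constant N + 1 tokens through all blocks
  m0 <- vit_init(vit_config(image_size = 16, channels = 1, patch = 4, dim = 16,
                            depth = 2, heads = 2, mlp_ratio = 2, n_classes = 2))
  out0 <- vit_forward(m0, img)
  expect_equal(drop(out0$token_counts), c(17, 17))
})

test_that("a full-budget schedule reproduces the plain ViT deterministically", {
  img <- array(runif(256), c(16, 16, 1))
  base <- vit_init(vit_config(image_size = 16, channels = 1, patch = 4, dim = 16,
                              depth = 2, heads = 2, mlp_ratio = 2, n_classes = 3,
                              seed = 5))
  full <- vit_init(vit_config(image_size = 16, channels = 1, patch = 4, dim = 16,
                              depth = 2, heads = 2, mlp_ratio = 2, n_classes = 3,
                              token_schedule = c(16L, 16L), seed = 5))
  lo <- vit_forward(base, img, mode = "off")$logits
  lf <- vit_forward(full, img, mode = "deterministic-quantile")$logits
  expect_equal(lo, lf, tolerance = 1e-12)

  # identical images in a batch give identical logits in deterministic mode
  out <- vit_forward(full, list(img, img), mode = "deterministic-quantile")
  expect_equal(out$logits[1, ], out$logits[2, ])
})

test_that("backward gradients match central finite differences", {
  set.seed(42)
  model <- tiny_model(n_classes = 3L, token_schedule = c(8L, 4L), seed = 7L)
  img <- array(runif(256), c(16, 16, 1))
  y <- matrix(c(1, 0, 0), 1)
  loss_of <- function(m) {
    out <- vit_forward(m, img, mode = "deterministic-topup", keep_cache = TRUE)
    l <- bce_with_logits(out$logits, y)
    as.numeric(l) + 0.5 * sum(out$tokens[[1]]^2)
  }
  out <- vit_forward(model, img, mode = "deterministic-topup", keep_cache = TRUE)
  l <- bce_with_logits(out$logits, y)
  grads <- vit_backward(model, out$caches, attr(l, "grad"), out$tokens)

  flat <- atsvit:::flatten_params(model$params)
  gflat <- atsvit:::flatten_params(grads)
  eps <- 1e-5
  set.seed(99)
  for (j in sample(length(flat), 25L)) {
    m1 <- model; m2 <- model
    f1 <- flat; f1[j] <- f1[j] + eps
    f2 <- flat; f2[j] <- f2[j] - eps
    m1$params <- atsvit:::unflatten_params(f1, model$params)
    m2$params <- atsvit:::unflatten_params(f2, model$params)
    num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
    expect_equal(gflat[j], num, tolerance = 1e-4)
  }
  expect_true(all(is.finite(gflat)))
})

test_that("top tokens map to disjoint in-bounds pixel boxes", {
  m <- tiny_model(token_schedule = c(8L, 4L))
  img <- array(runif(256), c(16, 16, 1))
  bx <- top_tokens(m, img, k = 4L)
  expect_equal(nrow(bx), 4)
  expect_true(all(bx$x0 >= 0 & bx$x1 <= 16 & bx$y0 >= 0 & bx$y1 <= 16))
  expect_equal(anyDuplicated(bx$patch), 0)
  expect_error(top_tokens(m, img, k = 5L), "budget")
})

test_that("checkpoints round-trip the model", {
  m <- tiny_model(seed = 13L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  img <- array(runif(256), c(16, 16, 1))
  expect_equal(vit_forward(m, img, mode = "deterministic-quantile")$logits,
               vit_forward(m2, img, mode = "deterministic-quantile")$logits)
  p2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), p2)
  expect_error(load_checkpoint(p2), "not an atsvit checkpoint")
})
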