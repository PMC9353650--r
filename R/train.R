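# Semi-supervised consistency training. Each optimization step draws one
# labeled and one unlabeled batch; the labeled batch contributes the
# supervised one-vs-all BCE loss, the unlabeled batch is forwarded twice
# through the SAME model (clean and augmented) for the pseudo-label MSE and
# the token-sequence EM losses. One Adam step is taken on the joint objective
# L = L_CE + L_MSE + L_EM.

# largest-remainder apportionment of n into proportions props
apportion <- function(n, props) {
  props <- props / sum(props)
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * props - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified semi-supervised data split
#'
#' Splits a labeled dataset into train/validation/test sets stratified by
#' class, then splits the training part into labeled and unlabeled subsets
#' (the latter's labels are hidden from the trainer but retained for audit).
#' Per-class counts use floor rounding with remainders assigned to the splits
#' with the largest fractional remainder, so every split's class proportions
#' match the full dataset within one sample per class. Fully reproducible
#' given `seed`.
#'
#' @param labels Class label vector (factor, character, or integer).
#' @param ratios Train/validation/test proportions (default 7:1:2).
#' @param labeled_frac Fraction of the training split kept labeled (default
#'   0.8; the remaining 20% is treated as unlabeled).
#' @param seed RNG seed.
#' @return List of class `"ssl_split"` with index vectors `train_labeled`,
#'   `train_unlabeled`, `val`, `test`, and `hidden_labels` (the audit record
#'   of the unlabeled subset's true labels).
#' @export
split_ssl <- function(labels, ratios = c(0.7, 0.1, 0.2), labeled_frac = 0.8,
                      seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  f <- factor(labels)
  n_splits <- sum(ratios > 0)
  rng <- make_rng(seed)
  out <- list(train_labeled = integer(0), train_unlabeled = integer(0),
              val = integer(0), test = integer(0))
  for (cl in levels(f)) {
    idx <- which(f == cl)
    if (length(idx) < n_splits) {
      stop(sprintf("class '%s' has %d samples, fewer than the %d splits",
                   cl, length(idx), n_splits))
    }
    idx <- rng_eval(rng, sample(idx))
    k <- apportion(length(idx), ratios)
    tr <- idx[seq_len(k[1L])]
    out$val <- c(out$val, idx[k[1L] + seq_len(k[2L])])
    out$test <- c(out$test, idx[k[1L] + k[2L] + seq_len(k[3L])])
    kl <- apportion(length(tr), c(labeled_frac, 1 - labeled_frac))
    out$train_labeled <- c(out$train_labeled, tr[seq_len(kl[1L])])
    out$train_unlabeled <- c(out$train_unlabeled, tr[kl[1L] + seq_len(kl[2L])])
  }
  out <- lapply(out, sort)
  out$hidden_labels <- labels[out$train_unlabeled]
  structure(out, class = "ssl_split")
}

# ---- augmentation -----------------------------------------------------------

#' Image augmentation set
#'
#' The perturbation family used by consistency training: random crop to a
#' fraction of the image followed by resize back, horizontal and vertical
#' flips, contrast scaling, and brightness jitter. All parameter draws come
#' from the set's private seeded stream.
#'
#' @param transforms Character vector naming the member transforms; any of
#'   `"crop"`, `"hflip"`, `"vflip"`, `"contrast"`, `"brightness"`,
#'   `"identity"`.
#' @param crop_frac Side fraction kept by the crop (default 0.875).
#' @param contrast_range Contrast scale range (default U\[0.7, 1.3\]).
#' @param brightness_range Additive brightness range on \[0,1\] intensities
#'   (default U\[-0.1, 0.1\]).
#' @param seed RNG seed.
#' @return List of class `"augmentation_set"`.
#' @export
augmentation_set <- function(transforms = c("crop", "hflip", "vflip",
                                            "contrast", "brightness"),
                             crop_frac = 0.875,
                             contrast_range = c(0.7, 1.3),
                             brightness_range = c(-0.1, 0.1),
                             seed = 1L) {
  known <- c("crop", "hflip", "vflip", "contrast", "brightness", "identity")
  if (length(transforms) == 0L) stop("augmentation set must not be empty")
  if (!all(transforms %in% known)) {
    stop("unknown transform: ", paste(setdiff(transforms, known), collapse = ", "))
  }
  structure(list(transforms = transforms, crop_frac = crop_frac,
                 contrast_range = contrast_range,
                 brightness_range = brightness_range,
                 rng = make_rng(seed)),
            class = "augmentation_set")
}

#' Apply a single named transform
#'
#' @param x Image array `H x W x C`.
#' @param transform Transform name (see [augmentation_set()]).
#' @param param Numeric parameter where the transform takes one: crop offsets
#'   in \[0,1\] (length 2), contrast scale, brightness shift.
#' @return Transformed image of identical shape.
#' @export
apply_transform <- function(x, transform, param = NULL) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  switch(transform,
    identity = x,
    hflip = x[, dim(x)[2L]:1L, , drop = FALSE],
    vflip = x[dim(x)[1L]:1L, , , drop = FALSE],
    contrast = clamp01(0.5 + (x - 0.5) * param),
    brightness = clamp01(x + param),
    crop = {
      S <- dim(x)[1L]
      s2 <- max(2L, round(S * attr(param, "frac")))
      r0 <- 1L + floor(param[1L] * (S - s2))
      c0 <- 1L + floor(param[2L] * (S - s2))
      cropped <- x[r0:(r0 + s2 - 1L), c0:(c0 + s2 - 1L), , drop = FALSE]
      resize_image(cropped, S)
    },
    stop("unknown transform: ", transform))
}

#' Draw and apply one random augmentation
#'
#' One transform is chosen uniformly from the set, its parameters drawn from
#' the set's stream, and applied.
#'
#' @param x Image array.
#' @param aug An [augmentation_set()].
#' @return List with `image` (same shape as `x`), `index` of the chosen
#'   transform, and `transform` (its name).
#' @export
apply_augmentation <- function(x, aug) {
  stopifnot(inherits(aug, "augmentation_set"))
  draws <- rng_eval(aug$rng, stats::runif(3L))
  i <- as.integer(1L + floor(draws[1L] * length(aug$transforms)))
  i <- min(i, length(aug$transforms))
  tr <- aug$transforms[i]
  param <- switch(tr,
    crop = structure(draws[2:3], frac = aug$crop_frac),
    contrast = aug$contrast_range[1L] +
      draws[2L] * diff(aug$contrast_range),
    brightness = aug$brightness_range[1L] +
      draws[2L] * diff(aug$brightness_range),
    NULL)
  list(image = apply_transform(x, tr, param), index = i, transform = tr)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference full-scale training setting: Adam with
#' learning rate 2e-5 and eps 1e-8, batch size 64, 300 epochs. Desk-scale
#' experiments override them.
#'
#' @param learning_rate Adam learning rate.
#' @param eps Adam denominator epsilon.
#' @param batch_size Labeled (and unlabeled) batch size per step.
#' @param epochs Training epochs.
#' @param seed Seed for batch order and augmentation draws.
#' @param loss_weights Weights of (CE, MSE, EM); default `c(1, 1, 1)`.
#' @param consistency_rampup Epochs over which the consistency-loss weight is
#'   ramped from ~0 to its full value with the standard Gaussian schedule
#'   `exp(-5 (1 - t)^2)`; 0 applies full weight from the first step.
#'   Ramping gives the supervised loss time to shape features before the
#'   invariance pressure of the consistency terms sets in, which otherwise
#'   can pin short training runs at a collapsed representation.
#' @param augmentations An [augmentation_set()], or `NULL` for the default set.
#' @param sample_mode Token-sampler mode for the supervised branch.
#' @param consistency_mode Sampler mode for the two consistency branches;
#'   `"deterministic-topup"` guarantees both branches retain equally many
#'   tokens so the EM matching is well defined.
#' @param verbose Print per-epoch progress.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 2e-5, eps = 1e-8, batch_size = 64L,
                         epochs = 300L, seed = 1L, loss_weights = c(1, 1, 1),
                         consistency_rampup = 0L,
                         augmentations = NULL,
                         sample_mode = "stochastic",
                         consistency_mode = "deterministic-topup",
                         verbose = FALSE) {
  structure(list(learning_rate = learning_rate, eps = eps,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), loss_weights = loss_weights,
                 consistency_rampup = as.integer(consistency_rampup),
                 augmentations = augmentations, sample_mode = sample_mode,
                 consistency_mode = consistency_mode, verbose = verbose),
            class = "train_config")
}

# Gaussian consistency ramp (0..1]; reaches 1 at epoch >= rampup
rampup_weight <- function(epoch, rampup) {
  if (rampup <= 0L) return(1)
  t <- min(1, epoch / rampup)
  exp(-5 * (1 - t)^2)
}

#' Train the classifier with semi-supervised consistency losses
#'
#' Runs the end-to-end loop: per step, a labeled batch is forwarded for the
#' supervised BCE loss; an unlabeled batch and its augmented twin are
#' forwarded through the same shared-parameter model for the pseudo-label MSE
#' (class probabilities, clean branch detached) and the EM loss (final-block
#' token sequences, clean branch detached); a single Adam update is applied to
#' the weighted sum. With no unlabeled data the loop degrades to supervised
#' training with a warning.
#'
#' @param model An [vit_init()] model.
#' @param x_l List of labeled training images.
#' @param y_l Integer 1-based class labels for `x_l`.
#' @param x_u Optional list of unlabeled images.
#' @param val Optional list with `images` and `labels` for per-epoch
#'   validation and best-checkpoint (by macro F1) selection.
#' @param config A [train_config()].
#' @return Object of class `"atsvit_fit"`: `model` (final parameters),
#'   `best_model` / `best_epoch` / `best_f1` (when validated), `log`
#'   (per-epoch data frame), `step_log` (per-step loss components).
#' @export
train_atsvit <- function(model, x_l, y_l, x_u = NULL, val = NULL,
                         config = train_config()) {
  stopifnot(inherits(model, "atsvit_model"), inherits(config, "train_config"))
  n_classes <- model$config$n_classes
  y_onehot <- one_hot(as.integer(y_l), n_classes)
  w <- config$loss_weights
  aug <- config$augmentations
  if (is.null(aug)) aug <- augmentation_set(seed = config$seed + 1L)
  has_unlab <- !is.null(x_u) && length(x_u) > 0L
  if (!has_unlab) {
    warning("no unlabeled data: training proceeds supervised-only")
  }
  rng <- make_rng(config$seed)
  opt <- adam_init(model$params)
  n <- length(x_l)
  steps_per_epoch <- ceiling(n / config$batch_size)
  step_rows <- list(); epoch_rows <- list()
  best <- list(f1 = -Inf, params = NULL, epoch = NA_integer_)
  u_queue <- integer(0)
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- rng_eval(rng, sample.int(n))
    cw <- rampup_weight(epoch, config$consistency_rampup)
    w_mse <- w[2L] * cw
    w_em <- w[3L] * cw
    ep_loss <- c(L_CE = 0, L_MSE = 0, L_EM = 0, L = 0)
    for (b in seq_len(steps_per_epoch)) {
      step <- step + 1L
      take <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      xb <- x_l[take]
      yb <- y_onehot[take, , drop = FALSE]

      fwd <- vit_forward(model, xb, mode = config$sample_mode, keep_cache = TRUE)
      l_ce <- bce_with_logits(fwd$logits, yb)
      grads <- vit_backward_flat(model, fwd$caches, attr(l_ce, "grad") * w[1L])

      l_mse <- 0; l_em <- 0
      if (has_unlab) {
        mb <- length(take)
        while (length(u_queue) < mb) {
          u_queue <- c(u_queue, rng_eval(rng, sample.int(length(x_u))))
        }
        ub <- u_queue[seq_len(mb)]
        u_queue <- u_queue[-seq_len(mb)]
        xu <- x_u[ub]
        zu <- lapply(xu, function(im) apply_augmentation(im, aug)$image)
        clean <- vit_forward(model, xu, mode = config$consistency_mode)
        fa <- vit_forward(model, zu, mode = config$consistency_mode,
                          keep_cache = TRUE)
        mse <- pseudo_label_mse(clean$probs, fa$probs)
        l_mse <- as.numeric(mse)
        dprob <- attr(mse, "grad")
        dlog_aug <- dprob * fa$probs * (1 - fa$probs) * w_mse
        dtok <- vector("list", mb)
        em_sum <- 0
        for (i in seq_len(mb)) {
          e <- em_loss(clean$tokens[[i]], fa$tokens[[i]])
          em_sum <- em_sum + as.numeric(e)
          dtok[[i]] <- attr(e, "grad_q") * (w_em / mb)
        }
        l_em <- em_sum / mb
        grads <- grads + vit_backward_flat(model, fa$caches, dlog_aug, dtok)
      }

      # logged components are the weighted contributions, so the logged
      # objective is always their plain sum
      bundle <- total_loss(w[1L] * l_ce, w_mse * l_mse, w_em * l_em)
      upd <- adam_step_flat(flatten_params(model$params), grads, opt,
                            lr = config$learning_rate, eps = config$eps)
      model$params <- unflatten_params(upd$theta, model$params)
      opt <- upd$state

      step_rows[[step]] <- data.frame(step = step, epoch = epoch,
                                      L_CE = bundle$L_CE, L_MSE = bundle$L_MSE,
                                      L_EM = bundle$L_EM, L = bundle$L)
      ep_loss <- ep_loss + c(bundle$L_CE, bundle$L_MSE, bundle$L_EM, bundle$L)
    }
    ep_loss <- ep_loss / steps_per_epoch
    row <- data.frame(epoch = epoch, L_CE = ep_loss[1L], L_MSE = ep_loss[2L],
                      L_EM = ep_loss[3L], L = ep_loss[4L],
                      val_Acc = NA_real_, val_Pre = NA_real_,
                      val_Rec = NA_real_, val_F1 = NA_real_)
    if (!is.null(val)) {
      ev <- evaluate_model(model, val$images, val$labels)
      row$val_Acc <- ev$metrics$Acc; row$val_Pre <- ev$metrics$Pre
      row$val_Rec <- ev$metrics$Rec; row$val_F1 <- ev$metrics$F1
      if (ev$metrics$F1 > best$f1) {
        best <- list(f1 = ev$metrics$F1, params = model$params, epoch = epoch)
      }
    }
    epoch_rows[[epoch]] <- row
    if (config$verbose) {
      message(sprintf("epoch %d: L = %.4f (CE %.4f, MSE %.4f, EM %.4f)%s",
                      epoch, row$L, row$L_CE, row$L_MSE, row$L_EM,
                      if (!is.null(val)) sprintf(", val F1 %.3f", row$val_F1) else ""))
    }
  }

  best_model <- NULL
  if (!is.null(best$params)) {
    best_model <- model
    best_model$params <- best$params
  }
  structure(list(model = model, best_model = best_model,
                 best_epoch = best$epoch,
                 best_f1 = if (is.finite(best$f1)) best$f1 else NA_real_,
                 log = do.call(rbind, epoch_rows),
                 step_log = do.call(rbind, step_rows),
                 config = config),
            class = "atsvit_fit")
}

#' Evaluate a model on labeled images
#'
#' Deterministic forward pass plus macro-averaged metrics.
#'
#' @param model An `"atsvit_model"`.
#' @param images List of images.
#' @param labels 1-based integer labels.
#' @param mode Sampler mode (deterministic by default).
#' @return List with `metrics` (a [metrics_report()]) and `pred` (1-based
#'   predicted labels).
#' @export
evaluate_model <- function(model, images, labels,
                           mode = "deterministic-quantile") {
  out <- vit_forward(model, images, mode = mode)
  pred <- max.col(out$logits, ties.method = "first")
  cc <- confusion_counts(as.integer(labels), pred, model$config$n_classes)
  list(metrics = metrics_report(cc), pred = pred)
}
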