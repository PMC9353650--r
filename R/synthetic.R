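# Synthetic desk-scale image generator. Emulates the statistical structure the
# classifier and the token sampler assume: a noisy uninformative background
# shared by all classes, with the class signal carried by a localized
# lesion-like region (grayscale ultrasound mode) or by region texture and
# chromaticity (RGB histopathology mode). Every sample carries a ground-truth
# binary mask of the informative region so token selection can be scored
# against known geometry.

#' Specification of a synthetic dataset
#'
#' @param mode `"busi"` — grayscale, class identity carried by a lesion-like
#'   region (smooth bright ellipse = benign, irregular dark spiculated blob =
#'   malignant, background only = normal); `"breakhis"` — RGB, class identity
#'   carried by the texture frequency and chromaticity of a tissue region.
#' @param n_per_class Named integer vector of class sizes. Defaults emulate
#'   the class imbalance of the public breast-image datasets: 437/210/133
#'   (benign/malignant/normal, total 780) in `"busi"` mode and 2480/5429
#'   (benign/malignant) in `"breakhis"` mode.
#' @param image_size Square image side in pixels.
#' @param lesion_radius Length-2 range of lesion radii in pixels.
#' @param contrast Class-signal strength in \[0,1\]: scales how far lesion
#'   intensities sit from the background level.
#' @param noise Background noise level (speckle dispersion).
#' @param margin Placement margin in pixels kept between the lesion and the
#'   image border (one 16-pixel patch by default — capped at a quarter of the
#'   image for very small images — so lesions always cover whole patches only
#'   partially).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(mode = c("busi", "breakhis"),
                           n_per_class = NULL,
                           image_size = 256L,
                           lesion_radius = NULL,
                           contrast = 1,
                           noise = 0.16,
                           margin = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(margin)) margin <- min(16L, image_size %/% 4L)
  if (is.null(n_per_class)) {
    n_per_class <- if (mode == "busi") {
      c(benign = 437L, malignant = 210L, normal = 133L)
    } else {
      c(benign = 2480L, malignant = 5429L)
    }
  }
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- if (mode == "busi") {
      c("benign", "malignant", "normal")[seq_along(n_per_class)]
    } else {
      c("benign", "malignant")[seq_along(n_per_class)]
    }
  }
  if (length(n_per_class) < 2L) stop("need at least 2 classes")
  if (is.null(lesion_radius)) {
    lesion_radius <- round(image_size * c(0.14, 0.23))
  }
  if (max(lesion_radius) + margin >= image_size / 2) {
    stop(sprintf("lesion radius %d + margin %d does not fit in a %d-pixel image",
                 max(lesion_radius), margin, image_size))
  }
  structure(list(mode = mode, n_per_class = n_per_class,
                 image_size = as.integer(image_size),
                 channels = if (mode == "busi") 1L else 3L,
                 lesion_radius = lesion_radius, contrast = contrast,
                 noise = noise, margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# speckled multiplicative background, mean `level`
speckle_bg <- function(S, level, noise) {
  matrix(level * stats::rgamma(S * S, shape = 1 / noise^2, scale = noise^2), S, S)
}

# heterogeneous echo field: per-tile brightness offsets (tiles of S/4 pixels),
# emulating the patchy echogenicity of real tissue
patchwork_field <- function(S, amp = 0.15) {
  t <- S %/% 4L
  offs <- matrix(stats::runif(16L, -amp, amp), 4L, 4L)
  offs[rep(seq_len(4L), each = t), rep(seq_len(4L), each = t)]
}

# soft elliptical membership weight in [0,1]; 0.5 level set = the ellipse
ellipse_weight <- function(S, cx, cy, a, b, theta, edge = 0.08) {
  x <- matrix(seq_len(S), S, S, byrow = TRUE) - cx  # x along columns
  y <- matrix(seq_len(S), S, S) - cy
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  d <- sqrt((xr / a)^2 + (yr / b)^2)
  1 / (1 + exp((d - 1) / edge))
}

# jagged star-shaped membership (hard edge): inside iff r <= r0 * (1 + spikes)
star_weight <- function(S, cx, cy, r0, n_lobes = 7L, amp = 0.35) {
  ak <- stats::runif(n_lobes, -amp, amp) / sqrt(n_lobes)
  ph <- stats::runif(n_lobes, 0, 2 * pi)
  x <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  y <- matrix(seq_len(S), S, S) - cy
  th <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  mod <- rep(1, length(th))
  for (k in seq_len(n_lobes)) mod <- mod + ak[k] * sin((k + 1L) * th + ph[k])
  w <- r <= r0 * pmax(matrix(mod, S, S), 0.3)
  w * 1
}

busi_sample <- function(spec, class_name) {
  S <- spec$image_size
  # The background is a speckled field with patchy per-tile echogenicity that
  # is statistically identical across classes, so aggregate image statistics
  # are dominated by tile noise. The class signal is the lesion's local
  # contrast: "benign" is a smooth ellipse brighter than any background tile,
  # "malignant" an irregular spiculated blob darker than any background tile.
  # The lesion patches are therefore the intensity extremes of each image —
  # informative, localized, and linearly readable patch by patch.
  bg_level <- 0.42
  bg <- speckle_bg(S, bg_level, spec$noise) + patchwork_field(S)
  mask <- matrix(0L, S, S)
  if (class_name != "normal") {
    r <- stats::runif(1, spec$lesion_radius[1L], spec$lesion_radius[2L])
    lo <- r + spec$margin; hi <- S - r - spec$margin
    cx <- stats::runif(1, lo, hi); cy <- stats::runif(1, lo, hi)
    if (class_name == "benign") {
      # smooth homogeneous bright ellipse
      ab <- r * stats::runif(2, 0.75, 1.15)
      w <- ellipse_weight(S, cx, cy, ab[1L], ab[2L], stats::runif(1, 0, pi))
      level <- bg_level + spec$contrast * 0.30 + stats::rnorm(1, 0, 0.05)
    } else {
      # irregular dark blob with spiculated border
      w <- star_weight(S, cx, cy, r)
      level <- bg_level - spec$contrast * 0.30 + stats::rnorm(1, 0, 0.05)
    }
    lesion <- level + matrix(stats::rnorm(S * S, 0, 0.04), S, S)
    img <- bg * (1 - w) + lesion * w
    mask[w > 0.5] <- 1L
  } else {
    img <- bg
  }
  image <- array(clamp01(img), c(S, S, 1L))
  list(image = image, mask = mask)
}

breakhis_sample <- function(spec, class_name) {
  S <- spec$image_size
  base <- c(0.88, 0.80, 0.84)  # pale tissue background
  img <- array(0, c(S, S, 3L))
  noise <- matrix(stats::rnorm(S * S, 0, spec$noise / 2), S, S)
  r <- stats::runif(1, spec$lesion_radius[1L], spec$lesion_radius[2L])
  lo <- r + spec$margin; hi <- S - r - spec$margin
  cx <- stats::runif(1, lo, hi); cy <- stats::runif(1, lo, hi)
  ab <- r * stats::runif(2, 0.8, 1.2)
  w <- ellipse_weight(S, cx, cy, ab[1L], ab[2L], stats::runif(1, 0, pi), edge = 0.1)
  xg <- matrix(seq_len(S), S, S, byrow = TRUE) / S
  yg <- matrix(seq_len(S), S, S) / S
  if (class_name == "benign") {
    freq <- stats::runif(1, 2.5, 4)      # coarse stroma-like texture
    chroma <- c(0.85, 0.55, 0.65)        # pink (eosin-dominated)
    tex <- 0.5 + 0.5 * sin(2 * pi * freq * xg + stats::runif(1, 0, 2 * pi)) *
      sin(2 * pi * freq * yg + stats::runif(1, 0, 2 * pi))
  } else {
    freq <- stats::runif(1, 9, 13)       # dense high-frequency nuclear texture
    chroma <- c(0.55, 0.35, 0.70)        # purple (hematoxylin-dominated)
    tex <- 0.5 + 0.5 * sin(2 * pi * freq * xg + stats::runif(1, 0, 2 * pi)) *
      sin(2 * pi * freq * yg + stats::runif(1, 0, 2 * pi))
    tex[matrix(stats::runif(S * S) < 0.06, S, S)] <- 0  # nuclei-like dark dots
  }
  for (ch in 1:3) {
    region <- chroma[ch] * (0.55 + spec$contrast * 0.45 * tex)
    img[, , ch] <- clamp01(base[ch] + noise * (1 - w) + (region - base[ch]) * w)
  }
  list(image = img, mask = (w > 0.5) * 1L)
}

#' Generate a synthetic labeled image dataset
#'
#' Deterministic given `spec$seed`. Lesion centers are uniform at random
#' subject to the border margin; "normal"-class samples have all-zero masks.
#'
#' @param spec A [synthetic_spec()].
#' @return List of samples, each a list with `image` (`S x S x C` array in
#'   \[0,1\]), `label` (1-based class index), `class` (class name), and `mask`
#'   (`S x S` binary matrix of the informative region). Class names are
#'   attached as attribute `"classes"`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- make_rng(spec$seed)
  classes <- names(spec$n_per_class)
  samples <- rng_eval(rng, {
    out <- vector("list", sum(spec$n_per_class))
    i <- 0L
    for (k in seq_along(classes)) {
      for (j in seq_len(spec$n_per_class[[k]])) {
        i <- i + 1L
        s <- if (spec$mode == "busi") {
          busi_sample(spec, classes[k])
        } else {
          breakhis_sample(spec, classes[k])
        }
        s$label <- k
        s$class <- classes[k]
        out[[i]] <- s
      }
    }
    out
  })
  attr(samples, "classes") <- classes
  samples
}

#' Export a synthetic dataset as a PNG image folder
#'
#' Writes one subdirectory per class of PNG images, masks under `masks/`, and
#' a `manifest.csv` (filename, class, 0-based label, mask path). Grayscale
#' images are written as single-channel PNGs.
#'
#' @param samples Output of [generate_synthetic()].
#' @param directory Target directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
export_dataset <- function(samples, directory) {
  classes <- attr(samples, "classes")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  for (cl in classes) dir.create(file.path(directory, cl), showWarnings = FALSE)
  rows <- vector("list", length(samples))
  counter <- integer(length(classes))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    counter[s$label] <- counter[s$label] + 1L
    fn <- sprintf("%s_%04d.png", s$class, counter[s$label])
    img <- s$image
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    png::writePNG(img, file.path(directory, s$class, fn))
    mask_fn <- file.path("masks", sprintf("%s_%04d_mask.png", s$class, counter[s$label]))
    png::writePNG(s$mask * 1.0, file.path(directory, mask_fn))
    rows[[i]] <- data.frame(filename = file.path(s$class, fn), class = s$class,
                            label = s$label - 1L, mask = mask_fn)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Patches overlapping an informative-region mask
#'
#' Exact geometric answer to "which patch-grid cells contain mask pixels",
#' the reference that retained-token localization is scored against.
#'
#' @param mask Binary `S x S` matrix.
#' @param P Patch side in pixels.
#' @return Integer vector of 1-based row-major patch indices.
#' @export
patches_overlapping_mask <- function(mask, P) {
  S <- nrow(mask)
  g <- S %/% P
  hit <- integer(0)
  for (r in seq_len(g)) {
    for (cc in seq_len(g)) {
      blk <- mask[((r - 1L) * P + 1L):(r * P), ((cc - 1L) * P + 1L):(cc * P)]
      if (any(blk > 0)) hit <- c(hit, (r - 1L) * g + cc)
    }
  }
  hit
}

#' Fraction of retained patches that overlap the mask
#'
#' @param patch_ids 1-based row-major patch indices (e.g. a `patch_map` from
#'   [vit_forward()]).
#' @param mask Binary mask matrix.
#' @param P Patch side.
#' @return Fraction in \[0,1\]; `NA` if `patch_ids` is empty.
#' @export
patch_overlap_fraction <- function(patch_ids, mask, P) {
  if (length(patch_ids) == 0L) return(NA_real_)
  mean(patch_ids %in% patches_overlapping_mask(mask, P))
}
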