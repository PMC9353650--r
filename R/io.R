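# Dataset loading, run configuration, overlay rendering, and the command-line
# surface. Images travel as H x W x C arrays with intensities in [0,1]; class
# indices come from lexicographically sorted directory names.

resize_image <- function(x, size) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1L] == size && dim(x)[2L] == size) return(x)
  y <- as.array(EBImage::resize(x, w = size, h = size))
  if (length(dim(y)) == 2L) dim(y) <- c(dim(y), 1L)
  clamp01(y)
}

normalize_decoded <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  ch <- dim(x)[3L]
  if (ch == 2L) x <- x[, , 1L, drop = FALSE]          # gray + alpha
  if (ch == 4L) x <- x[, , 1:3, drop = FALSE]         # RGB + alpha
  x
}

#' Load a class-per-subdirectory PNG image folder
#'
#' Class labels come from subdirectory names, sorted lexicographically to
#' 1-based indices. Images are decoded, optionally resized to a square input
#' size, and intensity-scaled to \[0,1\] (no mean/variance normalization).
#' Unreadable files are skipped with a warning; an empty class is an error.
#'
#' @param directory Dataset root; a `masks` subdirectory, if present, is
#'   ignored.
#' @param input_size Optional target side length in pixels.
#' @return List with `images` (list of arrays), `labels` (1-based integers),
#'   `classes` (sorted class names), and `files` (relative paths).
#' @export
load_image_folder <- function(directory, input_size = NULL) {
  if (!dir.exists(directory)) stop("data directory not found: ", directory)
  classes <- sort(setdiff(list.dirs(directory, recursive = FALSE,
                                    full.names = FALSE), "masks"))
  if (length(classes) == 0L) stop("no class subdirectories in ", directory)
  images <- list(); labels <- integer(0); files <- character(0)
  for (k in seq_along(classes)) {
    fns <- sort(list.files(file.path(directory, classes[k]), pattern = "\\.png$",
                           full.names = FALSE))
    if (length(fns) == 0L) stop("class directory is empty: ", classes[k])
    for (fn in fns) {
      path <- file.path(directory, classes[k], fn)
      img <- tryCatch(png::readPNG(path), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", path)
        next
      }
      img <- normalize_decoded(img)
      if (!is.null(input_size)) img <- resize_image(img, input_size)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k)
      files <- c(files, file.path(classes[k], fn))
    }
  }
  list(images = images, labels = labels, classes = classes, files = files)
}

#' Default run configuration
#'
#' Flat key-value configuration covering the full-scale reference training
#' setting (Adam learning rate 2e-5, eps 1e-8, batch size 64, 300 epochs,
#' 256x256 inputs, token schedule 256/128/64/32/16/8) together with model,
#' augmentation, and split settings.
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(learning_rate = 2e-5, eps = 1e-8, batch_size = 64L, epochs = 300L,
       input_size = 256L, ats_tokens = c(256L, 128L, 64L, 32L, 16L, 8L),
       channels = 1L, patch = 16L, dim = 128L, depth = 6L, heads = 4L,
       mlp_ratio = 4L, split_ratios = c(0.7, 0.1, 0.2), labeled_frac = 0.8,
       seed = 1L, output_dir = "runs")
}

#' Read a run configuration file
#'
#' YAML-style flat key-value file; keys not present fall back to
#' [default_run_config()]. The train/val/test ratios must be positive and sum
#' to 1.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Named list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  r <- as.numeric(cfg$split_ratios)
  if (length(r) != 3L || any(r <= 0) || abs(sum(r) - 1) > 1e-9) {
    stop("split_ratios must be three positive numbers summing to 1")
  }
  cfg
}

#' Write a reproducibility snapshot of a run
#'
#' Saves the configuration, the seed, and (when available) the source tree's
#' `git describe` string next to the run outputs.
#'
#' @param config Run configuration list.
#' @param directory Output directory.
#' @return The snapshot path, invisibly.
#' @export
write_run_snapshot <- function(config, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  gd <- tryCatch(
    suppressWarnings(system2("git", c("describe", "--always", "--dirty"),
                             stdout = TRUE, stderr = FALSE))[1L],
    error = function(e) NA_character_)
  snap <- c(config, list(git_describe = if (is.na(gd)) "unavailable" else gd))
  path <- file.path(directory, "config.yaml")
  yaml::write_yaml(snap, path)
  invisible(path)
}

#' Write a training log as line-delimited records
#'
#' @param fit An `"atsvit_fit"` object.
#' @param path Output file; one tab-separated record per epoch with the loss
#'   components and validation metrics.
#' @return The path, invisibly.
#' @export
write_training_log <- function(fit, path) {
  utils::write.table(fit$log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw retained-token boxes onto an image
#'
#' Marks the pixel boxes of [top_tokens()] with a 1-pixel bright border (red
#' on RGB images) for visual inspection of where sampling focused.
#'
#' @param image `H x W x C` array in \[0,1\].
#' @param boxes Data frame from [top_tokens()].
#' @return Overlay image as an `H x W x 3` array.
#' @export
draw_token_overlay <- function(image, boxes) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (dim(image)[3L] == 1L) {
    image <- array(rep(image, 3L), c(dim(image)[1:2], 3L))
  }
  for (i in seq_len(nrow(boxes))) {
    rows <- (boxes$y0[i] + 1L):boxes$y1[i]
    cols <- (boxes$x0[i] + 1L):boxes$x1[i]
    edge_r <- c(rows[1L], rows[length(rows)])
    edge_c <- c(cols[1L], cols[length(cols)])
    image[edge_r, cols, 1L] <- 1; image[edge_r, cols, 2:3] <- 0
    image[rows, edge_c, 1L] <- 1; image[rows, edge_c, 2:3] <- 0
  }
  image
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: atsvit <command> [--flag value ...]",
    "",
    "commands:",
    "  generate-data  --out DIR [--mode busi|breakhis] [--size N] [--counts a,b,c] [--seed N]",
    "  train          --data DIR --out DIR [--config FILE] [--seed N]",
    "  evaluate       --data DIR --checkpoint FILE",
    "  visualize-tokens --data DIR --checkpoint FILE --out DIR [--top K]",
    sep = "\n")
}

parse_flags <- function(args, allowed) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (!key %in% allowed) stop("unknown flag: --", key)
    if (i == length(args)) stop("missing value for --", key)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Thin dispatcher backing the `inst/cli/atsvit.R` script. Subcommands:
#' `generate-data`, `train`, `evaluate`, `visualize-tokens`. Every run writes
#' a config snapshot with the seed and a `git describe` string.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit status (0 on success), invisibly.
#' @export
atsvit_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L) stop(cli_usage(), call. = FALSE)
    cmd <- argv[1L]
    args <- argv[-1L]
    switch(cmd,
      "generate-data" = cli_generate(args),
      "train" = cli_train(args),
      "evaluate" = cli_evaluate(args),
      "visualize-tokens" = cli_visualize(args),
      stop("unknown command: ", cmd, "\n", cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_generate <- function(args) {
  f <- parse_flags(args, c("out", "mode", "size", "counts", "seed"))
  if (is.null(f$out)) stop("generate-data requires --out")
  counts <- if (!is.null(f$counts)) as.integer(strsplit(f$counts, ",")[[1L]])
  spec <- synthetic_spec(mode = if (is.null(f$mode)) "busi" else f$mode,
                         n_per_class = counts,
                         image_size = if (is.null(f$size)) 256L else as.integer(f$size),
                         seed = if (is.null(f$seed)) 1L else as.integer(f$seed))
  export_dataset(generate_synthetic(spec), f$out)
  message("wrote ", sum(spec$n_per_class), " images to ", f$out)
}

cli_model_from_config <- function(cfg) {
  vit_init(vit_config(image_size = cfg$input_size, channels = cfg$channels,
                      patch = cfg$patch, dim = cfg$dim, depth = cfg$depth,
                      heads = cfg$heads, mlp_ratio = cfg$mlp_ratio,
                      n_classes = cfg$n_classes,
                      token_schedule = cfg$ats_tokens, seed = cfg$seed))
}

cli_train <- function(args) {
  f <- parse_flags(args, c("data", "out", "config", "seed"))
  if (is.null(f$data) || is.null(f$out)) stop("train requires --data and --out")
  cfg <- read_run_config(f$config)
  if (!is.null(f$seed)) cfg$seed <- as.integer(f$seed)
  ds <- load_image_folder(f$data, input_size = cfg$input_size)
  cfg$n_classes <- length(ds$classes)
  sp <- split_ssl(ds$labels, ratios = cfg$split_ratios,
                  labeled_frac = cfg$labeled_frac, seed = cfg$seed)
  model <- cli_model_from_config(cfg)
  fit <- train_atsvit(model,
                      x_l = ds$images[sp$train_labeled],
                      y_l = ds$labels[sp$train_labeled],
                      x_u = ds$images[sp$train_unlabeled],
                      val = list(images = ds$images[sp$val],
                                 labels = ds$labels[sp$val]),
                      config = train_config(learning_rate = cfg$learning_rate,
                                            eps = cfg$eps,
                                            batch_size = cfg$batch_size,
                                            epochs = cfg$epochs,
                                            seed = cfg$seed, verbose = TRUE))
  dir.create(f$out, recursive = TRUE, showWarnings = FALSE)
  write_run_snapshot(cfg, f$out)
  write_training_log(fit, file.path(f$out, "training_log.tsv"))
  save_checkpoint(if (!is.null(fit$best_model)) fit$best_model else fit$model,
                  file.path(f$out, "checkpoint.rds"))
  ev <- evaluate_model(fit$model, ds$images[sp$test], ds$labels[sp$test])
  format_metrics(ev$metrics, file.path(f$out, "test_metrics.tsv"))
  print(ev$metrics)
}

cli_evaluate <- function(args) {
  f <- parse_flags(args, c("data", "checkpoint"))
  if (is.null(f$data) || is.null(f$checkpoint)) {
    stop("evaluate requires --data and --checkpoint")
  }
  model <- load_checkpoint(f$checkpoint)
  ds <- load_image_folder(f$data, input_size = model$config$image_size)
  ev <- evaluate_model(model, ds$images, ds$labels)
  print(ev$metrics)
}

cli_visualize <- function(args) {
  f <- parse_flags(args, c("data", "checkpoint", "out", "top"))
  if (is.null(f$data) || is.null(f$checkpoint) || is.null(f$out)) {
    stop("visualize-tokens requires --data, --checkpoint and --out")
  }
  k <- if (is.null(f$top)) 8L else as.integer(f$top)
  model <- load_checkpoint(f$checkpoint)
  ds <- load_image_folder(f$data, input_size = model$config$image_size)
  dir.create(f$out, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$images)) {
    boxes <- top_tokens(model, ds$images[[i]], k = k)
    ov <- draw_token_overlay(ds$images[[i]], boxes)
    png::writePNG(ov, file.path(f$out, paste0("overlay_", basename(ds$files[i]))))
  }
  message("wrote ", length(ds$images), " overlays to ", f$out)
}
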