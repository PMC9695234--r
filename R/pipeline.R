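#' Adam optimizer parameters
#'
#' Defaults follow the study configuration: learning rate 1e-4 and the
#' standard recommended moment decays and epsilon.
#'
#' @param learning_rate Step size alpha (> 0).
#' @param beta1,beta2 Exponential decay rates for the first/second moment
#'   estimates (in \[0, 1)).
#' @param epsilon Division-by-zero guard.
#' @return An object of class `usseg_adam`.
#' @export
adam_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon), class = "usseg_adam")
}

#' Training configuration
#'
#' @param epochs Training epochs (default 25).
#' @param batch_size Images per optimizer step (default 8).
#' @param split_fractions Train/validation/test fractions, summing to 1
#'   (default 0.70 / 0.20 / 0.10).
#' @param split_unit `"examination"` (default: all frames of one examination
#'   stay in one partition, avoiding leakage of near-duplicate frames) or
#'   `"frame"` (fully random frame-level split).
#' @param seed Single global seed governing split, weight initialization and
#'   epoch shuffling.
#' @param resize_to Model input extent; frames and masks are resized to
#'   `resize_to x resize_to` during dataset assembly.
#' @param loss A [tversky_params()] or a preset name (`"dice"`, `"focal"`).
#' @return An object of class `usseg_train_config`.
#' @export
train_config <- function(epochs = 25L, batch_size = 8L,
                         split_fractions = c(0.70, 0.20, 0.10),
                         split_unit = c("examination", "frame"),
                         seed = 1L, resize_to = 256L, loss = "dice") {
  split_unit <- match.arg(split_unit)
  if (length(split_fractions) != 3L ||
      abs(sum(split_fractions) - 1) > 1e-9 || any(split_fractions < 0))
    stop("split_fractions must be three non-negative numbers summing to 1")
  if (is.character(loss)) loss <- loss_preset(loss)
  stopifnot(inherits(loss, "usseg_tversky_params"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_fractions = split_fractions, split_unit = split_unit,
                 seed = as.integer(seed), resize_to = as.integer(resize_to),
                 loss = loss), class = "usseg_train_config")
}

resize_frame <- function(m, size) {
  if (all(dim(m) == size)) return(m)
  EBImage::resize(m, w = size, h = size, filter = "bilinear")
}

resize_mask <- function(m, size) {
  if (all(dim(m) == size)) return(m)
  EBImage::resize(m, w = size, h = size, filter = "none")
}

new_dataset <- function(x, y, source, id) {
  structure(list(x = x, y = y, source = source, id = id),
            class = "usseg_dataset")
}

#' @export
print.usseg_dataset <- function(x, ...) {
  cat(sprintf("<usseg_dataset> %d frame/mask pairs (%dx%d), %d examinations\n",
              length(x$x), nrow(x$x[[1]]), ncol(x$x[[1]]),
              length(unique(x$source))))
  invisible(x)
}

#' Assemble a paired frame/mask dataset from directories
#'
#' Pairs every frame PNG with its mask by the `-mask` naming rule, resizes
#' frames with bilinear interpolation and masks with nearest-neighbour
#' (keeping them binary) to `resize_to x resize_to` without preserving
#' aspect ratio, and scales intensities to \[0, 1\].
#'
#' @param frames_dir Directory of grayscale frame PNGs.
#' @param masks_dir Directory of binary mask PNGs named
#'   `<frame base>-mask.png`.
#' @param resize_to Target extent in pixels.
#' @return A `usseg_dataset`: lists `x` (frame matrices in \[0, 1\]) and `y`
#'   (0/1 mask matrices), `source` (examination id parsed from the
#'   `<source>_f<id>` name, or the file name), `id` (frame file names).
#' @export
assemble_dataset <- function(frames_dir, masks_dir, resize_to = 256L) {
  frames <- sort(list.files(frames_dir, pattern = "\\.png$"))
  if (length(frames) == 0L) stop("no frame PNGs in ", frames_dir)
  expected <- vapply(frames, mask_filename, character(1))
  have <- file.exists(file.path(masks_dir, expected))
  if (any(!have))
    stop("frames without a matching mask: ",
         paste(utils::head(frames[!have], 10L), collapse = ", "))
  orphans <- setdiff(list.files(masks_dir, pattern = "\\.png$"), expected)
  if (length(orphans) > 0L)
    stop("masks without a matching frame: ",
         paste(utils::head(orphans, 10L), collapse = ", "))
  x <- vector("list", length(frames)); y <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- read_frame_png(file.path(frames_dir, frames[i]))
    mk <- read_mask(file.path(masks_dir, expected[i]))
    if (!identical(dim(fr), dim(mk$pixels)))
      stop("frame/mask extent mismatch for ", frames[i])
    x[[i]] <- resize_frame(fr / 255, resize_to)
    y[[i]] <- resize_mask(mk$pixels, resize_to)
  }
  source <- sub("_f[0-9]+\\.png$", "", frames)
  new_dataset(x, y, source, frames)
}

#' Build an in-memory dataset from a phantom suite
#'
#' @param suite Result of [phantom_suite()].
#' @param resize_to Target extent in pixels.
#' @return A `usseg_dataset` (see [assemble_dataset()]).
#' @export
as_dataset <- function(suite, resize_to = 256L) {
  x <- lapply(suite, function(p) resize_frame(p$frame / 255, resize_to))
  y <- lapply(suite, function(p) resize_mask(p$mask$pixels, resize_to))
  new_dataset(x, y, vapply(suite, `[[`, character(1), "source_id"),
              vapply(suite, `[[`, character(1), "source_id"))
}

#' Randomly partition a dataset into train / validation / test
#'
#' Frame-level: validation and test sizes are the floors of their fractions
#' and the remainder goes to training. Examination-level (the default):
#' examinations are randomly ordered and assigned whole to test, then
#' validation, then training, so no examination's frames straddle
#' partitions; sizes then match the fractions as closely as whole
#' examinations allow.
#'
#' @param dataset A `usseg_dataset`.
#' @param cfg A [train_config()]; supplies fractions, unit and seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, cfg) {
  n <- length(dataset$x)
  if (n < 3L) stop("dataset has fewer than 3 samples")
  fr <- cfg$split_fractions
  set.seed(cfg$seed)
  if (cfg$split_unit == "frame") {
    n_val <- floor(fr[2] * n); n_test <- floor(fr[3] * n)
    perm <- sample.int(n)
    test <- perm[seq_len(n_test)]
    val <- perm[n_test + seq_len(n_val)]
    train <- perm[-seq_len(n_test + n_val)]
  } else {
    exams <- unique(dataset$source)
    perm <- sample(exams)
    counts <- table(dataset$source)[perm]
    cum <- cumsum(as.integer(counts))
    n_test_target <- fr[3] * n
    n_val_target <- fr[2] * n
    k_test <- which.min(abs(cum - n_test_target))
    if (cum[k_test] > n - 2L) k_test <- 0L # keep train/val non-empty
    rest <- if (k_test > 0L) cum - cum[k_test] else cum
    k_val <- which.min(abs(rest - n_val_target))
    test_ex <- if (k_test > 0L) perm[seq_len(k_test)] else character(0)
    val_ex <- perm[setdiff(seq_len(k_val), seq_len(k_test))]
    test <- which(dataset$source %in% test_ex)
    val <- which(dataset$source %in% val_ex)
    train <- setdiff(seq_len(n), c(test, val))
  }
  if (length(train) == 0L || length(val) == 0L)
    stop("split left the training or validation partition empty")
  list(train = sort(train), validation = sort(val), test = sort(test))
}

flatten_grads <- function(grads) grads # placeholder kept for clarity

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, opt, t) {
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W -
      opt$learning_rate * (s$mW / corr1) / (sqrt(s$vW / corr2) + opt$epsilon)
    params[[nm]]$b <- params[[nm]]$b -
      opt$learning_rate * (s$mb / corr1) / (sqrt(s$vb / corr2) + opt$epsilon)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

eval_partition <- function(model, dataset, idx, loss_pars, threshold = 0.5) {
  reports <- vector("list", length(idx)); losses <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    prob <- unet_forward(model, dataset$x[[i]])$prob
    losses[j] <- focal_tversky_loss(prob, dataset$y[[i]], loss_pars)
    reports[[j]] <- compute_metrics(confusion((prob >= threshold) * 1,
                                              dataset$y[[i]]))
  }
  agg <- aggregate_metrics(reports, "macro")
  c(loss = mean(losses), agg$mean)
}

#' Train the compact U-Net on a paired dataset
#'
#' Runs `epochs` epochs of minibatch Adam on the focal Tversky loss
#' (computed per image, averaged over the batch). One global seed governs
#' the split, the weight initialization and the epoch shuffling, so two runs
#' with identical configuration are bit-identical. Per-epoch training
#' metrics are running averages over the minibatches (predictions taken
#' before each update); validation metrics are computed after each epoch on
#' thresholded (0.5) masks. The best-validation-IoU weights are retained
#' alongside the final weights.
#'
#' @param dataset A `usseg_dataset` whose extent matches
#'   `model_config$input_size`.
#' @param model_config A [unet_config()].
#' @param cfg A [train_config()].
#' @param opt An [adam_config()].
#' @param verbose Print one line per epoch.
#' @return list with `model` (final weights), `best` (best-validation-IoU
#'   weights and its epoch), `trace` (data.frame, one row per epoch: losses
#'   and training/validation IoU, recall, precision, accuracy), `split`
#'   (the index partition), `n_steps` (optimizer steps taken).
#' @export
train_unet <- function(dataset, model_config, cfg, opt = adam_config(),
                       verbose = FALSE) {
  stopifnot(inherits(dataset, "usseg_dataset"),
            inherits(model_config, "usseg_unet_config"),
            inherits(cfg, "usseg_train_config"))
  if (nrow(dataset$x[[1]]) != model_config$input_size)
    stop("dataset extent ", nrow(dataset$x[[1]]),
         " does not match model input_size ", model_config$input_size)
  split <- split_dataset(dataset, cfg) # seeds the RNG stream with cfg$seed
  model <- unet_build(model_config)
  state <- adam_init(model$params)
  loss_pars <- cfg$loss
  t <- 0L
  trace <- vector("list", cfg$epochs)
  best <- list(iou = -Inf, params = NULL, epoch = NA_integer_)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(split$train)
    batch_losses <- c()
    run_reports <- list()
    for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        fw <- unet_forward(model, dataset$x[[i]], keep_cache = TRUE)
        bl <- bl + focal_tversky_loss(fw$prob, dataset$y[[i]], loss_pars)
        dprob <- focal_tversky_grad(fw$prob, dataset$y[[i]], loss_pars) /
          length(batch)
        g <- unet_backward(model, fw$cache, dprob)
        grads <- if (is.null(grads)) g else
          mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                 grads, g, SIMPLIFY = FALSE)
        run_reports[[length(run_reports) + 1L]] <-
          compute_metrics(confusion((fw$prob >= 0.5) * 1, dataset$y[[i]]))
      }
      bl <- bl / length(batch)
      if (!is.finite(bl)) {
        warning("non-finite loss at epoch ", epoch, "; aborting training")
        return(list(model = model, best = best,
                    trace = do.call(rbind, trace[seq_len(epoch - 1L)]),
                    split = split, n_steps = t, diverged = TRUE))
      }
      batch_losses <- c(batch_losses, bl)
      t <- t + 1L
      upd <- adam_step(model$params, grads, state, opt, t)
      model$params <- upd$params; state <- upd$state
    }
    tr_agg <- aggregate_metrics(run_reports, "macro")$mean
    va <- eval_partition(model, dataset, split$validation, loss_pars)
    if (!is.na(va[["iou"]]) && va[["iou"]] > best$iou)
      best <- list(iou = va[["iou"]], params = model$params, epoch = epoch)
    trace[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(batch_losses),
      train_iou = tr_agg[["iou"]], train_recall = tr_agg[["recall"]],
      train_precision = tr_agg[["precision"]],
      train_accuracy = tr_agg[["accuracy"]],
      val_loss = va[["loss"]], val_iou = va[["iou"]],
      val_recall = va[["recall"]], val_precision = va[["precision"]],
      val_accuracy = va[["accuracy"]])
    if (verbose)
      message(sprintf(
        "epoch %2d | loss %.4f | train IoU %.4f | val loss %.4f | val IoU %.4f",
        epoch, mean(batch_losses), tr_agg[["iou"]], va[["loss"]], va[["iou"]]))
  }
  list(model = model,
       best = best,
       trace = do.call(rbind, trace),
       split = split, n_steps = t, diverged = FALSE)
}

#' Benchmark single-frame inference latency
#'
#' Measures per-frame wall-clock time of [unet_predict()] only; loading the
#' model from its checkpoint is timed once, separately, and excluded from
#' the per-call statistics. The sub-100 ms real-time budget (one frame
#' period at 7-12 fps) is flagged in the report, not asserted, since it is
#' hardware-dependent.
#'
#' @param checkpoint Path to a model checkpoint ([save_checkpoint()]), or a
#'   `usseg_unet` (then `model_load_s` is `NA`).
#' @param frames List of input frame matrices (typically 100 random frames).
#' @param json Optional path to write the report as JSON.
#' @return An object of class `usseg_timing`: list with `min_ms`, `max_ms`,
#'   `mean_ms`, `model_load_s`, `n`, `meets_100ms`, `environment`.
#' @export
benchmark_inference <- function(checkpoint, frames, json = NULL) {
  if (is.character(checkpoint)) {
    t0 <- proc.time()[["elapsed"]]
    model <- load_checkpoint(checkpoint)
    load_s <- proc.time()[["elapsed"]] - t0
  } else {
    model <- checkpoint
    load_s <- NA_real_
  }
  stopifnot(inherits(model, "usseg_unet"), length(frames) >= 1L)
  ms <- vapply(frames, function(f) {
    t0 <- proc.time()[["elapsed"]]
    unet_predict(model, f)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  rep <- structure(list(
    min_ms = min(ms), max_ms = max(ms), mean_ms = mean(ms),
    model_load_s = load_s, n = length(ms),
    meets_100ms = max(ms) < 100,
    environment = paste0(R.version.string, " / ", R.version$platform)
  ), class = "usseg_timing")
  if (!is.null(json))
    jsonlite::write_json(unclass(rep), json, auto_unbox = TRUE, digits = NA)
  rep
}

#' @export
print.usseg_timing <- function(x, ...) {
  cat(sprintf(
    "inference over %d frames: min %.2f / mean %.2f / max %.2f ms (load %s s)\n",
    x$n, x$min_ms, x$mean_ms, x$max_ms,
    if (is.na(x$model_load_s)) "-" else sprintf("%.2f", x$model_load_s)))
  cat(sprintf("  real-time (<100 ms/frame): %s\n",
              if (x$meets_100ms) "yes" else "no"))
  invisible(x)
}

# Output extents of every convolution for a 'same'-padded configuration.
unet_layer_extents <- function(cfg) {
  nb <- cfg$encoder_blocks; nc <- cfg$convs_per_block
  s <- cfg$input_size; ext <- c()
  for (i in seq_len(nb)) { ext <- c(ext, rep(s, nc)); s <- s %/% 2L }
  ext <- c(ext, rep(s, nc))
  for (i in rev(seq_len(nb))) { s <- 2L * s; ext <- c(ext, rep(s, nc)) }
  c(ext, s) # head
}

#' Model complexity report
#'
#' Parameter counts as reported by the stored weight arrays, cross-checked
#' against the closed-form layer sum `(k^2 c_in + 1) c_out`, plus a forward
#' FLOP estimate under the stated convention that one multiply-add counts as
#' 2 FLOPs (bias additions included).
#'
#' @param model A `usseg_unet`.
#' @return list with `parameter_count_total`, `parameter_count_trainable`,
#'   `closed_form_count`, `flops`, `flop_convention`.
#' @export
report_complexity <- function(model) {
  stopifnot(inherits(model, "usseg_unet"))
  cfg <- model$config
  reported <- sum(vapply(model$params,
                         function(p) length(p$W) + length(p$b), numeric(1)))
  closed <- unet_parameter_count(cfg)
  tab <- unet_layer_table(cfg)
  flops <- NA_real_
  if (cfg$padding_mode == "same") {
    ext <- unet_layer_extents(cfg)
    flops <- sum((2 * tab$kernel^2 * tab$c_in + 1) * tab$c_out * ext^2)
  }
  list(parameter_count_total = reported,
       parameter_count_trainable = model$parameter_count_trainable,
       closed_form_count = closed,
       flops = flops,
       flop_convention = "1 multiply-add = 2 FLOPs; bias add = 1 FLOP")
}
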