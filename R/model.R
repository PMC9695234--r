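#' Configuration of the compact U-Net encoder-decoder
#'
#' Describes a U-shaped fully convolutional network for binary segmentation:
#' `encoder_blocks` blocks of `convs_per_block` 3x3 convolutions (ReLU) each
#' followed by 2x2/stride-2 max pooling, a bottleneck block, a mirrored
#' decoder (nearest-neighbour 2x upsampling, concatenation with the matching
#' encoder output, convolutions), and a 1x1 convolution + sigmoid head that
#' emits one per-pixel lesion probability channel. Filter counts start at
#' `base_filters` and double after every pooling step.
#'
#' @param input_size Pixels per side of the (square) input tensor. With
#'   `padding_mode = "same"` it must be divisible by `pool^encoder_blocks`.
#' @param encoder_blocks Number of encoder (and decoder) blocks.
#' @param convs_per_block Convolutions per block.
#' @param kernel Convolution kernel side (odd).
#' @param base_filters Filters in the first encoder block; doubles per level.
#' @param pool Max-pool size and stride (only 2 is supported).
#' @param padding_mode `"same"` (zero padding, output extent = input extent;
#'   the mode the training pipeline requires) or `"valid"` (no padding; each
#'   convolution trims `kernel - 1` pixels, so only special input sizes keep
#'   every intermediate extent positive and even at pooling).
#' @param output_channels Output channels (1: lesion probability).
#' @return An object of class `usseg_unet_config`.
#' @export
unet_config <- function(input_size = 256L, encoder_blocks = 4L,
                        convs_per_block = 2L, kernel = 3L, base_filters = 16L,
                        pool = 2L, padding_mode = c("same", "valid"),
                        output_channels = 1L) {
  padding_mode <- match.arg(padding_mode)
  input_size <- as.integer(input_size)
  encoder_blocks <- as.integer(encoder_blocks)
  convs_per_block <- as.integer(convs_per_block)
  kernel <- as.integer(kernel)
  base_filters <- as.integer(base_filters)
  if (pool != 2L) stop("only pool size/stride 2 is supported")
  if (kernel %% 2L != 1L || kernel < 1L) stop("kernel side must be odd and positive")
  if (encoder_blocks < 1L || convs_per_block < 1L || base_filters < 1L)
    stop("encoder_blocks, convs_per_block and base_filters must be >= 1")
  if (output_channels != 1L) stop("only a single output channel is supported")
  cfg <- structure(list(
    input_size = input_size, encoder_blocks = encoder_blocks,
    convs_per_block = convs_per_block, kernel = kernel,
    base_filters = base_filters, pool = 2L, upsample = "nearest",
    activation = "relu", output_channels = 1L, padding_mode = padding_mode
  ), class = "usseg_unet_config")
  unet_plan(cfg) # validates extents, errors on indivisible input_size
  cfg
}

# Per-level extents and channel counts; errors if the geometry is infeasible.
# Returns list(sizes = extent entering each encoder block (and of its output
# for "same"), bottom, out_size).
unet_plan <- function(cfg) {
  nb <- cfg$encoder_blocks
  shrink <- if (cfg$padding_mode == "valid") (cfg$kernel - 1L) * cfg$convs_per_block else 0L
  s <- cfg$input_size
  enc_out <- integer(nb)
  for (i in seq_len(nb)) {
    s <- s - shrink
    if (s < 1L) stop("input_size ", cfg$input_size, " too small for encoder block ", i)
    enc_out[i] <- s
    if (s %% 2L != 0L)
      stop("extent ", s, " entering pooling after encoder block ", i,
           " is not divisible by the pool stride 2; choose another input_size")
    s <- s %/% 2L
  }
  s <- s - shrink
  if (s < 1L) stop("input_size ", cfg$input_size, " too small for the bottleneck")
  bottom <- s
  for (i in rev(seq_len(nb))) {
    s <- 2L * s
    if (cfg$padding_mode == "valid" && s > enc_out[i])
      stop("decoder extent ", s, " exceeds the matching encoder skip (", enc_out[i], ")")
    s <- s - shrink
    if (s < 1L) stop("input_size ", cfg$input_size, " too small for decoder block ", i)
  }
  list(enc_out = enc_out, bottom = bottom, out_size = s)
}

# Channel counts of every convolution, in forward order.
# Returns a data.frame(layer, c_in, c_out, kernel).
unet_layer_table <- function(cfg) {
  nb <- cfg$encoder_blocks; nc <- cfg$convs_per_block; b <- cfg$base_filters
  rows <- list()
  add <- function(name, cin, cout, k) rows[[length(rows) + 1L]] <<-
    data.frame(layer = name, c_in = cin, c_out = cout, kernel = k,
               stringsAsFactors = FALSE)
  cin <- 1L
  for (i in seq_len(nb)) {
    cout <- b * 2L^(i - 1L)
    for (j in seq_len(nc)) { add(sprintf("enc%d_%d", i, j), cin, cout, cfg$kernel); cin <- cout }
  }
  cout <- b * 2L^nb
  for (j in seq_len(nc)) { add(sprintf("bottleneck_%d", j), cin, cout, cfg$kernel); cin <- cout }
  for (i in rev(seq_len(nb))) {
    skip <- b * 2L^(i - 1L)
    cout <- skip
    cin <- cin + skip # concatenated upsampled features + skip
    for (j in seq_len(nc)) { add(sprintf("dec%d_%d", i, j), cin, cout, cfg$kernel); cin <- cout }
  }
  add("head", cin, cfg$output_channels, 1L)
  do.call(rbind, rows)
}

#' Closed-form parameter count of a U-Net configuration
#'
#' Sums `(kernel^2 * c_in + 1) * c_out` over every convolution, including the
#' 1x1 output head. Serves as the independent check of the counts reported by
#' a built model.
#'
#' @param config A [unet_config()].
#' @return Total parameter count (integer-valued numeric).
#' @export
unet_parameter_count <- function(config) {
  tab <- unet_layer_table(config)
  sum((tab$kernel^2 * tab$c_in + 1) * tab$c_out)
}

#' Build a compact U-Net segmentation model
#'
#' Allocates and initializes all convolution weights (He-normal, zero biases;
#' the sigmoid head uses Glorot scaling) using the current RNG state, so
#' `set.seed()` before calling gives reproducible weights. Inputs are
#' zero-centered inside the forward pass, so datasets keep the plain
#' \[0, 1\] intensity scale.
#'
#' @param config A [unet_config()].
#' @return An object of class `usseg_unet`: list with `config`, `params`
#'   (one `list(W, b)` per convolution, named as in the layer table),
#'   `parameter_count_total` and `parameter_count_trainable`.
#' @export
unet_build <- function(config) {
  stopifnot(inherits(config, "usseg_unet_config"))
  tab <- unet_layer_table(config)
  params <- vector("list", nrow(tab))
  names(params) <- tab$layer
  for (r in seq_len(nrow(tab))) {
    k <- tab$kernel[r]; cin <- tab$c_in[r]; cout <- tab$c_out[r]
    fan_in <- k^2 * cin
    sd <- if (tab$layer[r] == "head") sqrt(1 / fan_in) else sqrt(2 / fan_in)
    params[[r]] <- list(
      W = matrix(stats::rnorm(fan_in * cout, sd = sd), fan_in, cout),
      b = numeric(cout)
    )
  }
  n_par <- sum(vapply(params, function(p) length(p$W) + length(p$b), numeric(1)))
  structure(list(config = config, params = params,
                 parameter_count_total = n_par,
                 parameter_count_trainable = n_par),
            class = "usseg_unet")
}

#' @export
print.usseg_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<usseg_unet> input %dx%d, %d encoder blocks, base filters %d, padding '%s'\n",
    cfg$input_size, cfg$input_size, cfg$encoder_blocks, cfg$base_filters,
    cfg$padding_mode))
  cat(sprintf("  parameters: %d total, %d trainable\n",
              x$parameter_count_total, x$parameter_count_trainable))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

crop_border <- function(a, m) {
  if (m == 0L) return(a)
  d <- dim(a)
  a[(m + 1L):(d[1] - m), (m + 1L):(d[2] - m), , drop = FALSE]
}

# One conv + ReLU. 'valid' padding is realised by trimming the border of the
# 'same' result, which is value-identical to an unpadded convolution.
conv_relu <- function(x, p, k, padding_mode) {
  y <- .conv2d_same(x, p$W, p$b, k)
  if (padding_mode == "valid") y <- crop_border(y, (k - 1L) %/% 2L)
  relu(y)
}

center_crop <- function(a, size) {
  d <- dim(a)
  if (d[1] == size && d[2] == size) return(a)
  o1 <- (d[1] - size) %/% 2L; o2 <- (d[2] - size) %/% 2L
  a[(o1 + 1L):(o1 + size), (o2 + 1L):(o2 + size), , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

#' Forward pass of the U-Net
#'
#' @param model A built [unet_build()] model.
#' @param x Input array `input_size x input_size x 1` (or a matrix), values
#'   expected in \[0, 1\].
#' @param keep_cache Keep intermediate activations for backpropagation
#'   (training use; only supported with `"same"` padding).
#' @return list with `prob` (per-pixel probability matrix) and, if requested,
#'   `cache`.
#' @export
unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size)
    stop("input extent ", dim(x)[1], "x", dim(x)[2],
         " does not match the configured input_size ", cfg$input_size)
  if (keep_cache && cfg$padding_mode != "same")
    stop("training (cached) forward passes require padding_mode = 'same'")
  x <- x - 0.5 # zero-center [0,1] intensities; eases early ReLU optimization
  p <- model$params; k <- cfg$kernel; nb <- cfg$encoder_blocks
  nc <- cfg$convs_per_block; pad <- cfg$padding_mode
  cache <- if (keep_cache) list(conv_in = list(), conv_out = list(),
                                pool_idx = list(), pool_in_dim = list()) else NULL
  store <- function(name, xin, xout) {
    if (keep_cache) {
      cache$conv_in[[name]] <<- xin
      cache$conv_out[[name]] <<- xout
    }
  }
  a <- x
  skips <- vector("list", nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nc)) {
      nm <- sprintf("enc%d_%d", i, j)
      out <- conv_relu(a, p[[nm]], k, pad); store(nm, a, out); a <- out
    }
    skips[[i]] <- a
    pl <- .maxpool2(a)
    if (keep_cache) {
      cache$pool_idx[[i]] <- pl$idx
      cache$pool_in_dim[[i]] <- dim(a)
    }
    a <- pl$y
  }
  for (j in seq_len(nc)) {
    nm <- sprintf("bottleneck_%d", j)
    out <- conv_relu(a, p[[nm]], k, pad); store(nm, a, out); a <- out
  }
  for (i in rev(seq_len(nb))) {
    u <- .upsample2(a)
    s <- if (pad == "valid") center_crop(skips[[i]], dim(u)[1]) else skips[[i]]
    a <- concat_channels(u, s)
    for (j in seq_len(nc)) {
      nm <- sprintf("dec%d_%d", i, j)
      out <- conv_relu(a, p[[nm]], k, pad); store(nm, a, out); a <- out
    }
  }
  d <- dim(a)
  A <- matrix(a, d[1] * d[2], d[3])
  z <- A %*% p$head$W + p$head$b
  prob <- matrix(1 / (1 + exp(-z)), d[1], d[2])
  if (keep_cache) {
    cache$head_in <- a
    cache$prob <- prob
  }
  list(prob = prob, cache = cache)
}

# Backpropagation through a cached forward pass ('same' padding only).
# dprob: gradient of the scalar loss w.r.t. the output probabilities.
# Returns gradients in the same structure as model$params.
unet_backward <- function(model, cache, dprob) {
  cfg <- model$config; p <- model$params; k <- cfg$kernel
  nb <- cfg$encoder_blocks; nc <- cfg$convs_per_block
  grads <- vector("list", length(p)); names(grads) <- names(p)

  prob <- cache$prob
  dz <- as.vector(dprob * prob * (1 - prob))
  hin <- cache$head_in
  d <- dim(hin)
  A <- matrix(hin, d[1] * d[2], d[3])
  grads$head <- list(W = crossprod(A, dz), b = sum(dz))
  ga <- array(outer(dz, as.vector(p$head$W)), dim = d)

  back_conv <- function(nm, ga) {
    out <- cache$conv_out[[nm]]
    ga[out <= 0] <- 0
    bw <- .conv2d_same_backward(cache$conv_in[[nm]], p[[nm]]$W, ga, k)
    grads[[nm]] <<- list(W = bw$gw, b = as.vector(bw$gb))
    bw$gx
  }

  skip_grads <- vector("list", nb)
  for (i in seq_len(nb)) {
    for (j in rev(seq_len(nc))) ga <- back_conv(sprintf("dec%d_%d", i, j), ga)
    nup <- dim(ga)[3] - dim(cache$conv_out[[sprintf("enc%d_%d", i, nc)]])[3]
    gu <- ga[, , seq_len(nup), drop = FALSE]
    skip_grads[[i]] <- ga[, , (nup + 1L):dim(ga)[3], drop = FALSE]
    ga <- .upsample2_backward(gu)
  }
  for (j in rev(seq_len(nc))) ga <- back_conv(sprintf("bottleneck_%d", j), ga)
  for (i in rev(seq_len(nb))) {
    din <- cache$pool_in_dim[[i]]
    ga <- .maxpool2_backward(ga, cache$pool_idx[[i]], din[1], din[2])
    ga <- ga + skip_grads[[i]]
    for (j in rev(seq_len(nc))) ga <- back_conv(sprintf("enc%d_%d", i, j), ga)
  }
  grads
}

#' Segment one frame with a trained model
#'
#' Runs exactly one forward pass and thresholds the per-pixel lesion
#' probabilities into a binary mask (probability >= `threshold` is lesion).
#'
#' @param model A `usseg_unet`.
#' @param frame A `usseg_frame`, a numeric matrix in \[0, 255\], or a matrix
#'   already scaled to \[0, 1\].
#' @param threshold Binarization threshold in \[0, 1\].
#' @return list with `prob` (probability matrix) and `mask` (a
#'   [binary_mask()]).
#' @export
unet_predict <- function(model, frame, threshold = 0.5) {
  x <- if (inherits(frame, "usseg_frame")) frame$pixels else frame
  if (!is.matrix(x) && !(is.array(x) && length(dim(x)) == 3L))
    stop("frame must be a matrix or usseg_frame")
  if (max(x) > 1) x <- x / 255
  fw <- unet_forward(model, x)
  list(prob = fw$prob,
       mask = binary_mask((fw$prob >= threshold) * 1L))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the weights and the embedded
#' configuration (stored as plain lists, so it is portable across package
#' versions).
#'
#' @param model A `usseg_unet`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `usseg_unet`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config), params = model$params,
              parameter_count_total = model$parameter_count_total,
              parameter_count_trainable = model$parameter_count_trainable)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "usseg_unet_config")
  structure(list(config = cfg, params = obj$params,
                 parameter_count_total = obj$parameter_count_total,
                 parameter_count_trainable = obj$parameter_count_trainable),
            class = "usseg_unet")
}
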