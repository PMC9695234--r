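#' Tversky loss parameters
#'
#' The triple (alpha, beta, gamma) controlling the focal Tversky loss regime:
#' `alpha` weights false positives (|X \\ Y|), `beta` weights false negatives
#' (|Y \\ X|), and `gamma` is the focusing exponent. `alpha = beta = 0.5`
#' makes the Tversky index the Dice coefficient; `alpha = beta = 1` makes it
#' the Jaccard index (IoU).
#'
#' @param alpha False-positive weight, >= 0.
#' @param beta False-negative weight, >= 0.
#' @param gamma Focusing parameter, > 0.
#' @return An object of class `usseg_tversky_params`.
#' @export
tversky_params <- function(alpha, beta, gamma = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "usseg_tversky_params")
}

#' The two studied loss regimes
#'
#' `"dice"` is (alpha = 0.5, beta = 0.5, gamma = 1): the Tversky index equals
#' the Dice coefficient and the loss treats all labels equally. `"focal"` is
#' (alpha = 0.7, beta = 0.3, gamma = 0.75): false negatives are relatively
#' down-weighted in the denominator and the focusing exponent emphasises
#' hard-to-segment inputs.
#'
#' @param name `"dice"` or `"focal"`.
#' @return A [tversky_params()].
#' @export
loss_preset <- function(name = c("dice", "focal")) {
  switch(match.arg(name),
         dice  = tversky_params(0.5, 0.5, 1),
         focal = tversky_params(0.7, 0.3, 0.75))
}

.LOSS_EPS_PROB <- 1e-7   # probability clamp before logs
.LOSS_SMOOTH   <- 1e-6   # Tversky numerator/denominator smoothing

check_pair <- function(pred, ref) {
  if (inherits(ref, "usseg_mask")) ref <- ref$pixels
  if (!identical(dim(pred), dim(ref)))
    stop("prediction extent (", paste(dim(pred), collapse = "x"),
         ") does not match reference extent (",
         paste(dim(ref), collapse = "x"), ")")
  ref
}

#' Cross entropy over the two-class per-pixel distribution
#'
#' Mean over pixels of `-sum_i t_i log(s_i)` with the two classes
#' (lesion, background) encoded as `(t, 1 - t)` and `(s, 1 - s)`.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param pred Predicted lesion probability matrix, values in \[0, 1\].
#' @param ref Reference [binary_mask()] (or 0/1 matrix).
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(pred, ref) {
  t <- check_pair(pred, ref)
  s <- pmin(pmax(pred, .LOSS_EPS_PROB), 1 - .LOSS_EPS_PROB)
  mean(-(t * log(s) + (1 - t) * log(1 - s)))
}

#' Binary cross entropy
#'
#' The two-class specialisation of [cross_entropy()]: mean over pixels of
#' `-(y log p + (1 - y) log(1 - p))`.
#'
#' @inheritParams cross_entropy
#' @return Non-negative scalar loss.
#' @export
binary_cross_entropy <- function(pred, ref) cross_entropy(pred, ref)

# Soft-set Tversky counts for one prediction/reference pair.
tversky_counts <- function(s, t) {
  list(inter = sum(s * t),      # |X  intersect  Y|
       fp    = sum(s * (1 - t)), # |X \ Y|
       fn    = sum((1 - s) * t)) # |Y \ X|
}

#' Tversky index of a prediction against a reference mask
#'
#' Soft-set realisation `TI = (|X n Y| + e) / (|X n Y| + a|X\\Y| + b|Y\\X| + e)`
#' with `|X n Y| = sum(s t)`, `|X\\Y| = sum(s (1 - t))`,
#' `|Y\\X| = sum((1 - s) t)` and smoothing `e = 1e-6` so that frames with an
#' empty reference and empty prediction score 1 rather than 0/0. For binary
#' predictions this reduces to exact set counting.
#'
#' @inheritParams cross_entropy
#' @param params A [tversky_params()].
#' @param smooth Smoothing constant added to numerator and denominator
#'   (default `1e-6`, the training-time guard). Set to 0 to evaluate the
#'   pure index, e.g. when checking the Dice/Jaccard identities; then an
#'   empty reference with an empty prediction is 0/0 = `NaN`.
#' @return TI in \[0, 1\].
#' @export
tversky_index <- function(pred, ref, params, smooth = .LOSS_SMOOTH) {
  stopifnot(inherits(params, "usseg_tversky_params"))
  t <- check_pair(pred, ref)
  ct <- tversky_counts(pred, t)
  (ct$inter + smooth) /
    (ct$inter + params$alpha * ct$fp + params$beta * ct$fn + smooth)
}

#' Focal Tversky loss
#'
#' `FTL = (1 - TI)^gamma`; `gamma = 1` gives exactly `1 - TI`.
#'
#' @inheritParams tversky_index
#' @return Loss in \[0, 1\].
#' @export
focal_tversky_loss <- function(pred, ref, params, smooth = .LOSS_SMOOTH) {
  (1 - tversky_index(pred, ref, params, smooth = smooth))^params$gamma
}

# Gradient of the focal Tversky loss w.r.t. the predicted probabilities.
# d TI / d s_i = (t_i * D - N * (t_i + alpha (1 - t_i) - beta t_i)) / D^2
# with N, D the smoothed numerator/denominator; d FTL / d TI =
# -gamma (1 - TI)^(gamma - 1).
focal_tversky_grad <- function(pred, ref, params) {
  t <- check_pair(pred, ref)
  ct <- tversky_counts(pred, t)
  N <- ct$inter + .LOSS_SMOOTH
  D <- ct$inter + params$alpha * ct$fp + params$beta * ct$fn + .LOSS_SMOOTH
  ti <- N / D
  dti_ds <- (t * D - N * (t + params$alpha * (1 - t) - params$beta * t)) / D^2
  # floor keeps the gamma < 1 focus factor finite as TI -> 1
  dftl_dti <- -params$gamma * max(1 - ti, 1e-6)^(params$gamma - 1)
  dftl_dti * dti_ds
}
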