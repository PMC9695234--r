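#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,ref [binary_mask()] objects (or 0/1 matrices) of identical
#'   extent.
#' @return An object of class `usseg_confusion`: list with integer `TP`,
#'   `TN`, `FP`, `FN` summing to the pixel count.
#' @export
confusion <- function(pred, ref) {
  p <- if (inherits(pred, "usseg_mask")) pred$pixels else pred
  r <- if (inherits(ref, "usseg_mask")) ref$pixels else ref
  if (!identical(dim(p), dim(r)))
    stop("prediction extent (", paste(dim(p), collapse = "x"),
         ") does not match reference extent (", paste(dim(r), collapse = "x"), ")")
  confusion_counts(TP = sum(p == 1 & r == 1), TN = sum(p == 0 & r == 0),
                   FP = sum(p == 1 & r == 0), FN = sum(p == 0 & r == 1))
}

#' @rdname confusion
#' @param TP,TN,FP,FN Non-negative counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "usseg_confusion")
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Imbalance-aware segmentation metrics from confusion counts
#'
#' Computes IoU (Jaccard), recall, precision, Dice and pixel accuracy:
#' `IoU = TP / (TP + FP + FN)`, `Recall = TP / (TP + FN)`,
#' `Precision = TP / (TP + FP)`, `Dice = 2 TP / (2 TP + FP + FN)`,
#' `Accuracy = (TP + TN) / total`. A zero denominator (e.g. both masks
#' empty) yields the explicit undefined marker `NA`, never a silent 0 -- at
#' the small lesion-area fractions typical of B-mode frames, silent zeros
#' would bias per-frame averages, and a high accuracy alone is misleading
#' (an all-background prediction on a 10\% lesion scores accuracy 0.90 with
#' IoU and recall 0). IoU and Dice are linked by
#' `IoU = Dice / (2 - Dice)`.
#'
#' @param counts A [confusion_counts()] (or the result of [confusion()]).
#' @return An object of class `usseg_metrics`: list with `iou`, `recall`,
#'   `precision`, `dice`, `accuracy` and the `counts`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "usseg_confusion"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  structure(list(
    iou = ratio_or_na(TP, TP + FP + FN),
    recall = ratio_or_na(TP, TP + FN),
    precision = ratio_or_na(TP, TP + FP),
    dice = ratio_or_na(2 * TP, 2 * TP + FP + FN),
    accuracy = ratio_or_na(TP + TN, TP + TN + FP + FN),
    counts = counts
  ), class = "usseg_metrics")
}

#' @export
print.usseg_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("IoU %s | Dice %s | recall %s | precision %s | accuracy %s\n",
              fmt(x$iou), fmt(x$dice), fmt(x$recall), fmt(x$precision),
              fmt(x$accuracy)))
  invisible(x)
}

#' Pixel-level ROC AUC of a probability map against a reference mask
#'
#' Trapezoidal area under the ROC curve over all distinct probability
#' thresholds; ties contribute half, so the value equals the Mann-Whitney
#' probability that a random lesion pixel outranks a random background
#' pixel. A single-class reference has no ranking to evaluate and yields the
#' undefined marker `NA`.
#'
#' @param prob Numeric probability matrix.
#' @param ref A [binary_mask()] (or 0/1 matrix) of the same extent.
#' @return AUC in \[0, 1\], or `NA` for a single-class reference.
#' @export
roc_auc <- function(prob, ref) {
  r <- if (inherits(ref, "usseg_mask")) ref$pixels else ref
  if (!identical(dim(prob), dim(r)))
    stop("probability map extent does not match the reference extent")
  y <- as.vector(r); s <- as.vector(prob)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE) # curve vertices at distinct values
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Aggregate per-frame metrics over a dataset
#'
#' `macro` averages each metric over frames, excluding frames where it is
#' undefined (the exclusion count is reported); `micro` pools the confusion
#' counts first and computes each metric once.
#'
#' @param reports List of `usseg_metrics`.
#' @param average `"macro"` or `"micro"`.
#' @return For `macro`: list with `mean` (named numeric) and `n_excluded`
#'   (named integer). For `micro`: a single `usseg_metrics` on the pooled
#'   counts.
#' @export
aggregate_metrics <- function(reports, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (average == "micro") {
    tot <- Reduce(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                  lapply(reports, function(r) unclass(r$counts)))
    return(compute_metrics(do.call(confusion_counts, tot)))
  }
  keys <- c("iou", "recall", "precision", "dice", "accuracy")
  vals <- sapply(reports, function(r) unlist(r[keys]))
  list(mean = rowMeans(vals, na.rm = TRUE),
       n_excluded = apply(vals, 1, function(v) sum(is.na(v))))
}

#' Evaluate predicted mask PNGs against reference mask PNGs
#'
#' Pairs files by name (prediction `<name>.png` against reference
#' `<name>.png` in the other directory), computes per-frame confusion counts
#' and all metrics, and optionally writes a CSV log (one row per frame) and a
#' JSON macro/micro summary.
#'
#' @param pred_dir,ref_dir Directories of binary mask PNGs.
#' @param csv,json Optional output file paths.
#' @return list with `per_frame` (data.frame) and `summary` (macro mean,
#'   exclusion counts, micro metrics).
#' @export
evaluate_masks <- function(pred_dir, ref_dir, csv = NULL, json = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.png$"))
  refs <- sort(list.files(ref_dir, pattern = "\\.png$"))
  common <- intersect(preds, refs)
  if (length(common) == 0L) stop("no matching mask file names between ",
                                 pred_dir, " and ", ref_dir)
  reports <- lapply(common, function(f)
    compute_metrics(confusion(read_mask(file.path(pred_dir, f)),
                              read_mask(file.path(ref_dir, f)))))
  per_frame <- do.call(rbind, lapply(seq_along(common), function(i) {
    r <- reports[[i]]
    data.frame(frame = common[i], TP = r$counts$TP, TN = r$counts$TN,
               FP = r$counts$FP, FN = r$counts$FN, iou = r$iou,
               recall = r$recall, precision = r$precision, dice = r$dice,
               accuracy = r$accuracy, stringsAsFactors = FALSE)
  }))
  macro <- aggregate_metrics(reports, "macro")
  micro <- aggregate_metrics(reports, "micro")
  summary <- list(n_frames = length(common), macro = as.list(macro$mean),
                  n_excluded = as.list(macro$n_excluded),
                  micro = unclass(micro)[c("iou", "recall", "precision",
                                           "dice", "accuracy")])
  if (!is.null(csv)) utils::write.csv(per_frame, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(summary, json, auto_unbox = TRUE,
                                           digits = NA)
  list(per_frame = per_frame, summary = summary)
}
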