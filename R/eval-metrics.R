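# Pixel-level binary-segmentation evaluation: confusion counting and the
# precision / recall / F1 triple, with canopy as the positive class.

#' Pixel confusion counts
#'
#' Compares a predicted binary mask against ground truth pixel by pixel.
#' Canopy (1) is the positive class: TP are canopy pixels predicted canopy,
#' FP background pixels predicted canopy, FN canopy pixels predicted
#' background, TN background pixels predicted background.
#'
#' @param pred,truth 0/1 masks of identical dimensions.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` (their sum equals the pixel count).
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop_rifseg("pred and truth must have identical dimensions",
                "rifseg_shape_error")
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

undefined_metric <- function(which) {
  stop(errorCondition(
    sprintf("%s is undefined: its denominator is zero", which),
    class = c("rifseg_undefined_metric", "rifseg_error")))
}

#' Precision, recall and F1 of a segmentation
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and
#' `f1_score = 2 P R / (P + R)` (the harmonic mean of the two). A zero
#' denominator raises a typed condition (`rifseg_undefined_metric`) rather
#' than silently returning 0, so undefined values cannot corrupt averages.
#'
#' @param c A [confusion()] object.
#' @return Scalar in `[0, 1]`.
#' @export
precision <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fp == 0) undefined_metric("precision")
  c$tp / (c$tp + c$fp)
}

#' @rdname precision
#' @export
recall <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) undefined_metric("recall")
  c$tp / (c$tp + c$fn)
}

#' @rdname precision
#' @param P,R Precision and recall values in `[0, 1]`.
#' @export
f1_score <- function(P, R) {
  check_number(P, "P", lower = 0, upper = 1)
  check_number(R, "R", lower = 0, upper = 1)
  if (P + R == 0) undefined_metric("f1_score")
  2 * P * R / (P + R)
}

metric_row <- function(cc) {
  P <- tryCatch(precision(cc), rifseg_undefined_metric = function(e) NA_real_)
  R <- tryCatch(recall(cc), rifseg_undefined_metric = function(e) NA_real_)
  f1 <- if (is.na(P) || is.na(R) || P + R == 0) NA_real_ else f1_score(P, R)
  data.frame(precision = P, recall = R, f1 = f1)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-image precision/recall/F1 plus two aggregates: the
#' micro-average (metrics of the pooled confusion counts over all images)
#' and the macro-average (mean of the defined per-image metrics).
#'
#' @param pred,truth Lists of 0/1 masks, pairwise comparable.
#' @param ids Optional image identifiers.
#' @return List with `per_image` (data frame), `pooled` (micro-averaged
#'   metrics), `macro` (macro-averaged metrics), and `counts` (pooled
#'   [confusion()]).
#' @export
evaluate_masks <- function(pred, truth, ids = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  ids <- ids %||% sprintf("img%03d", seq_along(pred))
  rows <- vector("list", length(pred))
  tot <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_along(pred)) {
    cc <- confusion(pred[[i]], truth[[i]])
    for (k in names(tot)) tot[[k]] <- tot[[k]] + cc[[k]]
    rows[[i]] <- cbind(data.frame(id = ids[i]), metric_row(cc))
  }
  per_image <- do.call(rbind, rows)
  pooled_cc <- structure(tot, class = "confusion_counts")
  list(per_image = per_image,
       pooled = metric_row(pooled_cc),
       macro = data.frame(precision = mean(per_image$precision, na.rm = TRUE),
                          recall = mean(per_image$recall, na.rm = TRUE),
                          f1 = mean(per_image$f1, na.rm = TRUE)),
       counts = pooled_cc)
}
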