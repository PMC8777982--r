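#' Generalized Dice Loss
#'
#' Overlap-based loss for class-imbalanced pixel classification (Sudre et
#' al., 2017). With reference one-hot labels `r[n, l]`, predicted
#' probabilities `p[n, l]` and class weights `w[l] = 1 / (sum_n r[n, l])^2`,
#' the loss is
#' \deqn{1 - 2 \frac{\sum_l w_l \sum_n r_{ln} p_{ln}}
#'                 {\sum_l w_l \sum_n (r_{ln} + p_{ln})}.}
#' The squared-inverse class-volume weights give the scarce vessel class the
#' same influence as the abundant background, which is what makes the loss
#' robust to the roughly 1:10 vessel/background imbalance of fundus masks.
#' A class absent from the reference would have infinite weight; its weight
#' is replaced by the finite cap `weight_cap`.
#'
#' @param reference numeric matrix `n_pixels x n_classes` of one-hot labels
#'   (each row sums to 1).
#' @param prob numeric matrix `n_pixels x n_classes` of predicted
#'   probabilities (each row sums to 1 within `tol`).
#' @param weight_cap finite replacement for an absent class's weight.
#' @param tol row-sum validation tolerance.
#' @return loss in `[0, 1]`; 0 iff `prob` equals `reference`.
#' @export
generalized_dice_loss <- function(reference, prob, weight_cap = 1e8,
                                  tol = 1e-6) {
  reference <- as.matrix(reference)
  prob <- as.matrix(prob)
  if (!identical(dim(reference), dim(prob))) {
    stop("reference and prob must have identical dimensions", call. = FALSE)
  }
  if (nrow(prob) < 1L) stop("at least one pixel is required", call. = FALSE)
  if (any(abs(rowSums(prob) - 1) > tol)) {
    stop("validation error: probability rows must sum to 1", call. = FALSE)
  }
  if (any(abs(rowSums(reference) - 1) > tol) ||
      !all(reference %in% c(0, 1))) {
    stop("validation error: reference rows must be one-hot", call. = FALSE)
  }
  vol <- colSums(reference)
  w <- ifelse(vol > 0, 1 / vol^2, weight_cap)
  num <- sum(w * colSums(reference * prob))
  den <- sum(w * (vol + colSums(prob)))
  1 - 2 * num / den
}

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,ref binary masks (vessel = 1, background = 0) of identical
#'   shape.
#' @param roi optional binary region-of-interest mask; when given, only
#'   pixels with `roi == 1` are tallied (e.g. a field-of-view disc).
#' @return object of class `confusion_counts` with elements `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(pred, ref, roi = NULL) {
  if (!identical(dim(pred) %||% length(pred), dim(ref) %||% length(ref))) {
    stop("input error: mask shapes differ", call. = FALSE)
  }
  p <- as.logical(pred)
  r <- as.logical(ref)
  if (!is.null(roi)) {
    keep <- as.logical(roi)
    if (length(keep) != length(p)) {
      stop("input error: roi shape differs from the masks", call. = FALSE)
    }
    p <- p[keep]
    r <- r[keep]
  }
  structure(
    list(TP = sum(p & r), FP = sum(p & !r), TN = sum(!p & !r),
         FN = sum(!p & r)),
    class = "confusion_counts"
  )
}

#' Pixel accuracy, sensitivity and specificity
#'
#' The three ratio statistics computed from pixel confusion counts:
#' accuracy `(TP + TN) / (TP + FN + FP + TN)`, sensitivity (vessel detection
#' rate) `TP / (TP + FN)`, specificity (background rejection rate)
#' `TN / (TN + FP)`.
#'
#' @param counts a [confusion()] result (or any list with `TP`, `FP`, `TN`,
#'   `FN`).
#' @return numeric scalar.
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$FN + counts$FP + counts$TN
  if (tot == 0) stop("domain error: no evaluated pixels", call. = FALSE)
  (counts$TP + counts$TN) / tot
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  if (counts$TP + counts$FN == 0) {
    stop("undefined-signal error: reference contains no vessel pixels",
         call. = FALSE)
  }
  counts$TP / (counts$TP + counts$FN)
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  if (counts$TN + counts$FP == 0) {
    stop("undefined-signal error: reference contains no background pixels",
         call. = FALSE)
  }
  counts$TN / (counts$TN + counts$FP)
}

#' Area under the ROC curve of a vessel-probability map
#'
#' Trapezoidal area under the ROC curve swept over all distinct predicted
#' probabilities, which equals the Mann-Whitney statistic
#' `P(score+ > score-) + 0.5 P(tie)`; ties are handled by the midrank
#' convention.
#'
#' @param prob per-pixel vessel-class probabilities (any numeric scores).
#' @param ref binary reference mask of the same length/shape.
#' @param roi optional binary region-of-interest mask.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(prob, ref, roi = NULL) {
  s <- as.numeric(prob)
  r <- as.logical(ref)
  if (length(s) != length(r)) {
    stop("input error: probability and mask lengths differ", call. = FALSE)
  }
  if (!is.null(roi)) {
    keep <- as.logical(roi)
    s <- s[keep]
    r <- r[keep]
  }
  np <- sum(r)
  nn <- sum(!r)
  if (np == 0L || nn == 0L) {
    stop("undefined-signal error: reference must contain both classes",
         call. = FALSE)
  }
  rk <- rank(s, ties.method = "average")
  (sum(rk[r]) - np * (np + 1) / 2) / (as.numeric(np) * nn)
}

#' Paired two-tailed t-test on per-image metrics
#'
#' Compares two segmentation methods on the same test images: a
#' paired-samples t-test on the per-image metric differences, with the
#' two-sided p-value from Student's t on `n - 1` degrees of freedom.
#'
#' @param xs,ys equal-length numeric vectors of per-image metrics (same
#'   image order).
#' @return list with `statistic`, `p_value`, `df`, `mean_difference`.
#' @export
paired_two_tailed_ttest <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 2L) {
    stop("test-undefined error: need equal-length samples of size >= 2",
         call. = FALSE)
  }
  d <- xs - ys
  if (stats::sd(d) == 0) {
    stop("test-undefined error: zero variance of paired differences",
         call. = FALSE)
  }
  ht <- stats::t.test(xs, ys, paired = TRUE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
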