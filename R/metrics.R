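# Segmentation metrics and agreement statistics.

check_masks <- function(pred, gt) {
  assert_that(length(pred) > 0L, "masks must contain at least one pixel")
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt)) {
    stop("prediction and reference masks must have identical shape", call. = FALSE)
  }
}

#' Confusion counts between two label masks
#'
#' @param pred,gt integer label masks of identical shape.
#' @return list with `true_p` (pixels classified identically) and `false_p`
#'   (pixels classified differently); they sum to the pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  check_masks(pred, gt)
  tp <- sum(pred == gt)
  list(true_p = tp, false_p = length(pred) - tp)
}

#' Overall pixel precision
#'
#' The proportion of correctly classified pixels among all pixels,
#' `true_p / (true_p + false_p)`, counted jointly over all classes.
#'
#' @param pred,gt integer label masks of identical shape.
#' @return fraction in \[0, 1\].
#' @export
pixel_precision <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  cc$true_p / (cc$true_p + cc$false_p)
}

# Per-class intersection and union pixel counts for classes 0..K-1.
class_overlap <- function(pred, gt, num_classes) {
  K <- as.integer(num_classes)
  assert_that(all(pred >= 0L & pred < K) && all(gt >= 0L & gt < K),
              sprintf("labels must lie in 0..%d", K - 1L))
  inter <- uni <- numeric(K)
  for (k in seq_len(K) - 1L) {
    p <- pred == k; g <- gt == k
    inter[k + 1L] <- sum(p & g)
    uni[k + 1L] <- sum(p | g)
  }
  list(intersection = inter, union = uni)
}

#' Mean intersection over union
#'
#' Per-class IoU = intersection / union of the predicted and reference
#' regions, averaged over classes. Classes absent from both masks (empty
#' union) are excluded from the mean; if every class has an empty union the
#' function errors.
#'
#' @param pred,gt integer label masks of identical shape with labels in
#'   0..`num_classes`-1.
#' @param num_classes number of classes K.
#' @return list-free scalar MIoU in \[0, 1\]; per-class values are available
#'   via [iou_report()].
#' @export
mean_iou <- function(pred, gt, num_classes) {
  iou_report(pred, gt, num_classes)$miou
}

#' @rdname mean_iou
#' @return `iou_report` returns a list with `per_class_iou` (NA for
#'   empty-union classes) and `miou`.
#' @export
iou_report <- function(pred, gt, num_classes) {
  check_masks(pred, gt)
  ov <- class_overlap(pred, gt, num_classes)
  valid <- ov$union > 0
  if (!any(valid)) stop("every class has an empty union; MIoU undefined", call. = FALSE)
  iou <- ifelse(valid, ov$intersection / pmax(ov$union, 1), NA_real_)
  list(per_class_iou = iou, miou = mean(iou[valid]))
}

#' Coefficient of determination between estimates and reference values
#'
#' Two conventions are exposed. `"agreement"` (default) measures departure
#' from the identity line: residuals are `estimated - reference` and
#' R2 = 1 - SS_res / SS_tot with SS_tot about the reference mean — the
#' appropriate convention when an automated system is validated against
#' manual measurements. `"regression"` is the squared Pearson correlation of
#' the two series.
#'
#' @param estimated,reference numeric vectors of equal length >= 2.
#' @param method `"agreement"` or `"regression"`.
#' @return unitless scalar (at most 1; agreement R2 can be negative for a
#'   badly biased estimator).
#' @export
r_squared <- function(estimated, reference, method = c("agreement", "regression")) {
  method <- match.arg(method)
  assert_that(length(estimated) == length(reference), "series lengths differ")
  assert_that(length(reference) >= 2L, "need at least two observations")
  if (stats::sd(reference) == 0) {
    stop("reference series is constant; R^2 undefined", call. = FALSE)
  }
  if (method == "regression") {
    return(stats::cor(estimated, reference)^2)
  }
  ss_res <- sum((estimated - reference)^2)
  ss_tot <- sum((reference - mean(reference))^2)
  1 - ss_res / ss_tot
}

#' Root mean square error
#'
#' @param estimated,reference numeric vectors of equal length >= 1.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(estimated, reference) {
  assert_that(length(estimated) == length(reference), "series lengths differ")
  assert_that(length(estimated) >= 1L, "need at least one observation")
  sqrt(mean((estimated - reference)^2))
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson correlations across the columns of a trait table, with
#' two-sided p-values from the t transform `t = r * sqrt((n-2)/(1-r^2))` on
#' n-2 degrees of freedom.
#'
#' @param traits numeric matrix or data.frame (rows = varieties, columns =
#'   traits); no missing values, >= 3 rows, no zero-variance column.
#' @return list with symmetric matrices `r` (unit diagonal) and `p`
#'   (diagonal NA).
#' @export
trait_correlation <- function(traits) {
  x <- as.matrix(traits)
  assert_that(is.numeric(x), "trait table must be numeric")
  assert_that(nrow(x) >= 3L, "need at least three rows")
  assert_that(!anyNA(x), "trait table contains missing values")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(x)
  n <- nrow(x)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(r = r, p = p)
}
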