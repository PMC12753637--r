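#' Pixel-level segmentation metrics
#'
#' Builds the 3x3 confusion matrix between ground-truth and predicted
#' masks and reports overall accuracy plus one-vs-rest sensitivity
#' (TP / (TP + FN)) and specificity (TN / (TN + FP)) per class. The macro
#' figures are unweighted means over the two foreground classes; a class
#' absent from the ground truth has undefined sensitivity, reported as `NA`
#' and excluded from the macro mean.
#'
#' @param gt,pred label masks of identical shape.
#' @return an object of class `pixel_metrics`: `accuracy`, `sensitivity`
#'   and `specificity` (named vectors over background/positive/negative),
#'   `macro_sensitivity`, `macro_specificity`, `confusion`.
#' @export
pixel_metrics <- function(gt, pred) {
  gt <- validate_mask(gt); pred <- validate_mask(pred)
  if (!all(dim(gt) == dim(pred))) {
    stop("ground-truth and predicted masks must have identical shape",
         call. = FALSE)
  }
  lev <- c(0L, 1L, 2L)
  cm <- table(factor(as.vector(gt), levels = lev),
              factor(as.vector(pred), levels = lev))
  cm <- matrix(as.numeric(cm), 3, 3,
               dimnames = list(gt = c("background", "positive", "negative"),
                               pred = c("background", "positive", "negative")))
  n <- sum(cm)
  sens <- spec <- setNames(rep(NA_real_, 3),
                           c("background", "positive", "negative"))
  for (k in 1:3) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    if (tp + fn > 0) sens[k] <- tp / (tp + fn)
    if (tn + fp > 0) spec[k] <- tn / (tn + fp)
  }
  fg_sens <- sens[c("positive", "negative")]
  fg_spec <- spec[c("positive", "negative")]
  structure(
    list(accuracy = sum(diag(cm)) / n,
         sensitivity = sens,
         specificity = spec,
         macro_sensitivity = if (all(is.na(fg_sens))) NA_real_
                             else mean(fg_sens, na.rm = TRUE),
         macro_specificity = if (all(is.na(fg_spec))) NA_real_
                             else mean(fg_spec, na.rm = TRUE),
         confusion = cm),
    class = "pixel_metrics"
  )
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf("pixel accuracy %.4f | macro sensitivity %.4f | macro specificity %.4f\n",
              x$accuracy, x$macro_sensitivity, x$macro_specificity))
  invisible(x)
}

#' Object-level segmentation metrics
#'
#' Extracts cell objects from both masks with [label_cells()] and matches
#' predicted objects to ground-truth objects one-to-one, greedily by
#' descending pixel overlap (ties broken toward the smaller object index).
#' By default any positive overlap (>= 1 px) qualifies as a candidate
#' match; `iou_threshold > 0` additionally requires that intersection over
#' union.
#'
#' Degenerate inputs follow an explicit convention: with no ground-truth
#' and no predicted objects both precision and recall are 1; an empty
#' prediction against a non-empty ground truth scores precision 0 (flagged
#' via `degenerate`) and recall 0.
#'
#' @param gt,pred label masks of identical shape.
#' @param class_label 1 or 2: which cell class to evaluate.
#' @param merge_radius_px merge radius passed to [label_cells()].
#' @param iou_threshold minimum IoU for a candidate match (default 0:
#'   any overlap).
#' @return an object of class `object_metrics`: `precision`, `recall`,
#'   `n_gt_objects`, `n_pred_objects`, `n_matched`, `degenerate`.
#' @export
object_metrics <- function(gt, pred, class_label, merge_radius_px = 4L,
                           iou_threshold = 0) {
  gt <- validate_mask(gt); pred <- validate_mask(pred)
  if (!all(dim(gt) == dim(pred))) {
    stop("masks must have identical shape", call. = FALSE)
  }
  gt_obj <- label_cells(gt, class_label, merge_radius_px)
  pr_obj <- label_cells(pred, class_label, merge_radius_px)
  n_gt <- length(gt_obj); n_pr <- length(pr_obj)

  cand <- NULL
  if (n_gt > 0 && n_pr > 0) {
    rows <- list()
    for (i in seq_len(n_gt)) {
      for (j in seq_len(n_pr)) {
        ov <- length(intersect(gt_obj[[i]], pr_obj[[j]]))
        if (ov == 0) next
        if (iou_threshold > 0) {
          iou <- ov / length(union(gt_obj[[i]], pr_obj[[j]]))
          if (iou < iou_threshold) next
        }
        rows[[length(rows) + 1L]] <- c(i, j, ov)
      }
    }
    if (length(rows)) cand <- do.call(rbind, rows)
  }

  matched <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    gt_used <- rep(FALSE, n_gt); pr_used <- rep(FALSE, n_pr)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!gt_used[i] && !pr_used[j]) {
        gt_used[i] <- TRUE; pr_used[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }

  degenerate <- (n_pr == 0L && n_gt > 0L) || (n_gt == 0L && n_pr > 0L)
  precision <- if (n_pr > 0L) matched / n_pr else if (n_gt == 0L) 1 else 0
  recall    <- if (n_gt > 0L) matched / n_gt else if (n_pr == 0L) 1 else 0
  structure(
    list(precision = precision, recall = recall,
         n_gt_objects = n_gt, n_pred_objects = n_pr,
         n_matched = matched, degenerate = degenerate),
    class = "object_metrics"
  )
}

#' @export
print.object_metrics <- function(x, ...) {
  cat(sprintf("object precision %.4f, recall %.4f (%d matched / %d pred / %d gt)%s\n",
              x$precision, x$recall, x$n_matched, x$n_pred_objects,
              x$n_gt_objects, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Patient-level agreement between ground-truth and algorithm TPS
#'
#' Pearson correlation of the paired case scores (the coefficient plotted
#' when ground-truth and model TPS are compared case by case), Spearman
#' rank correlation for comparison, and interval concordance: the fraction
#' of cases whose predicted interval equals the ground-truth interval,
#' either under the three clinical categories (`scheme = "clinical"`) or
#' under the bands of an [interval_scheme()].
#'
#' @param gt_scores,pred_scores equal-length numeric vectors of TPS
#'   percentages.
#' @param scheme `"clinical"` or an [interval_scheme()].
#' @return an object of class `patient_metrics`: `pearson_r`,
#'   `spearman_rho`, `interval_concordance`, `n_cases` and the per-case
#'   `scores` data frame.
#' @export
patient_metrics <- function(gt_scores, pred_scores, scheme = "clinical") {
  gt_scores <- as.numeric(gt_scores); pred_scores <- as.numeric(pred_scores)
  if (length(gt_scores) != length(pred_scores)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  if (length(gt_scores) < 2L) {
    stop("need at least two cases for patient-level metrics", call. = FALSE)
  }
  if (anyNA(gt_scores) || anyNA(pred_scores)) {
    stop("scores must not contain NA; handle unscored cases upstream",
         call. = FALSE)
  }
  const <- stats::sd(gt_scores) == 0 || stats::sd(pred_scores) == 0
  if (const) {
    warning("constant score vector: correlation undefined, reported as NA",
            call. = FALSE)
    pearson <- NA_real_; spearman <- NA_real_
  } else {
    pearson <- stats::cor(gt_scores, pred_scores, method = "pearson")
    spearman <- stats::cor(gt_scores, pred_scores, method = "spearman")
  }
  catf <- if (identical(scheme, "clinical")) {
    clinical_category
  } else {
    stopifnot(inherits(scheme, "interval_scheme"))
    function(v) vapply(v, function(s) assign_interval(s, scheme)$band, "")
  }
  gt_int <- catf(gt_scores); pred_int <- catf(pred_scores)
  structure(
    list(pearson_r = pearson,
         spearman_rho = spearman,
         interval_concordance = mean(gt_int == pred_int),
         n_cases = length(gt_scores),
         scores = data.frame(gt = gt_scores, pred = pred_scores,
                             gt_interval = gt_int, pred_interval = pred_int,
                             stringsAsFactors = FALSE)),
    class = "patient_metrics"
  )
}

#' @export
print.patient_metrics <- function(x, ...) {
  cat(sprintf("patient-level: Pearson r %.4f, Spearman rho %.4f, interval concordance %.4f (n = %d)\n",
              x$pearson_r, x$spearman_rho, x$interval_concordance, x$n_cases))
  invisible(x)
}
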