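# IoU between a prediction and a ground-truth instance for either variant
instance_iou <- function(pred, gt, variant) {
  if (variant == "mask") {
    gt_mask <- if (is.logical(gt)) gt else gt$mask
    iou_masks(pred$mask, gt_mask)
  } else {
    gt_box <- if (inherits(gt, "bounding_box")) gt
              else if (is.logical(gt)) mask_to_bbox(gt)
              else gt$bbox
    iou_boxes(pred$bbox, gt_box)
  }
}

#' Match predictions to ground truth at an IoU threshold
#'
#' Greedy one-to-one matching in the COCO convention: predictions are
#' processed in descending score order (ties broken by larger area then
#' top-left corner); each is matched to the still-unmatched ground-truth
#' instance of highest IoU, provided that IoU reaches the threshold.
#' Unmatched predictions are false positives (so a duplicate detection of
#' an already-claimed spheroid is penalized); unmatched ground truths are
#' false negatives.
#'
#' @param preds List of [detected_instance()]s for one image.
#' @param gts List of ground-truth masks (logical matrices) or
#'   [bounding_box()]es for the box variant.
#' @param iou_threshold IoU required for a match, in (0, 1].
#' @param variant `"mask"` or `"box"`.
#' @return A `match_result`: list with `pairs` (data frame `pred`, `gt`,
#'   `iou`), `tp`, `fp`, `fn`, `iou_threshold`, `variant`, and `pred_tp`
#'   (logical per canonical-order prediction, used by [pr_curve()]).
#' @export
match_instances <- function(preds, gts, iou_threshold = 0.5,
                            variant = c("mask", "box")) {
  variant <- match.arg(variant)
  assert_number(iou_threshold, "iou_threshold", lower = 1e-12, upper = 1)
  preds <- order_instances(preds)
  gt_free <- rep(TRUE, length(gts))
  pairs <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  pred_tp <- logical(length(preds))
  for (i in seq_along(preds)) {
    best <- 0; best_j <- 0L
    for (j in seq_along(gts)) {
      if (!gt_free[j]) next
      v <- instance_iou(preds[[i]], gts[[j]], variant)
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      gt_free[best_j] <- FALSE
      pred_tp[i] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = i, gt = best_j, iou = best))
    }
  }
  structure(list(pairs = pairs, tp = sum(pred_tp),
                 fp = sum(!pred_tp), fn = sum(gt_free),
                 iou_threshold = iou_threshold, variant = variant,
                 preds = preds, pred_tp = pred_tp),
            class = "match_result")
}

#' Precision and recall of a match result
#'
#' `Precision = TP / (TP + FP)`; `Recall = TP / (TP + FN)`.
#'
#' @param result A `match_result` from [match_instances()].
#' @return A float in `[0, 1]`.
#' @export
precision <- function(result) {
  if (result$tp + result$fp == 0L)
    stopf("precision undefined: no predictions")
  result$tp / (result$tp + result$fp)
}

#' @rdname precision
#' @export
recall <- function(result) {
  if (result$tp + result$fn == 0L)
    stopf("recall undefined: no ground-truth instances")
  result$tp / (result$tp + result$fn)
}

# normalize inputs to named per-image lists; a flat list of instances is
# treated as a single image
as_per_image <- function(x) {
  if (length(x) && (inherits(x[[1L]], "detected_instance") ||
                    is.logical(x[[1L]]) && is.matrix(x[[1L]]) ||
                    inherits(x[[1L]], "bounding_box")))
    x <- list(image = x)
  x
}

#' Dataset-wide precision-recall curve
#'
#' Predictions are matched per image at the given IoU threshold, then
#' pooled dataset-wide and ranked by descending score (deterministic
#' tie-break by image name, then larger area, then top-left corner).
#' Cumulative TP/FP counts at each rank give one (recall, precision)
#' point; recall denominators use the total ground-truth count.
#'
#' @param preds Named list (per image) of [detected_instance()] lists; a
#'   flat list is treated as one image.
#' @param gts Named list (per image) of ground-truth masks/boxes, with
#'   names matching `preds`.
#' @param iou_threshold IoU required for a true positive.
#' @param variant `"mask"` or `"box"`.
#' @return A `pr_curve`: list with `recall` (non-decreasing), `precision`,
#'   `scores` and `n_gt`.
#' @export
pr_curve <- function(preds, gts, iou_threshold = 0.5,
                     variant = c("mask", "box")) {
  variant <- match.arg(variant)
  preds <- as_per_image(preds)
  gts <- as_per_image(gts)
  imgs <- union(names(preds) %||% character(), names(gts) %||% character())
  n_gt <- 0L
  rows <- list()
  for (img in imgs) {
    p <- preds[[img]] %||% list()
    g <- gts[[img]] %||% list()
    n_gt <- n_gt + length(g)
    if (length(p) == 0L) next
    m <- match_instances(p, g, iou_threshold, variant)
    rows[[img]] <- data.frame(
      image = img,
      score = vapply(m$preds, `[[`, numeric(1), "score"),
      area = vapply(m$preds, function(d) sum(d$mask), numeric(1)),
      ymin = vapply(m$preds, function(d) d$bbox[["y_min"]], numeric(1)),
      xmin = vapply(m$preds, function(d) d$bbox[["x_min"]], numeric(1)),
      tp = m$pred_tp, stringsAsFactors = FALSE)
  }
  all <- if (length(rows)) do.call(rbind, rows)
         else data.frame(image = character(), score = numeric(),
                         area = numeric(), ymin = numeric(),
                         xmin = numeric(), tp = logical())
  ord <- order(-all$score, all$image, -all$area, all$ymin, all$xmin)
  all <- all[ord, , drop = FALSE]
  ctp <- cumsum(all$tp)
  n <- seq_len(nrow(all))
  structure(list(recall = if (n_gt > 0L) ctp / n_gt else rep(NaN, nrow(all)),
                 precision = if (nrow(all)) ctp / n else numeric(),
                 scores = all$score, n_gt = n_gt),
            class = "pr_curve")
}

#' Average precision: area under the precision-recall curve
#'
#' All-point interpolation: precision is replaced by its running maximum
#' from the right (the monotone envelope), then integrated over the
#' recall increments. `method = "coco101"` instead samples the envelope
#' at 101 equally spaced recall points (the COCO convention) for
#' cross-checking; the two agree closely but not bit-exactly.
#'
#' @param curve A [pr_curve()]. Must have `n_gt >= 1`.
#' @param method `"continuous"` (default) or `"coco101"`.
#' @return AP in `[0, 1]`; 0 for an empty prediction set.
#' @export
average_precision <- function(curve, method = c("continuous", "coco101")) {
  method <- match.arg(method)
  if (curve$n_gt == 0L)
    stopf("AP undefined: no ground-truth instances")
  if (length(curve$precision) == 0L) return(0)
  env <- rev(cummax(rev(curve$precision)))
  if (method == "continuous")
    return(sum(diff(c(0, curve$recall)) * env))
  r <- seq(0, 1, by = 0.01)
  p <- vapply(r, function(ri) {
    ok <- curve$recall >= ri - 1e-12
    if (any(ok)) max(env[ok]) else 0
  }, numeric(1))
  mean(p)
}

#' AP averaged over the standard IoU threshold grid
#'
#' Computes AP at each of the 10 IoU thresholds 0.50, 0.55, ..., 0.95 and
#' their arithmetic mean (the `AP@[0.5:0.95]` convention), plus `AP@0.75`.
#' With a single object category, the class-mean mAP equals this AP.
#'
#' @inheritParams pr_curve
#' @return An `eval_report`: list with `ap_per_threshold` (named by
#'   threshold), `thresholds`, `mean_ap`, `ap_at_075` and `variant`.
#' @export
mean_ap <- function(preds, gts, variant = c("mask", "box")) {
  variant <- match.arg(variant)
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap <- vapply(thresholds, function(th)
    average_precision(pr_curve(preds, gts, th, variant)), numeric(1))
  names(ap) <- sprintf("%.2f", thresholds)
  structure(list(ap_per_threshold = ap, thresholds = thresholds,
                 mean_ap = mean(ap), ap_at_075 = ap[["0.75"]],
                 variant = variant),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Instance-segmentation evaluation (%s variant)\n", x$variant))
  cat(sprintf("  AP@[0.5:0.95] = %.4f   AP@0.75 = %.4f\n", x$mean_ap, x$ap_at_075))
  cat("  per-threshold AP:\n")
  print(round(x$ap_per_threshold, 4))
  invisible(x)
}

#' Evaluate predictions against a VIA annotation set
#'
#' Rasterizes the ground-truth polygons and reports `AP@[0.5:0.95]` and
#' `AP@0.75` for both the bounding-box and the mask variant. Images
#' present in only one of the two sets still count (their instances
#' become false negatives / false positives).
#'
#' @param preds Named list (per image filename) of [detected_instance()]
#'   lists.
#' @param truth A `via_annotation_set` from [parse_via_annotations()].
#' @param shape `c(height, width)` used to rasterize ground-truth
#'   polygons; `NULL` infers it per image from the prediction masks, or
#'   from polygon extents when an image has no predictions.
#' @param out_json Optional path for a machine-readable JSON report.
#' @return List with elements `box` and `mask`, each an `eval_report`.
#' @export
evaluate_dataset <- function(preds, truth, shape = NULL, out_json = NULL) {
  imgs <- union(names(preds), names(truth))
  gt_masks <- list()
  for (img in imgs) {
    polys <- truth[[img]] %||% list()
    sh <- shape
    if (is.null(sh)) {
      if (length(preds[[img]])) sh <- dim(preds[[img]][[1L]]$mask)
      else if (length(polys))
        sh <- c(ceiling(max(vapply(polys, function(p) max(p$y), 1))) + 2,
                ceiling(max(vapply(polys, function(p) max(p$x), 1))) + 2)
      else next
    }
    gt_masks[[img]] <- lapply(polys, polygon_to_mask, shape = sh)
  }
  reports <- list(box = mean_ap(preds, gt_masks, "box"),
                  mask = mean_ap(preds, gt_masks, "mask"))
  if (!is.null(out_json)) {
    payload <- lapply(reports, function(r)
      list(variant = r$variant, thresholds = r$thresholds,
           ap_per_threshold = as.list(r$ap_per_threshold),
           ap_at_075 = r$ap_at_075, mean_ap = r$mean_ap))
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA)
  }
  reports
}
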