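# backend registry: name -> function(image, ...) returning a list of
# list(mask = <logical matrix>, score = <float in [0,1]>)
.backends <- new.env(parent = emptyenv())

#' Register a detection backend
#'
#' A backend maps a grayscale image to a list of raw detections
#' `list(mask, score)`. [detect_spheroids()] validates every returned
#' mask (logical, image-shaped, nonempty) and score (single number in
#' `[0, 1]`), derives bounding boxes, applies the score threshold and
#' ordering. Deep-learning adapters plug in through this same contract;
#' no trained weights ship with the package.
#'
#' @param name Backend name used in [detector_config()].
#' @param fn Backend `function(image, ...)`.
#' @param overwrite Allow replacing an existing backend.
#' @export
register_detection_backend <- function(name, fn, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (!overwrite && !is.null(.backends[[name]]))
    stopf("backend '%s' is already registered (use overwrite = TRUE)", name)
  assign(name, fn, envir = .backends)
  invisible(NULL)
}

#' @rdname register_detection_backend
#' @export
detection_backends <- function() sort(ls(.backends))

#' Adapter for an external deep-learning segmentation model
#'
#' Wraps a weights file path into a backend conforming to the
#' [register_detection_backend()] contract. This package does not bundle
#' a deep-learning runtime or trained weights: constructing the adapter
#' checks that the weights file exists and the returned backend must be
#' replaced by (or composed with) the user's own inference function via
#' `infer`.
#'
#' @param weights_path Path to the model weights; a missing file is an
#'   immediate, explicit error.
#' @param infer `function(image)` running the model, returning a list of
#'   `list(mask, score)`.
#' @return A backend function suitable for [register_detection_backend()].
#' @export
dl_backend_adapter <- function(weights_path, infer = NULL) {
  if (!file.exists(weights_path))
    stopf("model weights not found: '%s' (no trained weights ship with spheromorph; supply your own)",
          weights_path)
  if (is.null(infer))
    stopf("no inference function supplied: pass infer = function(image) ... running your model")
  function(image, ...) infer(image)
}

#' Detector configuration
#'
#' @param backend Registered backend name (default `"baseline"`, the
#'   classical threshold-and-label detector).
#' @param score_threshold Minimum confidence for an instance to be
#'   reported, in `[0, 1]`. Raising it can only shrink the result list.
#' @param ... Backend-specific parameters passed through to the backend.
#' @return A `detector_config` list.
#' @export
detector_config <- function(backend = "baseline", score_threshold = 0.5, ...) {
  assert_number(score_threshold, "score_threshold", lower = 0, upper = 1)
  structure(list(backend = backend, score_threshold = score_threshold,
                 params = list(...)),
            class = "detector_config")
}

#' Construct a detected instance
#'
#' @param mask Logical instance mask (nonempty).
#' @param score Detector confidence in `[0, 1]`.
#' @return A `detected_instance` with fields `mask`, `bbox` (always
#'   `mask_to_bbox(mask)`), `score` and `label = "spheroid"`.
#' @export
detected_instance <- function(mask, score) {
  assert_mask(mask)
  if (!any(mask)) stopf("detected instance has an empty mask")
  assert_number(score, "score", lower = 0, upper = 1)
  structure(list(mask = mask, bbox = mask_to_bbox(mask), score = score,
                 label = "spheroid"),
            class = "detected_instance")
}

# canonical ordering: descending score, then larger area, then top-left
order_instances <- function(instances) {
  if (length(instances) == 0L) return(instances)
  score <- vapply(instances, `[[`, numeric(1), "score")
  area <- vapply(instances, function(d) sum(d$mask), numeric(1))
  ymin <- vapply(instances, function(d) d$bbox[["y_min"]], numeric(1))
  xmin <- vapply(instances, function(d) d$bbox[["x_min"]], numeric(1))
  instances[order(-score, -area, ymin, xmin)]
}

#' Detect spheroids in an image
#'
#' Dispatches to the configured backend, validates its raw output,
#' filters by the score threshold and returns instances sorted by
#' descending score (ties broken by larger area, then top-left bounding
#' box corner, making the order deterministic). Zero detections return an
#' empty list, not an error — callers log such images for failure audits.
#'
#' @param image Grayscale image matrix (0-255) or multichannel array
#'   (converted with [to_grayscale()]).
#' @param config A [detector_config()].
#' @return List of [detected_instance()]s with `score >= score_threshold`.
#' @export
detect_spheroids <- function(image, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  assert_image(image)
  if (length(dim(image)) == 3L) image <- to_grayscale(image)
  fn <- .backends[[config$backend]]
  if (is.null(fn))
    stopf("unknown detection backend '%s' (registered: %s)", config$backend,
          paste(detection_backends(), collapse = ", "))
  raw <- do.call(fn, c(list(image), config$params))
  instances <- lapply(seq_along(raw), function(i) {
    d <- raw[[i]]
    if (is.null(d$mask) || is.null(d$score))
      stopf("backend '%s' returned detection %d without mask/score", config$backend, i)
    if (!identical(dim(d$mask), dim(image)))
      stopf("backend '%s' returned a mask of shape %s for a %s image",
            config$backend, paste(dim(d$mask), collapse = "x"),
            paste(dim(image), collapse = "x"))
    detected_instance(matrix(as.logical(d$mask), nrow(d$mask)), d$score)
  })
  keep <- vapply(instances, function(d) d$score >= config$score_threshold, logical(1))
  order_instances(instances[keep])
}

#' Classical threshold-and-label baseline detector
#'
#' Global intensity threshold (Otsu by default, or a fixed value),
#' morphological opening with a disc brush, connected-component labeling
#' and a minimum-area filter. The confidence score of a component is its
#' Weber contrast against the non-foreground background, clamped to
#' `[0, 1]`. Intended for controlled (synthetic or clean brightfield)
#' images: classical thresholding does not adapt to heterogeneous real
#' assay conditions, which is precisely why learned detectors exist; use
#' it as the reference backend for testing pipelines end to end.
#'
#' @param image Grayscale matrix, 0-255.
#' @param min_area Discard components smaller than this (pixels).
#' @param threshold Fixed intensity threshold; `NULL` selects it with
#'   Otsu's method.
#' @param polarity `"dark"` (default: spheroids darker than background,
#'   the brightfield contraction-assay case) or `"light"`.
#' @param morphology_radius Disc radius of the opening that removes
#'   speckle; 0 disables.
#' @return List of raw detections `list(mask, score)` (unthresholded;
#'   use [detect_spheroids()] for the full contract).
#' @export
baseline_threshold_detector <- function(image, min_area = 100,
                                        threshold = NULL,
                                        polarity = c("dark", "light"),
                                        morphology_radius = 1L) {
  polarity <- match.arg(polarity)
  assert_image(image)
  g <- if (length(dim(image)) == 3L) to_grayscale(image) else image
  if (diff(range(g)) < 1e-9) return(list())   # featureless image
  th <- threshold %||% (EBImage::otsu(EBImage::Image(g / 255)) * 255)
  fg <- if (polarity == "dark") g < th else g > th
  if (morphology_radius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(morphology_radius) + 1L, "disc")
    fg <- EBImage::opening(fg, brush) > 0
  }
  if (!any(fg)) return(list())
  lab <- EBImage::bwlabel(fg)
  bg_mean <- mean(g[!fg])
  out <- list()
  for (k in seq_len(max(lab))) {
    mask <- lab == k
    if (sum(mask) < min_area) next
    fg_mean <- mean(g[mask])
    contrast <- abs(bg_mean - fg_mean) / max(bg_mean, fg_mean, 1)
    out[[length(out) + 1L]] <- list(mask = mask,
                                    score = min(1, max(0, contrast)))
  }
  out
}
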