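#' Construct a polygon region
#'
#' The shared polygon type: an ordered vertex list in 0-based pixel
#' coordinates (x = column, y = row), implicitly closed (the last vertex
#' connects back to the first).
#'
#' @param x,y Numeric vectors of equal length (>= 3) of vertex coordinates.
#' @param attributes Optional named list of region attributes (kept through
#'   VIA round trips).
#' @return A `polygon_region`: a data frame with columns `x` and `y`.
#' @examples
#' sq <- polygon_region(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' polygon_area(sq)
#' @export
polygon_region <- function(x, y, attributes = NULL) {
  if (length(x) != length(y))
    stopf("x and y must have equal length")
  if (length(x) < 3L)
    stopf("a polygon needs at least 3 vertices, got %d", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("polygon coordinates must be finite")
  p <- data.frame(x = as.numeric(x), y = as.numeric(y))
  class(p) <- c("polygon_region", "data.frame")
  if (!is.null(attributes)) attr(p, "region_attributes") <- attributes
  p
}

#' Signed-area magnitude of a polygon (shoelace formula)
#'
#' @param polygon A [polygon_region()].
#' @return Enclosed area in square pixels (continuous, not rasterized).
#' @export
polygon_area <- function(polygon) {
  x <- polygon$x
  y <- polygon$y
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Construct a half-open bounding box
#'
#' `x_min`/`y_min` are inclusive, `x_max`/`y_max` exclusive, so the box
#' covering the single pixel at (x=5, y=3) is `bounding_box(5, 3, 6, 4)`
#' and box area is simply `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels.
#' @return Named numeric vector of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  if (x_max <= x_min || y_max <= y_min)
    stopf("degenerate box: need x_max > x_min and y_max > y_min")
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bounding_box")
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel is true iff its center lies inside the polygon under the
#' even-odd rule. Centers that fall exactly on the boundary follow a
#' top-left rule: scanline spans are half-open, so a center on a left/top
#' edge is inside and one on a right/bottom edge is outside. This removes
#' double counting between abutting polygons.
#'
#' @param polygon A [polygon_region()]. Vertices outside the image are
#'   clipped to it with a warning.
#' @param shape Integer vector `c(height, width)` of the target mask.
#' @return Logical `height x width` matrix.
#' @examples
#' m <- polygon_to_mask(polygon_region(c(0, 10, 10, 0), c(0, 0, 10, 10)), c(16, 16))
#' sum(m)  # 100: rows 0..9 x cols 0..9
#' @export
polygon_to_mask <- function(polygon, shape) {
  stopifnot(length(shape) == 2L)
  h <- as.integer(shape[1])
  w <- as.integer(shape[2])
  if (polygon_area(polygon) <= .Machine$double.eps)
    stopf("degenerate polygon: enclosed area is zero")
  xs <- polygon$x
  ys <- polygon$y
  if (min(xs) < -0.5 || min(ys) < -0.5 || max(xs) > w - 0.5 || max(ys) > h - 0.5)
    warnf("polygon extends outside the %d x %d image; mask is clipped", h, w)
  x2 <- c(xs[-1], xs[1])
  y2 <- c(ys[-1], ys[1])
  e_ymin <- pmin(ys, y2)
  e_ymax <- pmax(ys, y2)
  mask <- matrix(FALSE, h, w)
  r0 <- max(0L, as.integer(ceiling(min(ys))))
  r1 <- min(h - 1L, as.integer(ceiling(max(ys))) - 1L)
  if (r1 < r0) return(mask)
  for (r in r0:r1) {
    sel <- e_ymin <= r & r < e_ymax     # half-open in y skips horizontal edges
    if (!any(sel)) next
    t <- (r - ys[sel]) / (y2[sel] - ys[sel])
    xi <- sort(xs[sel] + t * (x2[sel] - xs[sel]))
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      c0 <- max(0L, as.integer(ceiling(xi[k])))
      c1 <- min(w - 1L, as.integer(ceiling(xi[k + 1L])) - 1L)
      if (c1 >= c0) mask[r + 1L, (c0:c1) + 1L] <- TRUE
    }
  }
  mask
}

#' Tightest bounding box of a mask
#'
#' @param mask Logical matrix with at least one true pixel.
#' @return A [bounding_box()] (half-open) containing all true pixels.
#' @export
mask_to_bbox <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("mask is empty")
  bounding_box(x_min = min(idx[, 2L]) - 1L, y_min = min(idx[, 1L]) - 1L,
               x_max = max(idx[, 2L]),      y_max = max(idx[, 1L]))
}

#' Intersection over union of two binary masks
#'
#' Overlap area of the two regions divided by the area of their union;
#' 1 means the regions coincide exactly.
#'
#' @param a,b Logical matrices of identical shape.
#' @return IoU in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[2:3, 2:3] <- TRUE
#' iou_masks(a, b)  # 1/7
#' @export
iou_masks <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  if (!identical(dim(a), dim(b)))
    stopf("masks have different shapes: %s vs %s",
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  uni <- sum(a | b)
  if (uni == 0L) stopf("IoU undefined: both masks are empty")
  sum(a & b) / uni
}

#' Intersection over union of two bounding boxes
#'
#' Half-open arithmetic: boxes that merely touch have IoU 0.
#'
#' @param a,b [bounding_box()] objects (or length-4 vectors
#'   `x_min, y_min, x_max, y_max`).
#' @return IoU in `[0, 1]`.
#' @export
iou_boxes <- function(a, b) {
  iw <- min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]])
  ih <- min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]])
  inter <- max(0, iw) * max(0, ih)
  area <- function(z) (z[[3L]] - z[[1L]]) * (z[[4L]] - z[[2L]])
  uni <- area(a) + area(b) - inter
  if (uni <= 0) stopf("IoU undefined: union has zero area")
  inter / uni
}

#' Trace the external contour of a mask as a polygon
#'
#' Extracts the boundary of the largest connected component, after filling
#' holes (spheroids are treated as filled regions). The contour follows the
#' 0.5-level isoline between inside and outside pixel centers, so
#' re-rasterizing it with [polygon_to_mask()] reproduces the (hole-filled)
#' component exactly.
#'
#' @param mask Logical matrix with at least one true pixel.
#' @return A [polygon_region()] tracing the outer boundary.
#' @export
mask_to_polygon <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stopf("cannot trace a contour on an empty mask")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  comp <- EBImage::fillHull(comp * 1) > 0
  h <- nrow(comp); w <- ncol(comp)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- comp
  cl <- grDevices::contourLines(x = seq(-1, h), y = seq(-1, w),
                                z = padded, levels = 0.5)
  ring <- cl[[which.max(vapply(cl, function(c) length(c$x), 1L))]]
  px <- ring$y   # contourLines x follows matrix rows (= image y)
  py <- ring$x
  n <- length(px)
  if (n > 3L && px[1L] == px[n] && py[1L] == py[n]) {  # drop closing duplicate
    px <- px[-n]; py <- py[-n]
  }
  polygon_region(px, py)
}
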