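#' Spheroid area in pixels
#'
#' The area of an instance is the exact count of pixels inside its contour
#' boundary, i.e. the number of true pixels of its mask.
#'
#' @param mask Logical instance mask.
#' @return Integer pixel count (>= 1).
#' @export
spheroid_area <- function(mask) {
  assert_mask(mask)
  a <- sum(mask)
  if (a == 0L) stopf("cannot measure an empty mask")
  as.integer(a)
}

#' Perimeter of a contour polygon
#'
#' Sum of Euclidean edge lengths of the closed contour (the last vertex
#' connects back to the first).
#'
#' @param contour A [polygon_region()].
#' @return Perimeter in pixels.
#' @export
spheroid_perimeter <- function(contour) {
  x <- contour$x; y <- contour$y
  sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
}

#' Circularity shape factor
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect disk (the maximizer among
#' all shapes), smaller for elongated or irregular outlines. Rasterization
#' can push measured values slightly above 1 for small near-circular
#' regions; values are not clamped.
#'
#' @param area Area in square pixels (> 0).
#' @param perimeter Perimeter in pixels (> 0).
#' @return Dimensionless shape factor.
#' @examples
#' circularity(100, 40)  # square: pi/4
#' @export
circularity <- function(area, perimeter) {
  assert_number(area, "area")
  assert_number(perimeter, "perimeter")
  if (area <= 0 || perimeter <= 0)
    stopf("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Intermediate contour-fill image of the intensity routine
#'
#' Builds a zero image of the given shape and sets every pixel inside the
#' contour boundary to intensity 255. This is the inspectable intermediate
#' of [mean_intensity()].
#'
#' @param contour A [polygon_region()].
#' @param shape `c(height, width)` of the image.
#' @return Numeric matrix containing only the values 0 and 255.
#' @export
fill_contour_image <- function(contour, shape) {
  m <- polygon_to_mask(contour, shape)
  out <- matrix(0, shape[1L], shape[2L])
  out[m] <- 255
  out
}

#' Mean intensity inside a contour
#'
#' Implements the masked-intensity procedure literally: (1) create a zero
#' image with the same shape as the input; (2) set all pixels inside the
#' contour boundary to 255; (3) extract the coordinates of the 255-valued
#' pixels; (4) average the original image at those coordinates. The result
#' equals the mean of the image over the rasterized contour interior.
#'
#' @param image Single-channel numeric matrix (0-255 scale); multichannel
#'   input is converted with [to_grayscale()].
#' @param contour A [polygon_region()] whose interior overlaps the image.
#' @return Mean intensity, a float in `[0, 255]`.
#' @export
mean_intensity <- function(image, contour) {
  assert_image(image)
  if (length(dim(image)) == 3L) image <- to_grayscale(image)
  filled <- fill_contour_image(contour, dim(image))
  coords <- which(filled == 255)
  if (length(coords) == 0L)
    stopf("contour interior contains no pixels inside the image")
  mean(image[coords])
}

# circular moving-average smoothing of a closed contour; tames the
# staircase of pixel-edge contours so perimeter estimates of smooth shapes
# are not inflated. window must be odd.
smooth_contour <- function(contour, window = 5L) {
  n <- nrow(contour)
  if (n <= window) return(contour)
  half <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  polygon_region(rowMeans(matrix(contour$x[idx], n)),
                 rowMeans(matrix(contour$y[idx], n)))
}

#' Measure one instance: area, perimeter, circularity, intensity
#'
#' Composes contour extraction and the individual measurements. Hollow
#' (ring-like) masks are measured over the filled outer contour, matching
#' the contour-fill intensity procedure. The perimeter is taken on a
#' lightly smoothed copy of the traced contour so the pixel-edge staircase
#' does not inflate it; area and intensity use the exact contour.
#'
#' @param image Intensity image (matrix or `h x w x channels` array,
#'   0-255 scale); converted to grayscale for multichannel input.
#' @param mask Logical instance mask.
#' @return A list of class `morphometry_result` with fields `area_px`,
#'   `perimeter_px`, `circularity`, `mean_intensity` and the traced
#'   `contour`.
#' @export
measure_instance <- function(image, mask) {
  assert_image(image)
  assert_mask(mask)
  if (!any(mask)) stopf("cannot measure an empty mask")
  if (length(dim(image)) == 3L) image <- to_grayscale(image)
  if (!identical(dim(image), dim(mask)))
    stopf("image and mask shapes differ")
  contour <- mask_to_polygon(mask)
  filled <- polygon_to_mask(contour, dim(mask))
  area <- spheroid_area(filled)
  perim <- spheroid_perimeter(smooth_contour(contour))
  structure(list(area_px = area,
                 perimeter_px = perim,
                 circularity = circularity(area, perim),
                 mean_intensity = mean_intensity(image, contour),
                 contour = contour),
            class = "morphometry_result")
}
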