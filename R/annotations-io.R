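#' Parse VGG Image Annotator (VIA) annotations
#'
#' Reads VIA 2.x JSON in either the project-file form (regions under
#' `"_via_img_metadata"`) or the bare export form (top-level
#' `filename+size` keys). Every region shape is normalized to a polygon:
#' `polygon`/`polyline` vertices are taken as-is, `rect` becomes its 4
#' corners, `circle` and `ellipse` are discretized to 64-gons. Regions
#' that cannot form a polygon (< 3 points, `point` shapes) are skipped
#' with a warning and tallied in the skip report.
#'
#' @param json Either VIA JSON text or a path to a `.json` file.
#' @return A `via_annotation_set`: a named list mapping image filename to
#'   a list of [polygon_region()]s (with region attributes preserved).
#'   The attribute `"skipped"` is a data frame reporting skipped regions.
#' @export
parse_via_annotations <- function(json) {
  txt <- json
  if (length(json) == 1L && !grepl("^[[:space:]]*\\{", json)) {
    if (!file.exists(json)) stopf("VIA file not found: %s", json)
    txt <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stopf("malformed VIA JSON (%s): %s",
                          if (identical(txt, json)) "literal text" else json,
                          conditionMessage(e)))
  meta <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]] else doc
  meta <- Filter(function(e) is.list(e) && !is.null(e$filename), meta)
  out <- list()
  skipped <- data.frame(filename = character(), reason = character())
  for (entry in meta) {
    fname <- entry$filename
    regions <- list()
    for (reg in entry$regions %||% list()) {
      poly <- via_region_to_polygon(reg)
      if (is.character(poly)) {
        skipped <- rbind(skipped, data.frame(filename = fname, reason = poly))
        warnf("skipping region in '%s': %s", fname, poly)
      } else {
        regions[[length(regions) + 1L]] <- poly
      }
    }
    out[[fname]] <- regions
  }
  structure(out, class = "via_annotation_set", skipped = skipped)
}

# one VIA region -> polygon_region, or a character reason to skip
via_region_to_polygon <- function(reg) {
  sa <- reg$shape_attributes
  if (is.null(sa$name)) return("region without shape_attributes$name")
  attrs <- reg$region_attributes
  if (length(attrs) == 0L) attrs <- NULL
  shape <- sa$name
  if (shape %in% c("polygon", "polyline")) {
    x <- unlist(sa$all_points_x)
    y <- unlist(sa$all_points_y)
    if (length(x) < 3L)
      return(sprintf("%s with %d < 3 points", shape, length(x)))
    return(polygon_region(x, y, attributes = attrs))
  }
  if (shape == "rect") {
    x <- sa$x; y <- sa$y; w <- sa$width; h <- sa$height
    return(polygon_region(c(x, x + w, x + w, x), c(y, y, y + h, y + h),
                          attributes = attrs))
  }
  if (shape %in% c("circle", "ellipse")) {
    rx <- if (shape == "circle") sa$r else sa$rx
    ry <- if (shape == "circle") sa$r else sa$ry
    th <- sa$theta %||% 0
    ang <- seq(0, 2 * pi, length.out = 65L)[-65L]
    return(polygon_region(
      sa$cx + rx * cos(ang) * cos(th) - ry * sin(ang) * sin(th),
      sa$cy + rx * cos(ang) * sin(th) + ry * sin(ang) * cos(th),
      attributes = attrs))
  }
  sprintf("unsupported shape '%s'", shape)
}

#' Write a VIA project JSON for an annotation set
#'
#' Inverse of [parse_via_annotations()]: `parse(write(s))` reproduces `s`
#' up to coordinate formatting (coordinates are written with 6 significant
#' decimals). All regions are written as polygons.
#'
#' @param set A `via_annotation_set` (named list filename -> list of
#'   [polygon_region()]s).
#' @param path Optional output file; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_via_annotations <- function(set, path = NULL) {
  meta <- list()
  for (fname in names(set)) {
    regions <- lapply(set[[fname]], function(p) {
      list(shape_attributes = list(
             name = "polygon",
             all_points_x = round(p$x, 6),
             all_points_y = round(p$y, 6)),
           region_attributes = attr(p, "region_attributes") %||%
             structure(list(), names = character()))
    })
    meta[[paste0(fname, "-1")]] <- list(
      filename = fname, size = -1L,
      regions = regions,
      file_attributes = structure(list(), names = character()))
  }
  doc <- list(
    `_via_settings` = list(ui = list(), core = list(), project = list(name = "spheromorph")),
    `_via_img_metadata` = if (length(meta)) meta else structure(list(), names = character()),
    `_via_attributes` = list(region = structure(list(), names = character()),
                             file = structure(list(), names = character())))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

results_csv_header <-
  "image_id,instance_id,area_px,perimeter_px,circularity,mean_intensity,score"

#' Write the per-instance results CSV
#'
#' One row per detected instance, sorted by `image_id` then `instance_id`.
#' The first line is a schema-version comment; the column header line is
#' exactly `image_id,instance_id,area_px,perimeter_px,circularity,mean_intensity,score`.
#'
#' @param records Data frame with the seven schema columns.
#' @param path Optional output file; when `NULL` the CSV text is returned.
#' @return CSV text (invisibly when written to `path`).
#' @export
write_results_csv <- function(records, path = NULL) {
  cols <- strsplit(results_csv_header, ",")[[1L]]
  if (nrow(records) > 0L) {
    missing <- setdiff(cols, names(records))
    if (length(missing))
      stopf("records are missing columns: %s", paste(missing, collapse = ", "))
    records <- records[order(records$image_id, records$instance_id), cols,
                       drop = FALSE]
  } else {
    records <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  con <- textConnection("csv_out", "w", local = TRUE)
  writeLines("# spheromorph results schema v1", con)
  write.csv(records, con, row.names = FALSE, quote = FALSE)
  close(con)
  txt <- paste(csv_out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a results CSV written by [write_results_csv()]
#'
#' @param path File path or CSV text.
#' @return Data frame with the seven schema columns.
#' @export
read_results_csv <- function(path) {
  if (length(path) == 1L && !file.exists(path) && grepl("\n", path)) {
    return(read.csv(text = path, comment.char = "#", stringsAsFactors = FALSE))
  }
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load a raster image
#'
#' Reads PNG, TIFF or JPEG into the package's matrix convention
#' (rows = y, columns = x, intensities 0-255). Sample values are rescaled
#' from the file's bit depth to the 0-255 scale (a 16-bit TIFF maps
#' 65535 -> 255), preserving fractional precision.
#'
#' @param path Image file path.
#' @return Numeric matrix, or `height x width x channels` array for
#'   multichannel images.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read image: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stopf("unsupported image format '.%s' (PNG/TIFF/JPEG supported)", ext))
  img * 255
}

#' Convert an image to 8-bit grayscale
#'
#' Multichannel input is collapsed with the ITU-R BT.601 luminance
#' weighting `0.299 R + 0.587 G + 0.114 B` (alpha, if present, is
#' ignored), then rounded to integer 0-255. Pure red maps to 76 and pure
#' blue to 29, so the channels remain distinguishable after conversion.
#'
#' @param image Numeric matrix or `h x w x channels` array on the 0-255
#'   scale.
#' @return Numeric matrix of integers in 0-255.
#' @export
to_grayscale <- function(image) {
  assert_image(image)
  if (length(dim(image)) == 2L) return(clip8(image))
  nch <- dim(image)[3L]
  if (nch == 1L) return(clip8(image[, , 1L]))
  if (nch < 3L) stopf("expected 1, 3 or 4 channels, got %d", nch)
  clip8(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
}
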