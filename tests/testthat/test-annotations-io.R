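via_project_fixture <- function() {
  paste0('{"_via_settings": {},
    "_via_img_metadata": {
      "img1.png123456": {
        "filename": "img1.png", "size": 123456,
        "regions": [
          {"shape_attributes": {"name": "polygon",
             "all_points_x": [2, 12, 12, 2], "all_points_y": [3, 3, 9, 9]},
           "region_attributes": {"type": "spheroid"}}
        ],
        "file_attributes": {}
      }
    },
    "_via_attributes": {}}')
}

test_that("VIA project files parse into polygon sets keyed by filename", {
  set <- parse_via_annotations(via_project_fixture())
  expect_named(set, "img1.png")
  expect_length(set[["img1.png"]], 1)
  p <- set[["img1.png"]][[1]]
  expect_equal(p$x, c(2, 12, 12, 2))
  expect_equal(p$y, c(3, 3, 9, 9))
  expect_equal(attr(p, "region_attributes")$type, "spheroid")

  empty <- parse_via_annotations('{"_via_img_metadata": {}}')
  expect_length(empty, 0)
  expect_error(parse_via_annotations('{"broken'), "malformed")
})

test_that("the bare export dialect and non-polygon shapes are normalized", {
  bare <- '{
    "well.png77": {"filename": "well.png", "size": 77, "regions": [
      {"shape_attributes": {"name": "rect", "x": 0, "y": 0, "width": 10, "height": 10},
       "region_attributes": {}},
      {"shape_attributes": {"name": "circle", "cx": 30, "cy": 30, "r": 8},
       "region_attributes": {}}
    ], "file_attributes": {}}}'
  set <- parse_via_annotations(bare)
  regions <- set[["well.png"]]
  expect_length(regions, 2)
  expect_equal(nrow(regions[[1]]), 4)
  # rect (0,0,10,10) rasterizes to area 100 under the shared convention
  expect_equal(sum(polygon_to_mask(regions[[1]], c(48, 48))), 100)
  expect_identical(polygon_to_mask(regions[[1]], c(48, 48)),
                   oracle_rasterize(regions[[1]], c(48, 48)))
  expect_equal(nrow(regions[[2]]), 64)             # circle -> 64-gon
  expect_lt(abs(polygon_area(regions[[2]]) - pi * 64) / (pi * 64), 0.01)
})

test_that("degenerate regions are skipped with a warning and tallied", {
  bad <- '{
    "a.png1": {"filename": "a.png", "size": 1, "regions": [
      {"shape_attributes": {"name": "polyline", "all_points_x": [1, 2], "all_points_y": [1, 2]},
       "region_attributes": {}},
      {"shape_attributes": {"name": "polygon",
         "all_points_x": [0, 8, 4], "all_points_y": [0, 0, 6]}, "region_attributes": {}}
    ], "file_attributes": {}}}'
  expect_warning(set <- parse_via_annotations(bad), "skipping")
  expect_length(set[["a.png"]], 1)                 # image key never dropped
  skipped <- attr(set, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_equal(skipped$filename, "a.png")
})

test_that("VIA annotations survive a write/parse round trip", {
  withr::with_seed(31, {
    for (i in 1:3) {
      set <- structure(list(), class = "via_annotation_set")
      for (img in paste0("im", seq_len(sample(1:3, 1)), ".png"))
        set[[img]] <- replicate(sample(1:3, 1), random_polygon(), simplify = FALSE)
      back <- parse_via_annotations(write_via_annotations(set))
      expect_setequal(names(back), names(set))
      for (img in names(set))
        for (k in seq_along(set[[img]])) {
          expect_equal(back[[img]][[k]]$x, round(set[[img]][[k]]$x, 6))
          expect_equal(back[[img]][[k]]$y, round(set[[img]][[k]]$y, 6))
        }
    }
  })
  # attributes preserved; empty set yields a valid VIA skeleton
  p <- polygon_region(c(1, 5, 3), c(1, 1, 6), attributes = list(grade = "A"))
  rt <- parse_via_annotations(write_via_annotations(list(x.png = list(p))))
  expect_equal(attr(rt[["x.png"]][[1]], "region_attributes")$grade, "A")
  expect_length(parse_via_annotations(write_via_annotations(list())), 0)
})

test_that("results CSV has the fixed schema, stable ordering and round trips", {
  txt <- write_results_csv(data.frame())
  lines <- strsplit(txt, "\n")[[1]]
  expect_match(lines[1], "^# spheromorph results schema")
  expect_identical(lines[2],
    "image_id,instance_id,area_px,perimeter_px,circularity,mean_intensity,score")
  expect_length(lines, 2)                          # header-only when empty

  rec <- data.frame(image_id = c("b.png", "b.png", "a.png"),
                    instance_id = c(2L, 1L, 1L),
                    area_px = c(40L, 30L, 20L), perimeter_px = c(25, 21, 17),
                    circularity = c(0.8, 0.85, 0.87),
                    mean_intensity = c(90, 95, 99), score = c(0.7, 0.9, 0.95))
  out <- read_results_csv(write_results_csv(rec))
  expect_equal(out$image_id, c("a.png", "b.png", "b.png"))
  expect_equal(out$instance_id, c(1L, 1L, 2L))
  expect_equal(out$area_px, c(20L, 30L, 40L))
  expect_equal(out$score, c(0.95, 0.9, 0.7))
})

test_that("image loading rescales to 0-255 and grayscale uses BT.601 luminance", {
  dir <- withr::local_tempdir()
  rgb <- array(7 / 255, dim = c(8, 10, 3))
  png::writePNG(rgb, file.path(dir, "const.png"))
  img <- load_image(file.path(dir, "const.png"))
  expect_equal(dim(img), c(8, 10, 3))
  expect_true(all(to_grayscale(img) == 7))

  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 1
  blue <- array(0, dim = c(4, 4, 3)); blue[, , 3] <- 1
  png::writePNG(red, file.path(dir, "red.png"))
  png::writePNG(blue, file.path(dir, "blue.png"))
  expect_true(all(to_grayscale(load_image(file.path(dir, "red.png"))) == 76))
  expect_true(all(to_grayscale(load_image(file.path(dir, "blue.png"))) == 29))

  # 16-bit TIFF: full scale maps to 255 with fractions preserved pre-rounding
  m16 <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  tiff::writeTIFF(m16, file.path(dir, "deep.tif"), bits.per.sample = 16)
  deep <- load_image(file.path(dir, "deep.tif"))
  expect_equal(sort(unique(as.vector(deep))), c(0, 63.75, 127.5, 255),
               tolerance = 0.01)

  expect_error(load_image(file.path(dir, "missing.png")), "cannot read")
  gray <- matrix(seq(0, 1, length.out = 20), 4, 5)
  png::writePNG(gray, file.path(dir, "gray.png"))
  expect_equal(dim(load_image(file.path(dir, "gray.png"))), c(4, 5))
})
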