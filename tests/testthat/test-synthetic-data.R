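single_ellipse_scene <- function(noise = 0, ...) {
  scene_spec(noise_sigma = noise,
             spheroids = list(ellipse_spec(128, 128, 30, 20, rotation = 0.3)),
             ...)
}

test_that("rendered ground truth matches its polygon rasterization and analytic area", {
  r <- render_spheroid_image(single_ellipse_scene(), seed = 5)
  inst <- r$instances[[1]]
  expect_identical(inst$mask, polygon_to_mask(inst$polygon, dim(r$image)))
  expect_lt(abs(sum(inst$mask) - pi * 30 * 20) / (pi * 30 * 20), 0.02)
  expect_equal(inst$analytic_area, pi * 30 * 20)
  # the spheroid interior carries the fill level in the noise-free image
  expect_true(all(r$image[inst$mask] == 80))
})

test_that("rendering is deterministic and validates its scene", {
  sp <- single_ellipse_scene(noise = 10)
  r1 <- render_spheroid_image(sp, seed = 3)
  r2 <- render_spheroid_image(sp, seed = 3)
  expect_identical(r1$image, r2$image)
  expect_false(identical(r1$image, render_spheroid_image(sp, seed = 4)$image))

  empty <- render_spheroid_image(scene_spec(noise_sigma = 0), seed = 1)
  expect_length(empty$instances, 0)
  expect_true(all(empty$image == 200))

  expect_error(scene_spec(spheroids = list(ellipse_spec(250, 128, 30, 20))),
               "inside")
  expect_error(scene_spec(image_height = 32), "image_height")
})

test_that("debris blobs are rendered but excluded from the ground truth", {
  r <- render_spheroid_image(single_ellipse_scene(debris_count = 3), seed = 8)
  expect_length(r$instances, 1)
  outside <- !r$instances[[1]]$mask
  expect_gt(sum(r$image[outside] == 50), 10)       # debris pixels exist
})

test_that("hollow spheroids keep the filled outline as ground truth", {
  r <- render_spheroid_image(single_ellipse_scene(hollow = TRUE), seed = 2)
  inst <- r$instances[[1]]
  expect_true(any(r$image[inst$mask] == 200))      # ring interior = background
  expect_true(any(r$image[inst$mask] == 80))       # ring rim = fill
  expect_equal(sum(inst$mask), sum(polygon_to_mask(inst$polygon, dim(r$image))))
})

test_that("largest-remainder splitting reproduces printed dataset designs", {
  expect_identical(split_sizes(480, c(train = 0.7, validation = 0.3)),
                   c(train = 336L, validation = 144L))
  expect_identical(unname(split_sizes(10, c(1.0))), 10L)
  expect_error(split_sizes(100, c(0.8, 0.4)), "sum")

  man <- generate_dataset(12, seed = 2,
                          split_counts = c(train = 7, validation = 3, test = 2))
  expect_identical(table(man$images$split)[c("train", "validation", "test")],
                   table(factor(rep(c("train", "validation", "test"), c(7, 3, 2)),
                                levels = c("train", "validation", "test"))))
})

test_that("generated datasets are disjoint, complete, deterministic and written to disk", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(8, c(train = 0.5, validation = 0.5), seed = 21,
                          out_dir = dir)
  counts <- table(man$images$split)
  expect_equal(counts[["train"]], 4L)
  expect_equal(counts[["validation"]], 4L)
  expect_identical(anyDuplicated(man$images$image), 0L)
  expect_setequal(man$images$image, names(man$ground_truth))

  man2 <- generate_dataset(8, c(train = 0.5, validation = 0.5), seed = 21)
  expect_identical(man$images, man2$images)
  expect_equal(man$ground_truth, man2$ground_truth)

  pngs <- list.files(dir, pattern = "\\.png$", recursive = TRUE)
  expect_length(pngs, 8)
  via <- parse_via_annotations(file.path(dir, "annotations_train.json"))
  expect_length(via, 4)
  expect_length(via[[1]], 1)                       # one spheroid per scene
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})

test_that("contraction series follows exponential decay with exact noise-free recovery", {
  spec <- contraction_series_spec(list(
    list(name = "control", initial_area = 10000, rate = 0, noise_cv = 0),
    list(name = "treated", initial_area = 10000, rate = 0.05, noise_cv = 0)),
    replicates = 2)
  s <- simulate_contraction_series(spec, seed = 1)
  ctrl <- s[s$group == "control", ]
  expect_true(all(ctrl$area_px == 10000))
  tr <- s[s$group == "treated" & s$replicate == 1, ]
  expect_equal(tr$area_px[tr$timepoint_h == 24], 10000 * exp(-1.2))  # ~3012
  expect_true(all(s$area_px > 0))

  # log-linear fit recovers the generating rate exactly without noise
  fit <- lm(log(area_px) ~ timepoint_h, data = tr)
  expect_equal(unname(coef(fit)[2]), -0.05, tolerance = 1e-10)

  expect_identical(simulate_contraction_series(spec, seed = 9),
                   simulate_contraction_series(spec, seed = 9))
  expect_error(contraction_series_spec(list(
    list(name = "bad", initial_area = -5, rate = 0, noise_cv = 0))),
    "positive")
})
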