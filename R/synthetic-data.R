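#' Specify one elliptical spheroid
#'
#' @param center_x,center_y Center in 0-based pixel coordinates.
#' @param semi_axis_a,semi_axis_b Semi-axes in pixels (>= 3).
#' @param rotation Rotation of axis `a` in radians.
#' @param fill_level Interior intensity, 0-255 (dark-on-light brightfield
#'   spheroids use values well below the background).
#' @return An `ellipse_spec` list; the analytic area `pi * a * b` is
#'   recorded in `$analytic_area`.
#' @export
ellipse_spec <- function(center_x, center_y, semi_axis_a, semi_axis_b,
                         rotation = 0, fill_level = 80) {
  assert_number(semi_axis_a, "semi_axis_a", lower = 3)
  assert_number(semi_axis_b, "semi_axis_b", lower = 3)
  assert_number(fill_level, "fill_level", lower = 0, upper = 255)
  structure(list(center_x = center_x, center_y = center_y,
                 semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
                 rotation = rotation, fill_level = fill_level,
                 analytic_area = pi * semi_axis_a * semi_axis_b),
            class = "ellipse_spec")
}

#' Specify a synthetic spheroid scene
#'
#' Describes one brightfield-style well image: dark elliptical
#' spheroid(s) on a lighter background with additive Gaussian noise,
#' optionally an illumination gradient, small dark debris blobs (never
#' part of the ground truth) and hollow ring-like spheroids.
#'
#' Defaults emulate a typical live-cell imager frame: 256 x 256 pixels,
#' background 200, noise sigma 8 (visible grain without obscuring the
#' spheroid), spheroid fill 80.
#'
#' @param image_height,image_width Image size in pixels (>= 64).
#' @param background_level Background intensity, 0-255.
#' @param noise_sigma Standard deviation of the additive Gaussian noise,
#'   in intensity units (>= 0).
#' @param spheroids List of [ellipse_spec()]s; each must lie fully inside
#'   the image.
#' @param debris_count Number of small high-contrast blobs (>= 0),
#'   excluded from the ground truth.
#' @param hollow If `TRUE`, spheroids are rendered as rings (interior
#'   restored to background); ground truth remains the filled outline.
#' @param illumination_gradient Fractional left-to-right slope of the
#'   background (0 disables).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_height = 256, image_width = 256,
                       background_level = 200, noise_sigma = 8,
                       spheroids = list(), debris_count = 0,
                       hollow = FALSE, illumination_gradient = 0) {
  assert_number(image_height, "image_height", lower = 64)
  assert_number(image_width, "image_width", lower = 64)
  assert_number(background_level, "background_level", lower = 0, upper = 255)
  assert_number(noise_sigma, "noise_sigma", lower = 0)
  assert_number(debris_count, "debris_count", lower = 0)
  for (e in spheroids) {
    r <- max(e$semi_axis_a, e$semi_axis_b)
    if (e$center_x - r < 0 || e$center_x + r > image_width - 1 ||
        e$center_y - r < 0 || e$center_y + r > image_height - 1)
      stopf("ellipse at (%.1f, %.1f) with max semi-axis %.1f is not fully inside the %d x %d image",
            e$center_x, e$center_y, r, image_height, image_width)
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 background_level = background_level,
                 noise_sigma = noise_sigma, spheroids = spheroids,
                 debris_count = as.integer(debris_count), hollow = hollow,
                 illumination_gradient = illumination_gradient),
            class = "scene_spec")
}

#' Polygon outline of an ellipse
#'
#' Discretizes the ellipse boundary to a regular n-gon inscribed in it.
#'
#' @param e An [ellipse_spec()].
#' @param n_vertices Number of polygon vertices (default 128, which keeps
#'   the polygon area within 0.1% of `pi * a * b`).
#' @return A [polygon_region()].
#' @export
ellipse_polygon <- function(e, n_vertices = 128L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ca <- cos(e$rotation); sa <- sin(e$rotation)
  ex <- e$semi_axis_a * cos(ang); ey <- e$semi_axis_b * sin(ang)
  polygon_region(e$center_x + ex * ca - ey * sa,
                 e$center_y + ex * sa + ey * ca)
}

#' Render a synthetic spheroid image with ground truth
#'
#' Deterministic for a fixed `(spec, seed)` pair. Each spheroid's ground
#' truth is its boundary polygon (a 128-gon), the rasterization of that
#' polygon as a binary mask, and the analytic ellipse area. Debris blobs
#' are rendered but never included in the ground truth, enabling
#' false-positive tests downstream.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed for noise and debris placement.
#' @return A list with `image` (numeric matrix, integer 0-255) and
#'   `instances`, a list of `list(polygon, mask, analytic_area)` per
#'   spheroid.
#' @export
render_spheroid_image <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_height; w <- spec$image_width
  img <- matrix(spec$background_level, h, w)
  if (spec$illumination_gradient != 0) {
    ramp <- spec$background_level * spec$illumination_gradient *
      ((seq_len(w) - 1) / (w - 1) - 0.5)
    img <- img + matrix(ramp, h, w, byrow = TRUE)
  }
  instances <- vector("list", length(spec$spheroids))
  for (i in seq_along(spec$spheroids)) {
    e <- spec$spheroids[[i]]
    poly <- ellipse_polygon(e)
    mask <- polygon_to_mask(poly, c(h, w))
    img[mask] <- e$fill_level
    if (isTRUE(spec$hollow)) {
      inner <- e
      inner$semi_axis_a <- max(3, 0.55 * e$semi_axis_a)
      inner$semi_axis_b <- max(3, 0.55 * e$semi_axis_b)
      img[polygon_to_mask(ellipse_polygon(inner), c(h, w))] <- spec$background_level
    }
    instances[[i]] <- list(polygon = poly, mask = mask,
                           analytic_area = e$analytic_area)
  }
  img <- withr::with_seed(seed, {
    if (spec$debris_count > 0L)
      img <- add_debris(img, spec)
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    img
  })
  list(image = clip8(img), instances = instances)
}

# small dark blobs away from every spheroid (so ground truth stays clean)
add_debris <- function(img, spec) {
  h <- spec$image_height; w <- spec$image_width
  placed <- 0L
  tries <- 0L
  while (placed < spec$debris_count && tries < 200L) {
    tries <- tries + 1L
    r <- runif(1, 2, 4)
    cx <- runif(1, r + 1, w - r - 2)
    cy <- runif(1, r + 1, h - r - 2)
    clear <- all(vapply(spec$spheroids, function(e) {
      sqrt((cx - e$center_x)^2 + (cy - e$center_y)^2) >
        max(e$semi_axis_a, e$semi_axis_b) + r + 4
    }, logical(1)))
    if (!clear) next
    xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    ys <- matrix(seq_len(h) - 1, h, w)
    img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 50
    placed <- placed + 1L
  }
  img
}

#' Split sizes by largest-remainder apportionment
#'
#' Computes how many images each split receives: integer parts of
#' `n * fractions` first, then the remaining images go to the splits with
#' the largest fractional remainders, so the counts always sum to the
#' images assigned. A 70/30 split of 480 images gives exactly 336/144.
#'
#' @param n Total number of images.
#' @param fractions Split fractions in (0, 1], summing to at most 1.
#' @return Integer vector of split sizes (named like `fractions`).
#' @examples
#' split_sizes(480, c(train = 0.7, validation = 0.3))
#' @export
split_sizes <- function(n, fractions) {
  if (any(fractions <= 0) || any(fractions > 1))
    stopf("split fractions must lie in (0, 1]")
  if (sum(fractions) > 1 + 1e-9)
    stopf("split fractions sum to %.3f > 1", sum(fractions))
  stats::setNames(apportion_counts(n, fractions), names(fractions))
}

# largest-remainder apportionment of n into round(sum(n * fractions)) slots
apportion_counts <- function(n, fractions) {
  target <- n * fractions
  base <- floor(target + 1e-9)
  extra <- round(sum(target)) - sum(base)
  if (extra > 0L) {
    ord <- order(target - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  as.integer(base)
}

#' Generate an image dataset with train/validation/test splits
#'
#' Renders `n_images` scenes (one per call of `scene_sampler`), randomly
#' assigns them to splits and optionally writes PNG images plus one VIA
#' JSON annotation file per split and a manifest CSV.
#'
#' Split sizes use largest-remainder apportionment of `n_images *
#' split_fractions`, so counts sum exactly to the images assigned and a
#' 70/30 split of 480 images yields 336/144. Exact designs (such as a
#' 265/117/50 train/validation/test split) are requested through
#' `split_counts`, which overrides fractions.
#'
#' @param n_images Number of images (>= 1).
#' @param split_fractions Named fractions in (0, 1] summing to at most 1.
#' @param seed Integer seed; fixes the scene draw and the split
#'   assignment.
#' @param scene_sampler `function(i)` returning a [scene_spec()]; the
#'   default draws one random ellipse per image under the package's
#'   standard brightfield conditions.
#' @param split_counts Optional named integer vector of exact split sizes
#'   (must sum to `n_images`).
#' @param out_dir Optional directory: writes `<split>/img_####.png`,
#'   `annotations_<split>.json` and `manifest.csv`.
#' @return A `dataset_manifest`: list with `images` (data frame `image`,
#'   `split`), `ground_truth` (named list of polygon lists),
#'   `analytic_areas` (named list), `seed` and `split_fractions`.
#' @export
generate_dataset <- function(n_images, split_fractions = c(train = 0.7, validation = 0.3),
                             seed = 1L, scene_sampler = NULL,
                             split_counts = NULL, out_dir = NULL) {
  if (n_images < 1L) stopf("n_images must be >= 1")
  if (is.null(split_counts)) {
    counts <- split_sizes(n_images, split_fractions)
  } else {
    if (sum(split_counts) != n_images)
      stopf("split_counts sum to %d, expected n_images = %d",
            sum(split_counts), n_images)
    counts <- as.integer(split_counts)
    split_fractions <- split_counts / n_images
  }
  labels <- names(split_fractions) %||% paste0("split", seq_along(counts))
  sampler <- scene_sampler %||% default_scene_sampler
  withr::with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
    assignment <- sample(rep(labels, counts))
    if (length(assignment) < n_images)   # fractions summing below 1 leave a rest
      assignment <- c(assignment, rep(NA_character_, n_images - length(assignment)))
    scenes <- lapply(seq_len(n_images), sampler)
  })
  images <- sprintf("img_%04d.png", seq_len(n_images))
  gt <- list(); areas <- list(); rendered <- list()
  for (i in seq_len(n_images)) {
    r <- render_spheroid_image(scenes[[i]], seed = scene_seeds[i])
    gt[[images[i]]] <- lapply(r$instances, `[[`, "polygon")
    areas[[images[i]]] <- vapply(r$instances, `[[`, numeric(1), "analytic_area")
    rendered[[images[i]]] <- r$image
  }
  manifest <- list(images = data.frame(image = images, split = assignment,
                                       stringsAsFactors = FALSE),
                   ground_truth = gt, analytic_areas = areas,
                   seed = seed, split_fractions = split_fractions)
  class(manifest) <- "dataset_manifest"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in labels)
      dir.create(file.path(out_dir, lab), showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      sub <- if (is.na(assignment[i])) "." else assignment[i]
      png::writePNG(rendered[[images[i]]] / 255,
                    file.path(out_dir, sub, images[i]))
    }
    for (lab in labels) {
      in_split <- images[!is.na(assignment) & assignment == lab]
      write_via_annotations(structure(gt[in_split], class = "via_annotation_set"),
                            file.path(out_dir, sprintf("annotations_%s.json", lab)))
    }
    write.csv(manifest$images, file.path(out_dir, "manifest.csv"),
              row.names = FALSE, quote = FALSE)
  }
  manifest
}

# one random ellipse per scene under the default brightfield conditions
default_scene_sampler <- function(i) {
  a <- runif(1, 20, 40)
  b <- runif(1, 15, 30)
  r <- max(a, b)
  scene_spec(spheroids = list(ellipse_spec(
    center_x = runif(1, r + 2, 253 - r),
    center_y = runif(1, r + 2, 253 - r),
    semi_axis_a = a, semi_axis_b = b,
    rotation = runif(1, 0, pi))))
}

#' Specify a contraction time series
#'
#' The well-area kinetics follow exponential decay
#' `area(t) = initial_area * exp(-rate * t)` with multiplicative
#' lognormal noise of coefficient of variation `noise_cv` (unit mean, so
#' `noise_cv = 0` reproduces the decay exactly). Defaults mirror hourly
#' imaging over 24 hours.
#'
#' @param groups List of `list(name, initial_area, rate, noise_cv)`:
#'   initial area in pixels, contraction rate per hour (>= 0), noise CV
#'   as a fraction.
#' @param n_timepoints Number of acquisitions (default 25: t = 0..24 h).
#' @param interval Hours between acquisitions.
#' @param replicates Replicates per group.
#' @return A `contraction_series_spec` list.
#' @export
contraction_series_spec <- function(groups, n_timepoints = 25L, interval = 1,
                                    replicates = 3L) {
  if (n_timepoints < 1L || interval <= 0 || replicates < 1L)
    stopf("need n_timepoints >= 1, interval > 0, replicates >= 1")
  for (g in groups) {
    if (g$initial_area <= 0) stopf("initial_area must be positive")
    if (g$rate < 0) stopf("contraction rate must be >= 0")
    if (g$noise_cv < 0) stopf("noise_cv must be >= 0")
  }
  structure(list(groups = groups, n_timepoints = as.integer(n_timepoints),
                 interval = interval, replicates = as.integer(replicates)),
            class = "contraction_series_spec")
}

#' Simulate spheroid contraction kinetics
#'
#' @param spec A [contraction_series_spec()].
#' @param seed Integer seed.
#' @return Long-format data frame with columns `group`, `replicate`,
#'   `timepoint_h`, `area_px`; areas are strictly positive.
#' @examples
#' spec <- contraction_series_spec(list(
#'   list(name = "control", initial_area = 10000, rate = 0, noise_cv = 0),
#'   list(name = "treated", initial_area = 10000, rate = 0.05, noise_cv = 0)))
#' head(simulate_contraction_series(spec, seed = 1))
#' @export
simulate_contraction_series <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "contraction_series_spec"))
  t <- (seq_len(spec$n_timepoints) - 1L) * spec$interval
  withr::with_seed(seed, {
    rows <- lapply(spec$groups, function(g) {
      sdlog <- sqrt(log(1 + g$noise_cv^2))
      do.call(rbind, lapply(seq_len(spec$replicates), function(rep) {
        noise <- if (g$noise_cv > 0)
          rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        else rep(1, length(t))
        data.frame(group = g$name, replicate = rep, timepoint_h = t,
                   area_px = g$initial_area * exp(-g$rate * t) * noise,
                   stringsAsFactors = FALSE)
      }))
    })
  })
  do.call(rbind, rows)
}
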