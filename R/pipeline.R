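image_file_pattern <- "\\.(png|tif|tiff|jpg|jpeg)$"

#' Batch prediction: images in, results CSV out
#'
#' Runs the configured detector on every readable image in `input_dir`,
#' measures each detected instance ([measure_instance()]) and writes one
#' results row per instance. Images with zero detections are not errors:
#' they are reported in the `"skipped"` attribute and in the per-image
#' log, mirroring the failure-audit style of spheroid assay pipelines.
#'
#' @param input_dir Directory with PNG/TIFF/JPEG images (searched
#'   recursively).
#' @param config A [detector_config()].
#' @param out_csv Optional results CSV path ([write_results_csv()]).
#' @param overlay_dir Optional directory for grayscale PNGs with detected
#'   boundaries burned in at intensity 255.
#' @param quiet Suppress the per-image log messages.
#' @return Invisibly, the results data frame (columns `image_id`,
#'   `instance_id`, `area_px`, `perimeter_px`, `circularity`,
#'   `mean_intensity`, `score`), with attribute `"skipped"` listing
#'   images without detections.
#' @export
cmd_predict <- function(input_dir, config = detector_config(),
                        out_csv = NULL, overlay_dir = NULL, quiet = FALSE) {
  files <- list.files(input_dir, pattern = image_file_pattern,
                      ignore.case = TRUE, recursive = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stopf("no readable images (PNG/TIFF/JPEG) found under '%s'", input_dir)
  rows <- list()
  skipped <- character()
  for (f in files) {
    id <- basename(f)
    img <- to_grayscale(load_image(f))
    dets <- detect_spheroids(img, config)
    if (!quiet)
      message(sprintf("%s: %d detection(s)%s", id, length(dets),
                      if (length(dets))
                        sprintf(", max score %.3f", dets[[1L]]$score) else ""))
    if (length(dets) == 0L) {
      skipped <- c(skipped, id)
      next
    }
    for (i in seq_along(dets)) {
      m <- measure_instance(img, dets[[i]]$mask)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, instance_id = i, area_px = m$area_px,
        perimeter_px = m$perimeter_px, circularity = m$circularity,
        mean_intensity = m$mean_intensity, score = dets[[i]]$score,
        stringsAsFactors = FALSE)
    }
    if (!is.null(overlay_dir)) {
      dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
      ov <- img
      for (d in dets) {
        edge <- d$mask & !(EBImage::erode(d$mask, EBImage::makeBrush(3, "disc")) > 0)
        ov[edge] <- 255
      }
      png::writePNG(ov / 255, file.path(overlay_dir, id))
    }
  }
  res <- if (length(rows)) do.call(rbind, rows)
         else read_results_csv(write_results_csv(data.frame()))
  if (!quiet && length(skipped))
    message(sprintf("no spheroid identified in %d of %d images",
                    length(skipped), length(files)))
  if (!is.null(out_csv)) write_results_csv(res, out_csv)
  attr(res, "skipped") <- skipped
  invisible(res)
}

#' Evaluate predictions against VIA ground truth
#'
#' `pred_source` is either (a) a directory of images, in which case the
#' configured detector is run to produce predictions, or (b) a VIA JSON
#' of predicted polygons, whose regions may carry a `"score"` region
#' attribute (missing scores default to 1.0). A results CSV alone cannot
#' be evaluated, since it carries no masks. Ground-truth filenames with
#' no matching prediction are reported and counted as false negatives.
#'
#' @param pred_source Image directory or predicted-polygon VIA JSON.
#' @param truth_json Ground-truth VIA JSON (file or text).
#' @param out_report Optional JSON report path.
#' @param config [detector_config()] used when `pred_source` is a
#'   directory.
#' @param shape `c(height, width)` for polygon rasterization; inferred
#'   when `NULL` (see [evaluate_dataset()]).
#' @param quiet Suppress messages.
#' @return List with `box` and `mask` `eval_report`s and `unmatched`
#'   (ground-truth images without predictions).
#' @export
cmd_evaluate <- function(pred_source, truth_json, out_report = NULL,
                         config = detector_config(), shape = NULL,
                         quiet = FALSE) {
  truth <- parse_via_annotations(truth_json)
  if (dir.exists(pred_source)) {
    files <- list.files(pred_source, pattern = image_file_pattern,
                        ignore.case = TRUE, recursive = TRUE, full.names = TRUE)
    preds <- list()
    for (f in files) {
      img <- to_grayscale(load_image(f))
      preds[[basename(f)]] <- detect_spheroids(img, config)
      if (is.null(shape)) shape <- dim(img)
    }
  } else {
    pred_set <- parse_via_annotations(pred_source)
    if (is.null(shape)) {
      allp <- unlist(unname(pred_set), recursive = FALSE)
      allp <- c(allp, unlist(unname(truth), recursive = FALSE))
      shape <- c(ceiling(max(vapply(allp, function(p) max(p$y), 1))) + 2,
                 ceiling(max(vapply(allp, function(p) max(p$x), 1))) + 2)
    }
    preds <- lapply(pred_set, function(polys) lapply(polys, function(p) {
      score <- attr(p, "region_attributes")$score %||% 1
      detected_instance(polygon_to_mask(p, shape), as.numeric(score))
    }))
  }
  unmatched <- setdiff(names(truth), names(preds))
  if (!quiet && length(unmatched))
    message(sprintf("%d annotated image(s) have no predictions (counted as false negatives): %s",
                    length(unmatched), paste(unmatched, collapse = ", ")))
  reports <- evaluate_dataset(preds, truth, shape = shape, out_json = out_report)
  reports$unmatched <- unmatched
  reports
}

# per-image area: total segmented area per image, joined to metadata
grouped_results <- function(results, metadata = NULL) {
  per_image <- aggregate(area_px ~ image_id, results, sum)
  if (!is.null(metadata)) {
    per_image <- merge(per_image, metadata, by = "image_id", all.x = TRUE)
  }
  if (is.null(per_image$group)) per_image$group <- NA_character_
  per_image$group[is.na(per_image$group)] <- "ungrouped"
  if (is.null(per_image$replicate)) per_image$replicate <- per_image$image_id
  per_image
}

#' Visualization and summary statistics for results
#'
#' Takes a results CSV (or data frame) and an optional metadata table
#' mapping `image_id` to `group` and, for kinetics, `timepoint_h` and
#' `replicate`. Produces publication-style PNG plots and a summary CSV:
#'
#' * `area_kinetics.png` — mean total area per group over time (ribbon:
#'   +/- SD), when timepoints are available;
#' * `normalized_area.png` — area as % of each replicate's first
#'   timepoint (the standard contraction-assay readout);
#' * `final_area_distribution.png` — per-group distribution of
#'   final-timepoint areas;
#' * `summary.csv` — per group: n, mean/SD of final area, mean
#'   normalized final area (%); with exactly two groups a Wilcoxon
#'   rank-sum test on final areas is appended as a comparison row
#'   (omitted, with a notice, otherwise).
#'
#' @param results Results CSV path or data frame (needs `image_id`,
#'   `area_px`).
#' @param metadata Optional CSV path or data frame with `image_id`,
#'   `group` and optionally `timepoint_h`, `replicate`. Unlisted images
#'   fall into `"ungrouped"`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress messages.
#' @return Invisibly, a list with `summary` (data frame), `comparison`
#'   (Wilcoxon result or `NULL`) and `files` (written paths).
#' @export
cmd_visualize <- function(results, metadata = NULL, out_dir, quiet = FALSE) {
  if (is.character(results)) results <- read_results_csv(results)
  for (col in c("image_id", "area_px"))
    if (is.null(results[[col]]))
      stopf("results are missing required column '%s'", col)
  if (is.character(metadata)) metadata <- read.csv(metadata, stringsAsFactors = FALSE)
  if (!is.null(metadata) && is.null(metadata$image_id))
    stopf("metadata is missing required column 'image_id'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- grouped_results(results, metadata)
  files <- character()
  has_time <- !is.null(d$timepoint_h) && !all(is.na(d$timepoint_h))

  if (has_time) {
    d <- d[order(d$group, d$replicate, d$timepoint_h), ]
    base <- d[!duplicated(paste(d$group, d$replicate)), c("group", "replicate", "area_px")]
    names(base)[3L] <- "area_t0"
    d <- merge(d, base, by = c("group", "replicate"))
    d$norm_pct <- 100 * d$area_px / d$area_t0

    kin <- stats::aggregate(cbind(area_px, norm_pct) ~ group + timepoint_h, d, mean)
    kin_sd <- stats::aggregate(cbind(area_px, norm_pct) ~ group + timepoint_h, d, sd)
    kin$area_sd <- kin_sd$area_px
    kin$norm_sd <- kin_sd$norm_pct
    kin[is.na(kin)] <- 0

    p1 <- ggplot2::ggplot(kin, ggplot2::aes(x = .data$timepoint_h, y = .data$area_px,
                                            colour = .data$group, fill = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$area_px - .data$area_sd,
                                        ymax = .data$area_px + .data$area_sd),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line(linewidth = 0.8) + ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(x = "Time (h)", y = "Spheroid area (px)",
                    title = "Spheroid area kinetics") +
      ggplot2::theme_minimal()
    files <- c(files, save_plot(p1, file.path(out_dir, "area_kinetics.png")))

    p2 <- ggplot2::ggplot(kin, ggplot2::aes(x = .data$timepoint_h, y = .data$norm_pct,
                                            colour = .data$group, fill = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$norm_pct - .data$norm_sd,
                                        ymax = .data$norm_pct + .data$norm_sd),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line(linewidth = 0.8) + ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(x = "Time (h)", y = "Area (% of first timepoint)",
                    title = "Normalized contraction kinetics") +
      ggplot2::theme_minimal()
    files <- c(files, save_plot(p2, file.path(out_dir, "normalized_area.png")))

    final_t <- stats::aggregate(timepoint_h ~ group + replicate, d, max)
    finals <- merge(d, final_t, by = c("group", "replicate", "timepoint_h"))
  } else {
    d$norm_pct <- NA_real_
    finals <- d
  }

  p3 <- ggplot2::ggplot(finals, ggplot2::aes(x = .data$group, y = .data$area_px)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Final spheroid area (px)",
                  title = "Endpoint area by group") +
    ggplot2::theme_minimal()
  files <- c(files, save_plot(p3, file.path(out_dir, "final_area_distribution.png")))

  summ <- do.call(rbind, lapply(split(finals, finals$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g),
               mean_final_area = mean(g$area_px),
               sd_final_area = if (nrow(g) > 1L) sd(g$area_px) else 0,
               mean_final_norm_pct = mean(g$norm_pct),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL

  comparison <- NULL
  groups <- unique(finals$group)
  if (length(groups) == 2L) {
    w <- wilcox.test(area_px ~ group, data = finals, exact = FALSE)
    comparison <- data.frame(test = "wilcoxon_rank_sum",
                             group_a = groups[1L], group_b = groups[2L],
                             statistic = unname(w$statistic),
                             p_value = w$p.value)
  } else if (!quiet) {
    message(sprintf("%d group(s) present; two-group comparison omitted", length(groups)))
  }

  summary_path <- file.path(out_dir, "summary.csv")
  write.csv(summ, summary_path, row.names = FALSE)
  files <- c(files, summary_path)
  if (!is.null(comparison)) {
    cmp_path <- file.path(out_dir, "comparison.csv")
    write.csv(comparison, cmp_path, row.names = FALSE)
    files <- c(files, cmp_path)
  }
  invisible(list(summary = summ, comparison = comparison, files = files))
}

save_plot <- function(p, path, width = 6, height = 4) {
  grDevices::png(path, width = width * 150, height = height * 150, res = 150)
  print(p)
  grDevices::dev.off()
  path
}

#' Runtime-linearity harness for the prediction pipeline
#'
#' Times [cmd_predict()] on generated datasets of the requested sizes and
#' (for two or more sizes) fits `seconds ~ n`. Linear scaling is a
#' property of the per-image pipeline: the fit's R-squared should be high
#' when the sizes span a wide range; no wall-clock constant is asserted
#' anywhere.
#'
#' @param n_images Integer vector of dataset sizes.
#' @param config A [detector_config()].
#' @param seed Integer seed for dataset generation.
#' @param image_size Square image side in pixels for the generated
#'   datasets.
#' @return Data frame with columns `n_images` and `seconds`, attribute
#'   `"fit"` holding `list(r_squared, seconds_per_image)` when more than
#'   one size was timed.
#' @export
runtime_benchmark <- function(n_images = c(5, 10, 20, 40),
                              config = detector_config(), seed = 1L,
                              image_size = 128) {
  sampler <- function(i) {
    a <- runif(1, 12, 20); b <- runif(1, 10, 16); r <- max(a, b)
    scene_spec(image_height = image_size, image_width = image_size,
               spheroids = list(ellipse_spec(
                 center_x = runif(1, r + 2, image_size - 3 - r),
                 center_y = runif(1, r + 2, image_size - 3 - r),
                 semi_axis_a = a, semi_axis_b = b,
                 rotation = runif(1, 0, pi))))
  }
  secs <- vapply(seq_along(n_images), function(k) {
    dir <- file.path(tempfile("bench"))
    generate_dataset(n_images[k], split_fractions = c(all = 1),
                     seed = seed + k, scene_sampler = sampler, out_dir = dir)
    t <- system.time(cmd_predict(dir, config, quiet = TRUE))[["elapsed"]]
    unlink(dir, recursive = TRUE)
    t
  }, numeric(1))
  out <- data.frame(n_images = n_images, seconds = secs)
  if (length(n_images) > 1L) {
    fit <- lm(seconds ~ n_images, data = out)
    attr(out, "fit") <- list(r_squared = summary(fit)$r.squared,
                             seconds_per_image = unname(coef(fit)[2L]))
  }
  out
}
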