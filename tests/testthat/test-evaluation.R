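rect_mask <- function(r0, c0, r1, c1, shape = c(24, 24)) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:r1, c0:c1] <- TRUE
  m
}

test_that("greedy matching counts TP/FP/FN per the one-to-one rule", {
  gt <- rect_mask(5, 5, 12, 12)
  pred <- detected_instance(gt, 0.9)
  m <- match_instances(list(pred), list(gt), 0.5, "mask")
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  expect_equal(m$pairs$iou, 1)

  # two predictions on one gt: the duplicate is penalized as FP
  p1 <- detected_instance(rect_mask(5, 5, 12, 11), 0.95)   # IoU 0.875
  p2 <- detected_instance(rect_mask(5, 5, 12, 13), 0.80)
  m2 <- match_instances(list(p1, p2), list(gt), 0.5, "mask")
  expect_identical(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  expect_equal(m2$pairs$pred, 1)                   # higher score matched first

  m3 <- match_instances(list(), list(gt, rect_mask(1, 1, 3, 3)), 0.5, "mask")
  expect_identical(c(m3$tp, m3$fp, m3$fn), c(0L, 0L, 2L))

  expect_error(match_instances(list(pred), list(matrix(TRUE, 5, 5)), 0.5, "mask"),
               "shape")
})

test_that("precision and recall are the exact TP ratios", {
  fake <- structure(list(tp = 3L, fp = 1L, fn = 0L), class = "match_result")
  expect_equal(precision(fake), 0.75)
  expect_equal(recall(fake), 1)
  fake0 <- structure(list(tp = 0L, fp = 5L, fn = 0L), class = "match_result")
  expect_equal(precision(fake0), 0)
  expect_error(recall(fake0), "undefined")
  none <- structure(list(tp = 0L, fp = 0L, fn = 2L), class = "match_result")
  expect_error(precision(none), "undefined")
})

test_that("PR curves follow hand-computed rankings", {
  gt <- rect_mask(5, 5, 12, 12)
  hit <- detected_instance(gt, 0.9)
  miss <- detected_instance(rect_mask(18, 18, 22, 22), 0.5)

  perfect <- pr_curve(list(hit), list(gt), 0.5, "mask")
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$n_gt, 1)

  tp_fp <- pr_curve(list(hit, miss), list(gt), 0.5, "mask")
  expect_equal(tp_fp$recall, c(1, 1))
  expect_equal(tp_fp$precision, c(1, 0.5))
  expect_equal(average_precision(tp_fp), 1)        # envelope keeps precision 1

  fp_tp <- pr_curve(list(detected_instance(gt, 0.4),
                         detected_instance(rect_mask(18, 18, 22, 22), 0.8)),
                    list(gt), 0.5, "mask")
  expect_equal(fp_tp$recall, c(0, 1))
  expect_equal(fp_tp$precision, c(0, 0.5))
  expect_equal(average_precision(fp_tp), 0.5)
})

test_that("AP handles empty and undefined cases", {
  gt <- rect_mask(5, 5, 12, 12)
  empty <- pr_curve(list(), list(gt), 0.5, "mask")
  expect_equal(average_precision(empty), 0)
  no_gt <- pr_curve(list(detected_instance(gt, 0.9)), list(), 0.5, "mask")
  expect_error(average_precision(no_gt), "undefined")
})

test_that("AP matches the brute-force reference on random scenes (both integrators)", {
  withr::with_seed(23, {
    for (i in 1:40) {
      gts <- replicate(sample(1:4, 1), random_rect_mask(), simplify = FALSE)
      preds <- replicate(sample(1:5, 1), {
        base <- gts[[sample(length(gts), 1)]]
        jit <- random_rect_mask()
        detected_instance(if (runif(1) < 0.6) base else jit, runif(1))
      }, simplify = FALSE)
      thr <- sample(c(0.5, 0.75), 1)
      curve <- pr_curve(preds, gts, thr, "mask")
      ours <- average_precision(curve)
      ref <- oracle_scene_ap(lapply(preds, function(p)
        list(mask = p$mask, score = p$score)), gts, thr)
      expect_equal(ours, ref, tolerance = 1e-9)
      expect_lt(abs(average_precision(curve, "coco101") - ours), 0.02)
    }
  })
})

test_that("mean AP averages the ten-threshold grid and is monotone in IoU", {
  gt <- rect_mask(5, 5, 14, 14)
  pred <- detected_instance(rect_mask(5, 5, 14, 13), 0.9)   # IoU 0.9
  rep <- mean_ap(list(pred), list(gt), "mask")
  expect_length(rep$thresholds, 10)
  expect_equal(rep$thresholds, seq(0.5, 0.95, by = 0.05))
  expect_equal(rep$mean_ap, mean(rep$ap_per_threshold))
  expect_equal(rep$ap_at_075, rep$ap_per_threshold[["0.75"]])
  expect_true(all(diff(rep$ap_per_threshold) <= 1e-12))     # non-increasing

  perfect <- mean_ap(list(detected_instance(gt, 1)), list(gt), "mask")
  expect_equal(perfect$mean_ap, 1)
  perfect_box <- mean_ap(list(detected_instance(gt, 1)), list(gt), "box")
  expect_equal(perfect_box$mean_ap, 1)
})

test_that("permuting equal-scored predictions never changes AP", {
  gts <- list(rect_mask(2, 2, 8, 8), rect_mask(14, 14, 20, 20))
  preds <- list(detected_instance(rect_mask(2, 2, 8, 8), 0.7),
                detected_instance(rect_mask(14, 14, 20, 20), 0.7),
                detected_instance(rect_mask(10, 2, 12, 4), 0.7))
  ap1 <- average_precision(pr_curve(preds, gts, 0.5, "mask"))
  ap2 <- average_precision(pr_curve(rev(preds), gts, 0.5, "mask"))
  expect_identical(ap1, ap2)
})

test_that("evaluate_dataset scores perfect predictions at 1.0 and writes JSON", {
  sp <- scene_spec(noise_sigma = 0,
                   spheroids = list(ellipse_spec(80, 90, 28, 20, rotation = 0.2)))
  r <- render_spheroid_image(sp, seed = 3)
  truth <- structure(list(well.png = list(r$instances[[1]]$polygon)),
                     class = "via_annotation_set")
  preds <- list(well.png = list(detected_instance(r$instances[[1]]$mask, 0.98)))
  out <- withr::local_tempfile(fileext = ".json")
  reports <- evaluate_dataset(preds, truth, shape = c(256, 256), out_json = out)
  expect_equal(reports$box$mean_ap, 1)
  expect_equal(reports$mask$mean_ap, 1)

  parsed <- jsonlite::fromJSON(out)
  expect_equal(parsed$mask$mean_ap, 1)
  expect_length(parsed$box$thresholds, 10)

  none <- evaluate_dataset(list(well.png = list()), truth, shape = c(256, 256))
  expect_equal(none$mask$mean_ap, 0)
  expect_equal(none$box$mean_ap, 0)
})
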