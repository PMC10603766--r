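# Independent brute-force oracles. These deliberately share no code with
# the package: slow scalar loops, textbook formulas.

# even-odd ray cast for one point; half-open edge treatment matches the
# top-left convention (a point on a left edge is inside, right edge outside)
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# per-pixel rasterization by the ray cast above
oracle_rasterize <- function(polygon, shape) {
  h <- shape[1]; w <- shape[2]
  m <- matrix(FALSE, h, w)
  for (r in seq_len(h))
    for (c in seq_len(w))
      m[r, c] <- oracle_point_in_polygon(c - 1, r - 1, polygon$x, polygon$y)
  m
}

# pixel-center point-in-ellipse count
oracle_ellipse_mask <- function(e, shape) {
  h <- shape[1]; w <- shape[2]
  m <- matrix(FALSE, h, w)
  ca <- cos(e$rotation); sa <- sin(e$rotation)
  for (r in seq_len(h))
    for (c in seq_len(w)) {
      dx <- (c - 1) - e$center_x
      dy <- (r - 1) - e$center_y
      u <- (dx * ca + dy * sa) / e$semi_axis_a
      v <- (-dx * sa + dy * ca) / e$semi_axis_b
      m[r, c] <- u * u + v * v <= 1
    }
  m
}

oracle_masked_mean <- function(image, mask) mean(image[mask])

# AP from a ranked TP/FP sequence: explicit cumulative precision/recall,
# backward precision envelope, rectangle sum over recall increments
oracle_ap_from_ranking <- function(tp, n_gt) {
  if (length(tp) == 0L) return(0)
  prec <- numeric(length(tp)); rec <- numeric(length(tp))
  hits <- 0
  for (i in seq_along(tp)) {
    hits <- hits + as.integer(tp[i])
    prec[i] <- hits / i
    rec[i] <- hits / n_gt
  }
  env <- numeric(length(tp)); m <- 0
  for (i in rev(seq_along(tp))) {
    m <- max(m, prec[i])
    env[i] <- m
  }
  ap <- 0; last_r <- 0
  for (i in seq_along(tp)) {
    ap <- ap + (rec[i] - last_r) * env[i]
    last_r <- rec[i]
  }
  ap
}

# full reference: greedy score-ordered matching + ranked AP, one scene
oracle_scene_ap <- function(preds, gts, iou_threshold) {
  sc <- vapply(preds, `[[`, numeric(1), "score")
  ar <- vapply(preds, function(p) sum(p$mask), numeric(1))
  preds <- preds[order(-sc, -ar)]
  used <- rep(FALSE, length(gts))
  tp <- logical(length(preds))
  for (i in seq_along(preds)) {
    best <- 0; bj <- 0L
    for (j in seq_along(gts)) {
      if (used[j]) next
      inter <- sum(preds[[i]]$mask & gts[[j]])
      uni <- sum(preds[[i]]$mask | gts[[j]])
      v <- if (uni > 0) inter / uni else 0
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0L && best >= iou_threshold) {
      used[bj] <- TRUE
      tp[i] <- TRUE
    }
  }
  oracle_ap_from_ranking(tp, length(gts))
}

# random star-shaped polygon with non-lattice vertices (no boundary ties)
random_polygon <- function(n_vertices = sample(5:10, 1), shape = c(40, 40)) {
  cx <- runif(1, 12, shape[2] - 13) + 0.137
  cy <- runif(1, 12, shape[1] - 13) + 0.211
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 4, 11)
  polygon_region(cx + rad * cos(ang), cy + rad * sin(ang))
}

# random axis-aligned rectangular mask
random_rect_mask <- function(shape = c(24, 24)) {
  h <- shape[1]; w <- shape[2]
  r0 <- sample(seq_len(h - 4), 1)
  c0 <- sample(seq_len(w - 4), 1)
  r1 <- min(h, r0 + sample(2:8, 1))
  c1 <- min(w, c0 + sample(2:8, 1))
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}
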