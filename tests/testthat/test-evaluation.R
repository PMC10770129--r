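# Object-level matching, F1 arithmetic, quantification, median split.

as_det <- function(poly, H, W, category = "TLS")
  structure(list(polygon = poly, category = category,
                 area_px = length(polygon_pixels(poly, H, W)),
                 area_mm2 = length(polygon_pixels(poly, H, W)) * (0.5e-3)^2,
                 confidence = 255,
                 pixels = polygon_pixels(poly, H, W), dims = c(H, W)),
            class = "DetectionObject")

test_that("identical predictions give a perfect match", {
  out <- small_synth(42)
  H <- out$annotations$height; W <- out$annotations$width
  preds <- lapply(tlsdetect:::category_polygons(out$annotations, "TLS"),
                  as_det, H = H, W = W)
  mr <- match_objects(out$annotations, preds, "TLS")
  expect_equal(mr$tp, length(preds))
  expect_equal(mr$fp, 0)
  expect_equal(mr$fn, 0)
})

test_that("a 49% cover is FN+FP, a 50% cover is TP", {
  H <- W <- 60
  gt <- list(rect_poly(10, 10, 20, 10))      # 200 px
  p49 <- as_det(rect_poly(10, 10, 14, 7), H, W)   # 98 px inside -> 49%
  expect_equal(p49$area_px, 98)
  skip_if_not_installed("mgcv")
  # verify the 49% with the independent rasterization oracle
  ginter <- length(intersect(oracle_polygon_pixels(gt[[1]], H, W),
                             oracle_polygon_pixels(p49$polygon, H, W)))
  expect_equal(ginter / 200, 0.49)
  mr <- match_objects(gt, list(p49), "TLS", dims = c(H, W))
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(0, 1, 1))
  p50 <- as_det(rect_poly(10, 10, 10, 10), H, W)    # exactly 50%
  mr2 <- match_objects(gt, list(p50), "TLS", dims = c(H, W))
  expect_equal(c(mr2$tp, mr2$fp, mr2$fn), c(1, 0, 0))
})

test_that("one large prediction may validate two ground truths", {
  H <- W <- 80
  gt <- list(rect_poly(10, 10, 10, 10), rect_poly(40, 10, 10, 10))
  big <- as_det(rect_poly(5, 5, 60, 20), H, W)
  mr <- match_objects(gt, list(big), "TLS", dims = c(H, W))
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(2, 0, 0))
})

test_that("matching agrees with the rasterized pixel-counting oracle on random fixtures", {
  skip_if_not_installed("mgcv")
  set.seed(41)
  H <- W <- 60
  for (i in 1:40) {
    n_gt <- sample(1:3, 1); n_pred <- sample(0:3, 1)
    gt <- replicate(n_gt, rect_poly(runif(1, 0, 40), runif(1, 0, 40),
                                    runif(1, 4, 18), runif(1, 4, 18)),
                    simplify = FALSE)
    preds <- replicate(n_pred, {
      p <- rect_poly(runif(1, 0, 40), runif(1, 0, 40),
                     runif(1, 4, 18), runif(1, 4, 18))
      as_det(p, H, W)
    }, simplify = FALSE)
    mr <- match_objects(gt, preds, "TLS", dims = c(H, W))
    om <- oracle_match(lapply(gt, oracle_polygon_pixels, H = H, W = W),
                       lapply(preds, function(o)
                         oracle_polygon_pixels(o$polygon, H, W)))
    expect_equal(c(mr$tp, mr$fp, mr$fn), c(om$tp, om$fp, om$fn))
  }
})

test_that("swapping predictions and ground truth swaps FP with FN", {
  H <- W <- 60
  gt <- list(rect_poly(5, 5, 10, 10), rect_poly(30, 30, 12, 12))
  preds <- list(as_det(rect_poly(5, 5, 10, 10), H, W),
                as_det(rect_poly(48, 48, 8, 8), H, W))
  fwd <- match_objects(gt, preds, "TLS", dims = c(H, W))
  swapped <- match_objects(lapply(preds, `[[`, "polygon"),
                           lapply(gt, as_det, H = H, W = W), "TLS",
                           dims = c(H, W))
  expect_equal(fwd$fp, swapped$fn)
  expect_equal(fwd$fn, swapped$fp)
})

test_that("F1 arithmetic matches the closed form and its conventions", {
  expect_equal(round(f1(0.94, 0.85), 2), 0.89)
  expect_equal(f1(1, 1), 1)
  expect_equal(f1_from_counts(0, 3, 2)$f1, 0)
  expect_equal(f1_from_counts(0, 0, 0)$f1, 0)
  expect_error(f1_from_counts(-1, 0, 0), "non-negative")
  # symmetric, and equal to precision when precision == recall
  expect_equal(f1(0.3, 0.7), f1(0.7, 0.3))
  expect_equal(f1(0.6, 0.6), 0.6)
})

test_that("pooled overall F1 differs from the mean of per-slide F1s", {
  m1 <- structure(list(category = "TLS", tp = 3, fp = 1, fn = 1),
                  class = "MatchResult")
  m2 <- structure(list(category = "TLS", tp = 1, fp = 0, fn = 1),
                  class = "MatchResult")
  ov <- overall_f1(list(m1, m2))
  hand <- 2 * (4 / 5) * (4 / 6) / ((4 / 5) + (4 / 6))
  expect_equal(ov$f1, hand)
  ps <- per_slide_f1(list(a = m1, b = m2))
  expect_false(isTRUE(all.equal(mean(ps$f1), ov$f1)))
  # empty-slide conventions
  empty_ok <- structure(list(category = "TLS", tp = 0, fp = 0, fn = 0),
                        class = "MatchResult")
  spurious <- structure(list(category = "TLS", tp = 0, fp = 2, fn = 0),
                        class = "MatchResult")
  conv <- per_slide_f1(list(empty_ok, spurious))
  expect_equal(conv$f1, c(1, 0))
  expect_error(per_slide_f1(list()), "empty")
})

test_that("TP + FN equals the ground-truth count (conservation)", {
  set.seed(51)
  H <- W <- 50
  for (i in 1:20) {
    n_gt <- sample(0:4, 1)
    gt <- replicate(n_gt, rect_poly(runif(1, 0, 35), runif(1, 0, 35),
                                    runif(1, 3, 12), runif(1, 3, 12)),
                    simplify = FALSE)
    preds <- replicate(sample(0:4, 1),
                       as_det(rect_poly(runif(1, 0, 35), runif(1, 0, 35),
                                        runif(1, 3, 12), runif(1, 3, 12)),
                              H, W), simplify = FALSE)
    mr <- match_objects(gt, preds, "TLS", dims = c(H, W))
    expect_equal(mr$tp + mr$fn, n_gt)
    expect_gte(mr$fp, 0)
  }
})

test_that("densities and mean sizes are computed per cm2 and mm2", {
  tm <- list(mask = matrix(TRUE, 10, 10), spacing = 4,
             area_cm2 = 2.0, threshold = 235)
  H <- W <- 400
  objs <- replicate(5, as_det(rect_poly(runif(1, 0, 300), runif(1, 0, 300),
                                        20, 20), H, W), simplify = FALSE)
  q <- quantify(objs, tm, slide_id = "s1")
  tls_row <- q[q$category == "TLS", ]
  expect_equal(tls_row$count, 5)
  expect_equal(tls_row$density_per_cm2, 2.5)
  expect_equal(tls_row$mean_area_mm2, 400 * (0.5e-3)^2)
  expect_true(is.na(q[q$category == "GC", "mean_area_mm2"]))
  expect_error(quantify(objs, list(area_cm2 = 0)), "positive")
})

test_that("generator ground truth reproduces the analytic density within 1%", {
  out <- small_synth(42)
  tm <- compute_tissue_mask(out$slide)
  q <- quantify(out$annotations, tm, source = "manual")
  n_tls <- length(tlsdetect:::category_polygons(out$annotations, "TLS"))
  expect_equal(q[q$category == "TLS", "count"], n_tls)
  expect_lt(abs(q[q$category == "TLS", "density_per_cm2"] -
                  n_tls / tm$area_cm2) / (n_tls / tm$area_cm2), 0.01)
})

test_that("median split takes the patient maximum and the strict-majority rule", {
  rec <- data.frame(cohort = "A", patient = c("p1", "p2", "p3", "p4"),
                    density_per_cm2 = c(0, 1, 2, 3))
  sp <- median_split(rec)
  expect_equal(sp$group, c("TLS-low", "TLS-low", "TLS-high", "TLS-high"))
  expect_equal(unique(sp$cohort_median), 1.5)
  # a patient with several slides gets the highest value
  rec2 <- data.frame(cohort = "A",
                     patient = c("p1", "p1", "p2"),
                     density_per_cm2 = c(0.2, 1.7, 0.5))
  sp2 <- median_split(rec2)
  expect_equal(sp2$density[sp2$patient == "p1"], 1.7)
  # all equal -> everyone low
  rec3 <- data.frame(cohort = "B", patient = c("q1", "q2"),
                     density_per_cm2 = c(1, 1))
  expect_true(all(median_split(rec3)$group == "TLS-low"))
})
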