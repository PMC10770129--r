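# Sampling, loss masking, the training loop, and hard-negative mining.

make_ann <- function(polys, w = 256, h = 256)
  annotation_set(polys, width = w, height = h)

test_that("sampling weights are normalized inverse pixel counts", {
  # counts TLS:100, Rest:300 -> weights 0.75 / 0.25
  ann <- make_ann(list(
    list(coords = rect_poly(10, 10, 10, 10), category = "TLS"),
    list(coords = rect_poly(50, 50, 30, 10), category = "Rest")))
  sw <- compute_sampling_weights(list(ann))
  expect_equal(unname(sw$counts), c(100, 0, 300))
  expect_equal(unname(sw$weights), c(0.75, 0, 0.25))
  # single nonzero category gets weight 1
  sw1 <- compute_sampling_weights(list(make_ann(list(
    list(coords = rect_poly(5, 5, 8, 8), category = "TLS")))))
  expect_equal(unname(sw1$weights), c(1, 0, 0))
  # zero-count categories are excluded, the rest renormalized
  ann2 <- make_ann(list(
    list(coords = rect_poly(10, 10, 10, 5), category = "GC"),
    list(coords = rect_poly(50, 50, 10, 5), category = "Rest")))
  sw2 <- compute_sampling_weights(list(ann2))
  expect_equal(unname(sw2$weights), c(0, 0.5, 0.5))
  # GC carved out of TLS: only annotated pixels count
  expect_error(compute_sampling_weights(list(make_ann(list(
    list(coords = rect_poly(5, 5, 50, 50), category = "LymphNode"))))),
    "no annotated pixels")
})

test_that("empirical category frequencies follow the sampler weights", {
  ann <- make_ann(list(
    list(coords = rect_poly(10, 10, 20, 10), category = "TLS"),
    list(coords = rect_poly(60, 60, 10, 10), category = "GC"),
    list(coords = rect_poly(100, 100, 40, 10), category = "Rest")))
  sw <- compute_sampling_weights(list(ann))
  n <- 10000
  draws <- tlsdetect:::with_seed(77, replicate(n, tlsdetect:::draw_category(sw)))
  freq <- tabulate(draws, nbins = 3) / n
  se <- sqrt(sw$weights * (1 - sw$weights) / n)
  expect_true(all(abs(freq - sw$weights) <= 3 * se + 1e-12))
})

test_that("batches are deterministic and centered on the drawn category", {
  out <- small_synth(42)
  slides <- list(out$slide); anns <- list(out$annotations)
  sw <- compute_sampling_weights(anns)
  cfg <- tiny_model_config()
  b1 <- sample_training_batch(slides, anns, sw, 4, cfg, seed = 13)
  b2 <- sample_training_batch(slides, anns, sw, 4, cfg, seed = 13)
  expect_identical(b1, b2)
  os <- cfg$geometry$output
  codes <- c(TLS = 1L, GC = 2L, Rest = 3L)
  for (s in b1)
    expect_equal(s$labels[os / 2, os / 2], unname(codes[s$category]))
})

test_that("loss ignores unlabeled and ignore pixels exactly", {
  m <- build_model(model_config(depth = 2, target_filters = c(2, 3),
                                target_bottleneck = 4,
                                context_filters = c(2, 3),
                                context_bottleneck = 4, input_size = 48,
                                seed = 3))
  set.seed(5)
  tg <- array(runif(48 * 48 * 3), c(48, 48, 3, 1))
  cx <- array(runif(48 * 48 * 3), c(48, 48, 3, 1))
  os <- m$config$geometry$output
  labels <- array(sample(c(0L, 1L, 2L, 255L), os * os, replace = TRUE),
                  c(os, os, 1))
  f <- tlsdetect:::model_forward(m, tg, cx, train = TRUE)
  l0 <- tlsdetect:::masked_ce(f$probs, f$logits, labels)
  # scramble labels only at excluded pixels
  labels2 <- labels
  excl <- labels == 0L | labels == 255L
  labels2[excl] <- ifelse(runif(sum(excl)) < 0.5, 0L, 255L)
  l1 <- tlsdetect:::masked_ce(f$probs, f$logits, labels2)
  expect_identical(l0$loss, l1$loss)
  expect_identical(l0$dlogits, l1$dlogits)
  # gradient at excluded pixels is exactly zero
  dl <- l0$dlogits
  for (k in 1:3) expect_true(all(dl[, , k, 1][excl[, , 1]] == 0))
})

test_that("a short seeded run reduces the training loss and is reproducible", {
  out <- small_synth(42)
  slides <- list(out$slide); anns <- list(out$annotations)
  cfg <- tiny_model_config(input_size = 220, seed = 8)
  tc <- train_config(iterations = 12, batch_size = 3, learning_rate = 2e-3,
                     seed = 4, val_every = 0)
  r1 <- train_model(build_model(cfg), slides, anns, tc)
  expect_lt(mean(tail(r1$log$loss, 3)), mean(head(r1$log$loss, 3)))
  r2 <- train_model(build_model(cfg), slides, anns, tc)
  expect_identical(r1$model$params, r2$model$params)
  expect_equal(r1$log$loss, r2$log$loss)
})

test_that("false-positive harvesting returns exactly the unmatched detections as Rest", {
  out <- small_synth(42)
  # an untrained tiny model produces arbitrary detections: every detection
  # that validates no ground truth must come back as a Rest polygon
  m <- build_model(tiny_model_config(seed = 31))
  thr <- list(TLS = list(t = 120, s = 5), GC = list(t = 250, s = 250))
  adds <- harvest_false_positives(m, list(out$slide), list(out$annotations),
                                  thr, iteration = 1L)
  expect_length(adds, 1)
  expect_true(all(vapply(adds[[1]]$polygons, `[[`, "", "category") == "Rest"))
  # recompute the detections and the matching independently
  tm <- compute_tissue_mask(out$slide)
  conf <- predict_wsi(m, out$slide, tm)
  det <- detect_slide(conf, thr)
  fp_areas <- numeric(0)
  for (cat in c("TLS", "GC")) {
    if (length(det[[cat]]) == 0) next
    mr <- match_objects(out$annotations, det[[cat]], cat,
                        dims = dim(conf$maps)[1:2])
    fp_areas <- c(fp_areas, vapply(det[[cat]][!mr$pred_validates],
                                   function(o)
                                     tlsdetect:::polygon_area(o$polygon), 0))
  }
  harvested_areas <- sort(vapply(adds[[1]]$polygons, function(p)
    tlsdetect:::polygon_area(p$coords), 0))
  expect_equal(harvested_areas, sort(fp_areas))
  # provenance tags identify the mining iteration
  if (length(adds[[1]]$polygons))
    expect_true(all(vapply(adds[[1]]$polygons, `[[`, "", "provenance") ==
                      "mined-iter1"))
})

test_that("perfect predictions harvest nothing", {
  out <- small_synth(42)
  # fabricate a confidence map that matches the ground truth exactly and
  # check the matching/harvest logic in isolation
  conf <- generate_confidence_fixture(out$annotations, 230, 0, seed = 1)
  det <- detect_slide(conf, list(TLS = list(t = 128, s = 5),
                                 GC = list(t = 128, s = 3)))
  mr <- match_objects(out$annotations, det$TLS, "TLS",
                      dims = dim(conf$maps)[1:2])
  expect_equal(mr$fp, 0)
  expect_equal(mr$fn, 0)
})
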