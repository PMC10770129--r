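# Object extraction, threshold behavior, and the GC containment filter.

block_map <- function(H = 64, W = 64, blocks = list()) {
  # blocks: list of list(x, y, w, h, value, channel)
  maps <- array(0L, c(H, W, 3))
  for (b in blocks) {
    ch <- if (is.null(b$channel)) 1 else b$channel
    maps[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w), ch] <-
      as.integer(b$value)
  }
  confidence_map(maps)
}

test_that("a value block is detected iff thresholds allow it", {
  cm <- block_map(blocks = list(list(x = 20, y = 20, w = 10, h = 10,
                                     value = 200)))
  objs <- extract_objects(cm, "TLS", t = 128, s = 7)   # min area 49
  expect_length(objs, 1)
  expect_equal(objs[[1]]$area_px, 100)
  expect_equal(objs[[1]]$confidence, 200)
  expect_length(extract_objects(cm, "TLS", t = 201, s = 7), 0)
  expect_length(extract_objects(cm, "TLS", t = 128, s = 11), 0)  # 121 > 100
  expect_error(extract_objects(cm, "TLS", t = 300, s = 0), "0..255")
})

test_that("the TLS score restores GC nesting; the flag disables it", {
  # GC hole inside a TLS region: P(TLS) drops where P(GC) is high
  maps <- array(0L, c(40, 40, 3))
  maps[11:30, 11:30, 1] <- 200L
  maps[18:23, 18:23, 1] <- 20L
  maps[18:23, 18:23, 2] <- 180L
  cm <- confidence_map(maps)
  sum_obj <- extract_objects(cm, "TLS", t = 150, s = 3)
  expect_length(sum_obj, 1)
  expect_equal(sum_obj[[1]]$area_px, 400)  # hole healed by the GC score
  only_obj <- extract_objects(cm, "TLS", t = 150, s = 3,
                              tls_score = "tls_only")
  expect_equal(only_obj[[1]]$area_px, 400 - 36)
})

test_that("object counts are non-increasing in t and in s", {
  # Maps are random mixtures of isolated unimodal peaks, the structure real
  # confidence maps have. (For arbitrary rasters a rising threshold can
  # split one region into several, so count monotonicity in t is a property
  # of isolated peaks, not of thresholding itself; region nesting, tested
  # below, is the universal invariant.)
  set.seed(23)
  H <- W <- 64
  for (i in 1:50) {
    sc <- matrix(0, H, W)
    n_blob <- sample(2:6, 1)
    ctr <- cbind(runif(n_blob, 8, W - 8), runif(n_blob, 8, H - 8))
    ok <- rep(TRUE, n_blob)
    for (a in seq_len(n_blob)) for (b in seq_len(n_blob))
      if (a < b && sum((ctr[a, ] - ctr[b, ])^2) < (2 * 7)^2) ok[b] <- FALSE
    ctr <- ctr[ok, , drop = FALSE]
    for (j in seq_len(nrow(ctr))) {
      amp <- runif(1, 80, 255); r <- runif(1, 3, 6.5)
      for (c in 1:W) for (r2 in 1:H) {
        d2 <- (c - 0.5 - ctr[j, 1])^2 + (r2 - 0.5 - ctr[j, 2])^2
        if (d2 < r^2) sc[r2, c] <- max(sc[r2, c], amp * (1 - d2 / r^2))
      }
    }
    maps <- array(0L, c(H, W, 3))
    maps[, , 1] <- as.integer(round(sc))
    cm <- confidence_map(maps)
    ts <- sort(sample(1:255, 4))
    n_t <- vapply(ts, function(t)
      length(extract_objects(cm, "TLS", t, s = 1)), 0L)
    expect_true(all(diff(n_t) <= 0))
    ss <- sort(sample(0:12, 4))
    n_s <- vapply(ss, function(s)
      length(extract_objects(cm, "TLS", t = 40, s)), 0L)
    expect_true(all(diff(n_s) <= 0))
  }
})

test_that("objects at a higher threshold nest inside objects at a lower one", {
  set.seed(29)
  maps <- array(0L, c(48, 48, 3))
  maps[, , 1] <- as.integer(round(runif(48 * 48, 0, 255)))
  cm <- confidence_map(maps)
  lo <- extract_objects(cm, "TLS", t = 80, s = 0)
  hi <- extract_objects(cm, "TLS", t = 160, s = 0)
  lo_sets <- lapply(lo, `[[`, "pixels")
  for (o in hi) {
    container <- vapply(lo_sets, function(s) all(o$pixels %in% s), TRUE)
    expect_true(any(container))
  }
})

test_that("GC filter keeps exactly the sufficiently contained objects", {
  maps <- array(0L, c(60, 60, 3))
  maps[11:30, 11:30, 1] <- 220L   # TLS block 20x20
  maps[13:18, 13:18, 2] <- 220L   # GC fully inside
  maps[41:50, 41:50, 2] <- 220L   # GC disjoint from any TLS
  maps[21:30, 26:35, 2] <- 220L   # GC 10x10 covered on exactly 50 px
  cm <- confidence_map(maps)
  tls <- extract_objects(cm, "TLS", t = 200, s = 2, tls_score = "tls_only")
  gc <- extract_objects(cm, "GC", t = 200, s = 2)
  kept <- filter_gc_objects(gc, tls)
  areas <- sort(vapply(kept, `[[`, 0, "area_px"))
  # the fully inside GC and the exactly-half-covered GC stay; disjoint goes
  expect_length(kept, 2)
  covs <- vapply(kept, function(g) {
    un <- logical(60 * 60)
    for (o in tls) un[o$pixels] <- TRUE
    mean(un[g$pixels])
  }, 0)
  expect_true(any(covs == 0.5))   # boundary case kept at exactly 50%
  expect_length(filter_gc_objects(gc, list()), 0)
  expect_identical(filter_gc_objects(list(), tls), list())
})

test_that("threshold search equals the exhaustive oracle on constructed fixtures", {
  # distractor of area 36 at 180; true objects >= 100 px at 220
  H <- 48; W <- 48
  maps <- array(0L, c(H, W, 3))
  maps[6:17, 6:17, 1] <- 220L     # 144 px true object
  maps[30:41, 28:39, 1] <- 220L   # 144 px true object
  maps[24:29, 8:13, 1] <- 180L    # 36 px distractor
  cm <- confidence_map(maps)
  ann <- annotation_set(list(
    list(coords = rect_poly(5, 5, 12, 12), category = "TLS"),
    list(coords = rect_poly(27, 29, 12, 12), category = "TLS")),
    width = W, height = H)
  thr <- optimize_thresholds(list(list(confidence = cm, annotations = ann)),
                             "TLS")
  expect_equal(thr$f1, 1)
  expect_true(thr$t > 180 || thr$s >= 7)  # distractor excluded
  gt_pix <- lapply(tlsdetect:::category_polygons(ann, "TLS"),
                   function(p) polygon_pixels(p, H, W))
  oracle <- oracle_threshold_search(
    list(tlsdetect:::category_score(cm, "TLS")), list(gt_pix))
  expect_equal(thr$t, oracle$t)
  expect_equal(thr$s, oracle$s)
  expect_equal(thr$f1, oracle$f1)
})

test_that("the F1 surface at (0,0) equals pooled F1 with no filtering", {
  out <- small_synth(42)
  cm <- generate_confidence_fixture(out$annotations, 220, 5, seed = 2)
  thr <- optimize_thresholds(list(list(confidence = cm,
                                       annotations = out$annotations)),
                             "TLS")
  objs <- extract_objects(cm, "TLS", t = 0, s = 0)
  mr <- match_objects(out$annotations, objs, "TLS",
                      dims = dim(cm$maps)[1:2])
  expect_equal(thr$f1_surface[1, 1],
               f1_from_counts(mr$tp, mr$fp, mr$fn)$f1)
})

test_that("threshold search errors without any ground truth", {
  cm <- block_map()
  empty <- annotation_set(width = 64, height = 64)
  expect_error(optimize_thresholds(list(list(confidence = cm,
                                             annotations = empty)), "TLS"),
               "undefined")
})
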