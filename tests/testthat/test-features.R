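# Bottleneck-feature extraction, constant filtering, clustering, enrichment.

test_that("region features are deterministic and translation-consistent", {
  out <- small_synth(42)
  m <- build_model(tiny_model_config(seed = 3))
  tls <- tlsdetect:::category_polygons(out$annotations, "TLS")
  f1v <- suppressMessages(extract_region_features(m, out$slide, tls[[1]]))
  f2v <- suppressMessages(extract_region_features(m, out$slide, tls[[1]]))
  expect_identical(f1v, f2v)
  # translating slide content and region together leaves features unchanged
  # (slide large enough that the context window never touches a border)
  set.seed(6)
  H <- W <- 1536
  img <- array(round(runif(H * W, 60, 240)), c(H, W, 1))[, , c(1, 1, 1)]
  slide1 <- slide_pyramid(list(img, tlsdetect:::block_average(img, 4)),
                          c(0.5, 2.0), "tex")
  shift <- 40  # multiple of the pyramid factor
  img2 <- img[c((shift + 1):H, 1:shift), , , drop = FALSE]
  slide2 <- slide_pyramid(list(img2, tlsdetect:::block_average(img2, 4)),
                          c(0.5, 2.0), "tex-shifted")
  poly <- rect_poly(740, 760, 50, 50)
  poly2 <- poly; poly2[, 2] <- poly2[, 2] - shift
  fa <- suppressMessages(extract_region_features(m, slide1, poly))
  fb <- suppressMessages(extract_region_features(m, slide2, poly2))
  expect_equal(fa, fb, tolerance = 1e-10)
})

test_that("constant features are dropped exactly and idempotently", {
  set.seed(5)
  mat <- matrix(rnorm(20 * 440), 20, 440)
  const_cols <- sample(440, 85)
  mat[, const_cols] <- rep(rnorm(85), each = 20)
  filt <- drop_constant_features(mat)
  expect_equal(ncol(filt), 355)
  expect_equal(attr(filt, "removed"), 85)
  again <- drop_constant_features(filt)
  expect_equal(ncol(again), 355)
  expect_equal(attr(again, "removed"), 0)
  # duplicating a row never changes which columns are constant
  filt2 <- drop_constant_features(rbind(mat, mat[1, ]))
  expect_equal(attr(filt2, "kept"), attr(filt, "kept"))
  expect_error(drop_constant_features(matrix(1, 5, 4)), "constant")
  expect_error(drop_constant_features(mat[1, , drop = FALSE]), "two rows")
})

test_that("well-separated blobs are recovered by the graph clustering", {
  # dense-neighborhood regime: each blob comes back as exactly one cluster,
  # agreeing with a nearest-centroid oracle
  set.seed(8)
  n <- 60
  blob1 <- matrix(rnorm(n * 5, mean = 0, sd = 0.5), n, 5)
  blob2 <- matrix(rnorm(n * 5, mean = 8, sd = 0.5), n, 5)
  mat <- rbind(blob1, blob2)
  cl <- cluster_regions(mat, k = 30, seed = 2)
  expect_equal(cl$n_clusters, 2)
  truth <- rep(1:2, each = n)  # nearest-centroid oracle on this geometry
  agreement <- max(mean((cl$cluster == 1) == (truth == 1)),
                   mean((cl$cluster == 2) == (truth == 1)))
  expect_gte(agreement, 0.99)
  # seeded determinism
  cl2 <- cluster_regions(mat, k = 30, seed = 2)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_regions(mat[1:10, ], k = 50), "smaller k")
  expect_equal(dim(cl$embedding), c(2 * n, 2))
  expect_equal(formals(cluster_regions)$k, 50)
})

test_that("sparser neighborhoods may split blobs but never mix them", {
  # modularity optimization on a sparse kNN graph can subdivide one blob
  # into several communities; what must hold is that no community spans
  # the gap between blobs (their kNN graphs are disconnected)
  set.seed(8)
  n <- 200
  mat <- rbind(matrix(rnorm(n * 5, 0, 0.5), n, 5),
               matrix(rnorm(n * 5, 8, 0.5), n, 5))
  cl <- cluster_regions(mat, k = 15, seed = 2)
  truth <- rep(1:2, each = n)
  purity <- vapply(seq_len(cl$n_clusters), function(cc)
    max(table(truth[cl$cluster == cc])) / sum(cl$cluster == cc), 0)
  expect_true(all(purity == 1))
})

test_that("cluster enrichment matches the hand-computed Yates chi-square", {
  member <- c(rep(1, 30), rep(2, 30))
  cats <- c(rep("GC", 25), rep("TLS", 5), rep("TLS", 28), rep("GC", 2))
  cl <- structure(list(cluster = member, n_clusters = 2), class = "ClusterResult")
  enr <- cluster_enrichment(cl, cats)
  # hand computation for cluster 1: a=25, b=5 (in), c=2, d=28 (out)
  a <- 25; b <- 5; cc <- 2; d <- 28; n <- a + b + cc + d
  yates <- n * (abs(a * d - b * cc) - n / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  r1 <- enr[enr$cluster == 1, ]
  expect_equal(r1$statistic, yates, tolerance = 1e-12)
  expect_equal(r1$p_value, pchisq(yates, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(r1$enriched)
  # Yates statistic is strictly below the uncorrected one
  uncorrected <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_lt(r1$statistic, uncorrected)
  # conservation: per-cluster rows sum to the overall totals
  expect_equal(r1$gc_in + r1$gc_out, sum(cats == "GC"))
  expect_equal(r1$tls_in + r1$tls_out, sum(cats == "TLS"))
  # balanced membership -> zero (pre-correction) statistic, not flagged
  member2 <- rep(1:2, 20)
  cats2 <- rep(c("TLS", "GC"), each = 20)
  enr2 <- cluster_enrichment(structure(list(cluster = member2),
                                       class = "ClusterResult"), cats2)
  expect_false(any(enr2$enriched))
  expect_error(cluster_enrichment(cl, rep("TLS", 60)), "present")
})

test_that("feature matrices carry row metadata for annotated regions", {
  out <- small_synth(42)
  m <- build_model(tiny_model_config(seed = 3))
  suppressMessages(
    fm <- build_feature_matrix(m, list(out$slide), list(out$annotations),
                               source = "annotation"))
  n_tls <- length(tlsdetect:::category_polygons(out$annotations, "TLS"))
  n_gc <- length(tlsdetect:::category_polygons(out$annotations, "GC"))
  expect_equal(nrow(fm$features), n_tls + n_gc)
  expect_equal(sum(fm$meta$category == "GC"), n_gc)
  expect_equal(ncol(fm$features), m$hook_channels + 32)
})
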