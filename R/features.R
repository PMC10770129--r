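#' Bottleneck encoding features for a region
#'
#' Extracts the concentric patch pair centered on the region's area-weighted
#' centroid (reflect-padded near slide borders) and max-pools the hooked
#' target-branch bottleneck (see [extract_bottleneck_features()]), giving
#' one feature per bottleneck channel (440 for the default full model).
#'
#' @param model trained model.
#' @param slide a [slide_pyramid()].
#' @param polygon region polygon (two-column matrix, 0.5 um/px coords).
#' @return numeric feature vector.
#' @export
extract_region_features <- function(model, slide, polygon) {
  ctr <- polygon_centroid(polygon)
  cfg <- model$config
  pair <- list(
    target = extract_patch(slide, ctr[1], ctr[2], cfg$input_size,
                           cfg$target_spacing),
    context = extract_patch(slide, ctr[1], ctr[2], cfg$input_size,
                            cfg$context_spacing))
  extract_bottleneck_features(model, pair)
}

#' Assemble a feature matrix over annotated or detected regions
#'
#' @param model trained model.
#' @param slides list of [slide_pyramid()]s.
#' @param region_sets list (parallel to `slides`) of [annotation_set()]s or
#'   detection lists; TLS and GC regions are encoded.
#' @param source "annotation" or "prediction" metadata tag.
#' @param cohort optional cohort label(s), recycled over slides.
#' @return list with `features` (rows x channels matrix) and `meta`
#'   (data frame: slide_id, category, source, cohort).
#' @export
build_feature_matrix <- function(model, slides, region_sets,
                                 source = c("annotation", "prediction"),
                                 cohort = "cohort1") {
  source <- match.arg(source)
  cohort <- rep_len(cohort, length(slides))
  feats <- list(); meta <- list()
  for (i in seq_along(slides)) {
    rs <- region_sets[[i]]
    if (inherits(rs, "AnnotationSet")) {
      regions <- lapply(c("TLS", "GC"), function(cat)
        lapply(category_polygons(rs, cat), function(p)
          list(coords = p, category = cat)))
      regions <- do.call(c, regions)
      sid <- rs$slide_id
    } else {
      regions <- lapply(Filter(function(o) o$category %in% c("TLS", "GC"),
                               rs),
                        function(o) list(coords = o$polygon,
                                         category = o$category))
      sid <- slides[[i]]$slide_id
    }
    for (rg in regions) {
      feats[[length(feats) + 1]] <-
        extract_region_features(model, slides[[i]], rg$coords)
      meta[[length(meta) + 1]] <- data.frame(slide_id = sid,
                                             category = rg$category,
                                             source = source,
                                             cohort = cohort[i])
    }
  }
  list(features = do.call(rbind, feats), meta = do.call(rbind, meta))
}

#' Remove zero-variance (constant) feature columns
#'
#' The encoding vector routinely contains channels that take an identical
#' value across all regions of a dataset; they carry no information and are
#' dropped before clustering. Idempotent; the removed count is recorded in
#' the `removed` attribute.
#'
#' @param features numeric matrix, rows = regions.
#' @return the filtered matrix (attribute `removed` = number of dropped
#'   columns, `kept` = retained column indices).
#' @export
drop_constant_features <- function(features) {
  if (nrow(features) < 2) stop("need at least two rows")
  v <- apply(features, 2, function(x) max(x) - min(x))
  keep <- v > 0
  if (!any(keep)) stop("all feature columns are constant")
  out <- features[, keep, drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  attr(out, "kept") <- which(keep)
  out
}

#' Graph-based clustering of region encodings
#'
#' Builds a k-nearest-neighbor graph on the (filtered) feature rows,
#' weights each edge by the Jaccard overlap of the two endpoints' neighbor
#' sets (the standard PhenoGraph construction), and partitions it by
#' Louvain modularity optimization. Also emits a 2-D principal-component
#' embedding as a plotting side artifact.
#'
#' @param features numeric matrix (run [drop_constant_features()] first).
#' @param k number of nearest neighbors (default 50).
#' @param seed integer seed for the community detection.
#' @return a `ClusterResult`: list with `cluster` (contiguous ids from 1),
#'   `n_clusters`, `k`, `embedding` (rows x 2), `sizes`.
#' @export
cluster_regions <- function(features, k = 50, seed = 1L) {
  n <- nrow(features)
  if (n <= k)
    stop("need more rows (", n, ") than neighbors k = ", k,
         "; use a smaller k")
  d <- as.matrix(dist(features))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  neigh <- lapply(seq_len(n), function(i) nn[i, ])
  edges <- list()
  wts <- numeric(0)
  seen <- new.env(hash = TRUE)
  for (i in seq_len(n)) for (j in neigh[[i]]) {
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    jac <- length(intersect(neigh[[a]], neigh[[b]])) /
      length(union(neigh[[a]], neigh[[b]]))
    edges[[length(edges) + 1]] <- c(a, b)
    wts <- c(wts, jac)
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  keep <- wts > 0
  g <- igraph::subgraph_from_edges(g, which(keep),
                                   delete.vertices = FALSE)
  cl <- with_seed(seed,
                  igraph::cluster_louvain(g, weights = wts[keep]))
  member <- igraph::membership(cl)
  member <- as.integer(factor(member))  # contiguous ids from 1
  emb <- prcomp(features, rank. = 2)$x
  structure(list(cluster = member, n_clusters = max(member), k = k,
                 embedding = emb, sizes = tabulate(member)),
            class = "ClusterResult")
}

#' Per-cluster category enrichment (chi-square with Yates correction)
#'
#' For each cluster, tests the 2x2 contingency of membership (in-cluster vs
#' out) against category (TLS vs GC) with a continuity-corrected chi-square
#' test, flagging clusters enriched at p < 0.05.
#'
#' @param clusters a [cluster_regions()] result.
#' @param categories character vector of row categories ("TLS"/"GC"),
#'   parallel to the clustered rows.
#' @return data frame: cluster, counts of each category in/out, statistic,
#'   p_value, enriched flag.
#' @export
cluster_enrichment <- function(clusters, categories) {
  member <- clusters$cluster
  stopifnot(length(member) == length(categories))
  if (!all(c("TLS", "GC") %in% categories))
    stop("both TLS and GC must be present overall")
  rows <- lapply(sort(unique(member)), function(cl) {
    inc <- member == cl
    tab <- matrix(c(sum(inc & categories == "GC"),
                    sum(inc & categories == "TLS"),
                    sum(!inc & categories == "GC"),
                    sum(!inc & categories == "TLS")), 2, 2)
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    data.frame(cluster = cl,
               gc_in = tab[1, 1], tls_in = tab[2, 1],
               gc_out = tab[1, 2], tls_out = tab[2, 2],
               statistic = unname(ct$statistic),
               p_value = ct$p.value,
               enriched = is.finite(ct$p.value) && ct$p.value < 0.05)
  })
  do.call(rbind, rows)
}
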