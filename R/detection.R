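#' Object extraction from confidence maps
#'
#' Candidate objects are 8-connected regions of pixels whose category score
#' reaches a probability threshold `t`, kept when their pixel area reaches
#' the minimum area `s^2`. For TLS the score is the quantized P(TLS) plus
#' quantized P(GC) clipped to 255 (softmax categories are exclusive, so a
#' germinal center would otherwise punch a hole into its parent TLS; summing
#' restores the biological nesting GC within TLS). For GC the score is
#' quantized P(GC) alone. The alternative TLS score (TLS channel only) is
#' available via `tls_score = "tls_only"`.
#'
#' @param confidence a [confidence_map()].
#' @param category "TLS" or "GC".
#' @param t probability threshold, integer 0..255.
#' @param s size index, integer 0..255; minimum object area is `s^2` pixels.
#' @param tls_score "sum" (default) or "tls_only".
#' @return list of `DetectionObject`s: each carries `polygon` (outer
#'   outline, pixel-edge coordinates on the output grid), `category`,
#'   `area_px`, `area_mm2`, `confidence` (mean quantized score over its
#'   pixels) and `pixels` (1-based linear indices into the map).
#' @export
extract_objects <- function(confidence, category = c("TLS", "GC"), t, s,
                            tls_score = c("sum", "tls_only")) {
  category <- match.arg(category)
  tls_score <- match.arg(tls_score)
  if (t < 0 || t > 255 || s < 0 || s > 255)
    stop("t and s must be integers in 0..255")
  score <- category_score(confidence, category, tls_score)
  labels <- label_components_cpp(score >= t)
  build_objects(labels, score, category, min_area = s^2,
                spacing = confidence$spacing)
}

category_score <- function(confidence, category, tls_score = "sum") {
  m <- confidence$maps
  if (category == "GC") return(m[, , 2])
  if (tls_score == "sum") {
    pmin(m[, , 1] + m[, , 2], 255L)
  } else {
    m[, , 1]
  }
}

build_objects <- function(labels, score, category, min_area, spacing) {
  sizes <- tabulate(labels)
  keep <- which(sizes >= max(min_area, 1))
  px_mm2 <- (spacing * 1e-3)^2
  lapply(keep, function(id) {
    pix <- which(labels == id)
    structure(list(polygon = trace_outline_cpp(labels, id),
                   category = category,
                   area_px = sizes[id],
                   area_mm2 = sizes[id] * px_mm2,
                   confidence = mean(score[pix]),
                   pixels = pix,
                   dims = dim(labels)),
              class = "DetectionObject")
  })
}

#' Joint probability-and-size threshold search on a validation set
#'
#' Evaluates the pooled validation F1 of [extract_objects()] +
#' [match_objects()] for every `(t, s)` pair in \{0..255\}^2 and returns the
#' maximizer (ties broken by largest `t`, then largest `s`: the most
#' conservative operating point among equals). Connected components are
#' computed once per probability threshold and reused across the size
#' sweep, which is exactly equivalent to the exhaustive search because the
#' component decomposition does not depend on `s`.
#'
#' @param validation list of slides, each a list with `confidence`
#'   (a [confidence_map()]) and `annotations` (an [annotation_set()]).
#' @param category "TLS" or "GC".
#' @param tls_score see [extract_objects()].
#' @param min_coverage ground-truth overlap fraction defining a match.
#' @return a `ThresholdConfig`: list with `category`, `t`, `s`, the pooled
#'   validation `f1`, and the `counts` (TP, FP, FN) at the optimum.
#' @export
optimize_thresholds <- function(validation, category = c("TLS", "GC"),
                                tls_score = c("sum", "tls_only"),
                                min_coverage = 0.5) {
  category <- match.arg(category)
  tls_score <- match.arg(tls_score)
  per_slide <- lapply(validation, function(v) {
    score <- category_score(v$confidence, category, tls_score)
    gt <- category_polygons(v$annotations, category)
    d <- dim(score)
    gt_pix <- lapply(gt, function(p) polygon_pixels(p, d[1], d[2]))
    list(score = score, gt_pix = gt_pix)
  })
  n_gt <- sum(vapply(per_slide, function(x) length(x$gt_pix), 0L))
  if (n_gt == 0)
    stop("no ground-truth ", category,
         " objects in the validation set; F1 undefined")
  s2 <- (0:255)^2
  best <- list(f1 = -1, t = 0L, s = 0L)
  surface <- matrix(0, 256, 256)
  for (t in 0:255) {
    valid_area <- numeric(0)   # per GT: max area of a validating component
    fp_areas <- numeric(0)     # areas of components validating no GT
    for (ps in per_slide) {
      labels <- label_components_cpp(ps$score >= t)
      sizes <- tabulate(labels)
      validated <- rep(FALSE, length(sizes))
      va <- vapply(ps$gt_pix, function(gp) {
        tab <- tabulate(labels[gp], nbins = length(sizes))
        ok <- which(tab / length(gp) >= min_coverage)
        validated[ok] <<- TRUE
        if (length(ok)) max(sizes[ok]) else 0
      }, 0)
      valid_area <- c(valid_area, va)
      if (length(sizes))
        fp_areas <- c(fp_areas, sizes[!validated & sizes > 0])
    }
    # sweep s: counts are monotone in the area cutoff
    tp_s <- vapply(s2, function(a) sum(valid_area >= pmax(a, 1)), 0)
    fp_s <- vapply(s2, function(a) sum(fp_areas >= pmax(a, 1)), 0)
    fn_s <- n_gt - tp_s
    f1_s <- mapply(function(tp, fp, fn) f1_from_counts(tp, fp, fn)$f1,
                   tp_s, fp_s, fn_s)
    surface[t + 1, ] <- f1_s
    # >= so later (larger) t wins ties; within a t, the largest s among the
    # maximizers wins
    mx <- max(f1_s)
    if (mx >= best$f1)
      best <- list(f1 = mx, t = t, s = max(which(f1_s == mx)) - 1L)
  }
  structure(list(category = category, t = best$t, s = best$s,
                 f1 = best$f1, tls_score = tls_score,
                 f1_surface = surface),
            class = "ThresholdConfig")
}

#' @export
print.ThresholdConfig <- function(x, ...) {
  cat(sprintf(
    "ThresholdConfig[%s]: t = %d, min area = %d^2 px, validation F1 = %.3f\n",
    x$category, x$t, x$s, x$f1))
  invisible(x)
}

#' Keep only germinal centers lying within detected TLSs
#'
#' GC objects are predicted independently from TLS objects; a GC detection
#' is kept iff at least `min_overlap` of its area intersects the union of
#' the TLS detections. The directionally inverted reading (50% of the TLS
#' covered by the GC) is available via `mode = "of_tls"`.
#'
#' @param gc_objects,tls_objects detection lists from [extract_objects()]
#'   on the same output grid.
#' @param min_overlap minimum contained-area fraction (default 0.5;
#'   an exactly half-covered GC is kept).
#' @param mode "of_gc" (default) or "of_tls".
#' @return the filtered GC list.
#' @export
filter_gc_objects <- function(gc_objects, tls_objects, min_overlap = 0.5,
                              mode = c("of_gc", "of_tls")) {
  mode <- match.arg(mode)
  if (length(gc_objects) == 0) return(gc_objects)
  if (length(tls_objects) == 0) return(list())
  n <- prod(gc_objects[[1]]$dims[1:2])
  if (mode == "of_gc") {
    tls_union <- logical(n)
    for (o in tls_objects) tls_union[o$pixels] <- TRUE
    keep <- vapply(gc_objects, function(g)
      mean(tls_union[g$pixels]) >= min_overlap, TRUE)
  } else {
    keep <- vapply(gc_objects, function(g) {
      gset <- logical(n); gset[g$pixels] <- TRUE
      any(vapply(tls_objects, function(tl)
        mean(gset[tl$pixels]) >= min_overlap, TRUE))
    }, TRUE)
  }
  gc_objects[keep]
}

#' Full detection on one slide: extract both categories and apply the GC
#' containment filter
#'
#' @param confidence a [confidence_map()].
#' @param thresholds named list with `TLS` and `GC` [optimize_thresholds()]
#'   configs (or any lists with `t` and `s`).
#' @param tls_score see [extract_objects()].
#' @return list with `TLS` and `GC` detection lists.
#' @export
detect_slide <- function(confidence, thresholds,
                         tls_score = c("sum", "tls_only")) {
  tls_score <- match.arg(tls_score)
  tls <- extract_objects(confidence, "TLS", thresholds$TLS$t,
                         thresholds$TLS$s, tls_score)
  gc <- extract_objects(confidence, "GC", thresholds$GC$t,
                        thresholds$GC$s, tls_score)
  list(TLS = tls, GC = filter_gc_objects(gc, tls))
}

#' Write detections as QuPath-style GeoJSON
#'
#' Same dialect as [write_annotations()]; the mean quantized confidence is
#' stored as a feature property.
#'
#' @param detections list of detection objects (one or both categories).
#' @param path output path.
#' @param slide_id slide identifier recorded in the file.
#' @export
write_detections <- function(detections, path, slide_id = "slide") {
  polys <- lapply(detections, function(o)
    list(coords = o$polygon, category = o$category,
         confidence = o$confidence))
  dims <- if (length(detections)) detections[[1]]$dims else c(NA, NA)
  ann <- annotation_set(polys, slide_id = slide_id,
                        width = dims[2], height = dims[1])
  write_annotations(ann, path)
}
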