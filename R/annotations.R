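#' Polygon annotation sets
#'
#' An `AnnotationSet` holds labeled polygons for one slide in QuPath-style
#' full-resolution pixel coordinates (0-based, y-down, 0.5 um/px). Categories
#' come from the fixed vocabulary TLS, GC, LymphNode, Rest. TLS, GC and
#' LymphNode are annotated exhaustively; Rest is sparse. Lymph nodes are
#' morphological TLS look-alikes that are excluded from all downstream
#' processing (they rasterize to the ignore label).
#'
#' @param polygons list of elements, each a list with `coords` (two-column
#'   matrix of x,y vertices, unclosed) and `category` (character scalar).
#' @param slide_id character identifier of the source slide.
#' @param width,height slide dimensions in pixels at 0.5 um/px (optional but
#'   required by consumers that rasterize full-slide masks).
#' @param exhaustive categories annotated exhaustively.
#' @return an object of class `AnnotationSet`.
#' @export
annotation_set <- function(polygons = list(), slide_id = "slide",
                           width = NA_integer_, height = NA_integer_,
                           exhaustive = c("TLS", "GC", "LymphNode")) {
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (is.null(p$coords) || is.null(p$category))
      stop("polygon ", i, " must have coords and category")
    if (!is.matrix(p$coords) || ncol(p$coords) != 2 || nrow(p$coords) < 3)
      stop("polygon ", i, ": coords must be an (n>=3) x 2 matrix")
    if (!all(is.finite(p$coords)) || any(p$coords < 0))
      stop("polygon ", i, ": coordinates must be finite and non-negative")
    polygons[[i]]$category <- normalize_category(p$category)
  }
  structure(list(slide_id = slide_id, polygons = polygons,
                 width = as.integer(width), height = as.integer(height),
                 exhaustive = exhaustive),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cats <- vapply(x$polygons, `[[`, "", "category")
  cat("AnnotationSet for slide '", x$slide_id, "': ",
      length(x$polygons), " polygons\n", sep = "")
  if (length(cats)) print(table(factor(cats, levels = TLS_CATEGORIES)))
  invisible(x)
}

# Case- and whitespace-insensitive mapping of classification names onto the
# fixed vocabulary. Unknown names are errors, never silently Rest.
normalize_category <- function(name) {
  key <- gsub("[[:space:]_-]", "", tolower(name))
  map <- c(tls = "TLS", tertiarylymphoidstructure = "TLS",
           gc = "GC", germinalcenter = "GC", germinalcentre = "GC",
           lymphnode = "LymphNode", ln = "LymphNode",
           rest = "Rest", other = "Rest")
  out <- map[key]
  if (is.na(out)) stop("unknown annotation category: '", name, "'")
  unname(out)
}

# Polygons of one category as a list of coordinate matrices.
category_polygons <- function(ann, category) {
  keep <- vapply(ann$polygons, function(p) p$category == category, TRUE)
  lapply(ann$polygons[keep], `[[`, "coords")
}

#' Read QuPath-style GeoJSON annotations
#'
#' Accepts a GeoJSON FeatureCollection whose features carry a
#' `classification` property with a `name` (the QuPath export dialect).
#' MultiPolygon features are split into their component polygons; only outer
#' rings are kept.
#'
#' @param path path to a GeoJSON file.
#' @param slide_id,width,height slide metadata not carried by GeoJSON;
#'   stored on the returned set.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, slide_id = NULL,
                             width = NA_integer_, height = NA_integer_) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed GeoJSON: ",
                                          conditionMessage(e)))
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  if (is.null(slide_id))
    slide_id <- if (!is.null(gj$slide_id)) gj$slide_id else "slide"
  if (!is.null(gj$width)) width <- gj$width
  if (!is.null(gj$height)) height <- gj$height
  polys <- list()
  feats <- gj$features
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    name <- f$properties$classification$name
    if (is.null(name))
      stop("feature ", i, ": missing classification name")
    category <- normalize_category(name)
    geom <- f$geometry
    if (is.null(geom$type))
      stop("feature ", i, ": missing geometry")
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1),
      stop("feature ", i, ": unsupported geometry type ", geom$type))
    for (ring in rings) {
      m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
      # drop GeoJSON closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
      polys[[length(polys) + 1]] <- list(coords = m, category = category)
    }
  }
  annotation_set(polys, slide_id = slide_id, width = width, height = height)
}

#' Write annotations as QuPath-compatible GeoJSON
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  feats <- lapply(ann$polygons, function(p) {
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    coords <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
    props <- list(objectType = "annotation",
                  classification = list(name = p$category))
    if (!is.null(p$confidence)) props$confidence <- p$confidence
    if (!is.null(p$provenance)) props$provenance <- p$provenance
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(coords)),
         properties = props)
  })
  out <- list(type = "FeatureCollection", slide_id = ann$slide_id,
              width = ann$width, height = ann$height, features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Rasterize annotations into a training label mask
#'
#' Pixel labels follow the precedence ignore (255, lymph node) > GC (2) >
#' TLS (1) > Rest (3) > unlabeled (0): GC pixels override the surrounding
#' TLS, and annotated lymph-node regions override everything so they are
#' excluded from any loss or metric.
#'
#' @param ann an [annotation_set()] (coordinates at 0.5 um/px).
#' @param window rectangle `c(x, y, width, height)` in 0.5 um/px pixels.
#' @param spacing target spacing in um/px (0.5 for full resolution).
#' @return a `LabelMask`: list with integer `mask` (height x width at the
#'   target spacing), `spacing` and `origin`.
#' @export
rasterize_annotations <- function(ann, window = NULL, spacing = 0.5) {
  if (is.null(window)) {
    if (is.na(ann$width) || is.na(ann$height))
      stop("annotation set has no slide dimensions; supply a window")
    window <- c(0, 0, ann$width, ann$height)
  }
  f <- 0.5 / spacing
  W <- as.integer(round(window[3] * f))
  H <- as.integer(round(window[4] * f))
  mask <- matrix(0L, H, W)
  # painting order encodes precedence (later wins)
  order <- c("Rest", "TLS", "GC", "LymphNode")
  xs <- list(); ys <- list(); vals <- integer(0)
  for (cat in order) {
    for (coords in category_polygons(ann, cat)) {
      if (polygon_area(coords) <= 0) {
        warning("skipping degenerate zero-area ", cat, " polygon")
        next
      }
      xs[[length(xs) + 1]] <- (coords[, 1] - window[1]) * f
      ys[[length(ys) + 1]] <- (coords[, 2] - window[2]) * f
      vals <- c(vals, LABEL_CODES[[cat]])
    }
  }
  if (length(vals))
    mask <- paint_polygons_cpp(mask, xs, ys, vals)
  structure(list(mask = mask, spacing = spacing,
                 origin = c(window[1], window[2])),
            class = "LabelMask")
}
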