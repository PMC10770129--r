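#' Quantized per-pixel confidence maps
#'
#' A `ConfidenceMap` holds per-category probability rasters on the
#' 0.5 um/px output grid, quantized from 0..1 to integers 0..255 by
#' `round(p * 255)`, plus the argmax category raster (ties broken by the
#' fixed category order TLS < GC < Rest; pixels where every category is 0,
#' e.g. outside tissue, get argmax 0).
#'
#' @param maps (H, W, 3) integer array of quantized scores, category order
#'   TLS, GC, Rest.
#' @param spacing um/px of the map grid.
#' @param slide_id source slide identifier.
#' @return an object of class `ConfidenceMap`.
#' @export
confidence_map <- function(maps, spacing = 0.5, slide_id = "slide") {
  if (length(dim(maps)) != 3 || dim(maps)[3] != length(SOFTMAX_CLASSES))
    stop("maps must be (H, W, ", length(SOFTMAX_CLASSES), ")")
  if (min(maps) < 0 || max(maps) > 255)
    stop("quantized values must lie in [0, 255]")
  storage.mode(maps) <- "integer"
  am <- apply(maps, c(1, 2), which.max)      # first max = fixed tie order
  am[apply(maps, c(1, 2), max) == 0L] <- 0L  # no evidence anywhere
  structure(list(maps = maps, argmax = am, spacing = spacing,
                 slide_id = slide_id),
            class = "ConfidenceMap")
}

#' @export
print.ConfidenceMap <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("ConfidenceMap '%s': %d x %d px at %.2f um/px, %d categories\n",
              x$slide_id, d[2], d[1], x$spacing, d[3]))
  invisible(x)
}

#' Tissue mask by intensity thresholding
#'
#' Tissue is defined as pixels whose grayscale intensity falls below a fixed
#' threshold applied at a coarse level (default 4 um/px), with the threshold
#' held common across a cohort. Tissue area is reported in cm^2.
#'
#' @param slide a [slide_pyramid()].
#' @param threshold grayscale intensity threshold in 0..255 (pixels strictly
#'   below it count as tissue).
#' @param spacing mask spacing in um/px.
#' @return a `TissueMask`: list with logical `mask`, `spacing`, `area_cm2`
#'   and the `threshold` used.
#' @export
compute_tissue_mask <- function(slide, threshold = 235, spacing = 4.0) {
  if (threshold < 0 || threshold > 255)
    stop("threshold must be in [0, 255]")
  li <- which.max(slide$spacings)
  img <- slide$levels[[li]]
  sp <- slide$spacings[li]
  f <- round(spacing / sp)
  if (f < 1 || abs(f * sp - spacing) / spacing > 0.15)
    stop("no pyramid level resolvable to ", spacing, " um/px")
  if (f > 1) {
    d <- dim(img)
    img <- img[seq_len(d[1] %/% f * f), seq_len(d[2] %/% f * f), ,
               drop = FALSE]
    img <- block_average(img, f)
  }
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  mask <- gray < threshold
  structure(list(mask = mask, spacing = spacing,
                 area_cm2 = sum(mask) * (spacing * 1e-4)^2,
                 threshold = threshold),
            class = "TissueMask")
}

#' Apply one cohort-wide tissue threshold to many slides
#'
#' The intensity threshold must be common for all slides of a cohort; this
#' wrapper enforces that at the API level.
#'
#' @param slides list of [slide_pyramid()] objects.
#' @inheritParams compute_tissue_mask
#' @return list of `TissueMask` objects.
#' @export
cohort_tissue_masks <- function(slides, threshold = 235, spacing = 4.0) {
  lapply(slides, compute_tissue_mask, threshold = threshold,
         spacing = spacing)
}

#' Lay out inference tiles over the tissue
#'
#' Tiles sit on a grid with stride equal to the model output size so output
#' windows abut exactly (assembly is a partition); tiles whose output window
#' misses the tissue mask are skipped. Border tiles rely on reflect padding
#' at patch extraction, so a slide smaller than one input tile is still
#' covered.
#'
#' @param slide a [slide_pyramid()].
#' @param tissue_mask a [compute_tissue_mask()] result.
#' @param output_size model output window side at 0.5 um/px.
#' @return data frame with output-window top-left corners `x`, `y`
#'   (0-based, 0.5 um/px).
#' @export
tile_slide <- function(slide, tissue_mask, output_size = 100) {
  li <- slide_level(slide, 0.5)
  H <- dim(slide$levels[[li]])[1]; W <- dim(slide$levels[[li]])[2]
  f <- tissue_mask$spacing / 0.5  # full-res px per mask px
  mh <- nrow(tissue_mask$mask); mw <- ncol(tissue_mask$mask)
  xs <- seq(0, W - 1, by = output_size)
  ys <- seq(0, H - 1, by = output_size)
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (y in ys) for (x in xs) {
    r0 <- max(1, floor(y / f) + 1); r1 <- min(mh, ceiling((y + output_size) / f))
    c0 <- max(1, floor(x / f) + 1); c1 <- min(mw, ceiling((x + output_size) / f))
    if (r0 <= r1 && c0 <= c1 &&
        any(tissue_mask$mask[r0:r1, c0:c1])) {
      keep_x <- c(keep_x, x); keep_y <- c(keep_y, y)
    }
  }
  data.frame(x = keep_x, y = keep_y)
}

#' Whole-slide inference: assemble a confidence map tile by tile
#'
#' Runs the model over the tile grid from [tile_slide()], writes each tile's
#' softmax output into the global output grid at its window position
#' (non-overlapping by construction; every covered pixel is written exactly
#' once), quantizes probabilities by `round(p * 255)`, and zeroes all
#' categories outside the tissue mask.
#'
#' @param model a trained [build_model()] object.
#' @param slide a [slide_pyramid()].
#' @param tissue_mask a [compute_tissue_mask()] result.
#' @param tiles optional precomputed tile table (e.g. shifted grids).
#' @return a [confidence_map()].
#' @export
predict_wsi <- function(model, slide, tissue_mask, tiles = NULL) {
  cfg <- model$config
  os <- cfg$geometry$output
  li <- slide_level(slide, 0.5)
  H <- dim(slide$levels[[li]])[1]; W <- dim(slide$levels[[li]])[2]
  if (is.null(tiles)) tiles <- tile_slide(slide, tissue_mask, os)
  maps <- array(0L, c(H, W, cfg$n_categories))
  written <- matrix(0L, H, W)
  for (i in seq_len(nrow(tiles))) {
    x <- tiles$x[i]; y <- tiles$y[i]
    if (x >= W || y >= H) next  # window fully outside the slide
    cx <- x + os / 2; cy <- y + os / 2
    pair <- list(
      target = extract_patch(slide, cx, cy, cfg$input_size,
                             cfg$target_spacing),
      context = extract_patch(slide, cx, cy, cfg$input_size,
                              cfg$context_spacing))
    probs <- predict_pair(model, pair)
    q <- array(as.integer(round(probs * 255)), dim(probs))
    rr <- (y + 1):min(y + os, H)
    cc <- (x + 1):min(x + os, W)
    maps[rr, cc, ] <- q[seq_along(rr), seq_along(cc), , drop = FALSE]
    written[rr, cc] <- written[rr, cc] + 1L
  }
  if (any(written > 1L))
    stop("internal error: tile outputs overlapped")
  # zero everything outside tissue
  f <- tissue_mask$spacing / 0.5
  rows <- pmin(nrow(tissue_mask$mask), floor((seq_len(H) - 1) / f) + 1)
  cols <- pmin(ncol(tissue_mask$mask), floor((seq_len(W) - 1) / f) + 1)
  tis <- tissue_mask$mask[rows, cols, drop = FALSE]
  for (k in seq_len(dim(maps)[3])) maps[, , k][!tis] <- 0L
  confidence_map(maps, spacing = 0.5, slide_id = slide$slide_id)
}
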