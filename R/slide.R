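#' Slide pyramids
#'
#' A `SlidePyramid` is a registered multi-resolution RGB raster: a list of
#' levels ordered by increasing spacing (um/px), each an (H, W, 3) numeric
#' array with values in 0..255, plus per-level spacing metadata. The default
#' pyramids used throughout the package carry levels at 0.5 um/px (target
#' detail) and 2.0 um/px (context), the 2.0 level being a 4x block-average
#' downsample of the 0.5 level.
#'
#' @param levels list of (H, W, 3) numeric arrays, values 0..255.
#' @param spacings numeric vector of um/px spacings, one per level,
#'   increasing.
#' @param slide_id character identifier.
#' @return an object of class `SlidePyramid`.
#' @export
slide_pyramid <- function(levels, spacings, slide_id = "slide") {
  if (length(levels) != length(spacings))
    stop("one spacing per level required")
  if (is.unsorted(spacings, strictly = TRUE))
    stop("levels must be ordered by increasing spacing")
  for (l in levels)
    if (length(dim(l)) != 3 || dim(l)[3] != 3)
      stop("each level must be an (H, W, 3) array")
  structure(list(levels = levels, spacings = as.numeric(spacings),
                 slide_id = slide_id),
            class = "SlidePyramid")
}

#' @export
print.SlidePyramid <- function(x, ...) {
  cat("SlidePyramid '", x$slide_id, "' with ", length(x$levels),
      " levels:\n", sep = "")
  for (i in seq_along(x$levels)) {
    d <- dim(x$levels[[i]])
    cat(sprintf("  level %d: %d x %d px at %.2f um/px\n",
                i, d[2], d[1], x$spacings[i]))
  }
  invisible(x)
}

# Level whose spacing matches the request within 15% relative tolerance;
# errors otherwise.
slide_level <- function(slide, spacing, tol = 0.15) {
  rel <- abs(slide$spacings - spacing) / spacing
  i <- which.min(rel)
  if (rel[i] > tol)
    stop(sprintf("no pyramid level within %.0f%% of %.2f um/px", 100 * tol,
                 spacing))
  i
}

# f x f block average of an (H, W, 3) array (H, W multiples of f).
block_average <- function(img, f) {
  d <- dim(img)
  if (d[1] %% f || d[2] %% f) stop("dimensions not divisible by factor")
  h <- d[1] %/% f; w <- d[2] %/% f
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    m <- img[, , ch]
    dim(m) <- c(f, h, f, w)
    out[, , ch] <- colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
  }
  out
}

#' Write / read a slide pyramid as multi-page TIFF plus JSON sidecar
#'
#' Levels are stored as pages of one 8-bit TIFF; spacings and the slide id go
#' to a `.json` sidecar next to it (fixture-friendly plain formats).
#'
#' @param slide a [slide_pyramid()].
#' @param path output TIFF path (sidecar gets the same path + ".json").
#' @export
write_slide <- function(slide, path) {
  imgs <- lapply(slide$levels, function(l) l / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8)
  jsonlite::write_json(list(slide_id = slide$slide_id,
                            spacings = slide$spacings),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  slide_pyramid(lapply(imgs, function(l) round(l * 255)),
                meta$spacings, meta$slide_id)
}

# Extract a patch (size x size x 3) centered at (cx, cy) [full-resolution
# 0.5 um/px coordinates] from the pyramid level at `spacing`, with reflect
# padding beyond the slide border.
extract_patch <- function(slide, cx, cy, size, spacing) {
  li <- slide_level(slide, spacing)
  img <- slide$levels[[li]]
  f <- 0.5 / spacing  # full-res px per level px is 1/f
  ccx <- cx * f; ccy <- cy * f  # center in level pixels
  half <- size / 2
  cols <- floor(ccx - half) + seq_len(size)  # 0-based col indices
  rows <- floor(ccy - half) + seq_len(size)
  H <- dim(img)[1]; W <- dim(img)[2]
  img[reflect_index(rows, H), reflect_index(cols, W), , drop = FALSE]
}

# Reflect 0-based indices into 1..n (R indices), mirror-style without
# repeating the edge sample period beyond necessity.
reflect_index <- function(idx, n) {
  if (n == 1) return(rep(1L, length(idx)))
  p <- 2L * n - 2L
  m <- ((idx) %% p + p) %% p
  m <- ifelse(m >= n, p - m, m)
  as.integer(m + 1L)
}
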