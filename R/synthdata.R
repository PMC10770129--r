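#' Configuration for the synthetic H&E-like slide generator
#'
#' The generator emulates the morphology the detector is built for: tertiary
#' lymphoid structures as dense aggregates of lymphocyte-like nuclei with an
#' irregular but distinguishable contour, optionally with a paler
#' germinal-center core of larger, sparser blasts; diffuse unorganized
#' infiltrates (labeled Rest); and lymph-node confounders (TLS-like texture
#' at much larger area with a capsule rim, labeled LymphNode so exclusion
#' logic is exercised). It makes no attempt at photorealistic staining.
#'
#' @param slide_width_px,slide_height_px slide dimensions in pixels at
#'   0.5 um/px; at least one inference tile (284 px) and a multiple of 4.
#' @param n_tls number of TLS structures.
#' @param gc_fraction fraction of TLSs given a germinal-center core, in 0..1.
#' @param n_inflammation_fields number of diffuse infiltrate regions (Rest).
#' @param n_lymphnode_confounders number of lymph-node confounders.
#' @param nucleus_radius_px nucleus disc radius in pixels.
#' @param tls_nucleus_fill target nucleus area fraction inside TLS (0, 1].
#' @param background_nucleus_fill nucleus area fraction outside structures;
#'   must be smaller than `tls_nucleus_fill`.
#' @param noise_sd additive per-pixel Gaussian noise scale (intensity units).
#' @param tls_radius_px range of TLS semi-axis lengths in pixels.
#' @param seed integer seed; all randomness flows through it.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(slide_width_px = 1024, slide_height_px = 1024,
                         n_tls = 6, gc_fraction = 0.5,
                         n_inflammation_fields = 2,
                         n_lymphnode_confounders = 1,
                         nucleus_radius_px = 3,
                         tls_nucleus_fill = 0.55,
                         background_nucleus_fill = 0.05,
                         noise_sd = 3, tls_radius_px = c(40, 70),
                         seed = 1L) {
  if (slide_width_px < 284 || slide_height_px < 284)
    stop("slide dimensions must cover at least one 284 px inference tile")
  if (slide_width_px %% 4 || slide_height_px %% 4)
    stop("slide dimensions must be multiples of 4 (pyramid factor)")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  if (n_tls < 0 || n_inflammation_fields < 0 || n_lymphnode_confounders < 0)
    stop("structure counts must be non-negative")
  if (tls_nucleus_fill <= 0 || tls_nucleus_fill > 1)
    stop("tls_nucleus_fill must be in (0, 1]")
  if (tls_nucleus_fill <= background_nucleus_fill)
    stop("tls_nucleus_fill must exceed background_nucleus_fill")
  if (nucleus_radius_px <= 0) stop("nucleus_radius_px must be positive")
  structure(as.list(environment()), class = "SynthConfig")
}

# Fixed H&E-like palette (no stain-deconvolution realism attempted)
SYNTH_PALETTE <- list(background = c(245, 242, 245),
                      stroma = c(230, 180, 200),
                      nucleus = c(80, 50, 120),
                      gc_base = c(240, 225, 235),
                      capsule = c(150, 110, 150))

#' Generate a seeded synthetic H&E-like slide with known ground truth
#'
#' Renders a two-level pyramid (0.5 and 2.0 um/px, the coarse level an exact
#' 4x block-average of the fine level) with white background, pink stroma
#' texture and dark-purple nucleus discs, plus exhaustive polygon
#' annotations. GC polygons are strictly inside their parent TLS;
#' lymph-node confounders have roughly 10x the median TLS area and a darker
#' capsule rim. Deterministic for a fixed `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `slide` ([slide_pyramid()]), `annotations`
#'   ([annotation_set()]), and `nuclei` (data frame of rendered disc centers
#'   with a `where` column; the ground truth used by density oracles).
#' @export
generate_synthetic_slide <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  with_seed(config$seed, generate_synthetic_slide_impl(config))
}

generate_synthetic_slide_impl <- function(cfg) {
  H <- cfg$slide_height_px; W <- cfg$slide_width_px
  pal <- SYNTH_PALETTE

  # base: background mixed with smooth pink stroma blotches
  img <- array(0, c(H, W, 3))
  g <- smooth_noise_field(H, W, cells = 24)
  wgt <- pmin(1, pmax(0, (g - 0.35) / 0.4))
  for (ch in 1:3)
    img[, , ch] <- (1 - 0.6 * wgt) * pal$background[ch] +
      0.6 * wgt * pal$stroma[ch]

  # ---- structure placement (non-overlapping, rejection sampling) ----
  placed <- list()   # list of list(coords, category, rx)
  place <- function(rx, ry, category, margin = 5) {
    for (attempt in 1:200) {
      cx <- runif(1, rx * 1.25 + margin, W - rx * 1.25 - margin)
      cy <- runif(1, ry * 1.25 + margin, H - ry * 1.25 - margin)
      ok <- TRUE
      for (p in placed) {
        ctr <- polygon_centroid(p$coords)
        if (sqrt((ctr[1] - cx)^2 + (ctr[2] - cy)^2) <
            1.3 * (max(rx, ry) + p$r)) { ok <- FALSE; break }
      }
      if (ok) {
        poly <- perturbed_ellipse(cx, cy, rx, ry)
        placed[[length(placed) + 1]] <<-
          list(coords = poly, category = category, r = max(rx, ry))
        return(poly)
      }
    }
    NULL  # no room; structure dropped
  }

  tls_polys <- list()
  tls_r <- runif(cfg$n_tls, cfg$tls_radius_px[1], cfg$tls_radius_px[2])
  for (i in seq_len(cfg$n_tls)) {
    p <- place(tls_r[i], tls_r[i] * runif(1, 0.8, 1.0), "TLS")
    if (!is.null(p)) tls_polys[[length(tls_polys) + 1]] <- p
  }
  # lymph-node confounders: >= 10x median TLS area
  ln_polys <- list()
  med_r <- if (length(tls_polys)) median(tls_r) else
    mean(cfg$tls_radius_px)
  for (i in seq_len(cfg$n_lymphnode_confounders)) {
    r <- med_r * sqrt(10) * runif(1, 1.0, 1.15)
    r <- min(r, (min(H, W) - 20) / 3)  # must fit the canvas
    p <- place(r, r * 0.9, "LymphNode")
    if (!is.null(p)) ln_polys[[length(ln_polys) + 1]] <- p
  }
  infl_polys <- list()
  for (i in seq_len(cfg$n_inflammation_fields)) {
    r <- runif(1, 50, 90)
    p <- place(r, r * runif(1, 0.7, 1.0), "Rest")
    if (!is.null(p)) infl_polys[[length(infl_polys) + 1]] <- p
  }
  # GC cores: centered pale disc, area 10-35% of the parent TLS
  has_gc <- rep(FALSE, length(tls_polys))
  if (length(tls_polys))
    has_gc[seq_len(round(cfg$gc_fraction * length(tls_polys)))] <- TRUE
  gc_polys <- vector("list", length(tls_polys))
  for (i in seq_along(tls_polys)) {
    if (!has_gc[i]) next
    f <- sqrt(runif(1, 0.10, 0.35))  # linear scale for target area fraction
    gc_polys[[i]] <- scale_polygon(tls_polys[[i]], f * 0.95)
  }

  # ---- rendering ----
  nuclei <- list()
  n_for <- function(area, fill)
    max(0L, round(fill * area / (pi * cfg$nucleus_radius_px^2)))
  sample_in_pixels <- function(pix, n) {
    if (n == 0 || length(pix) == 0)
      return(cbind(x = numeric(0), y = numeric(0)))
    k <- sample.int(length(pix), n, replace = TRUE)
    r <- (pix[k] - 1) %% H
    c <- (pix[k] - 1) %/% H
    cbind(x = c + runif(n), y = r + runif(n))
  }
  stamp <- function(centers, radius, color) {
    if (nrow(centers) == 0) return()
    img <<- stamp_discs_cpp(img, H, W, centers[, 1], centers[, 2],
                            radius, color)
    dim(img) <<- c(H, W, 3)
  }

  struct_pix <- rep(FALSE, H * W)  # any structure footprint (for background)
  all_structs <- c(tls_polys, ln_polys, infl_polys)
  for (p in all_structs) struct_pix[polygon_pixels(p, H, W)] <- TRUE

  # diffuse infiltrates: intermediate nucleus density, no sharp texture edge
  for (p in infl_polys) {
    pix <- polygon_pixels(p, H, W)
    ctr <- sample_in_pixels(pix, n_for(length(pix), 0.25))
    stamp(ctr, cfg$nucleus_radius_px, pal$nucleus)
    if (nrow(ctr))
      nuclei[[length(nuclei) + 1]] <- data.frame(x = ctr[, 1], y = ctr[, 2],
                                                 where = "Rest")
  }
  # lymph nodes: capsule rim + TLS-like dense texture
  for (p in ln_polys) {
    outer <- polygon_pixels(p, H, W)
    inner <- polygon_pixels(scale_polygon(p, 0.96), H, W)
    rim <- setdiff(outer, inner)
    rc <- cbind(((rim - 1) %/% H) + 0.5, ((rim - 1) %% H) + 0.5)
    stamp(rc, 2.5, pal$capsule)
    ctr <- sample_in_pixels(inner, n_for(length(inner),
                                         cfg$tls_nucleus_fill))
    stamp(ctr, cfg$nucleus_radius_px, pal$nucleus)
    if (nrow(ctr))
      nuclei[[length(nuclei) + 1]] <- data.frame(x = ctr[, 1], y = ctr[, 2],
                                                 where = "LymphNode")
  }
  # TLS bodies (nuclei kept out of the GC core), then GC cores
  for (i in seq_along(tls_polys)) {
    pix <- polygon_pixels(tls_polys[[i]], H, W)
    gc_member <- rep(FALSE, H * W)
    if (!is.null(gc_polys[[i]])) {
      gpix <- polygon_pixels(gc_polys[[i]], H, W)
      gc_member[gpix] <- TRUE
      # pale GC base before nuclei
      for (ch in 1:3) {
        m <- img[, , ch]
        m[gpix] <- pal$gc_base[ch]
        img[, , ch] <- m
      }
    }
    body <- pix[!gc_member[pix]]
    ctr <- sample_in_pixels(body, n_for(length(body), cfg$tls_nucleus_fill))
    stamp(ctr, cfg$nucleus_radius_px, pal$nucleus)
    if (nrow(ctr))
      nuclei[[length(nuclei) + 1]] <- data.frame(x = ctr[, 1], y = ctr[, 2],
                                                 where = "TLS")
    if (!is.null(gc_polys[[i]])) {
      gpix <- which(gc_member)
      ctr <- sample_in_pixels(gpix, n_for(length(gpix),
                                          cfg$tls_nucleus_fill / 2))
      stamp(ctr, cfg$nucleus_radius_px * 1.6, pal$nucleus)
      if (nrow(ctr))
        nuclei[[length(nuclei) + 1]] <- data.frame(x = ctr[, 1],
                                                   y = ctr[, 2],
                                                   where = "GC")
    }
  }
  # sparse background nuclei outside all structures
  bg_pix <- which(!struct_pix)
  ctr <- sample_in_pixels(bg_pix, n_for(length(bg_pix),
                                        cfg$background_nucleus_fill))
  stamp(ctr, cfg$nucleus_radius_px, pal$nucleus)
  if (nrow(ctr))
    nuclei[[length(nuclei) + 1]] <- data.frame(x = ctr[, 1], y = ctr[, 2],
                                               where = "background")

  if (cfg$noise_sd > 0)
    img <- img + rnorm(length(img), sd = cfg$noise_sd)
  img <- round(pmin(255, pmax(0, img)))
  dim(img) <- c(H, W, 3)

  slide <- slide_pyramid(list(img, block_average(img, 4)), c(0.5, 2.0),
                         slide_id = sprintf("synth-%d", cfg$seed))
  polys <- c(
    lapply(tls_polys, function(p) list(coords = pmax(p, 0),
                                       category = "TLS")),
    lapply(Filter(Negate(is.null), gc_polys),
           function(p) list(coords = pmax(p, 0), category = "GC")),
    lapply(ln_polys, function(p) list(coords = pmax(p, 0),
                                      category = "LymphNode")),
    lapply(infl_polys, function(p) list(coords = pmax(p, 0),
                                        category = "Rest")))
  ann <- annotation_set(polys, slide_id = slide$slide_id,
                        width = W, height = H)
  nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
    data.frame(x = numeric(0), y = numeric(0), where = character(0))
  list(slide = slide, annotations = ann, nuclei = nuclei)
}

# Smooth noise in [0,1]: coarse uniform grid, bilinear upsampling.
smooth_noise_field <- function(H, W, cells = 24) {
  gh <- cells + 2; gw <- cells + 2
  g <- matrix(runif(gh * gw), gh, gw)
  ry <- seq(1, gh - 1, length.out = H)
  rx <- seq(1, gw - 1, length.out = W)
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0; fx <- rx - x0
  a <- g[cbind(rep(y0, W), rep(x0, each = H))]
  b <- g[cbind(rep(y0 + 1, W), rep(x0, each = H))]
  cc <- g[cbind(rep(y0, W), rep(x0 + 1, each = H))]
  d <- g[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
  fyv <- rep(fy, W); fxv <- rep(fx, each = H)
  m <- (1 - fyv) * (1 - fxv) * a + fyv * (1 - fxv) * b +
    (1 - fyv) * fxv * cc + fyv * fxv * d
  matrix(m, H, W)
}

#' Synthetic confidence-map fixture from known objects
#'
#' Builds a quantized per-category confidence map in which pixels inside each
#' object's polygon sit near `inside_prob` and all other pixels near
#' `outside_prob`, plus seeded Gaussian noise clipped to 0..255. Used to
#' exercise object extraction, threshold search and evaluation without a
#' trained model.
#'
#' @param objects an [annotation_set()] with slide dimensions.
#' @param inside_prob,outside_prob quantized probabilities (0..255);
#'   `inside_prob` must exceed `outside_prob`.
#' @param noise_sd Gaussian noise scale in quantized units.
#' @param seed integer seed.
#' @return a `ConfidenceMap` (see [confidence_map()]).
#' @export
generate_confidence_fixture <- function(objects, inside_prob = 220,
                                        outside_prob = 5, noise_sd = 0,
                                        seed = 1L) {
  if (inside_prob <= outside_prob)
    stop("inside_prob must exceed outside_prob")
  if (is.na(objects$width) || is.na(objects$height))
    stop("annotation set must carry slide dimensions")
  H <- objects$height; W <- objects$width
  with_seed(seed, {
    maps <- array(0L, c(H, W, length(SOFTMAX_CLASSES)))
    for (k in seq_along(SOFTMAX_CLASSES)) {
      m <- matrix(as.numeric(outside_prob), H, W)
      for (coords in category_polygons(objects, SOFTMAX_CLASSES[k]))
        m[polygon_pixels(coords, H, W)] <- inside_prob
      if (noise_sd > 0) m <- m + rnorm(length(m), sd = noise_sd)
      maps[, , k] <- as.integer(pmin(255, pmax(0, round(m))))
    }
    confidence_map(maps, spacing = 0.5, slide_id = objects$slide_id)
  })
}
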