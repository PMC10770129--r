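# Shared fixtures and independent oracles, built in code at test time.

# cache across test files within one run
.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small synthetic slide shared by several suites
small_synth <- function(seed = 42) fixture(paste0("synth", seed), function()
  generate_synthetic_slide(synth_config(
    slide_width_px = 512, slide_height_px = 512, n_tls = 4,
    n_lymphnode_confounders = 0, n_inflammation_fields = 1, seed = seed)))

# reduced-width model configuration used wherever a real forward pass is
# needed but full capacity is not
tiny_model_config <- function(input_size = 284, seed = 1L)
  model_config(target_filters = c(2, 4, 8, 16), target_bottleneck = 32,
               context_filters = c(3, 6, 12, 24), context_bottleneck = 48,
               input_size = input_size, seed = seed)

rect_poly <- function(x0, y0, w, h)
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))

# independent point-in-polygon rasterization oracle: pixel centers tested
# with mgcv::in.out (even-odd rule), no package code involved
oracle_polygon_pixels <- function(poly, H, W) {
  centers <- cbind(rep(seq_len(W) - 0.5, each = H),
                   rep(seq_len(H) - 0.5, W))
  bnd <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(bnd, centers)
  which(inside)
}

# independent 8-connected labeling using igraph components
oracle_label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0) return(lab)
  pos <- match(seq_len(H * W), idx)  # pixel -> vertex id
  edges <- list()
  for (p in idx) {
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      q <- r2 + (c2 - 1) * H
      if (mask[q] && q > p)
        edges[[length(edges) + 1]] <- c(pos[p], pos[q])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# independent object-level matcher: pixel sets from the mgcv oracle (for
# polygons) or given directly, 50%-of-GT rule written out naively
oracle_match <- function(gt_pix, pred_pix, min_coverage = 0.5) {
  tp <- 0L
  pred_used <- rep(FALSE, length(pred_pix))
  for (g in gt_pix) {
    cov <- vapply(pred_pix, function(p) length(intersect(g, p)) / length(g),
                  0)
    if (length(cov) && any(cov >= min_coverage)) {
      tp <- tp + 1L
      pred_used[cov >= min_coverage] <- TRUE
    }
  }
  list(tp = tp, fp = sum(!pred_used), fn = length(gt_pix) - tp)
}

# independent exhaustive (t, s) search over the full 256 x 256 grid: for
# every t, label with the igraph oracle (components do not depend on s);
# for every s, filter candidates by area and rerun the naive matcher
oracle_threshold_search <- function(score_list, gt_pix_list,
                                    min_coverage = 0.5) {
  n_gt <- sum(lengths(gt_pix_list))
  best <- list(f1 = -1, t = 0L, s = 0L)
  for (t in 0:255) {
    per_slide <- lapply(seq_along(score_list), function(i) {
      lab <- oracle_label_components(score_list[[i]] >= t)
      sizes <- tabulate(lab)
      list(pred_pix = lapply(seq_along(sizes), function(id)
             which(lab == id)),
           sizes = sizes)
    })
    for (s in 0:255) {
      tp <- 0L; fp <- 0L
      for (i in seq_along(per_slide)) {
        ps <- per_slide[[i]]
        keep <- ps$sizes >= max(s^2, 1)
        m <- oracle_match(gt_pix_list[[i]], ps$pred_pix[keep], min_coverage)
        tp <- tp + m$tp; fp <- fp + m$fp
      }
      fn <- n_gt - tp
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1v <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      if (f1v >= best$f1)
        best <- list(f1 = f1v, t = t, s = s)
    }
  }
  best
}
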