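#' Configuration of the dual-branch multi-resolution U-Net
#'
#' The model couples two encoder-decoder U-Net branches working on
#' concentric patches: a target branch at 0.5 um/px (high-resolution detail)
#' and a context branch at 2.0 um/px (4x larger field of view). Decoder
#' features of the context branch are center-cropped and concatenated
#' ("hooked") into the target branch at its lowest level, where their
#' effective pixel stride matches, so the target decoder sees both scales.
#' All convolutions are unpadded ("valid") 3x3, two per level, with 2x2 max
#' pooling and 2x2 stride-2 transposed-convolution upsampling; batch
#' normalization and ReLU follow every convolution. Only the target branch
#' carries a segmentation head (softmax over TLS, GC, Rest); the context
#' branch receives no supervised loss and its decoder is built only down to
#' the hook level.
#'
#' With the default schedules the target-branch bottleneck for a 284 px
#' input is a 10 x 10 map with 224 channels, hooked context features add 216
#' channels (440 total), the output window is 100 x 100 px, and the
#' trainable parameter count is approximately 25 million.
#'
#' @param depth number of encoder levels (pooling stages).
#' @param target_filters,context_filters channel counts per encoder level.
#' @param target_bottleneck,context_bottleneck bottleneck channel counts.
#' @param n_categories softmax categories (TLS, GC, Rest).
#' @param input_size patch side in pixels (both branches).
#' @param target_spacing,context_spacing patch spacings in um/px.
#' @param l2_coefficient L2 weight-regularization coefficient.
#' @param seed integer seed for He-normal weight initialization.
#' @return a `ModelConfig` list.
#' @export
model_config <- function(depth = 4,
                         target_filters = c(14, 28, 56, 112),
                         target_bottleneck = 224,
                         context_filters = c(54, 108, 216, 432),
                         context_bottleneck = 960,
                         n_categories = 3,
                         input_size = 284,
                         target_spacing = 0.5,
                         context_spacing = 2.0,
                         l2_coefficient = 1e-5,
                         seed = 1L) {
  if (length(target_filters) != depth || length(context_filters) != depth)
    stop("filter schedules must have one entry per encoder level")
  geom <- tryCatch(unet_geometry(input_size, depth),
                   error = function(e) NULL)
  if (is.null(geom)) {
    feas <- feasible_input_sizes(depth, near = input_size)
    stop("input_size ", input_size, " is incompatible with depth-", depth,
         " valid-convolution arithmetic; nearby feasible sizes: ",
         paste(feas, collapse = ", "))
  }
  cfg <- structure(as.list(environment())[
    c("depth", "target_filters", "target_bottleneck", "context_filters",
      "context_bottleneck", "n_categories", "input_size", "target_spacing",
      "context_spacing", "l2_coefficient", "seed")],
    class = "ModelConfig")
  cfg$hook_ups <- min(2L, depth)  # context decoder stages before the hook
  cfg$geometry <- geom
  cfg
}

# Valid-convolution size arithmetic for one branch. Two 3x3 valid convs
# shrink a map by 4; pooling halves it (must stay even); the decoder doubles
# then shrinks by 4. Errors if any stage becomes degenerate or any skip
# crop offset non-integral.
unet_geometry <- function(input_size, depth) {
  s <- input_size
  skips <- integer(depth)
  for (i in seq_len(depth)) {
    s <- s - 4
    if (s < 2 || s %% 2) stop("invalid size at encoder level ", i)
    skips[i] <- s
    s <- s %/% 2
  }
  s <- s - 4
  if (s < 1) stop("degenerate bottleneck")
  bottleneck <- s
  dec <- integer(depth)
  for (i in rev(seq_len(depth))) {
    s <- 2 * s
    if ((skips[i] - s) %% 2 || skips[i] < s)
      stop("skip crop at level ", i, " not centered")
    s <- s - 4
    if (s < 1) stop("degenerate decoder level ", i)
    dec[i] <- s
  }
  list(input = input_size, skips = skips, bottleneck = bottleneck,
       decoder = dec, output = s)
}

feasible_input_sizes <- function(depth, near, span = 40) {
  cand <- max(16, near - span):(near + span)
  cand[vapply(cand, function(n)
    !is.null(tryCatch(unet_geometry(n, depth), error = function(e) NULL)),
    TRUE)]
}

# ---------------------------------------------------------------------------
# model construction

he_conv <- function(k, cin, cout) {
  w <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

#' Build the dual-branch model
#'
#' Weights are He-normal initialized from `config$seed`; two builds with the
#' same config produce identical initial weights.
#'
#' @param config a [model_config()].
#' @return an object of class `tls_model` holding the trainable parameters
#'   (`params`), batch-norm running statistics (`bn_stats`) and the config.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "ModelConfig"))
  with_seed(config$seed, {
    params <- list()
    bn_stats <- list()
    add_conv <- function(name, k, cin, cout) {
      params[[paste0(name, "_w")]] <<- he_conv(k, cin, cout)$w
      params[[paste0(name, "_b")]] <<- numeric(cout)
    }
    add_bn <- function(name, c) {
      params[[paste0(name, "_gamma")]] <<- rep(1, c)
      params[[paste0(name, "_beta")]] <<- numeric(c)
      bn_stats[[name]] <<- list(mean = numeric(c), var = rep(1, c))
    }
    add_block <- function(name, cin, cout) {  # conv-bn twice
      add_conv(paste0(name, "_c1"), 3, cin, cout)
      add_bn(paste0(name, "_b1"), cout)
      add_conv(paste0(name, "_c2"), 3, cout, cout)
      add_bn(paste0(name, "_b2"), cout)
    }
    branch <- function(p, filters, bottleneck, n_dec, dec_extra_in = 0) {
      cin <- 3
      for (i in seq_along(filters)) {
        add_block(sprintf("%s_e%d", p, i), cin, filters[i])
        cin <- filters[i]
      }
      add_block(paste0(p, "_bt"), cin, bottleneck)
      cin <- bottleneck + dec_extra_in
      d <- length(filters)
      for (i in rev(seq_len(d))) {
        if (d - i + 1 > n_dec) break
        params[[sprintf("%s_d%d_up_w", p, i)]] <<-
          array(rnorm(4 * cin * filters[i], sd = sqrt(2 / (4 * cin))),
                c(2, 2, cin, filters[i]))
        params[[sprintf("%s_d%d_up_b", p, i)]] <<- numeric(filters[i])
        add_block(sprintf("%s_d%d", p, i), 2 * filters[i], filters[i])
        cin <- filters[i]
      }
    }
    # context branch: decoder truncated at the hook level
    branch("c", config$context_filters, config$context_bottleneck,
           n_dec = config$hook_ups)
    hook_channels <- if (config$hook_ups == 0) config$context_bottleneck
      else config$context_filters[config$depth - config$hook_ups + 1]
    # target branch: full decoder; first up-convolution sees the hooked
    # (concatenated) bottleneck
    branch("t", config$target_filters, config$target_bottleneck,
           n_dec = config$depth, dec_extra_in = hook_channels)
    add_conv("t_head", 1, config$target_filters[1], config$n_categories)
    structure(list(config = config, params = params, bn_stats = bn_stats,
                   hook_channels = hook_channels),
              class = "tls_model")
  })
}

#' @export
print.tls_model <- function(x, ...) {
  g <- x$config$geometry
  cat("Dual-branch multi-resolution U-Net\n")
  cat(sprintf("  input %d px -> output %d px; bottleneck %dx%dx%d (%d target + %d hooked context)\n",
              g$input, g$output, g$bottleneck, g$bottleneck,
              x$config$target_bottleneck + x$hook_channels,
              x$config$target_bottleneck, x$hook_channels))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts every trainable scalar: convolution and up-convolution weights and
#' biases plus batch-normalization scale/shift. Running statistics are not
#' trainable and are not counted.
#'
#' @param model a built [build_model()] object.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# ---------------------------------------------------------------------------
# layer helpers (batch arrays (H, W, C, N))

bn_fwd <- function(x, gamma, beta, stats, train, momentum = 0.1,
                   eps = 1e-5) {
  if (train) {
    st <- bn_stats_cpp(x)
    new_stats <- list(mean = (1 - momentum) * stats$mean + momentum * st$mean,
                      var = (1 - momentum) * stats$var + momentum * st$var)
  } else {
    st <- stats
    new_stats <- stats
  }
  ap <- bn_apply_cpp(x, gamma, beta, st$mean, st$var, eps)
  list(y = ap$y, cache = list(xn = ap$xn, sd = sqrt(st$var + eps),
                              gamma = gamma),
       stats = new_stats)
}

bn_bwd <- function(dy, cache) {
  bn_bwd_cpp(dy, cache$xn, cache$gamma, cache$sd)
}

crop_center <- function(x, size) {
  d <- dim(x)
  off <- (d[1] - size) %/% 2
  x[(off + 1):(off + size), (off + 1):(off + size), , , drop = FALSE]
}

pad_center_grad <- function(dy, full_size) {
  d <- dim(dy)
  off <- (full_size - d[1]) %/% 2
  out <- array(0, c(full_size, full_size, d[3], d[4]))
  out[(off + 1):(off + d[1]), (off + 1):(off + d[1]), , ] <- dy
  out
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

softmax4 <- function(logits) {
  d <- dim(logits)
  mx <- as.vector(apply(logits, c(1, 2, 4), max))
  e <- array(0, d)
  for (k in seq_len(d[3]))
    e[, , k, ] <- exp(as.vector(logits[, , k, ]) - mx)
  s <- as.vector(apply(e, c(1, 2, 4), sum))
  for (k in seq_len(d[3]))
    e[, , k, ] <- as.vector(e[, , k, ]) / s
  e
}

# ---------------------------------------------------------------------------
# forward pass

# One conv-bn-relu step with cache
step_cbr <- function(model, name, bn_name, x, train, cache, stats_env) {
  w <- model$params[[paste0(name, "_w")]]
  b <- model$params[[paste0(name, "_b")]]
  y0 <- conv2d_fwd_cpp(x, w, b)
  bn <- bn_fwd(y0, model$params[[paste0(bn_name, "_gamma")]],
               model$params[[paste0(bn_name, "_beta")]],
               model$bn_stats[[bn_name]], train)
  if (train) stats_env$stats[[bn_name]] <- bn$stats
  y <- pmax(bn$y, 0)
  if (!is.null(cache)) {
    cache[[paste0(name, "_x")]] <- x
    cache[[paste0(bn_name, "_cache")]] <- bn$cache
    cache[[paste0(name, "_preact")]] <- bn$y
  }
  list(y = y, cache = cache)
}

branch_encode <- function(model, prefix, x, filters, bottleneck, train,
                          cache, stats_env) {
  skips <- list()
  for (i in seq_along(filters)) {
    for (cj in 1:2) {
      st <- step_cbr(model, sprintf("%s_e%d_c%d", prefix, i, cj),
                     sprintf("%s_e%d_b%d", prefix, i, cj), x, train, cache,
                     stats_env)
      x <- st$y; cache <- st$cache
    }
    skips[[i]] <- x
    mp <- maxpool2_fwd_cpp(x)
    if (!is.null(cache)) {
      cache[[sprintf("%s_p%d_idx", prefix, i)]] <- mp$idx
      cache[[sprintf("%s_p%d_in", prefix, i)]] <- dim(x)[1]
    }
    x <- mp$y
  }
  for (cj in 1:2) {
    st <- step_cbr(model, sprintf("%s_bt_c%d", prefix, cj),
                   sprintf("%s_bt_b%d", prefix, cj), x, train, cache,
                   stats_env)
    x <- st$y; cache <- st$cache
  }
  list(bottleneck = x, skips = skips, cache = cache)
}

branch_decode <- function(model, prefix, x, skips, n_dec, train, cache,
                          stats_env) {
  d <- length(skips)
  for (i in rev(seq_len(d))) {
    if (d - i + 1 > n_dec) break
    wup <- model$params[[sprintf("%s_d%d_up_w", prefix, i)]]
    bup <- model$params[[sprintf("%s_d%d_up_b", prefix, i)]]
    if (!is.null(cache)) cache[[sprintf("%s_d%d_up_x", prefix, i)]] <- x
    up <- upconv2_fwd_cpp(x, wup, bup)
    sk <- crop_center(skips[[i]], dim(up)[1])
    x <- concat_channels(up, sk)
    if (!is.null(cache)) {
      cache[[sprintf("%s_d%d_upch", prefix, i)]] <- dim(up)[3]
      cache[[sprintf("%s_d%d_skipdim", prefix, i)]] <- dim(skips[[i]])[1]
    }
    for (cj in 1:2) {
      st <- step_cbr(model, sprintf("%s_d%d_c%d", prefix, i, cj),
                     sprintf("%s_d%d_b%d", prefix, i, cj), x, train, cache,
                     stats_env)
      x <- st$y; cache <- st$cache
    }
  }
  list(y = x, cache = cache)
}

# Full forward pass. target/context: (H, W, 3, N) arrays with values scaled
# to [0, 1]. Returns per-pixel class probabilities and the hooked bottleneck.
model_forward <- function(model, target, context, train = FALSE,
                          keep_cache = FALSE) {
  cfg <- model$config
  cache <- if (keep_cache) list() else NULL
  stats_env <- new.env()
  stats_env$stats <- model$bn_stats
  ce <- branch_encode(model, "c", context, cfg$context_filters,
                      cfg$context_bottleneck, train, cache, stats_env)
  cache <- ce$cache
  cd <- branch_decode(model, "c", ce$bottleneck, ce$skips, cfg$hook_ups,
                      train, cache, stats_env)
  cache <- cd$cache
  te <- branch_encode(model, "t", target, cfg$target_filters,
                      cfg$target_bottleneck, train, cache, stats_env)
  cache <- te$cache
  ts <- dim(te$bottleneck)[1]
  hook <- crop_center(cd$y, ts)
  hooked <- concat_channels(te$bottleneck, hook)
  if (keep_cache) {
    cache$t_bt_ch <- dim(te$bottleneck)[3]
    cache$hook_fulldim <- dim(cd$y)[1]
  }
  td <- branch_decode(model, "t", hooked, te$skips, cfg$depth, train, cache,
                      stats_env)
  cache <- td$cache
  if (keep_cache) cache$head_x <- td$y
  logits <- conv2d_fwd_cpp(td$y, model$params$t_head_w, model$params$t_head_b)
  probs <- softmax4(logits)
  list(probs = probs, logits = logits, bottleneck = hooked,
       cache = cache, bn_stats = stats_env$stats,
       ctx = if (keep_cache) list(skips_dims = lapply(ce$skips, dim)) else NULL)
}

#' Forward pass on one concentric patch pair
#'
#' @param model a built model.
#' @param pair list with `target` and `context`, each an (H, W, 3) array of
#'   raw intensities 0..255 (scaled internally to 0..1).
#' @return (output, output, n_categories) array of per-pixel class
#'   probabilities (softmax over TLS, GC, Rest), centered within the target
#'   patch.
#' @export
predict_pair <- function(model, pair) {
  tg <- pair$target / 255; cx <- pair$context / 255
  sz <- model$config$input_size
  if (!all(dim(tg)[1:2] == sz) || !all(dim(cx)[1:2] == sz))
    stop("patch shape does not match model input size ", sz)
  dim(tg) <- c(dim(tg), 1)
  dim(cx) <- c(dim(cx), 1)
  out <- model_forward(model, tg, cx, train = FALSE)
  array(out$probs[, , , 1], dim(out$probs)[1:3])
}

#' Extract the hooked bottleneck feature vector for a patch pair
#'
#' Per-channel maximum over the spatial grid of the target-branch bottleneck
#' after context hooking (a 10 x 10 x 440 map for the default full
#' configuration, giving 440 features).
#'
#' @inheritParams predict_pair
#' @return numeric vector, one value per bottleneck channel.
#' @export
extract_bottleneck_features <- function(model, pair) {
  tg <- pair$target / 255; cx <- pair$context / 255
  dim(tg) <- c(dim(tg), 1)
  dim(cx) <- c(dim(cx), 1)
  out <- model_forward(model, tg, cx, train = FALSE)
  bt <- out$bottleneck[, , , 1, drop = FALSE]
  nch <- dim(bt)[3]
  if (nch != 440)
    message("bottleneck has ", nch, " channels (non-default schedule)")
  apply(bt, 3, max)
}

#' Change the patch size of a built model
#'
#' The network is fully convolutional, so trained weights apply to any
#' input size compatible with the valid-convolution arithmetic; training on
#' smaller patches and running whole-slide inference at the standard
#' 284 px geometry is a supported workflow.
#'
#' @param model a built model.
#' @param input_size new patch side in pixels.
#' @return the model with updated geometry.
#' @export
resize_model_input <- function(model, input_size) {
  cfg <- model$config
  cfg$input_size <- input_size
  cfg$geometry <- unet_geometry(input_size, cfg$depth)
  model$config <- cfg
  model
}

#' Save / load a model checkpoint
#'
#' A single RDS file holding the parameters, batch-norm statistics and the
#' full config.
#' @param model a built model.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "tls_model")
}
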