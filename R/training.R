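#' Pixel-count-based sampling weights
#'
#' Patch sampling follows a pixel-count-based strategy so the model gets
#' sufficient exposure to each class: the probability of drawing a category
#' is proportional to the inverse of its annotated pixel count across the
#' training set, normalized over the categories that have any annotated
#' pixels (zero-count categories get weight 0). Lymph-node pixels carry the
#' ignore label and are never sampled.
#'
#' @param annotations list of [annotation_set()]s (one per training slide),
#'   each with slide dimensions.
#' @return a `SamplerState`: per-category pixel counts and weights, plus the
#'   cached full-slide label masks.
#' @export
compute_sampling_weights <- function(annotations) {
  masks <- lapply(annotations, function(a) rasterize_annotations(a)$mask)
  cats <- SOFTMAX_CLASSES
  counts <- setNames(numeric(length(cats)), cats)
  per_slide <- matrix(0, length(annotations), length(cats),
                      dimnames = list(NULL, cats))
  for (i in seq_along(masks)) {
    tab <- tabulate(masks[[i]], nbins = 3)
    per_slide[i, ] <- tab
    counts <- counts + tab
  }
  if (all(counts == 0))
    stop("no annotated pixels in any loss-eligible category")
  w <- ifelse(counts > 0, 1 / counts, 0)
  structure(list(counts = counts, weights = w / sum(w),
                 per_slide = per_slide, masks = masks),
            class = "SamplerState")
}

#' Draw a class-balanced batch of concentric patch pairs
#'
#' Each batch element is drawn by (i) picking a category by the sampler
#' weights, (ii) picking a random annotated pixel of that category across
#' the training set, and (iii) extracting the concentric target/context
#' patch pair centered there together with the label mask cropped to the
#' model's output window. Deterministic given the seed.
#'
#' @param slides list of [slide_pyramid()]s matching `annotations`.
#' @param annotations list of [annotation_set()]s.
#' @param sampler a [compute_sampling_weights()] state.
#' @param batch_size number of pairs.
#' @param config a [model_config()] fixing the patch geometry.
#' @param seed integer seed.
#' @return list of samples, each with `target`, `context` (raw 0..255
#'   arrays), `labels` (output-window mask) and `category`.
#' @export
sample_training_batch <- function(slides, annotations, sampler, batch_size,
                                  config, seed) {
  with_seed(seed,
            replicate(batch_size,
                      sample_one(slides, sampler, config),
                      simplify = FALSE))
}

# category index drawn by the sampler weights (consumes the RNG stream)
draw_category <- function(sampler)
  sample.int(length(SOFTMAX_CLASSES), 1, prob = sampler$weights)

sample_one <- function(slides, sampler, config) {
  cats <- SOFTMAX_CLASSES
  k <- draw_category(sampler)
  slide_w <- sampler$per_slide[, k]
  si <- sample.int(length(slides), 1, prob = slide_w)
  mask <- sampler$masks[[si]]
  pix <- which(mask == k)
  p <- pix[sample.int(length(pix), 1)]
  H <- nrow(mask)
  cy <- (p - 1) %% H + 0.5
  cx <- (p - 1) %/% H + 0.5
  os <- config$geometry$output
  lab <- label_window(mask, cx, cy, os)
  list(target = extract_patch(slides[[si]], cx, cy, config$input_size,
                              config$target_spacing),
       context = extract_patch(slides[[si]], cx, cy, config$input_size,
                               config$context_spacing),
       labels = lab, category = cats[k], slide = si, center = c(cx, cy))
}

# Label mask for the centered output window; pixels beyond the slide border
# are unlabeled (0) and therefore excluded from the loss.
label_window <- function(mask, cx, cy, os) {
  half <- os / 2
  rows <- floor(cy - half) + seq_len(os)
  cols <- floor(cx - half) + seq_len(os)
  out <- matrix(0L, os, os)
  rok <- rows >= 0 & rows < nrow(mask)
  cok <- cols >= 0 & cols < ncol(mask)
  out[rok, cok] <- mask[rows[rok] + 1, cols[cok] + 1]
  out
}

#' Training configuration
#'
#' Optimization uses Adam with cross-entropy loss on the target branch only;
#' unlabeled and ignore pixels are excluded from the loss, and an L2 penalty
#' (the model config's `l2_coefficient`) acts on all convolution weights.
#'
#' @param iterations number of optimizer steps.
#' @param batch_size patch pairs per step.
#' @param learning_rate Adam step size.
#' @param augment apply flips/rotations and mild intensity jitter.
#' @param val_every validate (and checkpoint the best weights) every this
#'   many iterations; 0 disables validation.
#' @param seed seed controlling sampling, augmentation and initialization.
#' @return a `TrainConfig` list.
#' @export
train_config <- function(iterations = 200, batch_size = 6,
                         learning_rate = 1e-4, augment = TRUE,
                         val_every = 25, seed = 1L) {
  if (iterations <= 0 || batch_size <= 0 || learning_rate <= 0)
    stop("iterations, batch_size and learning_rate must be positive")
  structure(list(iterations = iterations, batch_size = batch_size,
                 learning_rate = learning_rate, augment = augment,
                 val_every = val_every, seed = as.integer(seed)),
            class = "TrainConfig")
}

# flips / 90-degree rotations applied identically to both patches and the
# mask; mild brightness and per-channel jitter on the images only
augment_sample <- function(s) {
  k <- sample(0:3, 1)
  fl <- sample(c(TRUE, FALSE), 1)
  rot_m <- function(m) if (k == 0) m else {
    for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
    m
  }
  tf_img <- function(a) {
    out <- array(0, dim(a))
    for (ch in 1:3) {
      m <- a[, , ch]
      if (fl) m <- m[, ncol(m):1, drop = FALSE]
      out[, , ch] <- rot_m(m)
    }
    out
  }
  s$target <- tf_img(s$target)
  s$context <- tf_img(s$context)
  m <- s$labels
  if (fl) m <- m[, ncol(m):1, drop = FALSE]
  s$labels <- rot_m(m)
  bright <- runif(1, 0.9, 1.1)
  chj <- runif(3, 0.95, 1.05)
  for (ch in 1:3) {
    s$target[, , ch] <- pmin(255, pmax(0, s$target[, , ch] * bright * chj[ch]))
    s$context[, , ch] <- pmin(255, pmax(0, s$context[, , ch] * bright * chj[ch]))
  }
  s
}

stack_batch <- function(batch) {
  n <- length(batch)
  d <- dim(batch[[1]]$target)
  os <- dim(batch[[1]]$labels)[1]
  tg <- array(0, c(d[1], d[2], 3, n))
  cx <- array(0, c(d[1], d[2], 3, n))
  lb <- array(0L, c(os, os, n))
  for (i in seq_len(n)) {
    tg[, , , i] <- batch[[i]]$target / 255
    cx[, , , i] <- batch[[i]]$context / 255
    lb[, , i] <- batch[[i]]$labels
  }
  list(target = tg, context = cx, labels = lb)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# one forward/backward/update step on a stacked batch; returns updated model
# pieces and the batch loss
train_step <- function(model, batch, opt, lr) {
  fwd <- model_forward(model, batch$target, batch$context, train = TRUE,
                       keep_cache = TRUE)
  ce <- masked_ce(fwd$probs, fwd$logits, batch$labels)
  grads <- model_backward(model, fwd, ce$dlogits)
  l2 <- model$config$l2_coefficient
  if (l2 > 0)
    for (nm in grep("_w$", names(grads), value = TRUE))
      grads[[nm]] <- grads[[nm]] + 2 * l2 * model$params[[nm]]
  up <- adam_step(model$params, grads, opt, lr)
  model$params <- up$params
  model$bn_stats <- fwd$bn_stats
  list(model = model, opt = up$state, loss = ce$loss)
}

#' Train the dual-branch model
#'
#' Minimizes the masked cross-entropy (unlabeled and ignore pixels excluded)
#' of the target-branch output plus the L2 weight penalty, with Adam.
#' When validation slides are supplied, the weights with the best validation
#' loss are returned; otherwise the final weights are.
#'
#' @param model a freshly built [build_model()] (or one to fine-tune).
#' @param slides,annotations training slides and their annotations.
#' @param config a [train_config()].
#' @param val_slides,val_annotations optional validation set.
#' @return list with `model` (trained), `log` (data frame of iteration,
#'   loss, val_loss) and `best_val`.
#' @export
train_model <- function(model, slides, annotations, config,
                        val_slides = NULL, val_annotations = NULL) {
  stopifnot(inherits(config, "TrainConfig"))
  sampler <- compute_sampling_weights(annotations)
  has_val <- !is.null(val_slides)
  val_batches <- NULL
  if (has_val) {
    val_sampler <- compute_sampling_weights(val_annotations)
    val_batches <- lapply(1:2, function(i)
      stack_batch(sample_training_batch(val_slides, val_annotations,
                                        val_sampler, config$batch_size,
                                        model$config,
                                        seed = config$seed + 90000 + i)))
  }
  opt <- adam_init(model$params)
  log_rows <- list()
  best <- list(val = Inf, params = model$params, bn = model$bn_stats)
  with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      batch <- replicate(config$batch_size,
                         sample_one(slides, sampler, model$config),
                         simplify = FALSE)
      if (config$augment) batch <- lapply(batch, augment_sample)
      st <- train_step(model, stack_batch(batch), opt,
                       config$learning_rate)
      model <- st$model; opt <- st$opt
      if (!is.finite(st$loss))
        stop("training diverged: non-finite loss at iteration ", it)
      vloss <- NA_real_
      if (has_val && config$val_every > 0 &&
          (it %% config$val_every == 0 || it == config$iterations)) {
        vloss <- mean(vapply(val_batches, function(vb) {
          f <- model_forward(model, vb$target, vb$context, train = FALSE)
          masked_ce(f$probs, f$logits, vb$labels)$loss
        }, 0))
        if (vloss < best$val)
          best <- list(val = vloss, params = model$params,
                       bn = model$bn_stats)
      }
      log_rows[[it]] <- data.frame(iteration = it, loss = st$loss,
                                   val_loss = vloss)
    }
  })
  if (has_val && is.finite(best$val)) {
    model$params <- best$params
    model$bn_stats <- best$bn
  }
  list(model = model, log = do.call(rbind, log_rows),
       best_val = if (has_val) best$val else NA_real_)
}

#' Harvest false-positive detections as Rest annotations
#'
#' Runs full-slide detection on the training slides, matches the detections
#' against the exhaustive ground truth with the object-level overlap rule,
#' and converts every false-positive TLS or GC detection polygon into a
#' Rest annotation. False negatives are never harvested. Returns only the
#' additions (one annotation set per slide), each polygon tagged with the
#' mining iteration for auditability.
#'
#' @param model trained model.
#' @param slides,annotations training slides with exhaustive annotations.
#' @param thresholds named list with `TLS` and `GC` threshold configs.
#' @param tissue_threshold cohort tissue-mask intensity threshold.
#' @param iteration mining iteration index recorded as provenance.
#' @return list of [annotation_set()]s containing only the new Rest
#'   polygons.
#' @export
harvest_false_positives <- function(model, slides, annotations, thresholds,
                                    tissue_threshold = 235, iteration = 1L) {
  lapply(seq_along(slides), function(i) {
    tm <- compute_tissue_mask(slides[[i]], tissue_threshold)
    conf <- predict_wsi(model, slides[[i]], tm)
    det <- detect_slide(conf, thresholds)
    adds <- list()
    for (cat in c("TLS", "GC")) {
      if (length(det[[cat]]) == 0) next
      m <- match_objects(annotations[[i]], det[[cat]], cat,
                         dims = dim(conf$maps)[1:2])
      for (p in which(!m$pred_validates)) {
        poly <- det[[cat]][[p]]$polygon
        adds[[length(adds) + 1]] <- list(coords = pmax(poly, 0),
                                         category = "Rest",
                                         provenance = paste0("mined-iter",
                                                             iteration))
      }
    }
    annotation_set(adds, slide_id = annotations[[i]]$slide_id,
                   width = annotations[[i]]$width,
                   height = annotations[[i]]$height,
                   exhaustive = character(0))
  })
}

# Merge harvested Rest additions into the original annotation sets without
# touching any original polygon.
merge_annotations <- function(annotations, additions) {
  lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    a$polygons <- c(a$polygons, additions[[i]]$polygons)
    a
  })
}

#' One hard-negative mining iteration
#'
#' Extends the training set with all harvested Rest additions, retrains the
#' model from randomly re-initialized weights (a fresh seed, never
#' fine-tuned), harvests the new model's false positives, and logs the
#' evaluation. Original annotations are never deleted or relabeled.
#'
#' @param state list with `model_config`, `train_config`, `slides`,
#'   `annotations` (originals), `additions` (list of per-slide Rest
#'   annotation sets accumulated so far), `thresholds`, `iteration`, and
#'   optionally `val_slides`/`val_annotations`.
#' @return the updated state: a newly trained `model`, extended `additions`,
#'   incremented `iteration`, and the per-iteration `history`.
#' @export
mining_iteration <- function(state) {
  it <- state$iteration + 1L
  train_ann <- state$annotations
  if (length(state$additions))
    for (add in state$additions)
      train_ann <- merge_annotations(train_ann, add)
  mc <- state$model_config
  mc$seed <- mc$seed + it  # fresh random initialization each iteration
  model <- build_model(mc)
  tc <- state$train_config
  tc$seed <- tc$seed + it
  tr <- train_model(model, state$slides, train_ann, tc,
                    state$val_slides, state$val_annotations)
  harvested <- harvest_false_positives(tr$model, state$slides,
                                       state$annotations, state$thresholds,
                                       iteration = it)
  n_new <- sum(vapply(harvested, function(a) length(a$polygons), 0L))
  state$model <- tr$model
  state$additions <- c(state$additions, list(harvested))
  state$iteration <- it
  state$history <- rbind(state$history,
                         data.frame(iteration = it, harvested_fp = n_new,
                                    final_loss = tail(tr$log$loss, 1)))
  state
}
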