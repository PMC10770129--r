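# Backward pass through the dual-branch U-Net, mirroring model_forward.
# Gradients are returned as a flat named list matching model$params.
# Only the target branch carries the loss head; the context branch receives
# gradients exclusively through the hook concatenation.

bwd_cbr <- function(model, name, bn_name, dy, cache, grads) {
  preact <- cache[[paste0(name, "_preact")]]
  dy <- relu_bwd_cpp(dy, preact)
  dim(dy) <- dim(preact)
  bn <- bn_bwd(dy, cache[[paste0(bn_name, "_cache")]])
  grads[[paste0(bn_name, "_gamma")]] <- bn$dgamma
  grads[[paste0(bn_name, "_beta")]] <- bn$dbeta
  cv <- conv2d_bwd_cpp(cache[[paste0(name, "_x")]],
                       model$params[[paste0(name, "_w")]], bn$dx)
  grads[[paste0(name, "_w")]] <- cv$dw
  grads[[paste0(name, "_b")]] <- cv$db
  list(dx = cv$dx, grads = grads)
}

# decoder backward; returns gradient at the decoder input plus per-level
# skip gradients (list indexed by encoder level, NULL where unused)
bwd_decode <- function(model, prefix, dy, depth, n_dec, cache, grads) {
  dskips <- vector("list", depth)
  first <- depth - n_dec + 1
  for (i in seq(first, depth)) {
    for (cj in 2:1) {
      st <- bwd_cbr(model, sprintf("%s_d%d_c%d", prefix, i, cj),
                    sprintf("%s_d%d_b%d", prefix, i, cj), dy, cache, grads)
      dy <- st$dx; grads <- st$grads
    }
    upch <- cache[[sprintf("%s_d%d_upch", prefix, i)]]
    dup <- dy[, , seq_len(upch), , drop = FALSE]
    dsk <- dy[, , -seq_len(upch), , drop = FALSE]
    dskips[[i]] <- pad_center_grad(dsk,
                                   cache[[sprintf("%s_d%d_skipdim", prefix, i)]])
    uc <- upconv2_bwd_cpp(cache[[sprintf("%s_d%d_up_x", prefix, i)]],
                          model$params[[sprintf("%s_d%d_up_w", prefix, i)]],
                          dup)
    grads[[sprintf("%s_d%d_up_w", prefix, i)]] <- uc$dw
    grads[[sprintf("%s_d%d_up_b", prefix, i)]] <- uc$db
    dy <- uc$dx
  }
  list(dx = dy, dskips = dskips, grads = grads)
}

bwd_encode <- function(model, prefix, dbottleneck, dskips, depth, cache,
                       grads) {
  dy <- dbottleneck
  for (cj in 2:1) {
    st <- bwd_cbr(model, sprintf("%s_bt_c%d", prefix, cj),
                  sprintf("%s_bt_b%d", prefix, cj), dy, cache, grads)
    dy <- st$dx; grads <- st$grads
  }
  for (i in rev(seq_len(depth))) {
    insz <- cache[[sprintf("%s_p%d_in", prefix, i)]]
    dy <- maxpool2_bwd_cpp(dy, cache[[sprintf("%s_p%d_idx", prefix, i)]],
                           insz, insz)
    if (!is.null(dskips[[i]])) dy <- dy + dskips[[i]]
    for (cj in 2:1) {
      st <- bwd_cbr(model, sprintf("%s_e%d_c%d", prefix, i, cj),
                    sprintf("%s_e%d_b%d", prefix, i, cj), dy, cache, grads)
      dy <- st$dx; grads <- st$grads
    }
  }
  grads
}

# dlogits: gradient of the loss w.r.t. the head logits
model_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  cache <- fwd$cache
  grads <- list()
  hd <- conv2d_bwd_cpp(cache$head_x, model$params$t_head_w, dlogits)
  grads$t_head_w <- hd$dw
  grads$t_head_b <- hd$db
  td <- bwd_decode(model, "t", hd$dx, cfg$depth, cfg$depth, cache, grads)
  grads <- td$grads
  # split hooked bottleneck gradient
  tch <- cache$t_bt_ch
  d_tbt <- td$dx[, , seq_len(tch), , drop = FALSE]
  d_hook <- td$dx[, , -seq_len(tch), , drop = FALSE]
  grads <- bwd_encode(model, "t", d_tbt, td$dskips, cfg$depth, cache, grads)
  d_ctx_dec <- pad_center_grad(d_hook, cache$hook_fulldim)
  cd <- bwd_decode(model, "c", d_ctx_dec, cfg$depth, cfg$hook_ups, cache,
                   grads)
  grads <- cd$grads
  grads <- bwd_encode(model, "c", cd$dx, cd$dskips, cfg$depth, cache, grads)
  grads
}

# Masked softmax cross-entropy.
# labels: (H, W, N) integer array with mask codes (0 unlabeled, 1 TLS,
# 2 GC, 3 Rest, 255 ignore); only codes 1..3 contribute.
# Returns loss value and dlogits (normalized by contributing pixel count).
masked_ce <- function(probs, logits, labels) {
  d <- dim(probs)
  K <- d[3]
  contrib <- labels >= 1 & labels <= K
  n <- sum(contrib)
  if (n == 0)
    return(list(loss = 0, dlogits = array(0, d), n = 0))
  dlogits <- array(0, d)
  loss <- 0
  for (k in seq_len(K)) {
    onehot <- (labels == k) * 1
    pk <- array(probs[, , k, ], dim(labels))
    loss <- loss - sum(log(pmax(pk, 1e-12)) * onehot)
    dlogits[, , k, ] <- (pk - onehot) * contrib / n
  }
  list(loss = loss / n, dlogits = dlogits, n = n)
}
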