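# Whole-network forward and backward passes. The forward pass in training
# mode returns every cache backprop needs; gradients come back in a flat
# named list aligned with net_params(), so the optimizer is a plain loop
# over named arrays.

net_pad <- function(config) (config$kernel - 1L) %/% 2L

unit_fw <- function(x, unit, act, training, pad) {
  c1 <- conv1d_fw(x, unit$conv1, stride = unit$stride, pad = pad)
  b1 <- bn_fw(c1, unit$bn1, training)
  a1 <- act_fw(b1$y, act)
  c2 <- conv1d_fw(a1, unit$conv2, stride = 1L, pad = pad)
  b2 <- bn_fw(c2, unit$bn2, training)
  if (is.null(unit$shortcut)) {
    if (unit$stride == 1L) {
      id <- x
      sc_cache <- NULL
    } else {
      id <- avgpool2_fw(x)
      sc_cache <- list(pool_only = TRUE)
    }
  } else {
    pooled <- if (unit$stride == 2L) avgpool2_fw(x) else x
    scc <- conv1d_fw(pooled, unit$shortcut$W, stride = 1L, pad = 0L)
    scb <- bn_fw(scc, unit$shortcut$bn, training)
    id <- scb$y
    sc_cache <- list(pooled = pooled, bn = scb$cache)
    unit$shortcut$bn <- scb$bn
  }
  pre <- b2$y + id
  y <- act_fw(pre, act)
  unit$bn1 <- b1$bn
  unit$bn2 <- b2$bn
  cache <- if (training) {
    list(x = x, c1 = c1, bn1 = b1$cache, a1 = a1, bn2 = b2$cache,
         pre = pre, y = y, sc = sc_cache)
  } else {
    NULL
  }
  list(y = y, unit = unit, cache = cache)
}

unit_bw <- function(dy, unit, cache, act, pad, prefix) {
  grads <- list()
  dpre <- act_bw(dy, cache$y, cache$pre, act)
  # residual branch
  b2 <- bn_bw(dpre, cache$bn2, unit$bn2$gamma)
  grads[[paste0(prefix, ".bn2.gamma")]] <- b2$grads$gamma
  grads[[paste0(prefix, ".bn2.beta")]] <- b2$grads$beta
  grads[[paste0(prefix, ".bn2.theta")]] <- b2$grads$theta
  c2 <- conv1d_bw(b2$dx, cache$a1, unit$conv2, stride = 1L, pad = pad)
  grads[[paste0(prefix, ".conv2")]] <- c2$dW
  da1 <- act_bw_from_y(c2$dx, cache$a1, act)
  b1 <- bn_bw(da1, cache$bn1, unit$bn1$gamma)
  grads[[paste0(prefix, ".bn1.gamma")]] <- b1$grads$gamma
  grads[[paste0(prefix, ".bn1.beta")]] <- b1$grads$beta
  grads[[paste0(prefix, ".bn1.theta")]] <- b1$grads$theta
  c1 <- conv1d_bw(b1$dx, cache$x, unit$conv1, stride = unit$stride, pad = pad)
  grads[[paste0(prefix, ".conv1")]] <- c1$dW
  dx <- c1$dx
  # identity / shortcut branch
  if (is.null(unit$shortcut)) {
    if (is.null(cache$sc)) {
      dx <- dx + dpre
    } else {
      dx <- dx + avgpool2_bw(dpre, dim(cache$x)[2])
    }
  } else {
    scb <- bn_bw(dpre, cache$sc$bn, unit$shortcut$bn$gamma)
    grads[[paste0(prefix, ".sc.bn.gamma")]] <- scb$grads$gamma
    grads[[paste0(prefix, ".sc.bn.beta")]] <- scb$grads$beta
    grads[[paste0(prefix, ".sc.bn.theta")]] <- scb$grads$theta
    scc <- conv1d_bw(scb$dx, cache$sc$pooled, unit$shortcut$W,
                     stride = 1L, pad = 0L)
    grads[[paste0(prefix, ".sc.W")]] <- scc$dW
    dpool <- scc$dx
    dx <- dx + if (unit$stride == 2L) avgpool2_bw(dpool, dim(cache$x)[2]) else dpool
  }
  list(dx = dx, grads = grads)
}

# Activation backward through the stored *output*: for every supported
# activation the output determines the local derivative (relu/leaky/elu:
# y > 0 <=> x > 0, elu derivative is y + 1 below zero; sigmoid: y(1-y)).
act_bw_from_y <- function(dy, y, type) {
  switch(type,
         relu = relu_bw_cpp(dy, y),
         leaky_relu = dy * ifelse(y > 0, 1, 0.01),
         elu = dy * ifelse(y > 0, 1, y + 1),
         sigmoid = dy * y * (1 - y))
}

net_forward <- function(net, x, aux = NULL, training = FALSE) {
  config <- net$config
  if (config$dimension != 1L) {
    abort("Forward/training is implemented for dimension = 1 networks.")
  }
  pad <- net_pad(config)
  caches <- list(stem = list(), stages = list())
  h <- x
  for (i in seq_along(net$stem)) {
    st <- net$stem[[i]]
    st_pad <- if (config$use_xresnet) pad else 3L
    cv <- conv1d_fw(h, st$W, stride = st$stride, pad = st_pad)
    bn <- bn_fw(cv, st$bn, training)
    a <- act_fw(bn$y, config$activation)
    net$stem[[i]]$bn <- bn$bn
    if (training) caches$stem[[i]] <- list(x = h, bn = bn$cache, a = a)
    h <- a
  }
  mp <- maxpool_fw(h)
  if (training) caches$pool <- mp$cache
  h <- mp$y
  for (s in seq_along(net$stages)) {
    caches$stages[[s]] <- list()
    for (u in seq_along(net$stages[[s]])) {
      res <- unit_fw(h, net$stages[[s]][[u]], config$activation, training, pad)
      net$stages[[s]][[u]] <- res$unit
      if (training) caches$stages[[s]][[u]] <- res$cache
      h <- res$y
    }
  }
  feat <- gap_fw(h)                      # (C, B)
  if (length(config$aux_features) > 0) {
    if (is.null(aux)) abort("Network expects auxiliary features but none were given.")
    feat_full <- rbind(feat, aux)
  } else {
    feat_full <- feat
  }
  z <- net$head$W %*% feat_full + net$head$b
  probs <- softmax_cols(z)
  if (training) {
    caches$body_out_L <- dim(h)[2]
    caches$feat_full <- feat_full
    caches$probs <- probs
  }
  list(probs = probs, net = net, caches = if (training) caches else NULL)
}

# dz: gradient at the pre-softmax logits, (K, B).
net_backward <- function(net, dz, caches) {
  config <- net$config
  pad <- net_pad(config)
  grads <- list()
  grads[["head.W"]] <- dz %*% t(caches$feat_full)
  grads[["head.b"]] <- rowSums(dz)
  dfeat_full <- crossprod(net$head$W, dz)
  C_body <- nrow(dfeat_full) - length(config$aux_features)
  dfeat <- dfeat_full[seq_len(C_body), , drop = FALSE]
  dh <- gap_bw(dfeat, caches$body_out_L)
  for (s in rev(seq_along(net$stages))) {
    for (u in rev(seq_along(net$stages[[s]]))) {
      res <- unit_bw(dh, net$stages[[s]][[u]], caches$stages[[s]][[u]],
                     config$activation, pad, sprintf("s%du%d", s, u))
      grads <- c(grads, res$grads)
      dh <- res$dx
    }
  }
  dh <- maxpool_bw(dh, caches$pool)
  for (i in rev(seq_along(net$stem))) {
    st <- net$stem[[i]]
    st_pad <- if (config$use_xresnet) pad else 3L
    cc <- caches$stem[[i]]
    da <- act_bw_from_y(dh, cc$a, config$activation)
    bb <- bn_bw(da, cc$bn, st$bn$gamma)
    grads[[sprintf("stem%d.bn.gamma", i)]] <- bb$grads$gamma
    grads[[sprintf("stem%d.bn.beta", i)]] <- bb$grads$beta
    grads[[sprintf("stem%d.bn.theta", i)]] <- bb$grads$theta
    cv <- conv1d_bw(bb$dx, cc$x, st$W, stride = st$stride, pad = st_pad)
    grads[[sprintf("stem%d.W", i)]] <- cv$dW
    dh <- cv$dx
  }
  grads
}

# Auxiliary feature matrix (n_aux x n) for the configured subset, z-scored
# with the provided (training-set) moments so head inputs are O(1).
aux_matrix <- function(config, trajs, moments = NULL) {
  if (length(config$aux_features) == 0) return(NULL)
  ft <- purrr::map(trajs, compute_features) |> dplyr::bind_rows()
  m <- t(as.matrix(ft[, config$aux_features, drop = FALSE]))
  if (!is.null(moments)) {
    m <- (m - moments$mean) / moments$sd
  }
  m
}

aux_moments <- function(m) {
  list(mean = apply(m, 1, mean), sd = pmax(apply(m, 1, sd), 1e-12))
}

# Autocorrelation input channels: one constant channel per lag carrying the
# increment autocorrelation of the (interleaved) trajectory at that lag.
acf_channels <- function(trajs, L, lags = c(8L, 16L, 24L)) {
  n <- length(trajs)
  out <- array(0, dim = c(length(lags), L, n))
  for (i in seq_len(n)) {
    tr <- trajs[[i]]
    for (j in seq_along(lags)) {
      lag <- min(lags[j], nrow(tr) - 2L)
      out[j, , i] <- increment_autocorrelation(tr, max(lag, 1L))
    }
  }
  out
}

encode_for_network <- function(net, data) {
  config <- net$config
  trajs <- if (inherits(data, "ad_dataset")) data$traj else data
  enc <- encode_trajectories(data, fixed_length = config$fixed_length)
  if (config$use_autocorrelation) {
    extra <- acf_channels(trajs, dim(enc$inputs)[2])
    enc$inputs <- abind_channels(enc$inputs, extra)
  }
  enc
}

abind_channels <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Classify trajectories with a trained network
#'
#' Runs the network in evaluation mode (frozen batch-norm statistics) and
#' returns one row per trajectory with the four class probabilities, the
#' predicted class and the coarse three-way diffusion category.
#'
#' @param network A trained `ad_network` (or an `ad_fit` from [train()]).
#' @param data An `ad_dataset` or a list of trajectory tibbles.
#' @param chunk_size Evaluation mini-batch size.
#' @return A tibble with columns `.pred_FBM`, `.pred_CD`, `.pred_DM`,
#'   `.pred_ND`, `.pred_class`, `.pred_coarse`.
#' @export
predict_trajectories <- function(network, data, chunk_size = 64L) {
  if (inherits(network, "ad_fit")) network <- network$network
  enc <- encode_for_network(network, data)
  trajs <- if (inherits(data, "ad_dataset")) data$traj else data
  aux <- aux_matrix(network$config, trajs, network$aux_moments)
  probs <- forward_in_chunks(network, enc$inputs, aux, chunk_size)
  classes <- diffusion_classes()
  out <- as_tibble(stats::setNames(as.data.frame(t(probs)),
                                   paste0(".pred_", classes)))
  pred <- factor(classes[max.col(t(probs), ties.method = "first")],
                 levels = classes)
  coarse <- c(FBM = "subdiffusion", CD = "subdiffusion",
              DM = "superdiffusion", ND = "normal")[as.character(pred)]
  out$.pred_class <- pred
  out$.pred_coarse <- factor(coarse,
                             levels = c("subdiffusion", "normal", "superdiffusion"))
  out
}

forward_in_chunks <- function(net, inputs, aux = NULL, chunk_size = 64L) {
  n <- dim(inputs)[3]
  K <- net$config$n_classes
  probs <- matrix(0, K, n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    xa <- inputs[, , idx, drop = FALSE]
    auxa <- if (is.null(aux)) NULL else aux[, idx, drop = FALSE]
    probs[, idx] <- net_forward(net, xa, auxa, training = FALSE)$probs
  }
  probs
}
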