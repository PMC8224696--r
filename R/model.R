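#' Architecture configuration for the residual-network family
#'
#' Describes one member of the configurable 1-D (or, for structural
#' ablations, 2-D) residual-network family. The default configuration is the
#' final model: XResNet-style blocks, 1-D input, depth 3, 32 base feature
#' maps, 1x5 kernels, ReLU with learnable per-channel activation thresholds,
#' and a single 4-unit dense classification head - the configuration whose
#' trainable-parameter count is exactly 399,556.
#'
#' Layout notes, fixed by calibrating the per-layer arithmetic against the
#' published parameter counts of the whole configuration grid:
#' the input is a single channel with x and y interleaved; the stem is three
#' convolutions with widths `x0/4, x0, x0` sharing the body kernel size;
#' each stage holds two residual units (two convolutions each) and stage
#' widths follow `x_i = x0 * 2^(i-1)`; downsampling shortcuts are
#' average-pool + 1x1 convolution + batch norm; convolutions carry no bias;
#' the activation threshold contributes one learnable scalar per batch-norm
#' channel.
#'
#' @param use_xresnet Use the modified stem (three small convolutions) and
#'   average-pool downsampling shortcuts; `FALSE` gives the plain variant
#'   with a single kernel-7 stem convolution and strided 1x1 shortcuts.
#' @param dimension 1 for interleaved 1-D input; 2 treats the trajectory as
#'   a 2 x fixed_length one-channel image with k x k kernels (construction
#'   and parameter accounting only).
#' @param depth Number of stages (1-4 supported).
#' @param x0 Base feature-map count; stage `i` has `x0 * 2^(i-1)` maps.
#' @param kernel Odd spatial kernel size (k in 1xk, or k x k for
#'   `dimension = 2`).
#' @param n_classes Output classes (4).
#' @param activation One of `"relu"`, `"leaky_relu"`, `"elu"`, `"sigmoid"`.
#' @param activation_threshold Learnable per-channel activation thresholds
#'   (one scalar per batch-norm channel).
#' @param aux_features Character subset of
#'   `c("asymmetry", "efficiency", "fractal_dimension", "tamsd_lag20")`
#'   concatenated to the pooled representation before the dense head.
#' @param use_autocorrelation Add increment-autocorrelation input channels
#'   (lags 8, 16, 24).
#' @param units_per_stage Residual units per stage (default 2).
#' @param fixed_length Trajectory padding length in points.
#'
#' @return An object of class `ad_arch_config`.
#' @export
arch_config <- function(use_xresnet = TRUE,
                        dimension = 1L,
                        depth = 3L,
                        x0 = 32L,
                        kernel = 5L,
                        n_classes = 4L,
                        activation = "relu",
                        activation_threshold = TRUE,
                        aux_features = character(),
                        use_autocorrelation = FALSE,
                        units_per_stage = 2L,
                        fixed_length = 600L) {
  if (kernel %% 2 == 0) abort("`kernel` must be odd.")
  if (!dimension %in% c(1L, 2L)) abort("`dimension` must be 1 or 2.")
  if (depth < 1 || depth > 4) abort("`depth` must be between 1 and 4.")
  if (x0 < 4) abort("`x0` must be at least 4.")
  allowed <- c("asymmetry", "efficiency", "fractal_dimension", "tamsd_lag20")
  if (!all(aux_features %in% allowed)) {
    abort(sprintf("`aux_features` must be a subset of %s.",
                  paste(allowed, collapse = ", ")))
  }
  activation <- match.arg(activation, c("relu", "leaky_relu", "elu", "sigmoid"))
  structure(
    list(use_xresnet = use_xresnet, dimension = as.integer(dimension),
         depth = as.integer(depth), x0 = as.integer(x0),
         kernel = as.integer(kernel), n_classes = as.integer(n_classes),
         activation = activation,
         activation_threshold = isTRUE(activation_threshold),
         aux_features = aux_features,
         use_autocorrelation = isTRUE(use_autocorrelation),
         units_per_stage = as.integer(units_per_stage),
         fixed_length = as.integer(fixed_length),
         input_channels = 1L + if (isTRUE(use_autocorrelation)) 3L else 0L),
    class = "ad_arch_config"
  )
}

#' Feature-map width schedule
#'
#' Stage widths double from the base: `x_i = x0 * 2^(i-1)` for
#' `i = 1, ..., depth`.
#'
#' @param x0 Base feature-map count (>= 1).
#' @param depth Number of stages (>= 1).
#' @return Integer vector of length `depth`.
#' @export
feature_map_widths <- function(x0, depth) {
  if (x0 < 1 || depth < 1) abort("`x0` and `depth` must be at least 1.")
  as.integer(x0 * 2^(seq_len(depth) - 1))
}

kernel_elements <- function(config) {
  if (config$dimension == 2L) config$kernel * config$kernel else config$kernel
}

# Per-layer description of a configuration; every parameterized layer gets
# one row, so the total is auditable line by line.
layer_plan <- function(config) {
  k <- kernel_elements(config)
  cin <- config$input_channels
  thr <- if (config$activation_threshold) 1L else 0L
  rows <- list()
  add <- function(name, type, in_ch, out_ch, kern, params) {
    rows[[length(rows) + 1L]] <<- tibble(
      layer = name, type = type, in_channels = as.integer(in_ch),
      out_channels = as.integer(out_ch), kernel = as.integer(kern),
      params = as.integer(params))
  }
  add_bn <- function(name, ch) add(name, "batchnorm+threshold", ch, ch, 0L,
                                   (2L + thr) * ch)
  if (config$use_xresnet) {
    widths <- c(max(1L, config$x0 %/% 4L), config$x0, config$x0)
    prev <- cin
    for (i in seq_along(widths)) {
      add(sprintf("stem_conv%d", i), "conv", prev, widths[i], k, k * prev * widths[i])
      add_bn(sprintf("stem_bn%d", i), widths[i])
      prev <- widths[i]
    }
  } else {
    k_stem <- if (config$dimension == 2L) 49L else 7L
    add("stem_conv1", "conv", cin, config$x0, k_stem, k_stem * cin * config$x0)
    add_bn("stem_bn1", config$x0)
    prev <- config$x0
  }
  stage_widths <- feature_map_widths(config$x0, config$depth)
  for (s in seq_along(stage_widths)) {
    w <- stage_widths[s]
    for (u in seq_len(config$units_per_stage)) {
      u_in <- if (u == 1L) prev else w
      nm <- sprintf("stage%d_unit%d", s, u)
      add(paste0(nm, "_conv1"), "conv", u_in, w, k, k * u_in * w)
      add_bn(paste0(nm, "_bn1"), w)
      add(paste0(nm, "_conv2"), "conv", w, w, k, k * w * w)
      add_bn(paste0(nm, "_bn2"), w)
      if (u == 1L && (u_in != w || s > 1L)) {
        if (u_in != w) {
          add(paste0(nm, "_shortcut_conv"), "conv", u_in, w, 1L, u_in * w)
          add_bn(paste0(nm, "_shortcut_bn"), w)
        }
      }
    }
    prev <- w
  }
  n_aux <- length(config$aux_features)
  head_in <- prev + n_aux
  add("head_dense", "dense", head_in, config$n_classes, 0L,
      head_in * config$n_classes + config$n_classes)
  dplyr::bind_rows(rows)
}

#' Build a residual classification network
#'
#' Constructs the network described by an [arch_config()]: stem,
#' `depth` stages of residual units with skip connections, global average
#' pooling, and a single dense softmax head. Auxiliary feature scalars, when
#' configured, are concatenated to the pooled representation immediately
#' before the dense layer. Weights are Kaiming-initialized; the final batch
#' norm scale of every residual branch is zero-initialized so each unit maps
#' its input to itself at initialization.
#'
#' @param config An [arch_config()].
#' @return An object of class `ad_network`.
#' @export
build_network <- function(config = arch_config()) {
  plan <- layer_plan(config)
  k <- kernel_elements(config)
  init_conv <- function(in_ch, out_ch, kern) {
    matrix(rnorm(out_ch * in_ch * kern, 0, sqrt(2 / (in_ch * kern))),
           out_ch, in_ch * kern)
  }
  net <- list(config = config, plan = plan)
  if (config$use_xresnet) {
    widths <- c(max(1L, config$x0 %/% 4L), config$x0, config$x0)
    prev <- config$input_channels
    stem <- list()
    for (i in seq_along(widths)) {
      stem[[i]] <- list(W = init_conv(prev, widths[i], k),
                        bn = new_bn(widths[i]),
                        stride = if (i == 1L) 2L else 1L)
      prev <- widths[i]
    }
    net$stem <- stem
  } else {
    net$stem <- list(list(W = init_conv(config$input_channels, config$x0, 7L),
                          bn = new_bn(config$x0), stride = 2L))
    prev <- config$x0
  }
  stage_widths <- feature_map_widths(config$x0, config$depth)
  stages <- list()
  for (s in seq_along(stage_widths)) {
    w <- stage_widths[s]
    units <- list()
    for (u in seq_len(config$units_per_stage)) {
      u_in <- if (u == 1L) prev else w
      stride <- if (u == 1L && s > 1L) 2L else 1L
      bn2 <- new_bn(w)
      bn2$gamma <- rep(0, w)            # zero-init residual branch scale
      unit <- list(conv1 = init_conv(u_in, w, k), bn1 = new_bn(w),
                   conv2 = init_conv(w, w, k), bn2 = bn2,
                   stride = stride, in_ch = u_in, out_ch = w)
      if (u_in != w) {
        unit$shortcut <- list(W = init_conv(u_in, w, 1L), bn = new_bn(w))
      }
      units[[u]] <- unit
    }
    stages[[s]] <- units
    prev <- w
  }
  net$stages <- stages
  head_in <- prev + length(config$aux_features)
  net$head <- list(W = matrix(rnorm(config$n_classes * head_in, 0,
                                    sqrt(1 / head_in)),
                              config$n_classes, head_in),
                   b = rep(0, config$n_classes))
  class(net) <- "ad_network"
  net
}

#' Count trainable parameters of a network
#'
#' Exact count of trainable scalars, with an auditable per-layer breakdown
#' available through [describe_network()]. The default configuration counts
#' 399,556 parameters.
#'
#' @param network An `ad_network` (or an [arch_config()], which is built on
#'   the fly for counting).
#' @return Integer total.
#' @export
count_parameters <- function(network) {
  if (inherits(network, "ad_arch_config")) {
    return(as.integer(sum(layer_plan(network)$params)))
  }
  as.integer(sum(network$plan$params))
}

#' Per-layer parameter table
#'
#' @param network An `ad_network` or `ad_arch_config`.
#' @return Tibble with one row per parameterized layer (`layer`, `type`,
#'   `in_channels`, `out_channels`, `kernel`, `params`).
#' @export
describe_network <- function(network) {
  if (inherits(network, "ad_arch_config")) layer_plan(network) else network$plan
}

#' @export
print.ad_network <- function(x, ...) {
  cat(sprintf("<ad_network> depth %d, x0 %d, kernel %d, %s%s: %s trainable parameters\n",
              x$config$depth, x$config$x0, x$config$kernel,
              if (x$config$use_xresnet) "xresnet" else "resnet",
              if (x$config$dimension == 2L) ", 2-D" else "",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Per-layer tidy summary of a network
#'
#' @param x An `ad_network`.
#' @param ... Unused.
#' @return The per-layer parameter tibble.
#' @export
tidy.ad_network <- function(x, ...) describe_network(x)

#' One-row summary of a network
#'
#' @param x An `ad_network`.
#' @param ... Unused.
#' @return Tibble with parameter totals and key configuration fields.
#' @export
glance.ad_network <- function(x, ...) {
  tibble(parameters = count_parameters(x), depth = x$config$depth,
         x0 = x$config$x0, kernel = x$config$kernel,
         use_xresnet = x$config$use_xresnet, dimension = x$config$dimension)
}

# Flatten all trainable arrays into a named list (stable order); used by the
# optimizer and by checkpointing.
net_params <- function(net) {
  out <- list()
  for (i in seq_along(net$stem)) {
    out[[sprintf("stem%d.W", i)]] <- net$stem[[i]]$W
    out <- c(out, bn_params(net$stem[[i]]$bn, sprintf("stem%d.bn", i)))
  }
  for (s in seq_along(net$stages)) {
    for (u in seq_along(net$stages[[s]])) {
      p <- sprintf("s%du%d", s, u)
      un <- net$stages[[s]][[u]]
      out[[paste0(p, ".conv1")]] <- un$conv1
      out <- c(out, bn_params(un$bn1, paste0(p, ".bn1")))
      out[[paste0(p, ".conv2")]] <- un$conv2
      out <- c(out, bn_params(un$bn2, paste0(p, ".bn2")))
      if (!is.null(un$shortcut)) {
        out[[paste0(p, ".sc.W")]] <- un$shortcut$W
        out <- c(out, bn_params(un$shortcut$bn, paste0(p, ".sc.bn")))
      }
    }
  }
  out[["head.W"]] <- net$head$W
  out[["head.b"]] <- net$head$b
  out
}

bn_params <- function(bn, prefix) {
  stats::setNames(list(bn$gamma, bn$beta, bn$theta),
                  paste0(prefix, c(".gamma", ".beta", ".theta")))
}

net_set_params <- function(net, params) {
  set_bn <- function(bn, prefix) {
    bn$gamma <- params[[paste0(prefix, ".gamma")]]
    bn$beta <- params[[paste0(prefix, ".beta")]]
    bn$theta <- params[[paste0(prefix, ".theta")]]
    bn
  }
  for (i in seq_along(net$stem)) {
    net$stem[[i]]$W <- params[[sprintf("stem%d.W", i)]]
    net$stem[[i]]$bn <- set_bn(net$stem[[i]]$bn, sprintf("stem%d.bn", i))
  }
  for (s in seq_along(net$stages)) {
    for (u in seq_along(net$stages[[s]])) {
      p <- sprintf("s%du%d", s, u)
      net$stages[[s]][[u]]$conv1 <- params[[paste0(p, ".conv1")]]
      net$stages[[s]][[u]]$bn1 <- set_bn(net$stages[[s]][[u]]$bn1, paste0(p, ".bn1"))
      net$stages[[s]][[u]]$conv2 <- params[[paste0(p, ".conv2")]]
      net$stages[[s]][[u]]$bn2 <- set_bn(net$stages[[s]][[u]]$bn2, paste0(p, ".bn2"))
      if (!is.null(net$stages[[s]][[u]]$shortcut)) {
        net$stages[[s]][[u]]$shortcut$W <- params[[paste0(p, ".sc.W")]]
        net$stages[[s]][[u]]$shortcut$bn <-
          set_bn(net$stages[[s]][[u]]$shortcut$bn, paste0(p, ".sc.bn"))
      }
    }
  }
  net$head$W <- params[["head.W"]]
  net$head$b <- params[["head.b"]]
  net
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the architecture configuration; loading verifies
#' that weights and configuration are consistent.
#'
#' @param network An `ad_network`.
#' @param path File path.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the network.
#' @export
save_network <- function(network, path) {
  saveRDS(list(config = network$config, params = net_params(network),
               running = net_running_stats(network)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$config)
  expect_names <- names(net_params(net))
  if (!identical(expect_names, names(ck$params))) {
    abort("Checkpoint weights are inconsistent with its embedded configuration.")
  }
  net <- net_set_params(net, ck$params)
  net <- net_set_running_stats(net, ck$running)
  net
}

net_running_stats <- function(net) {
  out <- list()
  walk_bn(net, function(bn, prefix) {
    out[[paste0(prefix, ".rm")]] <<- bn$run_mean
    out[[paste0(prefix, ".rv")]] <<- bn$run_var
    bn
  })
  out
}

net_set_running_stats <- function(net, stats) {
  walk_bn(net, function(bn, prefix) {
    bn$run_mean <- stats[[paste0(prefix, ".rm")]]
    bn$run_var <- stats[[paste0(prefix, ".rv")]]
    bn
  })
}

walk_bn <- function(net, fn) {
  for (i in seq_along(net$stem)) {
    net$stem[[i]]$bn <- fn(net$stem[[i]]$bn, sprintf("stem%d.bn", i))
  }
  for (s in seq_along(net$stages)) {
    for (u in seq_along(net$stages[[s]])) {
      p <- sprintf("s%du%d", s, u)
      net$stages[[s]][[u]]$bn1 <- fn(net$stages[[s]][[u]]$bn1, paste0(p, ".bn1"))
      net$stages[[s]][[u]]$bn2 <- fn(net$stages[[s]][[u]]$bn2, paste0(p, ".bn2"))
      if (!is.null(net$stages[[s]][[u]]$shortcut)) {
        net$stages[[s]][[u]]$shortcut$bn <-
          fn(net$stages[[s]][[u]]$shortcut$bn, paste0(p, ".sc.bn"))
      }
    }
  }
  net
}
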