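#' Training configuration
#'
#' Default hyperparameters are the final model's: mean squared error against
#' one-hot targets after softmax, batch size 512, learning rate 0.0003, and
#' training to `max_epochs` with the weights restored from the best
#' validation epoch (no early stopping). The optimizer is Adam; the
#' published protocol does not name one, and Adam is the community-standard
#' optimizer at this learning rate (plain SGD at 3e-4 would not approach the
#' reported accuracies within tens of epochs).
#'
#' @param batch_size Samples per parameter update.
#' @param learning_rate Adam step size.
#' @param cost `"mse"` or `"cross_entropy"`, both applied to the softmax
#'   output against one-hot targets.
#' @param max_epochs Number of epochs to run.
#' @param selective_mode `"none"`, `"loss_coverage"` (back-propagate the
#'   shortest high-loss prefix covering a fraction of the total loss) or
#'   `"top_fraction"` (always back-propagate the highest-loss fraction).
#' @param selective_fraction Fraction for the selective modes, in (0, 1].
#' @param seed Root seed for initialization and shuffling.
#' @param verbose Print one line per epoch.
#'
#' @return An object of class `ad_train_config`.
#' @export
train_config <- function(batch_size = 512L,
                         learning_rate = 3e-4,
                         cost = c("mse", "cross_entropy"),
                         max_epochs = 70L,
                         selective_mode = c("none", "loss_coverage", "top_fraction"),
                         selective_fraction = 0.98,
                         seed = 1L,
                         verbose = FALSE) {
  if (batch_size < 1) abort("`batch_size` must be at least 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  selective_mode <- match.arg(selective_mode)
  if (selective_mode != "none" &&
      (selective_fraction <= 0 || selective_fraction > 1)) {
    abort("`selective_fraction` must lie in (0, 1].")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, cost = match.arg(cost),
                 max_epochs = as.integer(max_epochs),
                 selective_mode = selective_mode,
                 selective_fraction = selective_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "ad_train_config")
}

#' Choose the samples to back-propagate
#'
#' Implements the two selective-backprop scenarios on a vector of per-sample
#' losses. `loss_coverage(f)`: sort losses in decreasing order and take the
#' shortest prefix whose sum reaches `f` of the total (ties broken by
#' original index; an all-zero loss vector selects everything).
#' `top_fraction(f)`: take the `ceiling(f * n)` highest-loss samples.
#'
#' @param losses Non-negative per-sample losses.
#' @param mode `"none"`, `"loss_coverage"` or `"top_fraction"`.
#' @param fraction Selection fraction in (0, 1].
#' @return Integer indices of the selected samples (increasing order).
#' @export
select_backprop_subset <- function(losses, mode = "none", fraction = 0.98) {
  n <- length(losses)
  if (n == 0) abort("`losses` must be non-empty.")
  if (any(losses < 0)) abort("`losses` must be non-negative.")
  if (mode == "none") return(seq_len(n))
  ord <- order(-losses, seq_len(n))
  if (mode == "loss_coverage") {
    total <- sum(losses)
    if (total == 0) return(seq_len(n))
    csum <- cumsum(losses[ord])
    take <- which(csum >= fraction * total - 1e-12)[1]
    return(sort(ord[seq_len(take)]))
  }
  if (mode == "top_fraction") {
    take <- ceiling(fraction * n)
    return(sort(ord[seq_len(take)]))
  }
  abort(sprintf("Unknown selective mode '%s'.", mode))
}

per_sample_loss <- function(probs, targets_t, cost) {
  if (cost == "mse") {
    colMeans((probs - targets_t)^2)
  } else {
    -colSums(targets_t * log(pmax(probs, 1e-12)))
  }
}

# Gradient at the logits for the weighted mean loss over a batch;
# w is a per-sample weight vector (0 for unselected samples).
logit_gradient <- function(probs, targets_t, w, cost) {
  K <- nrow(probs)
  if (cost == "mse") {
    ds <- sweep(2 * (probs - targets_t) / K, 2, w, "*")
    inner <- colSums(ds * probs)
    probs * sweep(ds, 2, inner, "-")
  } else {
    sweep(probs - targets_t, 2, w, "*")
  }
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a residual network on a labeled trajectory dataset
#'
#' Minimizes the configured cost between the softmax outputs and one-hot
#' class targets on the training split. Each epoch records the training
#' accuracy (running aggregate of the training-mode forward predictions over
#' the epoch), the validation accuracy (re-evaluated at epoch end with
#' frozen batch-norm statistics), the mean loss over back-propagated samples
#' and the fraction of samples back-propagated. Training runs to
#' `max_epochs`; the returned network carries the weights of the epoch with
#' the highest validation accuracy.
#'
#' @param network An `ad_network` from [build_network()] (its weights are
#'   re-initialized under the training seed so runs are reproducible).
#' @param dataset An `ad_dataset` with `train` and `validation` splits.
#' @param config An [train_config()].
#'
#' @return An object of class `ad_fit`: list with `network` (best weights),
#'   `history` (per-epoch tibble of class `ad_history`), `best_epoch`,
#'   `config`.
#' @export
train <- function(network, dataset, config = train_config()) {
  tr <- dataset[dataset$split == "train", ]
  va <- dataset[dataset$split == "validation", ]
  if (nrow(tr) == 0 || nrow(va) == 0) {
    abort("Dataset must contain non-empty train and validation splits.")
  }
  network <- with_seed(derive_seed(config$seed, 1L, 7L),
                      build_network(network$config))
  enc_tr <- encode_for_network(network, tr)
  enc_va <- encode_for_network(network, va)
  aux_tr <- aux_matrix(network$config, tr$traj)
  if (!is.null(aux_tr)) {
    network$aux_moments <- aux_moments(aux_tr)
    aux_tr <- (aux_tr - network$aux_moments$mean) / network$aux_moments$sd
  }
  aux_va <- aux_matrix(network$config, va$traj, network$aux_moments)
  classes <- diffusion_classes()
  y_tr <- t(enc_tr$targets)                       # (K, n)
  true_va <- enc_va$labels
  n_tr <- dim(enc_tr$inputs)[3]

  params <- net_params(network)
  state <- adam_init(params)
  history <- list()
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL, running = NULL)

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- with_seed(derive_seed(config$seed, epoch, 11L), sample.int(n_tr))
    n_selected <- 0L
    loss_sum <- 0
    loss_n <- 0L
    train_correct <- 0L
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      idx <- order_idx[start:min(start + config$batch_size - 1L, n_tr)]
      xb <- enc_tr$inputs[, , idx, drop = FALSE]
      yb <- y_tr[, idx, drop = FALSE]
      auxb <- if (is.null(aux_tr)) NULL else aux_tr[, idx, drop = FALSE]
      fw <- net_forward(network, xb, auxb, training = TRUE)
      network <- fw$net
      losses <- per_sample_loss(fw$probs, yb, config$cost)
      train_correct <- train_correct +
        sum(max.col(t(fw$probs), ties.method = "first") ==
              max.col(t(yb), ties.method = "first"))
      sel <- select_backprop_subset(losses, config$selective_mode,
                                    config$selective_fraction)
      n_selected <- n_selected + length(sel)
      loss_sum <- loss_sum + sum(losses[sel])
      loss_n <- loss_n + length(sel)
      w <- numeric(length(idx))
      w[sel] <- 1 / length(sel)
      dz <- logit_gradient(fw$probs, yb, w, config$cost)
      grads <- net_backward(network, dz, fw$caches)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      network <- net_set_params(network, params)
      if (any(!is.finite(losses))) {
        abort(sprintf("Non-finite loss in epoch %d.", epoch))
      }
    }
    p_va <- forward_in_chunks(network, enc_va$inputs, aux_va)
    pred_va <- factor(classes[max.col(t(p_va), ties.method = "first")], levels = classes)
    acc_tr <- train_correct / n_tr
    acc_va <- mean(pred_va == true_va)
    cm_va <- confusion_matrix(true_va, pred_va)
    rep_va <- classification_metrics(cm_va)
    history[[epoch]] <- tibble(
      epoch = epoch, train_accuracy = acc_tr, validation_accuracy = acc_va,
      mean_loss = loss_sum / loss_n, bp_fraction = n_selected / n_tr,
      val_macro_precision = rep_va$macro$precision,
      val_macro_recall = rep_va$macro$recall,
      val_macro_f1 = rep_va$macro$f1)
    if (acc_va > best$acc) {
      best <- list(acc = acc_va, epoch = epoch, params = params,
                   running = net_running_stats(network))
    }
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  loss %.5f  bp %.2f",
                      epoch, acc_tr, acc_va, loss_sum / loss_n,
                      n_selected / n_tr))
    }
  }
  network <- net_set_params(network, best$params)
  network <- net_set_running_stats(network, best$running)
  history <- dplyr::bind_rows(history)
  class(history) <- c("ad_history", class(history))
  structure(list(network = network, history = history,
                 best_epoch = best$epoch, config = config),
            class = "ad_fit")
}

#' @export
print.ad_fit <- function(x, ...) {
  cat(sprintf("<ad_fit> %d epochs, best epoch %d (validation accuracy %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$validation_accuracy[x$best_epoch]))
  invisible(x)
}

#' Per-epoch training history of a fit
#'
#' @param x An `ad_fit`.
#' @param ... Unused.
#' @return The `ad_history` tibble (one row per epoch).
#' @export
tidy.ad_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `ad_fit`.
#' @param ... Unused.
#' @return Tibble with best epoch, best validation accuracy, final training
#'   accuracy and parameter count.
#' @export
glance.ad_fit <- function(x, ...) {
  tibble(best_epoch = x$best_epoch,
         best_validation_accuracy = max(x$history$validation_accuracy),
         final_train_accuracy = x$history$train_accuracy[nrow(x$history)],
         epochs = nrow(x$history),
         parameters = count_parameters(x$network))
}

#' Plot accuracy trajectories of a training run
#'
#' @param object An `ad_history` tibble (or an `ad_fit`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ad_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("epoch", "train_accuracy", "validation_accuracy")],
    -"epoch", names_to = "series", values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL)
}

#' @export
autoplot.ad_fit <- function(object, ...) autoplot(object$history, ...)
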