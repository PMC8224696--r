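#' Confusion matrix over the four diffusion classes
#'
#' `C[i, j]` counts samples whose true class is `i` and predicted class is
#' `j`; rows are true labels, columns predictions, in the canonical order
#' FBM, CD, DM, ND.
#'
#' @param truth True labels (factor or character over the four classes).
#' @param estimate Predicted labels of the same length.
#' @return A 4x4 integer matrix with dimnames.
#' @export
confusion_matrix <- function(truth, estimate) {
  classes <- diffusion_classes()
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad) > 0) {
    abort(sprintf("Unknown label(s) %s; allowed: %s.",
                  paste(bad, collapse = ", "), paste(classes, collapse = ", ")))
  }
  tab <- table(factor(truth, levels = classes),
               factor(estimate, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision (`C[j,j] / colsum_j`), recall (`C[j,j] / rowsum_j`)
#' and F1 (harmonic mean of the two), overall accuracy (`trace / total`),
#' and unweighted macro averages. A class that is never predicted has
#' undefined precision; it is reported as 0 and flagged.
#'
#' @param confusion Non-negative integer matrix (rows true, columns
#'   predicted).
#' @return An object of class `ad_report`: list with `confusion`,
#'   `metrics` (per-class tibble), `macro` (one-row tibble), `accuracy`,
#'   `n`.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) abort("Confusion entries must be non-negative.")
  total <- sum(confusion)
  if (total == 0) abort("Confusion matrix is all zero.")
  diag_c <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  undefined <- colsum == 0
  precision <- ifelse(undefined, 0, diag_c / pmax(colsum, 1e-300))
  recall <- ifelse(rowsum == 0, 0, diag_c / pmax(rowsum, 1e-300))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  classes <- rownames(confusion) %||% diffusion_classes()[seq_len(nrow(confusion))]
  metrics <- tibble(class = classes, precision = unname(precision),
                    recall = unname(recall), f1 = unname(f1),
                    support = unname(rowsum),
                    precision_undefined = unname(undefined))
  macro <- tibble(precision = mean(precision), recall = mean(recall),
                  f1 = mean(f1))
  structure(list(confusion = confusion, metrics = metrics, macro = macro,
                 accuracy = sum(diag_c) / total, n = total),
            class = "ad_report")
}

#' Evaluate a trained network on a dataset split
#'
#' @param network An `ad_fit` or `ad_network`.
#' @param dataset An `ad_dataset`.
#' @param split Which split to evaluate (default `"test"`); `NULL` uses all
#'   rows.
#' @return An `ad_report`.
#' @export
evaluate <- function(network, dataset, split = "test") {
  if (!is.null(split)) dataset <- dataset[dataset$split == split, ]
  if (nrow(dataset) == 0) abort("No samples in the requested split.")
  preds <- predict_trajectories(network, dataset)
  classification_metrics(confusion_matrix(dataset$label, preds$.pred_class))
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Per-class metric rows of a report
#'
#' @param x An `ad_report`.
#' @param ... Unused.
#' @return Tibble of per-class precision/recall/F1 plus a `Total/Average`
#'   macro row.
#' @export
tidy.ad_report <- function(x, ...) {
  dplyr::bind_rows(
    x$metrics[, c("class", "precision", "recall", "f1")],
    tibble(class = "Total/Average", precision = x$macro$precision,
           recall = x$macro$recall, f1 = x$macro$f1))
}

#' One-row summary of a report
#'
#' @param x An `ad_report`.
#' @param ... Unused.
#' @return Tibble with accuracy, macro metrics and sample count.
#' @export
glance.ad_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_precision = x$macro$precision,
         macro_recall = x$macro$recall, macro_f1 = x$macro$f1, n = x$n)
}

#' Confusion-matrix heatmap
#'
#' @param object An `ad_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ad_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::labs(x = "predicted", y = "true")
}

#' Aggregate four-class predictions into three diffusion categories
#'
#' FBM and CD map to subdiffusion, ND to normal diffusion and DM to
#' superdiffusion; the returned unrounded proportions sum to 1.
#'
#' @param labels Predicted labels over the four classes.
#' @return Tibble with `category` and `proportion`.
#' @export
aggregate_three_class <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) abort("`labels` must be non-empty.")
  bad <- setdiff(unique(labels), diffusion_classes())
  if (length(bad) > 0) abort(sprintf("Unknown label(s) %s.", paste(bad, collapse = ", ")))
  map <- c(FBM = "subdiffusion", CD = "subdiffusion", ND = "normal",
           DM = "superdiffusion")
  cats <- factor(map[labels], levels = c("subdiffusion", "normal", "superdiffusion"))
  tibble(category = levels(cats),
         proportion = as.numeric(table(cats)) / length(cats))
}

#' Mean metric trajectories with confidence bands over trained instances
#'
#' Trains `k` independent instances of the same architecture (one seed
#' each), tracks the per-epoch validation metrics of every instance, and
#' returns the across-instance mean and normal-approximation 95% confidence
#' half-width per metric per epoch.
#'
#' @param dataset An `ad_dataset`.
#' @param arch An [arch_config()].
#' @param config An [train_config()]; its seed is replaced per instance.
#' @param k Number of instances (>= 2).
#' @param seeds Integer vector of length `k`.
#' @return Tibble of class `ad_bands` with columns `epoch`, `metric`,
#'   `mean`, `half_width`, `k`.
#' @export
metrics_over_instances <- function(dataset, arch, config, k = 2L,
                                   seeds = seq_len(k)) {
  if (k < 2) abort("`k` must be at least 2.")
  if (length(seeds) != k) abort("`seeds` must have length `k`.")
  histories <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    train(build_network(arch), dataset, cfg)$history
  })
  metric_bands(histories)
}

#' Confidence bands from a list of per-epoch metric tibbles
#'
#' Closed-form normal-approximation band: `mean +/- 1.96 * sd / sqrt(k)`
#' per epoch and metric. Exposed separately so the band arithmetic is
#' checkable against hand-supplied sequences.
#'
#' @param histories List of tibbles sharing an `epoch` column and numeric
#'   metric columns.
#' @return An `ad_bands` tibble.
#' @export
metric_bands <- function(histories) {
  k <- length(histories)
  long <- purrr::imap(histories, function(h, i) {
    tidyr::pivot_longer(h, -"epoch", names_to = "metric", values_to = "value") |>
      dplyr::mutate(instance = i)
  }) |> dplyr::bind_rows()
  out <- long |>
    dplyr::group_by(.data$epoch, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     half_width = 1.96 * sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(k = k)
  class(out) <- c("ad_bands", class(out))
  out
}

#' Plot metric means with confidence ribbons
#'
#' @param object An `ad_bands` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ad_bands <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epoch, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$half_width,
                                      ymax = .data$mean + .data$half_width),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
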