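#' Generate the labeled synthetic trajectory corpus
#'
#' Draws `n_per_class` trajectories for each of the four diffusion classes
#' (FBM, CD, DM, ND), each with fresh generative parameters and localization
#' noise derived from its signal-to-noise ratio, and assigns a stratified
#' 70/15/15 train/validation/test split. Every trajectory is generated under
#' its own child seed derived from `config$seed`, so the corpus is
#' bit-reproducible regardless of generation order.
#'
#' @param config An [sim_config()] object.
#' @param fractions Split fractions for train/validation/test; must sum to 1.
#'
#' @return A tibble of class `ad_dataset` with columns `id`, `label`,
#'   `split`, the generative-parameter columns of [sample_model_params()],
#'   and a list-column `traj` of trajectory tibbles.
#' @export
generate_dataset <- function(config = sim_config(),
                             fractions = c(0.70, 0.15, 0.15)) {
  classes <- diffusion_classes()
  recs <- purrr::imap(classes, function(cl, ci) {
    purrr::map(seq_len(config$n_per_class), function(i) {
      with_seed(derive_seed(config$seed, i, stream = ci), {
        p <- sample_model_params(cl, config)
        traj <- add_noise(simulate_trajectory(p), p$sigma_noise)
        dplyr::mutate(p, traj = list(traj))
      })
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  recs$label <- factor(recs$kind, levels = classes)
  recs$id <- sprintf("%06d", seq_len(nrow(recs)))
  out <- recs[, c("id", "label", "kind", "D", "N", "dt", "R", "v", "beta",
                  "B", "rc", "alpha", "H", "Q", "sigma_noise", "traj")]
  out <- stratified_split(out, fractions, seed = derive_seed(config$seed, 0L, 99L))
  attr(out, "sim_config") <- config
  class(out) <- c("ad_dataset", class(tibble()))
  out
}

#' Stratified train/validation/test split
#'
#' Partitions each class independently with the given fractions, so every
#' split preserves class balance. Within a class, counts follow the
#' largest-remainder rule (ties broken in split order train, validation,
#' test) and assignment is a seeded random shuffle.
#'
#' @param data Tibble with a `label` column.
#' @param fractions Numeric vector of three fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#'
#' @return `data` with a `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
stratified_split <- function(data, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (length(fractions) != 3) abort("`fractions` must have length 3 (train, validation, test).")
  splits <- c("train", "validation", "test")
  data$split <- factor(rep(NA_character_, nrow(data)), levels = splits)
  with_seed(seed, {
    for (cl in unique(data$label)) {
      idx <- which(data$label == cl)
      n <- length(idx)
      quota <- floor(fractions * n)
      rem <- fractions * n - quota
      short <- n - sum(quota)
      if (short > 0) {
        top <- order(rem, decreasing = TRUE)[seq_len(short)]
        quota[top] <- quota[top] + 1
      }
      assign_vec <- rep(splits, times = quota)
      data$split[idx] <- assign_vec[sample.int(n)]
    }
  })
  data
}

#' Encode trajectories as fixed-length network inputs
#'
#' Each trajectory is translated so its first position is the origin, then
#' its coordinates are interleaved (`x1, y1, x2, y2, ...`) into a single
#' input channel of length `2 * fixed_length`, zero-padded at the tail.
#' The interleaved single-channel layout is the one under which the network
#' family's trainable-parameter arithmetic reproduces the published counts.
#'
#' @param trajs List of trajectory tibbles (or an `ad_dataset`, whose `traj`
#'   column is used).
#' @param fixed_length Padded length in trajectory points (default 600, the
#'   maximum generated length).
#'
#' @return A list with `inputs` (array `c(channels, 2 * fixed_length, n)`),
#'   `lengths` (original point counts) and, when `trajs` is a dataset,
#'   `targets` (one-hot matrix `n x 4`) and `labels`.
#' @export
encode_trajectories <- function(trajs, fixed_length = 600L) {
  labels <- NULL
  if (inherits(trajs, "ad_dataset")) {
    labels <- trajs$label
    trajs <- trajs$traj
  }
  n <- length(trajs)
  L <- 2L * fixed_length
  inputs <- array(0, dim = c(1L, L, n))
  lengths <- integer(n)
  for (i in seq_len(n)) {
    tr <- trajs[[i]]
    np <- nrow(tr)
    if (np > fixed_length) {
      abort(sprintf("Trajectory %d has %d points, more than fixed_length = %d.",
                    i, np, fixed_length))
    }
    lengths[i] <- np
    v <- numeric(2L * np)
    v[seq(1, 2 * np, by = 2)] <- tr$x - tr$x[1]
    v[seq(2, 2 * np, by = 2)] <- tr$y - tr$y[1]
    inputs[1, seq_len(2L * np), i] <- v
  }
  out <- list(inputs = inputs, lengths = lengths)
  if (!is.null(labels)) {
    classes <- diffusion_classes()
    targets <- matrix(0, n, length(classes),
                      dimnames = list(NULL, classes))
    targets[cbind(seq_len(n), as.integer(factor(labels, levels = classes)))] <- 1
    out$targets <- targets
    out$labels <- factor(labels, levels = classes)
  }
  out
}

#' Write a dataset to a directory
#'
#' Writes one `t,x,y` CSV per trajectory plus a `manifest.csv` with columns
#' `id, file, label, split` and the generative-parameter columns. The
#' round-trip through [read_dataset()] is lossless for coordinates, labels,
#' splits and parameters.
#'
#' @param dataset An `ad_dataset` tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path("trajectories", paste0(dataset$id, ".csv"))
  dir.create(file.path(dir, "trajectories"), showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    readr::write_csv(dataset$traj[[i]], file.path(dir, files[i]), progress = FALSE)
  }
  manifest <- dataset |>
    dplyr::select(-"traj") |>
    dplyr::mutate(file = files, .after = "id")
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return An `ad_dataset` tibble.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) abort(sprintf("No manifest.csv under '%s'.", dir))
  manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  trajs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) {
      abort(sprintf("Row %d (id %s): trajectory file '%s' is missing.",
                    i, manifest$id[i], manifest$file[i]))
    }
    tr <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (!all(c("t", "x", "y") %in% names(tr))) {
      abort(sprintf("Row %d (id %s): malformed trajectory file.", i, manifest$id[i]))
    }
    trajs[[i]] <- structure(tr[, c("t", "x", "y")],
                            class = c("ad_trajectory", class(tibble())))
  }
  out <- manifest |>
    dplyr::select(-"file") |>
    dplyr::mutate(label = factor(.data$label, levels = diffusion_classes()),
                  split = factor(.data$split,
                                 levels = c("train", "validation", "test")),
                  traj = trajs)
  class(out) <- c("ad_dataset", class(tibble()))
  out
}
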