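#' Time-averaged mean squared displacement at one lag
#'
#' Discrete TAMSD of a 2-D trajectory at integer lag `n`:
#' `mean over i of |r_(i+n) - r_i|^2` with the average running over the
#' `N - n` available pairs.
#'
#' @param traj Trajectory tibble (`t`, `x`, `y`).
#' @param lag Integer lag in steps, `1 <= lag < nrow(traj)`.
#' @return TAMSD in um^2.
#' @export
tamsd <- function(traj, lag) {
  n <- nrow(traj)
  if (lag < 1 || lag >= n) abort("`lag` must satisfy 1 <= lag < n_points.")
  i <- seq_len(n - lag)
  mean((traj$x[i + lag] - traj$x[i])^2 + (traj$y[i + lag] - traj$y[i])^2)
}

#' TAMSD curve over a range of lags
#'
#' @param traj Trajectory tibble.
#' @param max_lag Largest lag in steps (default one quarter of the
#'   trajectory, the usual short-lag regime where the time average has good
#'   statistics).
#' @return A tibble of class `ad_tamsd` with columns `lag` (steps),
#'   `delta` (s) and `tamsd` (um^2).
#' @export
tamsd_curve <- function(traj, max_lag = max(1L, nrow(traj) %/% 4L)) {
  dt <- traj$t[2] - traj$t[1]
  lags <- seq_len(max_lag)
  out <- tibble(lag = lags, delta = lags * dt,
                tamsd = purrr::map_dbl(lags, ~ tamsd(traj, .x)))
  class(out) <- c("ad_tamsd", class(out))
  out
}

#' Fit the anomalous exponent to a trajectory's TAMSD
#'
#' Least-squares line fit of `log(tamsd)` against `log(lag * dt)` over lags
#' `1..max_lag`; the slope is the anomalous exponent `alpha` and the
#' intercept is `log(K_alpha)`, the generalized diffusion coefficient of the
#' power law `TAMSD ~ K_alpha * Delta^alpha`.
#'
#' @param traj Trajectory tibble.
#' @param max_lag Largest lag used in the fit (>= 2; default 10).
#' @return A one-row tibble with columns `alpha` and `K_alpha`.
#' @export
fit_anomalous_exponent <- function(traj, max_lag = 10L) {
  if (max_lag < 2) abort("`max_lag` must be at least 2.")
  curve <- tamsd_curve(traj, max_lag)
  if (any(curve$tamsd <= 0)) {
    abort("Degenerate trajectory: zero TAMSD at a fitted lag.")
  }
  fit <- lm(log(tamsd) ~ log(delta), data = curve)
  cf <- coef(fit)
  tibble(alpha = unname(cf[2]), K_alpha = exp(unname(cf[1])))
}

#' Theoretical ensemble MSD curves of the four diffusion models
#'
#' Evaluates the 2-D ensemble MSD at lag `delta` (seconds) for the chosen
#' model: `4 D delta` (ND), `4 D delta^alpha` (FBM),
#' `4 D delta + (v delta)^2` (DM) and
#' `rc^2 (1 - A1 exp(-4 A2 D delta / rc^2))` (CD), where `A1`, `A2` are
#' shape constants of the confinement (both default 1).
#'
#' @param kind One of `"ND"`, `"FBM"`, `"DM"`, `"CD"`.
#' @param delta Lag in seconds (> 0); vectorized.
#' @param D Diffusion coefficient (um^2/s).
#' @param alpha Anomalous exponent (FBM).
#' @param v Drift speed (DM, um/s).
#' @param rc Confinement radius (CD, um).
#' @param A1,A2 Confinement shape constants.
#' @return MSD in um^2.
#' @export
theoretical_msd <- function(kind, delta, D, alpha = NULL, v = NULL, rc = NULL,
                            A1 = 1, A2 = 1) {
  if (any(delta <= 0)) abort("`delta` must be positive.")
  switch(kind,
         ND = 4 * D * delta,
         FBM = 4 * D * delta^alpha,
         DM = 4 * D * delta + (v * delta)^2,
         CD = rc^2 * (1 - A1 * exp(-4 * A2 * D * delta / rc^2)),
         abort(sprintf("Unknown model kind '%s'.", kind)))
}

gyration_eigenvalues <- function(traj) {
  xc <- traj$x - mean(traj$x)
  yc <- traj$y - mean(traj$y)
  g <- matrix(c(mean(xc^2), mean(xc * yc), mean(xc * yc), mean(yc^2)), 2, 2)
  sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

#' Auxiliary scalar features of a trajectory
#'
#' The four hand-engineered attributes used as optional extra network
#' inputs:
#' \describe{
#'   \item{asymmetry}{`-log(1 - (l1 - l2)^2 / (2 (l1 + l2)^2))` from the
#'     gyration-tensor eigenvalues `l1 >= l2`; 0 for point-symmetric paths,
#'     `log 2` for a straight line.}
#'   \item{efficiency}{`|r_N - r_1|^2 / ((N - 1) * sum |r_(i+1) - r_i|^2)`;
#'     1 for a straight constant-speed path.}
#'   \item{fractal_dimension}{Katz's estimator
#'     `log(n) / (log(n) + log(d / L))` with `n` the step count, `L` the
#'     total path length and `d` the maximal distance from the first point;
#'     1 for a straight line, larger for space-filling paths.}
#'   \item{tamsd_lag20}{TAMSD at lag index 20 (um^2).}
#' }
#'
#' @param traj Trajectory tibble with more than 20 points.
#' @return A one-row tibble with the four features.
#' @export
compute_features <- function(traj) {
  n <- nrow(traj)
  if (n <= 20) abort("Trajectory must have more than 20 points.")
  ev <- gyration_eigenvalues(traj)
  asym <- -log(1 - (ev[1] - ev[2])^2 / (2 * (ev[1] + ev[2])^2))
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  net2 <- (traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2
  eff <- net2 / ((n - 1) * sum(steps^2))
  d <- max(sqrt((traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2))
  L <- sum(steps)
  fd <- log(n - 1) / (log(n - 1) + log(d / L))
  tibble(asymmetry = asym, efficiency = eff, fractal_dimension = fd,
         tamsd_lag20 = tamsd(traj, 20L))
}

#' Feature table for a set of trajectories
#'
#' Data-frame-first wrapper over [compute_features()]: one row per
#' trajectory, joined to the ids when `data` is an `ad_dataset`.
#'
#' @param data An `ad_dataset` or a list of trajectory tibbles.
#' @return A tibble with `id` (if available) and the four feature columns.
#' @export
feature_table <- function(data) {
  ids <- NULL
  trajs <- data
  if (inherits(data, "ad_dataset")) {
    ids <- data$id
    trajs <- data$traj
  }
  out <- purrr::map(trajs, compute_features) |> dplyr::bind_rows()
  if (!is.null(ids)) out <- dplyr::mutate(out, id = ids, .before = 1)
  out
}

#' Normalized autocorrelation of trajectory increments
#'
#' Sample autocorrelation of the per-coordinate increment (velocity-like)
#' series at the given lag, averaged over x and y. Positions themselves are
#' non-stationary, so the autocorrelation is taken on increments; negative
#' values at short lags are the signature of subdiffusive anti-persistence.
#'
#' @param traj Trajectory tibble.
#' @param lag Integer lag in steps, `0 <= lag < n_points - 1`.
#' @return Autocorrelation value in `[-1, 1]`.
#' @export
increment_autocorrelation <- function(traj, lag) {
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  m <- length(dx)
  if (lag >= m) abort("`lag` must be smaller than the number of increments.")
  acf1 <- function(z) {
    z <- z - mean(z)
    denom <- sum(z^2)
    if (denom == 0) abort("Constant trajectory: increment variance is zero.")
    if (lag == 0) return(1)
    i <- seq_len(m - lag)
    sum(z[i] * z[i + lag]) / denom
  }
  (acf1(dx) + acf1(dy)) / 2
}

#' Plot a TAMSD curve on log-log axes
#'
#' @param object An `ad_tamsd` tibble from [tamsd_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ad_tamsd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data$tamsd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Delta ~ "[s]"),
                  y = expression(delta^2 ~ "[µm²]"))
}
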