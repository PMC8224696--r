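#' Simulation configuration
#'
#' Defines the generative conditions for the synthetic corpus: the sampling
#' interval and the ranges from which per-trajectory parameters are drawn.
#' Defaults are the study conditions: trajectories of 30--600 points at
#' `dt = 1/30` s, diffusion coefficients 0.1--20 um^2/s, boundedness 1--6,
#' active-motion-to-diffusion ratio 1--17, anomalous exponent 0.3--0.7 and
#' signal-to-noise ratio 1--9, with 5000 trajectories per class.
#'
#' @param dt Sampling interval in seconds.
#' @param range_D Closed interval for the diffusion coefficient (um^2/s).
#' @param range_N Closed integer interval for the trajectory length (points).
#' @param range_B Closed interval for the boundedness parameter (CD only).
#' @param range_R Closed interval for the active-motion-to-diffusion ratio
#'   (DM only).
#' @param range_alpha Closed interval for the anomalous exponent (FBM only);
#'   the Hurst index is `alpha / 2`.
#' @param range_Q Closed interval for the signal-to-noise ratio.
#' @param n_per_class Trajectories generated per diffusion class.
#' @param fixed_length Padded length used when trajectories are encoded for
#'   the network; must be at least `max(range_N)`.
#' @param seed Root seed; every trajectory derives its own child seed from it.
#'
#' @return An object of class `ad_sim_config` (a named list).
#' @export
sim_config <- function(dt = 1 / 30,
                       range_D = c(0.1, 20),
                       range_N = c(30L, 600L),
                       range_B = c(1, 6),
                       range_R = c(1, 17),
                       range_alpha = c(0.3, 0.7),
                       range_Q = c(1, 9),
                       n_per_class = 5000L,
                       fixed_length = 600L,
                       seed = 1L) {
  ranges <- list(range_D = range_D, range_N = range_N, range_B = range_B,
                 range_R = range_R, range_alpha = range_alpha,
                 range_Q = range_Q)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("`%s` must be a finite interval c(lo, hi) with lo <= hi.", nm))
    }
  }
  if (dt <= 0) abort("`dt` must be positive.")
  if (n_per_class < 1) abort("`n_per_class` must be at least 1.")
  if (fixed_length < range_N[2]) {
    abort("`fixed_length` must be at least the upper trajectory-length bound.")
  }
  structure(
    list(dt = dt, range_D = as.numeric(range_D),
         range_N = as.integer(range_N), range_B = as.numeric(range_B),
         range_R = as.numeric(range_R), range_alpha = as.numeric(range_alpha),
         range_Q = as.numeric(range_Q), n_per_class = as.integer(n_per_class),
         fixed_length = as.integer(fixed_length), seed = as.integer(seed)),
    class = "ad_sim_config"
  )
}

runif_range <- function(r) if (r[1] == r[2]) r[1] else runif(1, r[1], r[2])

#' Drift speed from the active-motion-to-diffusion ratio
#'
#' The directed-motion simulator is parameterized by the dimensionless ratio
#' `R = v^2 T / (4 D)` comparing active transport to diffusive spreading over
#' the trajectory duration `T`; this inverts it to the drift speed.
#'
#' @param R Active-motion-to-diffusion ratio (dimensionless, >= 0).
#' @param D Diffusion coefficient (um^2/s, > 0).
#' @param T_total Trajectory duration `N * dt` in seconds (> 0).
#'
#' @return Drift speed in um/s: `sqrt(4 * D * R / T_total)`.
#' @export
drift_speed_from_ratio <- function(R, D, T_total) {
  if (any(R < 0)) abort("`R` must be non-negative.")
  if (any(D <= 0) || any(T_total <= 0)) abort("`D` and `T_total` must be positive.")
  sqrt(4 * D * R / T_total)
}

#' Confinement radius from the boundedness parameter
#'
#' Boundedness `B` compares the area a free Brownian walk of the same `D` and
#' duration would explore to the area of the confining circle,
#' `B ~ D N dt / rc^2`; this inverts it to the confinement radius.
#'
#' @param B Boundedness (dimensionless, > 0).
#' @param D Diffusion coefficient (um^2/s).
#' @param N Trajectory length in points.
#' @param dt Sampling interval in seconds.
#'
#' @return Confinement radius in um: `sqrt(D * N * dt / B)`.
#' @export
confinement_radius_from_boundedness <- function(B, D, N, dt) {
  if (any(B <= 0)) abort("`B` must be positive.")
  if (any(D <= 0) || any(N <= 0) || any(dt <= 0)) {
    abort("`D`, `N` and `dt` must be positive.")
  }
  sqrt(D * N * dt / B)
}

#' Localization-noise standard deviation from the signal-to-noise ratio
#'
#' The signal scale is the root-mean one-step displacement: `sqrt(D * dt)` for
#' ND, CD and FBM, and `sqrt(D * dt + (v * dt)^2)` for directed motion, whose
#' steps carry an extra deterministic drift component.
#'
#' @param Q Signal-to-noise ratio (> 0).
#' @param params One-row model-parameter tibble as returned by
#'   [sample_model_params()] (fields `kind`, `D`, `dt` and, for DM, `v`).
#'
#' @return Noise standard deviation sigma in um.
#' @export
noise_sigma_from_snr <- function(Q, params) {
  if (any(Q <= 0)) abort("`Q` must be positive.")
  signal <- if (identical(params$kind, "DM")) {
    sqrt(params$D * params$dt + (params$v * params$dt)^2)
  } else {
    sqrt(params$D * params$dt)
  }
  signal / Q
}

#' Draw per-trajectory generative parameters
#'
#' Samples one set of model parameters for a diffusion class. Continuous
#' parameters are drawn uniformly over their configured ranges and the length
#' `N` uniformly over integers; derived quantities (drift speed, confinement
#' radius, Hurst index, noise sigma) are computed from the drawn values.
#' Fields irrelevant to the class are `NA`.
#'
#' @param kind One of `"FBM"`, `"CD"`, `"DM"`, `"ND"`.
#' @param config An [sim_config()] object.
#'
#' @return A one-row tibble with columns `kind, D, N, dt, R, v, beta, B, rc,
#'   alpha, H, Q, sigma_noise`.
#' @export
sample_model_params <- function(kind, config = sim_config()) {
  if (!kind %in% diffusion_classes()) {
    abort(sprintf("`kind` must be one of %s.",
                  paste(diffusion_classes(), collapse = ", ")))
  }
  D <- runif_range(config$range_D)
  N <- if (config$range_N[1] == config$range_N[2]) config$range_N[1] else {
    sample(seq(config$range_N[1], config$range_N[2]), 1)
  }
  dt <- config$dt
  out <- tibble(kind = kind, D = D, N = as.integer(N), dt = dt,
                R = NA_real_, v = NA_real_, beta = NA_real_,
                B = NA_real_, rc = NA_real_,
                alpha = NA_real_, H = NA_real_,
                Q = NA_real_, sigma_noise = NA_real_)
  if (kind == "DM") {
    out$R <- runif_range(config$range_R)
    out$v <- drift_speed_from_ratio(out$R, D, N * dt)
    out$beta <- runif(1, 0, 2 * pi)
  } else if (kind == "CD") {
    out$B <- runif_range(config$range_B)
    out$rc <- confinement_radius_from_boundedness(out$B, D, N, dt)
  } else if (kind == "FBM") {
    out$alpha <- runif_range(config$range_alpha)
    out$H <- out$alpha / 2
  }
  out$Q <- runif_range(config$range_Q)
  out$sigma_noise <- noise_sigma_from_snr(out$Q, out)
  out
}

new_trajectory <- function(x, y, dt) {
  n <- length(x)
  structure(tibble(t = (seq_len(n) - 1) * dt, x = x, y = y),
            class = c("ad_trajectory", "tbl_df", "tbl", "data.frame"))
}

# Exact inverse-CDF Rayleigh step lengths with E[u^2] = 4 D dt.
rayleigh_steps <- function(n, D, dt) sqrt(-4 * D * dt * log1p(-runif(n)))

#' Simulate a normal-diffusion (Brownian) trajectory
#'
#' Each of the `N - 1` steps has an isotropic direction drawn uniformly on
#' `[0, 2*pi)` and a length drawn from the Rayleigh density with second moment
#' `4 D dt`. The trajectory starts at the origin and has `N` points at times
#' `0, dt, ..., (N-1) dt`.
#'
#' @param params One-row parameter tibble with `kind == "ND"` (fields `D`,
#'   `N`, `dt`); see [sample_model_params()].
#'
#' @return A trajectory tibble with columns `t` (s), `x`, `y` (um).
#' @export
simulate_nd <- function(params) {
  stopifnot(identical(params$kind, "ND"))
  check_dn(params)
  n <- params$N - 1L
  u <- rayleigh_steps(n, params$D, params$dt)
  phi <- runif(n, 0, 2 * pi)
  new_trajectory(c(0, cumsum(u * cos(phi))), c(0, cumsum(u * sin(phi))),
                 params$dt)
}

check_dn <- function(params) {
  if (!is.finite(params$D) || params$D <= 0) abort("`D` must be positive.")
  if (!is.finite(params$N) || params$N < 2) abort("`N` must be at least 2.")
  if (params$dt <= 0) abort("`dt` must be positive.")
}

#' Simulate a directed-motion trajectory
#'
#' A Brownian step (as in [simulate_nd()]) plus a deterministic per-step
#' drift `(v dt cos(beta), v dt sin(beta))`. The drift direction `beta` is a
#' single value for the whole trajectory; it is taken from `params$beta` or
#' drawn uniformly on `[0, 2*pi)` if absent.
#'
#' @param params One-row parameter tibble with `kind == "DM"` and drift speed
#'   `v` set (um/s).
#'
#' @return A trajectory tibble with columns `t`, `x`, `y`.
#' @export
simulate_dm <- function(params) {
  stopifnot(identical(params$kind, "DM"))
  check_dn(params)
  if (is.null(params$v) || is.na(params$v)) {
    abort("DM parameters must include the drift speed `v`.")
  }
  beta <- params$beta
  if (is.null(beta) || is.na(beta)) beta <- runif(1, 0, 2 * pi)
  n <- params$N - 1L
  u <- rayleigh_steps(n, params$D, params$dt)
  phi <- runif(n, 0, 2 * pi)
  dx <- u * cos(phi) + params$v * params$dt * cos(beta)
  dy <- u * sin(phi) + params$v * params$dt * sin(beta)
  new_trajectory(c(0, cumsum(dx)), c(0, cumsum(dy)), params$dt)
}

#' Simulate a confined-diffusion trajectory
#'
#' Diffusion inside a reflective circular boundary of radius `rc` centered on
#' the start position. Every recorded step is composed of 100 Brownian
#' substeps at `dt/100`; a substep is accepted only if the proposed position
#' lies strictly inside the circle, otherwise the particle stays in place for
#' that substep. Only the `N` per-step positions are recorded.
#'
#' @param params One-row parameter tibble with `kind == "CD"` and confinement
#'   radius `rc` set (um).
#'
#' @return A trajectory tibble with columns `t`, `x`, `y`.
#' @export
simulate_cd <- function(params) {
  stopifnot(identical(params$kind, "CD"))
  check_dn(params)
  if (is.null(params$rc) || is.na(params$rc) || params$rc <= 0) {
    abort("CD parameters must include a positive confinement radius `rc`.")
  }
  n_sub <- 100L
  n <- (params$N - 1L) * n_sub
  u <- rayleigh_steps(n, params$D, params$dt / n_sub)
  phi <- runif(n, 0, 2 * pi)
  pos <- cd_walk(u, phi, params$rc, n_sub)
  new_trajectory(c(0, pos[, 1]), c(0, pos[, 2]), params$dt)
}

#' Simulate a subdiffusive fractional Brownian motion trajectory
#'
#' `x` and `y` are independent fractional Brownian motion paths with Hurst
#' index `H`, sampled exactly at times `i * dt` (circulant-embedding of the
#' increment process, Cholesky fallback) and scaled by `sqrt(2 D)` so the 2-D
#' ensemble MSD is `4 D Delta^alpha` with `alpha = 2 H`.
#'
#' @param params One-row parameter tibble with `kind == "FBM"` and Hurst
#'   index `H` in (0, 1); values `>= 1/2` are outside the subdiffusive regime
#'   and trigger a warning.
#'
#' @return A trajectory tibble with columns `t`, `x`, `y`.
#' @export
simulate_fbm <- function(params) {
  stopifnot(identical(params$kind, "FBM"))
  check_dn(params)
  H <- params$H
  if (is.null(H) || is.na(H) || H <= 0 || H >= 1) {
    abort("FBM parameters must include a Hurst index `H` in (0, 1).")
  }
  if (H >= 0.5) {
    warn("`H` >= 1/2 is outside the subdiffusive regime targeted by the generator.")
  }
  s <- sqrt(2 * params$D)
  n <- params$N - 1L
  xi <- fgn_sample(n, H, params$dt)
  yi <- fgn_sample(n, H, params$dt)
  new_trajectory(s * c(0, cumsum(xi)), s * c(0, cumsum(yi)), params$dt)
}

#' Simulate one trajectory for any diffusion class
#'
#' Dispatches on `params$kind` to the class-specific simulator.
#'
#' @param params One-row parameter tibble from [sample_model_params()].
#' @return A trajectory tibble with columns `t`, `x`, `y`.
#' @export
simulate_trajectory <- function(params) {
  switch(params$kind,
         ND = simulate_nd(params),
         DM = simulate_dm(params),
         CD = simulate_cd(params),
         FBM = simulate_fbm(params),
         abort(sprintf("Unknown diffusion class '%s'; allowed: %s.",
                       params$kind,
                       paste(diffusion_classes(), collapse = ", "))))
}

#' Add Gaussian localization noise to a trajectory
#'
#' Independent zero-mean Gaussian noise with standard deviation `sigma` is
#' added to every coordinate of every position; times are unchanged.
#'
#' @param traj Trajectory tibble (`t`, `x`, `y`).
#' @param sigma Noise standard deviation in um (>= 0).
#'
#' @return The noisy trajectory tibble.
#' @export
add_noise <- function(traj, sigma) {
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (sigma == 0) return(traj)
  n <- nrow(traj)
  traj$x <- traj$x + rnorm(n, 0, sigma)
  traj$y <- traj$y + rnorm(n, 0, sigma)
  traj
}

#' Plot a trajectory in the xy-plane
#'
#' @param object Trajectory tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ad_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", colour = "t [s]")
}
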