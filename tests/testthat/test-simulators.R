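test_that("parameter sampling respects ranges and derived quantities", {
  cfg <- sim_config()
  set.seed(1)
  for (kind in diffusion_classes()) {
    for (i in 1:25) {
      p <- sample_model_params(kind, cfg)
      expect_true(p$D >= 0.1 && p$D <= 20)
      expect_true(p$N >= 30 && p$N <= 600)
      expect_equal(p$dt, 1 / 30)
      expect_true(p$Q >= 1 && p$Q <= 9)
      expect_gt(p$sigma_noise, 0)
      if (kind == "DM") {
        expect_true(p$R >= 1 && p$R <= 17)
        expect_equal(p$v, sqrt(4 * p$D * p$R / (p$N * p$dt)))
      }
      if (kind == "CD") {
        expect_true(p$B >= 1 && p$B <= 6)
        expect_equal(p$rc, sqrt(p$D * p$N * p$dt / p$B))
        expect_true(is.finite(p$rc) && p$rc > 0)
      }
      if (kind == "FBM") {
        expect_true(p$alpha >= 0.3 && p$alpha <= 0.7)
        expect_equal(p$H, p$alpha / 2)
        expect_true(p$H >= 0.15 && p$H <= 0.35)
      }
    }
  }
  expect_error(sample_model_params("LW", cfg), "FBM, CD, DM, ND")
})

test_that("degenerate zero-width ranges give deterministic parameters", {
  cfg <- sim_config(range_D = c(1, 1), range_N = c(50L, 50L),
                    range_B = c(1, 1), range_R = c(1, 1),
                    range_alpha = c(0.5, 0.5), range_Q = c(2, 2))
  set.seed(1)
  p <- sample_model_params("ND", cfg)
  expect_equal(p$D, 1)
  expect_equal(p$N, 50L)
  expect_equal(p$Q, 2)
})

test_that("ND steps have Rayleigh lengths and uniform headings", {
  set.seed(42)
  p <- make_params("ND", D = 1, N = 100001L)
  tr <- simulate_nd(p)
  u2 <- diff(tr$x)^2 + diff(tr$y)^2
  # E[u^2] = 4 D dt; Var[u^2] = (4 D dt)^2 (exponential), SE = 4Ddt/sqrt(n)
  m <- 4 * p$D * p$dt
  expect_lt(abs(mean(u2) - m), 3 * m / sqrt(length(u2)))
  phi <- atan2(diff(tr$y), diff(tr$x)) %% (2 * pi)
  ks <- stats::ks.test(phi, "punif", 0, 2 * pi)
  expect_gt(ks$p.value, 0.01)
})

test_that("near-zero diffusion gives a constant trajectory", {
  set.seed(1)
  tr <- simulate_nd(make_params("ND", D = 1e-300, N = 50L))
  expect_lt(max(abs(tr$x)) + max(abs(tr$y)), 1e-140)
  expect_error(simulate_nd(make_params("ND", D = -1)), "positive")
})

test_that("drift speed and confinement radius invert their ratios", {
  expect_equal(drift_speed_from_ratio(0, 2, 5), 0)
  expect_equal(drift_speed_from_ratio(1, 1, 10), sqrt(0.4), tolerance = 1e-12)
  expect_equal(round(drift_speed_from_ratio(1, 1, 10), 4), 0.6325)
  for (R in 1:17) {
    v <- drift_speed_from_ratio(R, 3, 7)
    expect_equal(v^2 * 7 / (4 * 3), R, tolerance = 1e-12)
  }
  expect_error(drift_speed_from_ratio(-1, 1, 1), "non-negative")

  expect_equal(confinement_radius_from_boundedness(1, 1, 300, 1 / 30),
               sqrt(10), tolerance = 1e-12)
  expect_equal(round(confinement_radius_from_boundedness(1, 1, 300, 1 / 30), 4),
               3.1623)
  r1 <- confinement_radius_from_boundedness(2, 1.3, 100, 0.05)
  r2 <- confinement_radius_from_boundedness(4, 1.3, 100, 0.05)
  expect_equal(r1^2 / 2, r2^2, tolerance = 1e-12)
  expect_error(confinement_radius_from_boundedness(0, 1, 10, 0.1), "positive")
})

test_that("directed motion adds the configured deterministic drift", {
  set.seed(9)
  p <- make_params("DM", D = 0.01, N = 300L, v = 1, beta = 0)
  tr <- simulate_dm(p)
  drift <- p$v * (p$N - 1) * p$dt
  sd_x <- sqrt(2 * p$D * (p$N - 1) * p$dt)
  expect_lt(abs((tr$x[p$N] - tr$x[1]) - drift), 3 * sd_x + p$v * p$dt)
  # v = 0 reduces to plain diffusion in second moments
  set.seed(10)
  tr0 <- simulate_dm(make_params("DM", D = 1, N = 50001L, v = 0, beta = 0))
  u2 <- diff(tr0$x)^2 + diff(tr0$y)^2
  m <- 4 / 30
  expect_lt(abs(mean(u2) - m), 3 * m / sqrt(length(u2)))
  expect_error(simulate_dm(make_params("DM", D = 1, N = 10L)), "drift speed")
})

test_that("sampled DM parameters are consistent with the stored ratio", {
  cfg <- sim_config()
  set.seed(4)
  for (i in 1:20) {
    p <- sample_model_params("DM", cfg)
    expect_equal(p$v^2 * (p$N * p$dt) / (4 * p$D), p$R, tolerance = 1e-10)
  }
})

test_that("confined diffusion never leaves the confinement circle", {
  set.seed(11)
  for (i in 1:20) {
    B <- runif(1, 1, 6)
    p <- make_params("CD", D = runif(1, 0.1, 20), N = 60L)
    p$rc <- confinement_radius_from_boundedness(B, p$D, p$N, p$dt)
    tr <- simulate_cd(p)
    r <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
    expect_true(all(r <= p$rc + 1e-12))
    expect_lte(tamsd(tr, p$N - 1L), 4 * p$rc^2)
  }
  expect_error(simulate_cd(make_params("CD", D = 1, N = 10L)), "confinement")
})

test_that("lower boundedness gives a higher confinement plateau", {
  set.seed(12)
  plateau <- function(B) {
    mean(replicate(200, {
      p <- make_params("CD", D = 1, N = 60L)
      p$rc <- confinement_radius_from_boundedness(B, p$D, p$N, p$dt)
      tamsd(simulate_cd(p), 40L)
    }))
  }
  expect_gt(plateau(1), plateau(6))
})

test_that("FBM increments have the exact fractional covariance", {
  set.seed(13)
  H <- 0.25
  dt <- 1 / 30
  n <- 6
  paths <- replicate(2000, cumsum(fgn_sample(n, H, dt)))
  emp <- stats::cov(t(paths))
  tt <- (1:n) * dt
  theo <- outer(tt, tt, function(a, b) {
    0.5 * (a^(2 * H) + b^(2 * H) - abs(a - b)^(2 * H))
  })
  pairs <- rbind(c(1, 1), c(2, 4), c(3, 3), c(1, 6), c(5, 6))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expect_lt(abs(emp[i, j] - theo[i, j]) / abs(theo[i, j]), 0.15)
  }
})

test_that("H = 1/2 increments are uncorrelated at distinct lags", {
  set.seed(14)
  z <- replicate(8000, suppressWarnings(
    fgn_sample(6, 0.5, 1)))
  expect_lt(abs(stats::cor(z[1, ], z[3, ])), 0.05)
  expect_lt(abs(stats::cor(z[2, ], z[6, ])), 0.05)
})

test_that("FBM ensemble MSD follows the anomalous power law", {
  set.seed(15)
  H <- 0.2
  D <- 1
  dtv <- 1 / 30
  p <- make_params("FBM", D = D, N = 64L, H = H)
  lag <- 8L
  disp <- replicate(2000, {
    tr <- simulate_fbm(p)
    (tr$x[1 + lag] - tr$x[1])^2 + (tr$y[1 + lag] - tr$y[1])^2
  })
  theo <- 4 * D * (lag * dtv)^(2 * H)
  expect_lt(abs(mean(disp) - theo) / theo, 0.05 + 3 / sqrt(2000))
  expect_error(simulate_fbm(make_params("FBM", D = 1, N = 10L, H = 1.2)),
               "Hurst")
  expect_warning(simulate_fbm(make_params("FBM", D = 1, N = 10L, H = 0.6)),
                 "subdiffusive")
})

test_that("noise sigma follows the signal-to-noise definition", {
  p_nd <- make_params("ND", D = 1, dt = 1 / 30)
  expect_equal(round(noise_sigma_from_snr(1, p_nd), 5), 0.18257)
  expect_lt(noise_sigma_from_snr(1e9, p_nd), 1e-9)
  p_dm0 <- make_params("DM", D = 1, dt = 1 / 30, v = 0)
  expect_equal(noise_sigma_from_snr(3, p_dm0), noise_sigma_from_snr(3, p_nd))
  p_dm <- make_params("DM", D = 1, dt = 1 / 30, v = 2)
  expect_equal(noise_sigma_from_snr(2, p_dm),
               sqrt(1 / 30 + (2 / 30)^2) / 2)
  expect_error(noise_sigma_from_snr(0, p_nd), "positive")
})

test_that("added localization noise has the requested variance and no xy correlation", {
  set.seed(16)
  n <- 100000L
  tr <- make_traj(numeric(n), numeric(n))
  noisy <- add_noise(tr, 0.1)
  v <- stats::var(noisy$x)
  se <- 0.01 * sqrt(2 / (n - 1))
  expect_lt(abs(v - 0.01), 3 * se)
  expect_lt(abs(stats::cor(noisy$x, noisy$y)), 0.02)
  expect_identical(add_noise(tr, 0), tr)
  expect_error(add_noise(tr, -0.1), "non-negative")
})

test_that("ND ensemble MSD matches 4 D k dt over lags", {
  set.seed(17)
  D <- 2
  p <- make_params("ND", D = D, N = 32L)
  trs <- replicate(2500, simulate_nd(p), simplify = FALSE)
  for (lag in c(1L, 4L, 16L)) {
    msd <- mean(vapply(trs, function(tr) {
      (tr$x[1 + lag] - tr$x[1])^2 + (tr$y[1 + lag] - tr$y[1])^2
    }, numeric(1)))
    theo <- 4 * D * lag * p$dt
    expect_lt(abs(msd - theo) / theo, 0.05 + 3 / sqrt(2500))
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_per_class = 3, range_N = c(30L, 60L), seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$label, d2$label)
  for (i in seq_len(nrow(d1))) {
    expect_identical(d1$traj[[i]], d2$traj[[i]])
  }
})
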