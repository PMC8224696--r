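final_arch <- arch_config()

test_that("feature-map width schedule doubles from the base", {
  expect_equal(feature_map_widths(64, 4), c(64L, 128L, 256L, 512L))
  expect_equal(feature_map_widths(32, 3), c(32L, 64L, 128L))
  expect_equal(feature_map_widths(1, 1), 1L)
  expect_error(feature_map_widths(0, 3), "at least 1")
})

test_that("final architecture counts 399,556 parameters, matching the golden manifest", {
  expect_identical(count_parameters(final_arch), 399556L)
  plan <- describe_network(final_arch)
  golden <- readr::read_csv(
    system.file("extdata", "final_architecture_layers.csv",
                package = "anomdiff"),
    show_col_types = FALSE)
  expect_equal(as.data.frame(plan), as.data.frame(golden))
  # the count of an actually built network agrees with the plan and with
  # the flattened parameter arrays themselves
  net <- build_network(final_arch)
  expect_identical(count_parameters(net), 399556L)
  expect_identical(sum(lengths(anomdiff:::net_params(net))), 399556L)
})

test_that("published counts across the configuration grid reproduce", {
  expect_identical(count_parameters(arch_config(x0 = 64)), 1590148L)
  expect_identical(count_parameters(arch_config(x0 = 16)), 100900L)
  expect_identical(count_parameters(arch_config(x0 = 64, kernel = 9)), 2823108L)
  expect_identical(
    count_parameters(arch_config(x0 = 64, kernel = 3, dimension = 2,
                                 depth = 4)),
    11220420L)
  expect_identical(
    count_parameters(arch_config(x0 = 64, kernel = 3, dimension = 2,
                                 depth = 4, use_xresnet = FALSE)),
    11177092L)
  # the 2-D 3x3 and 1-D 1x9 variants have identical parameter arithmetic
  expect_identical(
    count_parameters(arch_config(x0 = 64, kernel = 3, dimension = 2)),
    count_parameters(arch_config(x0 = 64, kernel = 9)))
})

test_that("each auxiliary feature adds exactly four head parameters", {
  base <- count_parameters(final_arch)
  for (f in c("asymmetry", "efficiency", "fractal_dimension", "tamsd_lag20")) {
    expect_identical(count_parameters(arch_config(aux_features = f)) - base, 4L)
  }
  all4 <- arch_config(aux_features = c("asymmetry", "efficiency",
                                       "fractal_dimension", "tamsd_lag20"))
  expect_identical(count_parameters(all4) - base, 16L)
})

test_that("a lone dense layer of 128 inputs and 4 outputs has 516 parameters", {
  plan <- describe_network(final_arch)
  head_row <- plan[plan$type == "dense", ]
  expect_equal(head_row$in_channels, 128L)
  expect_equal(head_row$params, 516L)
})

test_that("parameter count grows monotonically in x0, depth and kernel", {
  counts_x0 <- sapply(c(8, 16, 32, 64), function(x) {
    count_parameters(arch_config(x0 = x))
  })
  expect_true(all(diff(counts_x0) > 0))
  counts_depth <- sapply(1:4, function(d) {
    count_parameters(arch_config(depth = d))
  })
  expect_true(all(diff(counts_depth) > 0))
  counts_k <- sapply(c(3, 5, 7, 9, 11), function(k) {
    count_parameters(arch_config(kernel = k))
  })
  expect_true(all(diff(counts_k) > 0))
  expect_error(arch_config(kernel = 4), "odd")
})

test_that("network outputs are softmax probabilities", {
  set.seed(41)
  net <- build_network(arch_config(x0 = 8, fixed_length = 32))
  x <- array(rnorm(1 * 64 * 5), dim = c(1, 64, 5))
  probs <- anomdiff:::net_forward(net, x, training = FALSE)$probs
  expect_equal(dim(probs), c(4L, 5L))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(colSums(probs), rep(1, 5), tolerance = 1e-6)
})

test_that("residual units are the identity at initialization", {
  set.seed(42)
  net <- build_network(arch_config(x0 = 8, fixed_length = 32))
  # stage-1 units have identity shortcuts and zero-initialized final batch
  # norm scale, so on a non-negative input the unit returns its input
  unit <- net$stages[[1]][[1]]
  expect_true(all(unit$bn2$gamma == 0))
  x <- array(abs(rnorm(8 * 16 * 3)), dim = c(8, 16, 3))
  out <- anomdiff:::unit_fw(x, unit, "relu", training = FALSE, pad = 2L)$y
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("forward pass is deterministic in evaluation mode", {
  set.seed(43)
  net <- build_network(arch_config(x0 = 8, fixed_length = 32))
  x <- array(rnorm(1 * 64 * 4), dim = c(1, 64, 4))
  p1 <- anomdiff:::net_forward(net, x, training = FALSE)$probs
  p2 <- anomdiff:::net_forward(net, x, training = FALSE)$probs
  expect_identical(p1, p2)
  # duplicated input rows give identical outputs
  x2 <- x
  x2[, , 2] <- x[, , 1]
  p3 <- anomdiff:::net_forward(net, x2, training = FALSE)$probs
  expect_equal(p3[, 2], p3[, 1], tolerance = 1e-12)
})

test_that("width schedule of built networks matches feature_map_widths", {
  for (d in 2:4) {
    net <- build_network(arch_config(x0 = 16, depth = d, fixed_length = 64))
    widths <- vapply(net$stages, function(s) s[[1]]$out_ch, integer(1))
    expect_equal(widths, feature_map_widths(16, d))
  }
})

test_that("compiled convolution agrees with the sparse-matrix reference path", {
  set.seed(44)
  for (cfgs in list(c(3, 40, 4, 6, 5, 1L), c(8, 21, 2, 8, 3, 2L))) {
    C <- cfgs[1]; L <- cfgs[2]; B <- cfgs[3]; Co <- cfgs[4]; k <- cfgs[5]
    st <- cfgs[6]
    x <- array(rnorm(C * L * B), dim = c(C, L, B))
    W <- matrix(rnorm(Co * C * k), Co)
    pad <- (k - 1L) %/% 2L
    y <- anomdiff:::conv1d_fw(x, W, st, pad)
    y_ref <- anomdiff:::conv1d_fw_ref(x, W, st, pad)
    expect_equal(y, y_ref, tolerance = 1e-5)
    dy <- array(rnorm(length(y)), dim = dim(y))
    b <- anomdiff:::conv1d_bw(dy, x, W, st, pad)
    b_ref <- anomdiff:::conv1d_bw_ref(dy, x, W, st, pad)
    expect_equal(b$dx, b_ref$dx, tolerance = 1e-5)
    expect_equal(b$dW, b_ref$dW, tolerance = 1e-5)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(45)
  withr::local_options(anomdiff.precision = "double")
  net <- build_network(arch_config(x0 = 8, fixed_length = 8, kernel = 3))
  p <- anomdiff:::net_params(net)
  for (nm in names(p)) {
    if (grepl("bn2.gamma", nm)) p[[nm]] <- runif(length(p[[nm]]), 0.5, 1)
  }
  net <- anomdiff:::net_set_params(net, p)
  B <- 3
  x <- array(rnorm(1 * 16 * B), dim = c(1, 16, B))
  y <- matrix(0, 4, B)
  y[cbind(sample(1:4, B, replace = TRUE), 1:B)] <- 1
  w <- rep(1 / B, B)
  loss_of <- function(net, cost) {
    f <- anomdiff:::net_forward(net, x, training = TRUE)
    sum(anomdiff:::per_sample_loss(f$probs, y, cost) * w)
  }
  for (cost in c("mse", "cross_entropy")) {
    f <- anomdiff:::net_forward(net, x, training = TRUE)
    dz <- anomdiff:::logit_gradient(f$probs, y, w, cost)
    gr <- anomdiff:::net_backward(f$net, dz, f$caches)
    for (nm in sample(names(p), 12)) {
      i <- sample(length(p[[nm]]), 1)
      eps <- 1e-6
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- loss_of(anomdiff:::net_set_params(net, pp), cost)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- loss_of(anomdiff:::net_set_params(net, pp), cost)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip weights and reject mismatched configs", {
  set.seed(46)
  net <- build_network(arch_config(x0 = 8, fixed_length = 32))
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  back <- load_network(path)
  expect_equal(anomdiff:::net_params(back), anomdiff:::net_params(net))
  x <- array(rnorm(64 * 2), dim = c(1, 64, 2))
  expect_equal(anomdiff:::net_forward(back, x, training = FALSE)$probs,
               anomdiff:::net_forward(net, x, training = FALSE)$probs)
})

test_that("tidy and glance summarize a network", {
  net <- build_network(arch_config(x0 = 8, fixed_length = 32))
  td <- tidy(net)
  expect_true(all(c("layer", "params") %in% names(td)))
  g <- glance(net)
  expect_equal(g$parameters, sum(td$params))
  expect_equal(g$depth, 3L)
})
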