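test_that("selective backprop selects by loss coverage and top fraction", {
  losses <- c(0.7, 0.2, 0.08, 0.02)
  expect_equal(select_backprop_subset(losses, "loss_coverage", 0.98), 1:3)
  expect_equal(select_backprop_subset(losses, "top_fraction", 0.5), 1:2)
  expect_equal(select_backprop_subset(losses, "loss_coverage", 1.0), 1:4)
  expect_equal(select_backprop_subset(losses, "none"), 1:4)
  # all-zero losses with coverage mode select everything
  expect_equal(select_backprop_subset(rep(0, 5), "loss_coverage", 0.98), 1:5)
  # ties broken by original index
  expect_equal(select_backprop_subset(c(0.5, 0.5, 0.5), "top_fraction", 1 / 3), 1L)
  expect_error(select_backprop_subset(numeric(0), "none"), "non-empty")
  expect_error(select_backprop_subset(c(-1, 2), "none"), "non-negative")
})

test_that("an easily separable subset is overfit to high accuracy", {
  set.seed(61)
  cfg <- sim_config(n_per_class = 25, range_N = c(60L, 64L),
                    range_R = c(17, 17), range_Q = c(1e9, 1e9),
                    fixed_length = 64L, seed = 21)
  ds <- generate_dataset(cfg)
  ds <- ds[ds$label %in% c("ND", "DM"), ]
  class(ds) <- c("ad_dataset", class(tibble::tibble()))
  fit <- train(build_network(arch_config(x0 = 16, fixed_length = 64L)), ds,
               train_config(batch_size = 8, learning_rate = 1e-3,
                            max_epochs = 100, seed = 8))
  expect_gte(max(fit$history$train_accuracy), 0.99)
})

test_that("single-epoch training reports best epoch 1 and full coverage", {
  ds <- small_dataset()
  fit <- train(build_network(arch_config(x0 = 8, fixed_length = 64L)), ds,
               train_config(batch_size = 8, max_epochs = 1, seed = 3))
  expect_equal(fit$best_epoch, 1L)
  expect_equal(nrow(fit$history), 1L)
  # selective_mode none touches every training sample exactly once
  expect_equal(fit$history$bp_fraction, 1)
  g <- glance(fit)
  expect_equal(g$epochs, 1L)
})

test_that("training is deterministic for a fixed seed and data", {
  ds <- small_dataset()
  tc <- train_config(batch_size = 8, max_epochs = 2, seed = 12)
  arch <- arch_config(x0 = 8, fixed_length = 64L)
  f1 <- train(build_network(arch), ds, tc)
  f2 <- train(build_network(arch), ds, tc)
  expect_identical(anomdiff:::net_params(f1$network),
                   anomdiff:::net_params(f2$network))
  expect_equal(f1$history, f2$history)
})

test_that("predictions are probability rows with stable batch behavior", {
  ds <- small_dataset()
  set.seed(64)
  net <- build_network(arch_config(x0 = 8, fixed_length = 64L))
  preds <- predict_trajectories(net, ds)
  pm <- as.matrix(preds[, paste0(".pred_", diffusion_classes())])
  expect_equal(unname(rowSums(pm)), rep(1, nrow(ds)), tolerance = 1e-6)
  expect_true(all(pm >= 0 & pm <= 1))
  # batch-order independence: evaluating a subset gives the same rows
  sub <- predict_trajectories(net, ds$traj[c(3, 1)])
  expect_equal(as.numeric(sub[2, 1:4]), as.numeric(preds[1, 1:4]),
               tolerance = 1e-5)
  # coarse labels follow the four-to-three mapping
  expect_true(all(preds$.pred_coarse[preds$.pred_class == "DM"] ==
                    "superdiffusion"))
  # over-length trajectories are rejected
  long_tr <- make_traj(seq_len(100), seq_len(100))
  expect_error(predict_trajectories(net, list(long_tr)), "fixed_length")
})

test_that("mse and cross-entropy training both learn on an easy subset", {
  set.seed(62)
  cfg <- sim_config(n_per_class = 20, range_N = c(60L, 64L),
                    range_R = c(17, 17), range_Q = c(1e9, 1e9),
                    fixed_length = 64L, seed = 31)
  ds <- generate_dataset(cfg)
  ds <- ds[ds$label %in% c("ND", "DM"), ]
  class(ds) <- c("ad_dataset", class(tibble::tibble()))
  arch <- arch_config(x0 = 16, fixed_length = 64L)
  accs <- sapply(c("mse", "cross_entropy"), function(cost) {
    fit <- train(build_network(arch), ds,
                 train_config(batch_size = 16, max_epochs = 20, seed = 9,
                              cost = cost))
    max(fit$history$validation_accuracy)
  })
  expect_gte(accs[["mse"]], 0.85)
  expect_gte(accs[["cross_entropy"]], 0.85)
})

test_that("selective backprop reduces the back-propagated fraction", {
  set.seed(63)
  cfg <- sim_config(n_per_class = 20, range_N = c(60L, 64L),
                    range_R = c(17, 17), range_Q = c(1e9, 1e9),
                    fixed_length = 64L, seed = 41)
  ds <- generate_dataset(cfg)
  fit <- train(build_network(arch_config(x0 = 16, fixed_length = 64L)), ds,
               train_config(batch_size = 32, max_epochs = 8, seed = 10,
                            selective_mode = "loss_coverage",
                            selective_fraction = 0.98))
  expect_true(all(fit$history$bp_fraction <= 1))
  expect_lt(min(fit$history$bp_fraction), 1)
  # top_fraction always takes the configured share
  fit2 <- train(build_network(arch_config(x0 = 16, fixed_length = 64L)), ds,
                train_config(batch_size = 32, max_epochs = 2, seed = 10,
                             selective_mode = "top_fraction",
                             selective_fraction = 0.5))
  expect_equal(fit2$history$bp_fraction, rep(0.5, 2), tolerance = 0.05)
})

test_that("training rejects datasets without usable splits", {
  ds <- small_dataset()
  broken <- ds[ds$split == "train", ]
  class(broken) <- c("ad_dataset", class(tibble::tibble()))
  expect_error(train(build_network(arch_config(x0 = 8, fixed_length = 64L)),
                     broken, train_config(max_epochs = 1)),
               "validation")
})
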