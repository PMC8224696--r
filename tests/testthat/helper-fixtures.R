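# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code under fixed seeds; nothing is read from
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A trajectory from explicit coordinates (dt = 1 unless times given).
make_traj <- function(x, y, dt = 1) {
  structure(tibble::tibble(t = (seq_along(x) - 1) * dt, x = x, y = y),
            class = c("ad_trajectory", class(tibble::tibble())))
}

# Params row for direct simulator calls.
make_params <- function(kind, D = 1, N = 100L, dt = 1 / 30, ...) {
  extra <- list(...)
  p <- tibble::tibble(kind = kind, D = D, N = as.integer(N), dt = dt,
                      R = NA_real_, v = NA_real_, beta = NA_real_,
                      B = NA_real_, rc = NA_real_, alpha = NA_real_,
                      H = NA_real_, Q = NA_real_, sigma_noise = NA_real_)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  p
}

# Small labeled dataset shared across dataset/model/training tests.
small_dataset <- function() {
  fixture("small_dataset", function() {
    generate_dataset(sim_config(n_per_class = 8, range_N = c(40L, 64L),
                                fixed_length = 64L, seed = 303))
  })
}

# The scaled study run shared by the training-scale acceptance checks:
# 2,000 trajectories under the default generative conditions, the final
# architecture, 10 epochs. Built once; several acceptance tests read it.
scaled_study_run <- function() {
  fixture("scaled_study_run", function() {
    cfg <- sim_config(n_per_class = 500, seed = 101)
    ds <- generate_dataset(cfg)
    # batch and learning rate are scaled with the dataset so the 10-epoch
    # budget yields a comparable optimization effort to the full protocol
    tc <- train_config(batch_size = 64, learning_rate = 2e-3,
                       max_epochs = 10, seed = 101)
    fit <- train(build_network(arch_config()), ds, tc)
    list(dataset = ds, fit = fit,
         val_report = evaluate(fit, ds, split = "validation"),
         report = evaluate(fit, ds, split = "test"))
  })
}
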