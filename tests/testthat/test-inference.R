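test_that("average reconstruction error reduces to the recent-window mean", {
  expect_equal(average_reconstruction_error(rep(0, 50), 30), 0)
  expect_equal(average_reconstruction_error(rep(0.7, 50), 30), 0.7)
  # ramp: mean over the most recent window computed by direct summation
  e <- (1:300) / 300
  brute <- sum(e[201:300]) / 100
  expect_equal(average_reconstruction_error(e, 100), brute)
  # fewer steps than the window: average what exists
  expect_equal(average_reconstruction_error(c(0.2, 0.4), 300), 0.3)
  expect_error(average_reconstruction_error(numeric(0), 10), "errors")
})

test_that("inference config validation enforces the window relations", {
  expect_error(inference_config(window_len = 100, error_window = 200))
  expect_error(inference_config(error_window = 0))
  expect_error(inference_config(inner_epochs = 0))
  cfg <- inference_config()
  expect_equal(cfg$window_len, 400L)
  expect_equal(cfg$error_window, 300L)
})

test_that("a zero inner learning rate leaves A unchanged but yields records", {
  net <- tiny_net()
  cfg <- inference_config(window_len = 10, error_window = 5,
                          inner_epochs = 3, inner_lr = 0, seed = 1)
  state <- new_window_state(net)
  withr::with_seed(1, {
    for (t in 1:4) {
      out <- perceive_step(state, c(0.1 * t, -0.1 * t), net,
                           w_current = c(1, 1), cfg)
      state <- out$state
    }
  })
  expect_true(all(vapply(state$A, function(a) all(a == 0), logical(1))))
  expect_length(out$record$err, 4)
  expect_equal(dim(out$record$xbar), c(4, 2))
  expect_true(is.finite(out$record$er_sum))
})

test_that("the sliding window keeps exactly window_len steps and a consistent anchor", {
  net <- tiny_net(seed = 21)
  wl <- 6
  cfg <- inference_config(window_len = wl, error_window = 3,
                          inner_epochs = 2, inner_lr = 0.05, seed = 2)
  Tn <- 15
  X <- withr::with_seed(3, matrix(runif(Tn * 2, -0.5, 0.5), Tn, 2))
  state <- new_window_state(net)
  withr::with_seed(2, {
    for (t in seq_len(Tn)) {
      state <- perceive_step(state, X[t, ], net, c(0.1, 0.1), cfg)$state
    }
  })
  expect_equal(nrow(state$buffer), wl)
  expect_equal(state$buffer, X[(Tn - wl + 1):Tn, , drop = FALSE])
  for (a in state$A) expect_equal(ncol(a), wl)
  expect_equal(state$anchor_t, Tn - wl)

  # with no stochastic units the anchor chain is deterministic, so the
  # anchor must equal an independent replay of the evicted prefix
  dnet <- pvrnn_net(list(layer_spec(3, 0, 2, 0), layer_spec(2, 0, 4, 0)),
                    n_out = 2, seed = 22)
  sv <- pvrnn:::spec_vectors(dnet$specs)
  state2 <- new_window_state(dnet)
  withr::with_seed(2, {
    for (t in seq_len(Tn)) {
      state2 <- perceive_step(state2, X[t, ], dnet, c(0.1, 0.1), cfg)$state
    }
  })
  expect_equal(state2$anchor_t, Tn - wl)
  replay <- evaluate_window(dnet, targets = X[seq_len(Tn - wl), , drop = FALSE],
                            A = adaptive_sequence(dnet, Tn - wl),
                            eps = lapply(sv$n_z, function(nz) matrix(0, nz, Tn - wl)),
                            z_source = "posterior", unit_prior_first = TRUE)
  for (l in 1:2) {
    expect_equal(as.numeric(state2$anchor$d[[l]]),
                 as.numeric(replay$frames[[l]]$d[, Tn - wl]),
                 tolerance = 1e-12)
    expect_equal(as.numeric(state2$anchor$h[[l]]),
                 as.numeric(replay$frames[[l]]$h[, Tn - wl]),
                 tolerance = 1e-12)
  }
})

test_that("perception runs are deterministic given the seed", {
  net <- tiny_net(seed = 5)
  X <- withr::with_seed(9, matrix(runif(24, -0.5, 0.5), 12, 2))
  cfg <- inference_config(window_len = 8, error_window = 4,
                          inner_epochs = 3, inner_lr = 0.05, seed = 77)
  p1 <- perceive(net, X, cfg, w = c(0.1, 0.1))
  p2 <- perceive(net, X, cfg, w = c(0.1, 0.1))
  expect_identical(p1$log, p2$log)
  cfg2 <- cfg; cfg2$seed <- 78L
  p3 <- perceive(net, X, cfg2, w = c(0.1, 0.1))
  expect_false(identical(p1$log, p3$log))
})

test_that("low-w perception tracks a trained pattern; high-w decouples from it", {
  fit <- reduced_model()
  spec_gen <- reduced_generator()
  target <- repeat_pattern(spec_gen$patterns[[1]], 14)
  icfg <- reduced_inference_config(seed = 3)
  p_low <- perceive(fit$net, target, icfg, w = c(0.01, 0.01))
  p_high <- perceive(fit$net, target, icfg, w = c(100, 100))
  tail_idx <- 201:420
  low_err <- mean(p_low$log$window_mse[tail_idx])
  high_err <- mean(p_high$log$window_mse[tail_idx])
  expect_lt(low_err, 0.05)       # sensory-driven regime reconstructs the target
  expect_gt(high_err, low_err)   # top-down regime deviates from it
})

test_that("the controller is wired causally into the perception loop", {
  # a hot controller flips essentially every active step, so both directions
  # are exercised even on an untrained network; the log and the transition
  # record must stay mutually consistent and respect the warm-up
  net <- tiny_net(seed = 8)
  X <- withr::with_seed(13, matrix(runif(160, -0.5, 0.5), 80, 2))
  cfg <- inference_config(window_len = 20, error_window = 10,
                          inner_epochs = 2, inner_lr = 0.05, seed = 21)
  hot <- controller_config(temperature = 10)
  run <- perceive(net, X, cfg, controller = hot)
  tr <- run$transitions
  expect_gte(sum(tr$from == "FS" & tr$to == "MW"), 1)
  expect_gte(sum(tr$from == "MW" & tr$to == "FS"), 1)
  # controller inactive during warm-up
  expect_true(all(tr$t >= cfg$error_window))
  expect_true(all(run$log$state[seq_len(cfg$error_window - 1)] == "FS"))
  # logged regime matches the transition record step by step
  reg <- "FS"
  for (i in seq_len(nrow(run$log))) {
    hit <- tr[tr$t == i, ]
    if (nrow(hit) == 1) reg <- hit$to
    expect_identical(run$log$state[i], reg)
  }
  # logged meta-priors follow the regime
  expect_true(all(run$log$w_l1[run$log$state == "FS"] == hot$w_low[1]))
  expect_true(all(run$log$w_l1[run$log$state == "MW"] == hot$w_high[1]))
})
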