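test_that("kl_unit matches closed-form cases and is non-negative", {
  expect_equal(kl_unit(0.3, 1.2, 0.3, 1.2), 0)
  expect_equal(kl_unit(1, 1, 0, 1), 0.5)
  # analytic: mu_q=0, mu_p=0, sigma_q=2, sigma_p=1
  expect_equal(kl_unit(0, 2, 0, 1), log(1 / 2) + 4 / 2 - 0.5)
  expect_error(kl_unit(0, -1, 0, 1), "positive")
  expect_error(kl_unit(0, 1, 0, 0), "positive")
  withr::with_seed(11, {
    for (i in 1:200) {
      kq <- kl_unit(rnorm(1, 0, 2), exp(rnorm(1)), rnorm(1, 0, 2),
                    exp(rnorm(1)))
      expect_gte(kq, 0)
    }
  })
})

test_that("kl_unit agrees with a Monte-Carlo divergence estimate", {
  # E_q[log q(z) - log p(z)] by direct sampling, independent of the formula
  withr::with_seed(42, {
    for (i in 1:5) {
      mq <- rnorm(1); mp <- rnorm(1)
      sq <- exp(rnorm(1, 0, 0.5)); sp <- exp(rnorm(1, 0, 0.5))
      z <- rnorm(2e5, mq, sq)
      samp <- dnorm(z, mq, sq, log = TRUE) - dnorm(z, mp, sp, log = TRUE)
      expect_equal(kl_unit(mq, sq, mp, sp), mean(samp),
                   tolerance = 5 * sd(samp) / sqrt(length(z)) /
                     max(abs(mean(samp)), 1e-3))
    }
  })
})

test_that("prior and posterior heads reduce to their closed forms", {
  net <- tiny_net()
  # zero everything: unit Gaussian
  net0 <- net
  net0$params$W_mu[[1]][] <- 0
  net0$params$W_sg[[1]][] <- 0
  pr <- compute_prior(c(1, -1, 0.5), net0, 1)
  expect_equal(pr$mu, c(0, 0))
  expect_equal(pr$sigma, c(1, 1))
  # sigma bias ln 2 -> sigma = 2
  net0$params$b_sg_p[[1]][] <- log(2)
  expect_equal(compute_prior(c(1, -1, 0.5), net0, 1)$sigma, c(2, 2))
  # tanh keeps the mean inside (-1, 1) for any input
  withr::with_seed(8, {
    for (i in 1:20) {
      pr <- compute_prior(rnorm(3, 0, 2), net, 1)
      expect_true(all(abs(pr$mu) < 1))
      expect_true(all(pr$sigma > 0))
    }
  })
  # A = 0 with matching biases reproduces the prior
  netq <- net
  netq$params$b_mu_q <- netq$params$b_mu_p
  netq$params$b_sg_q <- netq$params$b_sg_p
  d <- c(0.2, -0.4, 0.1)
  A0 <- list(mu = c(0, 0), sigma = c(0, 0))
  expect_equal(compute_posterior(d, A0, netq, 1), compute_prior(d, netq, 1))
  # large negative A_sigma collapses the posterior
  Aneg <- list(mu = c(0, 0), sigma = c(-8, -8))
  expect_lt(max(compute_posterior(d, Aneg, netq, 1)$sigma), 1e-2)
  expect_error(compute_posterior(d, NULL, net, 1), "adaptive")
})

test_that("sample_z is a correct reparameterized draw", {
  expect_equal(sample_z(c(1, 2), c(1e-12, 1e-12), eps = c(1, -1)), c(1, 2),
               tolerance = 1e-9)
  expect_error(sample_z(0, 0), "positive")
  withr::with_seed(4, {
    z <- replicate(1e5, sample_z(0.7, 2))
    expect_lt(abs(mean(z) - 0.7), 3 * 2 / sqrt(1e5))
  })
  withr::with_seed(9, z1 <- sample_z(c(0, 0), c(1, 1)))
  withr::with_seed(9, z2 <- sample_z(c(0, 0), c(1, 1)))
  expect_identical(z1, z2)
})

test_that("recurrent step follows the leaky-integrator update", {
  net <- tiny_net()
  # zero all weights/biases
  zero <- net
  for (nm in c("W_dd", "W_zd", "W_td", "W_bu", "b_h", "W_mu", "W_sg"))
    zero$params[[nm]] <- lapply(zero$params[[nm]], function(m) { m[] <- 0; m })
  prev <- latent_frame_init(zero)
  prev$layers[[1]]$h <- c(1, -2, 4)
  prev$layers[[1]]$d <- tanh(prev$layers[[1]]$h)
  fr <- forward_step(prev, "prior", zero, eps = list(c(0, 0), 0))
  expect_equal(fr$layers[[1]]$h, 0.5 * c(1, -2, 4))  # tau = 2, zero drive
  expect_equal(fr$layers[[1]]$d, tanh(0.5 * c(1, -2, 4)))

  # tau = 1 with constant bias pins h at the bias
  one <- zero
  one$specs[[1]] <- layer_spec(3, 2, 1, 0.5)
  one$params$b_h[[1]][] <- c(0.3, -0.1, 2)
  fr1 <- forward_step(prev, "prior", one, eps = list(c(0, 0), 0))
  fr2 <- forward_step(fr1, "prior", one, eps = list(c(0, 0), 0))
  expect_equal(fr1$layers[[1]]$h, c(0.3, -0.1, 2))
  expect_equal(fr2$layers[[1]]$h, c(0.3, -0.1, 2))

  # d stays strictly inside (-1, 1) under large random drive
  big <- tiny_net(seed = 5)
  big$params$b_h[[1]][] <- 5
  fr3 <- forward_step(latent_frame_init(big), "prior", big)
  expect_true(all(abs(fr3$layers[[1]]$d) < 1))
})

test_that("readout is a bounded tanh-affine map of the bottom layer", {
  net <- tiny_net()
  z <- net
  z$params$W_out[] <- 0
  z$params$b_out[] <- 0
  expect_equal(readout(c(1, 2, 3), z), c(0, 0))
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- readout(rnorm(3, 0, 5), net)
      expect_true(all(abs(x) < 1))
    }
  })
})

test_that("stepwise R evaluation and the compiled window evaluation agree", {
  net <- tiny_net()
  Tn <- 6
  X <- withr::with_seed(1, matrix(runif(Tn * 2, -0.5, 0.5), Tn, 2))
  A <- random_A(net, Tn)
  eps <- random_eps(net, Tn)
  res <- evaluate_window(net, X, A = A, eps = eps, z_source = "posterior",
                         unit_prior_first = TRUE)

  prev <- latent_frame_init(net)
  frames <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    A_t <- pvrnn:::split_A_col(A, net, t)
    e_t <- lapply(eps, function(m) m[, t])
    prev <- forward_step(prev, "posterior", net, A_t = A_t, eps = e_t,
                         unit_prior = (t == 1))
    frames[[t]] <- prev
  }
  fe_r <- free_energy(frames, X, net)
  expect_equal(fe_r$total, res$fe$total, tolerance = 1e-12)
  expect_equal(fe_r$complexity_per_layer, as.numeric(res$fe$complexity),
               tolerance = 1e-12)
  expect_equal(fe_r$accuracy, res$fe$accuracy, tolerance = 1e-12)
  d_r <- vapply(frames, function(f) f$layers[[1]]$d, numeric(3))
  expect_equal(unname(res$frames[[1]]$d), unname(d_r), tolerance = 1e-12)
})

test_that("free energy vanishes when posterior equals prior and output equals target", {
  net <- tiny_net()
  Tn <- 4
  # posterior == prior: same biases, A = 0; evaluate at the posterior mean
  netq <- net
  netq$params$b_mu_q <- netq$params$b_mu_p
  netq$params$b_sg_q <- netq$params$b_sg_p
  A0 <- adaptive_sequence(netq, Tn)
  eps0 <- lapply(pvrnn:::spec_vectors(net$specs)$n_z,
                 function(nz) matrix(0, nz, Tn))
  res <- evaluate_window(netq, matrix(0, Tn, 2), A = A0, eps = eps0,
                         z_source = "posterior", unit_prior_first = FALSE)
  expect_equal(sum(res$fe$complexity), 0, tolerance = 1e-12)
  # feed xbar back as the target: accuracy term vanishes too
  res2 <- evaluate_window(netq, res$xbar, A = A0, eps = eps0,
                          z_source = "posterior", unit_prior_first = FALSE)
  expect_equal(res2$fe$total, 0, tolerance = 1e-12)
})

test_that("meta-prior weights scale only the complexity term", {
  net <- tiny_net()
  Tn <- 5
  X <- withr::with_seed(3, matrix(runif(Tn * 2, -0.6, 0.6), Tn, 2))
  A <- random_A(net, Tn)
  eps <- random_eps(net, Tn)
  w <- c(0.5, 0.2)
  r1 <- evaluate_window(net, X, A = A, eps = eps, w = w)
  r2 <- evaluate_window(net, X, A = A, eps = eps, w = 3 * w)
  expect_equal(as.numeric(r2$fe$complexity), 3 * as.numeric(r1$fe$complexity),
               tolerance = 1e-12)
  expect_equal(r2$fe$accuracy, r1$fe$accuracy, tolerance = 1e-12)
  r0 <- evaluate_window(net, X, A = A, eps = eps, w = c(0, 0))
  expect_equal(r0$fe$total, r1$fe$accuracy, tolerance = 1e-12)
})

test_that("window free energy matches an independent scalar recomputation", {
  net <- tiny_net(seed = 13)
  Tn <- 7
  X <- withr::with_seed(5, matrix(runif(Tn * 2, -0.7, 0.7), Tn, 2))
  A <- random_A(net, Tn, seed = 6)
  eps <- random_eps(net, Tn, seed = 7)
  res <- evaluate_window(net, X, A = A, eps = eps)
  orc <- oracle_free_energy(net, X, A, eps)
  expect_equal(res$fe$total, orc$total, tolerance = 1e-10)
  expect_equal(as.numeric(res$fe$complexity), orc$complexity,
               tolerance = 1e-10)
  expect_equal(res$fe$accuracy, orc$accuracy, tolerance = 1e-10)
})

test_that("free-energy gradients match central finite differences", {
  net <- pvrnn_net(list(layer_spec(3, 1, 2, 0.4)), n_out = 2, seed = 17)
  Tn <- 5
  X <- withr::with_seed(21, matrix(runif(Tn * 2, -0.6, 0.6), Tn, 2))
  A <- random_A(net, Tn, seed = 22)
  eps <- random_eps(net, Tn, seed = 23)
  res <- evaluate_window(net, X, A = A, eps = eps, grads = TRUE)
  fe_of <- function(net2, A2) {
    evaluate_window(net2, X, A = A2, eps = eps)$fe$total
  }
  h <- 1e-6
  max_rel <- 0
  for (nm in names(net$params)) {
    pl <- net$params[[nm]]
    entries <- if (is.list(pl)) {
      lapply(seq_along(pl), function(l) seq_len(length(pl[[l]])))
    } else list(seq_len(length(pl)))
    for (l in seq_along(entries)) {
      for (i in entries[[l]]) {
        plus <- net; minus <- net
        if (is.list(pl)) {
          plus$params[[nm]][[l]][i] <- pl[[l]][i] + h
          minus$params[[nm]][[l]][i] <- pl[[l]][i] - h
          ga <- res$grads$params[[nm]][[l]][i]
        } else {
          plus$params[[nm]][i] <- pl[i] + h
          minus$params[[nm]][i] <- pl[i] - h
          ga <- res$grads$params[[nm]][i]
        }
        gn <- (fe_of(plus, A) - fe_of(minus, A)) / (2 * h)
        max_rel <- max(max_rel, abs(ga - gn) / max(abs(ga), abs(gn), 1e-6))
      }
    }
  }
  for (i in seq_len(length(A[[1]]))) {
    Ap <- A; Ap[[1]][i] <- A[[1]][i] + h
    Am <- A; Am[[1]][i] <- A[[1]][i] - h
    gn <- (fe_of(net, Ap) - fe_of(net, Am)) / (2 * h)
    ga <- res$grads$A[[1]][i]
    max_rel <- max(max_rel, abs(ga - gn) / max(abs(ga), abs(gn), 1e-6))
  }
  expect_lt(max_rel, 1e-4)
})

test_that("stronger complexity weighting tightens KL at the cost of accuracy", {
  # on a fixed tiny trained-ish net and fixed target, optimizing A at high w
  # must end with smaller KL and larger reconstruction error than at low w
  net <- tiny_net(seed = 31)
  Tn <- 20
  th <- 2 * pi * (1:Tn) / 10
  X <- cbind(0.5 * sin(th), 0.5 * cos(th))
  sv <- pvrnn:::spec_vectors(net$specs)
  run_at <- function(wval) {
    withr::with_seed(55, {
      res <- pvrnn:::cpp_infer_window(net$params, sv, X,
                                      adaptive_sequence(net, Tn), NULL, TRUE,
                                      rep(wval, 2), 200, 0.05, 5)
      list(kl = sum(res$kl), err = sum(res$err))
    })
  }
  lo <- run_at(0.01)
  hi <- run_at(100)
  expect_lt(hi$kl, lo$kl)
  expect_gt(hi$err, lo$err)
})
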