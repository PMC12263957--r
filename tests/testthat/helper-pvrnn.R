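# Shared fixtures: tiny networks, random adaptive variables, and a cached
# reduced-scale trained model used by the slower behavioral tests.

tiny_specs <- function() {
  list(layer_spec(3, 2, 2, 0.5), layer_spec(2, 1, 4, 0.2))
}

tiny_net <- function(seed = 3) pvrnn_net(tiny_specs(), n_out = 2, seed = seed)

random_A <- function(net, len, seed = 1, sd = 0.3) {
  withr::with_seed(seed, lapply(adaptive_sequence(net, len), function(a) {
    a + rnorm(length(a), 0, sd)
  }))
}

random_eps <- function(net, len, seed = 2) {
  sv <- pvrnn:::spec_vectors(net$specs)
  withr::with_seed(seed, lapply(sv$n_z, function(nz) {
    matrix(rnorm(nz * len), nz, len)
  }))
}

# Independent scalar reimplementation of the free energy of a
# posterior-evaluated window: plain loops, no calls into the package's
# evaluation path beyond parameter access.
oracle_free_energy <- function(net, X, A, eps, w = NULL) {
  p <- net$params
  sv <- pvrnn:::spec_vectors(net$specs)
  if (is.null(w)) w <- vapply(net$specs, `[[`, numeric(1), "w")
  L <- length(sv$n_d)
  Tn <- nrow(X)
  h <- lapply(sv$n_d, numeric)
  d <- lapply(sv$n_d, numeric)
  complexity <- numeric(L)
  accuracy <- 0
  for (t in seq_len(Tn)) {
    d_old <- d
    h_old <- h
    z <- vector("list", L)
    for (l in seq_len(L)) {
      nz <- sv$n_z[l]
      a_mu_p <- as.numeric(p$W_mu[[l]] %*% d_old[[l]]) + as.numeric(p$b_mu_p[[l]])
      a_sg_p <- as.numeric(p$W_sg[[l]] %*% d_old[[l]]) + as.numeric(p$b_sg_p[[l]])
      mu_p <- tanh(a_mu_p)
      sg_p <- exp(pmin(pmax(a_sg_p, -10), 10))
      if (t == 1) { mu_p <- rep(0, nz); sg_p <- rep(1, nz) }
      amu <- A[[l]][seq_len(nz), t]
      asg <- A[[l]][nz + seq_len(nz), t]
      mu_q <- tanh(as.numeric(p$W_mu[[l]] %*% d_old[[l]]) + amu +
                     as.numeric(p$b_mu_q[[l]]))
      sg_q <- exp(pmin(pmax(as.numeric(p$W_sg[[l]] %*% d_old[[l]]) + asg +
                              as.numeric(p$b_sg_q[[l]]), -10), 10))
      for (r in seq_len(nz)) {
        complexity[l] <- complexity[l] + (w[l] / nz) *
          (log(sg_p[r] / sg_q[r]) +
             ((mu_q[r] - mu_p[r])^2 + sg_q[r]^2) / (2 * sg_p[r]^2) - 0.5)
      }
      z[[l]] <- mu_q + sg_q * eps[[l]][, t]
    }
    for (l in seq_len(L)) {
      u <- as.numeric(p$W_dd[[l]] %*% d_old[[l]]) + as.numeric(p$b_h[[l]])
      if (sv$n_z[l] > 0) u <- u + as.numeric(p$W_zd[[l]] %*% z[[l]])
      if (l < L) u <- u + as.numeric(p$W_td[[l]] %*% d_old[[l + 1]])
      if (l > 1) u <- u + as.numeric(p$W_bu[[l]] %*% d_old[[l - 1]])
      h[[l]] <- (1 - 1 / sv$tau[l]) * h_old[[l]] + (1 / sv$tau[l]) * u
      d[[l]] <- tanh(h[[l]])
    }
    xbar <- tanh(as.numeric(p$W_out %*% d[[1]]) + as.numeric(p$b_out))
    accuracy <- accuracy + sum((X[t, ] - xbar)^2) / net$n_out
  }
  list(complexity = complexity, accuracy = accuracy,
       total = sum(complexity) + accuracy)
}

# Reduced-scale study model shared by the behavioral and acceptance tests.
# Trained once per test run and cached; the generator uses two cyclic
# patterns and the architecture is a scaled-down two-layer network.
reduced_model_cache <- new.env(parent = emptyenv())

reduced_generator <- function() generator_spec(make_default_patterns(k = 2), seed = 11)

reduced_model <- function() {
  if (!is.null(reduced_model_cache$fit)) return(reduced_model_cache$fit)
  spec_gen <- reduced_generator()
  corpus <- make_training_corpus(spec_gen, n_seqs = 20, steps = 300)
  specs <- list(layer_spec(30, 3, 3, 0.001), layer_spec(15, 2, 5, 0.001))
  # 3 warm-restart cycles of 5,000 epochs (see the methods vignette)
  fit <- NULL
  for (cycle in 1:3) {
    fit <- train_pvrnn(corpus, specs,
                       train_config(epochs = 5000, seed = 5, log_every = 1000),
                       net = if (is.null(fit)) NULL else fit$net,
                       A_init = if (is.null(fit)) NULL else fit$A)
  }
  reduced_model_cache$fit <- fit
  reduced_model_cache$spec_gen <- spec_gen
  reduced_model_cache$corpus <- corpus
  fit
}

reduced_inference_config <- function(seed = 3) {
  inference_config(window_len = 150, error_window = 100, seed = seed)
}

repeat_pattern <- function(pat, n_cycles) {
  do.call(rbind, replicate(n_cycles, pat$points, simplify = FALSE))
}
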