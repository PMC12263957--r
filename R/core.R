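SIGMA_CLAMP <- 10  # bound on the argument of exp() when computing sigma

clamp_exp <- function(a) exp(pmin(pmax(a, -SIGMA_CLAMP), SIGMA_CLAMP))

#' Closed-form KL divergence between two univariate Gaussians
#'
#' `kl_unit(mq, sq, mp, sp)` is the divergence of `N(mq, sq^2)` from the
#' prior `N(mp, sp^2)`:
#' `log(sp/sq) + ((mq - mp)^2 + sq^2) / (2 sp^2) - 1/2`. Vectorized; always
#' non-negative.
#'
#' @param mu_q,sigma_q posterior mean and standard deviation (`sigma_q > 0`).
#' @param mu_p,sigma_p prior mean and standard deviation (`sigma_p > 0`).
#' @return Numeric vector of divergences.
#' @export
kl_unit <- function(mu_q, sigma_q, mu_p, sigma_p) {
  if (any(sigma_q <= 0) || any(sigma_p <= 0)) {
    stop("standard deviations must be strictly positive", call. = FALSE)
  }
  log(sigma_p / sigma_q) +
    ((mu_q - mu_p)^2 + sigma_q^2) / (2 * sigma_p^2) - 0.5
}

#' Prior and posterior latent distributions of one layer
#'
#' The prior head maps the layer's previous deterministic state to a Gaussian
#' via `mu_p = tanh(W_mu d + b_mu_p)`, `sigma_p = exp(W_sg d + b_sg_p)`; the
#' posterior additionally receives the step's adaptive variables:
#' `mu_q = tanh(W_mu d + A_mu + b_mu_q)`,
#' `sigma_q = exp(W_sg d + A_sg + b_sg_q)`. The two heads share the weight
#' matrices and differ in biases (and the posterior's `A`). The exp argument
#' is clamped to `[-10, 10]`, so sigma is positive by construction.
#'
#' @param d_prev the layer's deterministic state at the previous step.
#' @param net a `pvrnn_net`.
#' @param layer layer index (1 = bottom).
#' @param A_t list with elements `mu` and `sigma`: the adaptive variables of
#'   this step and layer (posterior only).
#' @return List with elements `mu` and `sigma`.
#' @export
compute_prior <- function(d_prev, net, layer) {
  p <- net$params
  mu <- tanh(drop(p$W_mu[[layer]] %*% d_prev + p$b_mu_p[[layer]]))
  sigma <- clamp_exp(drop(p$W_sg[[layer]] %*% d_prev + p$b_sg_p[[layer]]))
  list(mu = mu, sigma = sigma)
}

#' @rdname compute_prior
#' @export
compute_posterior <- function(d_prev, A_t, net, layer) {
  if (is.null(A_t) || is.null(A_t$mu) || is.null(A_t$sigma)) {
    stop("posterior undefined without adaptive variables A_t", call. = FALSE)
  }
  p <- net$params
  mu <- tanh(drop(p$W_mu[[layer]] %*% d_prev) + A_t$mu +
               drop(p$b_mu_q[[layer]]))
  sigma <- clamp_exp(drop(p$W_sg[[layer]] %*% d_prev) + A_t$sigma +
                       drop(p$b_sg_q[[layer]]))
  list(mu = mu, sigma = sigma)
}

#' Reparameterized Gaussian sample
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)` (or supplied explicitly).
#'
#' @param mu,sigma mean and standard deviation vectors (`sigma > 0`).
#' @param eps optional fixed noise vector; drawn from the standard normal
#'   when omitted.
#' @return Numeric vector `z`.
#' @export
sample_z <- function(mu, sigma, eps = NULL) {
  if (any(sigma <= 0)) {
    stop("sigma must be strictly positive", call. = FALSE)
  }
  if (is.null(eps)) eps <- rnorm(length(mu))
  mu + sigma * eps
}

#' Sensory readout from the bottom layer
#'
#' `xbar = tanh(W_out d + b_out)`; components lie strictly in (-1, 1).
#'
#' @param d_bottom bottom-layer deterministic state.
#' @param net a `pvrnn_net`.
#' @return Numeric vector of length `net$n_out`.
#' @export
readout <- function(d_bottom, net) {
  tanh(drop(net$params$W_out %*% d_bottom + net$params$b_out))
}

#' Zero-initialized latent frame
#'
#' The frame preceding the first time step: `h = d = 0` in every layer.
#'
#' @param net a `pvrnn_net`.
#' @return A `latent_frame`: per-layer lists with elements `h`, `d`, `mu_p`,
#'   `sigma_p`, `mu_q`, `sigma_q`, `z`.
#' @export
latent_frame_init <- function(net) {
  sv <- spec_vectors(net$specs)
  layers <- lapply(seq_along(sv$n_d), function(l) {
    list(h = numeric(sv$n_d[l]), d = numeric(sv$n_d[l]),
         mu_p = NULL, sigma_p = NULL, mu_q = NULL, sigma_q = NULL, z = NULL)
  })
  structure(list(layers = layers), class = "latent_frame")
}

#' One step of the recurrent dynamics
#'
#' Advances every layer by one time step:
#' `h_t = (1 - 1/tau) h_{t-1} + (1/tau)(W_dd d_{t-1} + W_zd z_t +
#' W_td d_{t-1}^{above} + W_bu d_{t-1}^{below} + b_h)`, `d_t = tanh(h_t)`,
#' with `z_t` drawn from the prior or the posterior of each layer (boundary
#' layers omit the missing neighbor term). When `unit_prior = TRUE` the
#' prior of this step is the unit Gaussian (the convention for the first
#' step of a sequence, where no previous state exists).
#'
#' @param prev the previous `latent_frame`.
#' @param z_source `"prior"` or `"posterior"`.
#' @param net a `pvrnn_net`.
#' @param A_t per-layer list of `list(mu =, sigma =)` adaptive variables
#'   (required for the posterior).
#' @param eps per-layer list of noise vectors; fresh standard-normal draws
#'   when omitted.
#' @param unit_prior use `N(0, I)` as this step's prior.
#' @return The next `latent_frame`.
#' @export
forward_step <- function(prev, z_source = c("posterior", "prior"), net,
                         A_t = NULL, eps = NULL, unit_prior = FALSE) {
  z_source <- match.arg(z_source)
  sv <- spec_vectors(net$specs)
  L <- length(sv$n_d)
  p <- net$params
  new_layers <- vector("list", L)
  for (l in seq_len(L)) {
    d_prev <- prev$layers[[l]]$d
    nz <- sv$n_z[l]
    pr <- compute_prior(d_prev, net, l)
    if (unit_prior) pr <- list(mu = numeric(nz), sigma = rep(1, nz))
    if (z_source == "posterior") {
      po <- compute_posterior(d_prev, A_t[[l]], net, l)
    } else {
      po <- pr
    }
    e <- if (is.null(eps)) rnorm(nz) else eps[[l]]
    z <- if (nz > 0) {
      if (z_source == "posterior") sample_z(po$mu, po$sigma, e)
      else sample_z(pr$mu, pr$sigma, e)
    } else numeric(0)
    u <- drop(p$W_dd[[l]] %*% d_prev + p$b_h[[l]])
    if (nz > 0) u <- u + drop(p$W_zd[[l]] %*% z)
    if (l < L) u <- u + drop(p$W_td[[l]] %*% prev$layers[[l + 1]]$d)
    if (l > 1) u <- u + drop(p$W_bu[[l]] %*% prev$layers[[l - 1]]$d)
    a <- 1 / sv$tau[l]
    h <- (1 - a) * prev$layers[[l]]$h + a * u
    new_layers[[l]] <- list(h = h, d = tanh(h), mu_p = pr$mu,
                            sigma_p = pr$sigma, mu_q = po$mu,
                            sigma_q = po$sigma, z = z)
  }
  structure(list(layers = new_layers), class = "latent_frame")
}

#' Normalized free energy of a posterior-evaluated window
#'
#' The total is the sum of a per-layer complexity term,
#' `(w_l / R_z^l) * sum_t sum_r KL(q || p)`, and the accuracy term
#' `(1 / R_X) * sum_t ||X_t - xbar_t||^2`, where `xbar_t` is the readout of
#' the bottom layer's deterministic state.
#'
#' @param frames list of `latent_frame` objects (posterior-populated), one
#'   per target step.
#' @param targets `T x R_X` matrix of observations.
#' @param net a `pvrnn_net`.
#' @return A `free_energy_breakdown`: `complexity_per_layer`, `accuracy`,
#'   `total`.
#' @export
free_energy <- function(frames, targets, net) {
  targets <- as.matrix(targets)
  if (length(frames) != nrow(targets)) {
    stop("number of frames must equal number of target steps", call. = FALSE)
  }
  sv <- spec_vectors(net$specs)
  w <- spec_w(net$specs)
  L <- length(sv$n_d)
  complexity <- numeric(L)
  accuracy <- 0
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    for (l in seq_len(L)) {
      if (sv$n_z[l] > 0) {
        ly <- fr$layers[[l]]
        complexity[l] <- complexity[l] + (w[l] / sv$n_z[l]) *
          sum(kl_unit(ly$mu_q, ly$sigma_q, ly$mu_p, ly$sigma_p))
      }
    }
    xbar <- readout(fr$layers[[1]]$d, net)
    accuracy <- accuracy + sum((targets[t, ] - xbar)^2) / net$n_out
  }
  structure(list(complexity_per_layer = complexity, accuracy = accuracy,
                 total = sum(complexity) + accuracy),
            class = "free_energy_breakdown")
}

#' @export
print.free_energy_breakdown <- function(x, ...) {
  cat(sprintf("<free_energy> total=%.6g (complexity %s; accuracy %.6g)\n",
              x$total, paste(signif(x$complexity_per_layer, 6),
                             collapse = " + "), x$accuracy))
  invisible(x)
}

#' Zero-initialized adaptive variables for a window
#'
#' One matrix per layer of size `2 n_z x len`: rows `1..n_z` hold the mean
#' part `A_mu`, rows `n_z+1..2 n_z` the sigma part `A_sigma`.
#'
#' @param net a `pvrnn_net`.
#' @param len number of window steps.
#' @return List of matrices, one per layer.
#' @export
adaptive_sequence <- function(net, len) {
  sv <- spec_vectors(net$specs)
  lapply(sv$n_z, function(nz) matrix(0, 2 * nz, len))
}

# Split one column of the stacked A matrix into the list(mu, sigma) form
# used by compute_posterior().
split_A_col <- function(A, net, t) {
  sv <- spec_vectors(net$specs)
  lapply(seq_along(A), function(l) {
    nz <- sv$n_z[l]
    if (nz == 0) return(list(mu = numeric(0), sigma = numeric(0)))
    list(mu = A[[l]][seq_len(nz), t],
         sigma = A[[l]][nz + seq_len(nz), t])
  })
}

#' Evaluate a window of steps in one call
#'
#' Batch counterpart of composing [forward_step] over a window (implemented
#' in compiled code): runs the recurrent dynamics with prior- or
#' posterior-sampled latents, computes the readout, free energy, per-step
#' normalized errors and per-layer KL, and optionally the gradients of the
#' free energy with respect to all parameters and the adaptive variables.
#'
#' @param net a `pvrnn_net`.
#' @param targets `T x R_X` matrix, or `NULL` for a pure rollout.
#' @param A list of per-layer `2 n_z x T` adaptive matrices (posterior).
#' @param eps list of per-layer `n_z x T` noise matrices; fresh draws when
#'   `NULL`.
#' @param z_source `"posterior"` or `"prior"`.
#' @param init anchor state `list(h =, d =)` (per-layer vectors), or `NULL`
#'   for the zero state.
#' @param unit_prior_first treat the first window step as the sequence start
#'   (unit-Gaussian prior).
#' @param w per-layer meta-prior weights; defaults to the specs' `w`.
#' @param grads also return gradients.
#' @param steps rollout length when neither `targets` nor `A` is given.
#' @return List with `xbar`, `frames`, `kl`, and (given targets) `fe`,
#'   `err`, and (if requested) `grads`.
#' @export
evaluate_window <- function(net, targets = NULL, A = NULL, eps = NULL,
                            z_source = c("posterior", "prior"), init = NULL,
                            unit_prior_first = TRUE, w = NULL, grads = FALSE,
                            steps = 0) {
  z_source <- match.arg(z_source)
  sv <- spec_vectors(net$specs)
  if (is.null(w)) w <- spec_w(net$specs)
  cpp_window_pass(net$params, sv,
                  if (is.null(targets)) NULL else as.matrix(targets),
                  A, eps, z_source, init, unit_prior_first, w, grads,
                  as.integer(steps))
}
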