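#' Per-layer architecture specification
#'
#' Each layer has `n_d` deterministic units with leaky-integrator time
#' constant `tau`, `n_z` Gaussian stochastic units, and a meta-prior weight
#' `w` multiplying its (dimension-normalized) KL complexity term in the free
#' energy.
#'
#' @param n_d number of deterministic units (>= 1).
#' @param n_z number of stochastic units (>= 0).
#' @param tau time constant (>= 1); larger is slower.
#' @param w meta-prior weight (>= 0).
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(n_d, n_z, tau, w) {
  stopifnot(n_d >= 1, n_z >= 0, tau >= 1, w >= 0)
  structure(list(n_d = as.integer(n_d), n_z = as.integer(n_z),
                 tau = as.numeric(tau), w = as.numeric(w)),
            class = "layer_spec")
}

#' Reference two-layer architecture
#'
#' The full-scale configuration used for the study-scale experiments: a fast
#' bottom layer (60 d units, 6 z units, tau = 3) and a slow top layer (30 d
#' units, 3 z units, tau = 5), both with training meta-prior 0.001.
#'
#' @return List of two [layer_spec] objects (bottom layer first).
#' @export
default_layer_specs <- function() {
  list(layer_spec(60, 6, 3, 0.001), layer_spec(30, 3, 5, 0.001))
}

# Collapse a list of layer_spec into the flat vectors the C++ core expects.
spec_vectors <- function(specs) {
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "layer_spec")))
  list(n_d = vapply(specs, `[[`, integer(1), "n_d"),
       n_z = vapply(specs, `[[`, integer(1), "n_z"),
       tau = vapply(specs, `[[`, numeric(1), "tau"))
}

spec_w <- function(specs) vapply(specs, `[[`, numeric(1), "w")

glorot <- function(nr, nc) {
  if (nr == 0 || nc == 0) return(matrix(0, nr, nc))
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a PV-RNN
#'
#' Builds all weights and biases for the generative and inference models.
#' Recurrent, latent-to-state and cross-layer maps are Glorot-uniform; all
#' biases start at zero, so every prior and posterior starts at the unit
#' Gaussian. The prior and posterior heads share the `W_dmu`/`W_dsigma`
#' weight matrices and differ only in their bias terms. The sensory readout
#' is a tanh-affine map from the bottom layer's deterministic units.
#'
#' @param specs list of [layer_spec], bottom layer first.
#' @param n_out sensory dimension (default 2).
#' @param seed integer seed for weight initialization.
#' @return An object of class `pvrnn_net` with elements `params`, `specs`,
#'   `n_out`.
#' @export
pvrnn_net <- function(specs, n_out = 2, seed = 1L) {
  sv <- spec_vectors(specs)
  L <- length(sv$n_d)
  params <- with_seed(seed, {
    p <- list(W_dd = list(), W_zd = list(), W_td = list(), W_bu = list(),
              b_h = list(), W_mu = list(), W_sg = list(),
              b_mu_p = list(), b_sg_p = list(), b_mu_q = list(),
              b_sg_q = list())
    for (l in seq_len(L)) {
      nd <- sv$n_d[l]; nz <- sv$n_z[l]
      nd_up <- if (l < L) sv$n_d[l + 1] else 0L
      nd_dn <- if (l > 1) sv$n_d[l - 1] else 0L
      p$W_dd[[l]] <- glorot(nd, nd)
      p$W_zd[[l]] <- glorot(nd, nz)
      p$W_td[[l]] <- glorot(nd, nd_up)
      p$W_bu[[l]] <- glorot(nd, nd_dn)
      p$b_h[[l]] <- matrix(0, nd, 1)
      p$W_mu[[l]] <- glorot(nz, nd)
      p$W_sg[[l]] <- glorot(nz, nd)
      p$b_mu_p[[l]] <- matrix(0, nz, 1)
      p$b_sg_p[[l]] <- matrix(0, nz, 1)
      p$b_mu_q[[l]] <- matrix(0, nz, 1)
      p$b_sg_q[[l]] <- matrix(0, nz, 1)
    }
    p$W_out <- glorot(n_out, sv$n_d[1])
    p$b_out <- matrix(0, n_out, 1)
    p
  })
  structure(list(params = params, specs = specs, n_out = as.integer(n_out)),
            class = "pvrnn_net")
}

#' @export
print.pvrnn_net <- function(x, ...) {
  sv <- spec_vectors(x$specs)
  cat(sprintf("<pvrnn_net> %d layer(s), output dim %d\n", length(sv$n_d),
              x$n_out))
  for (l in seq_along(sv$n_d)) {
    cat(sprintf("  layer %d: n_d=%d n_z=%d tau=%g w=%g\n", l, sv$n_d[l],
                sv$n_z[l], sv$tau[l], x$specs[[l]]$w))
  }
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are single-file binary archives holding all parameter tensors
#' keyed by layer and role, the layer specifications, and a version header.
#'
#' @param net a `pvrnn_net`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `pvrnn_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "pvrnn_net"))
  saveRDS(list(format = "pvrnn-checkpoint", version = 1L,
               params = net$params,
               specs = lapply(net$specs, unclass), n_out = net$n_out),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "pvrnn-checkpoint")) {
    stop("not a pvrnn checkpoint: ", path, call. = FALSE)
  }
  specs <- lapply(x$specs, function(s) layer_spec(s$n_d, s$n_z, s$tau, s$w))
  structure(list(params = x$params, specs = specs, n_out = x$n_out),
            class = "pvrnn_net")
}

#' Read / write a network architecture config as YAML
#'
#' The text config mirrors the per-layer fields by name (`n_d`, `n_z`,
#' `tau`, `w`), bottom layer first.
#'
#' @param specs list of [layer_spec] (for writing).
#' @param path file path.
#' @return `read_network_config` returns a list of [layer_spec].
#' @export
write_network_config <- function(specs, path) {
  yaml::write_yaml(list(layers = lapply(specs, unclass)), path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  x <- yaml::read_yaml(path)
  lapply(x$layers, function(s) layer_spec(s$n_d, s$n_z, s$tau, s$w))
}
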