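#' Training configuration
#'
#' Defaults follow the study-scale protocol: Adam with learning rate 0.001,
#' 150,000 epochs, full-batch gradients over the corpus, one reparameterized
#' sample per step per epoch, and no BPTT truncation.
#'
#' @param epochs number of full-batch gradient steps.
#' @param learning_rate Adam learning rate.
#' @param optimizer only `"adam"` is supported.
#' @param seed integer seed controlling initialization noise draws.
#' @param w_train optional per-layer meta-prior override; defaults to the
#'   `w` stored in the layer specs.
#' @param log_every record the loss every this many epochs.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 150000, learning_rate = 0.001,
                         optimizer = "adam", seed = 1L, w_train = NULL,
                         log_every = 100, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(epochs >= 0, learning_rate > 0, identical(optimizer, "adam"),
            log_every >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, seed = as.integer(seed),
                 w_train = w_train, log_every = as.integer(log_every),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

corpus_matrices <- function(corpus) {
  lapply(corpus, function(x) {
    if (inherits(x, "pvrnn_trajectory")) x$values else as.matrix(x)
  })
}

#' Train a PV-RNN on a corpus of sequences
#'
#' Jointly optimizes all network parameters and the per-sequence adaptive
#' variables `A` by full-batch Adam on the mean normalized free energy
#' across sequences, with back-propagation through time over the full
#' sequence length (no truncation) and fresh reparameterization noise every
#' epoch. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param corpus list of `pvrnn_trajectory` objects or `T x 2` matrices,
#'   all of the same length.
#' @param specs list of [layer_spec] (bottom layer first).
#' @param cfg a [train_config].
#' @param net optional pre-initialized (or pre-trained) `pvrnn_net` to
#'   continue from; initialized from `cfg$seed` when omitted.
#' @param A_init optional per-sequence adaptive variables to continue from
#'   (e.g. a previous fit's `A`); zero-initialized when omitted.
#' @return An object of class `pvrnn_fit`: `net` (trained), `A`
#'   (per-sequence adaptive variables), `history` (data frame with columns
#'   `epoch`, `complexity_l*`, `accuracy`, `total`), plus the `cfg` used.
#' @export
train_pvrnn <- function(corpus, specs, cfg = train_config(), net = NULL,
                        A_init = NULL) {
  mats <- corpus_matrices(corpus)
  stopifnot(length(mats) >= 1)
  dims <- vapply(mats, ncol, integer(1))
  lens <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1 || length(unique(lens)) != 1) {
    stop("all sequences must share the same length and dimensionality",
         call. = FALSE)
  }
  if (is.null(net)) net <- pvrnn_net(specs, n_out = dims[1], seed = cfg$seed)
  sv <- spec_vectors(net$specs)
  w <- if (is.null(cfg$w_train)) spec_w(net$specs) else cfg$w_train
  stopifnot(length(w) == length(sv$n_d))

  res <- with_seed(derive_seed(cfg$seed, 7L), {
    cpp_train(mats, net$params, sv, w, cfg$epochs, cfg$learning_rate,
              cfg$beta1, cfg$beta2, cfg$adam_eps, cfg$log_every, A_init)
  })
  net$params <- res$params
  hist <- as.data.frame(res$history)
  L <- length(sv$n_d)
  names(hist) <- c("epoch", paste0("complexity_l", seq_len(L)),
                   "accuracy", "total")
  structure(list(net = net, A = res$A, history = hist, cfg = cfg),
            class = "pvrnn_fit")
}

#' @export
print.pvrnn_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<pvrnn_fit> %d logged epochs", n))
  if (n > 0) {
    cat(sprintf("; final total=%.5g (accuracy %.5g)",
                x$history$total[n], x$history$accuracy[n]))
  }
  cat("\n")
  invisible(x)
}

#' Closed-loop generation from the learned prior
#'
#' Rolls the trained network forward for `steps` steps with every latent
#' drawn from the prior (the first step from the unit Gaussian), consuming
#' no observations: the network's spontaneous "imagery". Deterministic
#' given `seed`.
#'
#' @param net a trained `pvrnn_net`.
#' @param steps rollout length.
#' @param seed integer seed for the latent draws.
#' @return A `pvrnn_rollout`: `output` (`steps x n_out` matrix) and
#'   `frames` (per-layer state matrices, for inspecting `d` activity).
#' @export
prior_generate <- function(net, steps, seed = 1L) {
  if (steps == 0) {
    return(structure(list(output = matrix(numeric(0), 0, net$n_out),
                          frames = NULL), class = "pvrnn_rollout"))
  }
  res <- with_seed(seed, {
    evaluate_window(net, targets = NULL, A = NULL, eps = NULL,
                    z_source = "prior", init = NULL,
                    unit_prior_first = TRUE, steps = steps)
  })
  structure(list(output = res$xbar, frames = res$frames),
            class = "pvrnn_rollout")
}

#' @export
print.pvrnn_rollout <- function(x, ...) {
  cat(sprintf("<pvrnn_rollout> %d step(s), %d output dim(s)\n",
              nrow(x$output), ncol(x$output)))
  invisible(x)
}
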