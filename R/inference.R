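#' Online inference configuration
#'
#' During perception the network weights are frozen and only the adaptive
#' variables `A` inside a sliding window of recent observations are
#' optimized (error regression). `er_sum`, the controller's input signal, is
#' the mean of the per-step normalized errors *as they were recorded* over
#' the most recent `error_window` sensory steps: each step contributes the
#' newest window step's error at the moment it arrived, and past
#' contributions are never retroactively re-evaluated, so `er_sum` evolves
#' smoothly across regime changes.
#'
#' @param window_len length of the sliding inference window.
#' @param error_window steps over which `er_sum` is averaged
#'   (`0 < error_window <= window_len`).
#' @param inner_epochs gradient steps on `A` per sensory step.
#' @param inner_lr learning rate of the inner gradient descent on `A`
#'   (plain descent: an adaptive, gradient-normalizing optimizer would
#'   cancel the meta-prior's weighting of the complexity term).
#' @param inner_clip global gradient-norm clip of the inner descent
#'   (stability guard against the stiff KL curvature of confident priors);
#'   `0` disables clipping.
#' @param seed integer seed for inference-time noise draws.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(window_len = 400, error_window = 300,
                             inner_epochs = 30, inner_lr = 0.1,
                             inner_clip = 5, seed = 1L) {
  stopifnot(error_window > 0, error_window <= window_len, inner_epochs >= 1,
            inner_lr >= 0)
  structure(list(window_len = as.integer(window_len),
                 error_window = as.integer(error_window),
                 inner_epochs = as.integer(inner_epochs),
                 inner_lr = inner_lr, inner_clip = inner_clip,
                 seed = as.integer(seed)),
            class = "inference_config")
}

#' Fresh sliding-window state
#'
#' The window starts empty and grows until it reaches `window_len`; the
#' anchor is the network state immediately preceding the window (the zero
#' state until the first eviction).
#'
#' @param net a `pvrnn_net`.
#' @return An object of class `window_state`.
#' @export
new_window_state <- function(net) {
  structure(list(A = adaptive_sequence(net, 0),
                 buffer = matrix(numeric(0), 0, net$n_out),
                 anchor = NULL,    # NULL = zero state
                 anchor_t = 0L,    # global index of the anchor step
                 t = 0L,
                 err_history = numeric(0)),
            class = "window_state")
}

#' One step of online perception
#'
#' Appends the new observation, slides the window when full (committing the
#' evicted step into the anchor with a sampled z from its optimized
#' posterior), zero-initializes the incoming step's adaptive variables while
#' keeping the rest warm, then runs `inner_epochs` clipped gradient-descent
#' steps on all `A` in the window minimizing the free
#' energy under the supplied meta-priors, with fresh reparameterization
#' noise per inner epoch. The returned record is evaluated with a fresh
#' sampled z, so recorded trajectories carry the stochasticity of the
#' active regime.
#'
#' @param state a `window_state`.
#' @param observation sensory vector (length `net$n_out`).
#' @param net a trained `pvrnn_net` (parameters are not modified).
#' @param w_current per-layer meta-prior vector to use for this step.
#' @param cfg an [inference_config].
#' @return List with the updated `state` and a `record` holding the window
#'   reconstruction `xbar`, per-step normalized errors `err`, per-layer
#'   per-step mean KL `kl`, the free-energy breakdown `fe`, the window mean
#'   error `window_mse`, and `er_sum`.
#' @export
perceive_step <- function(state, observation, net, w_current, cfg) {
  sv <- spec_vectors(net$specs)
  state$t <- state$t + 1L
  state$buffer <- rbind(state$buffer, matrix(observation, 1))
  state$A <- lapply(state$A, function(a) cbind(a, numeric(nrow(a))))

  if (nrow(state$buffer) > cfg$window_len) {
    A1 <- lapply(state$A, function(a) a[, 1, drop = FALSE])
    state$anchor <- cpp_step_state(net$params, sv, A1, state$anchor,
                                   state$anchor_t == 0L)
    state$anchor_t <- state$anchor_t + 1L
    state$buffer <- state$buffer[-1, , drop = FALSE]
    state$A <- lapply(state$A, function(a) a[, -1, drop = FALSE])
  }

  res <- cpp_infer_window(net$params, sv, state$buffer, state$A,
                          state$anchor, state$anchor_t == 0L, w_current,
                          cfg$inner_epochs, cfg$inner_lr, cfg$inner_clip)
  state$A <- res$A
  err <- drop(res$err)
  # the error *experienced* at this step: the newest window step's error,
  # recorded once and never retroactively re-evaluated
  e_now <- err[length(err)]
  state$err_history <- c(tail(state$err_history, 2L * cfg$error_window), e_now)
  record <- list(t = state$t, xbar = res$xbar, err = err,
                 kl = res$kl, fe = res$fe,
                 window_mse = mean(err))
  record$er_sum <- average_reconstruction_error(state$err_history,
                                                cfg$error_window)
  list(state = state, record = record)
}

#' Average reconstruction error over the recent past
#'
#' Mean of the per-step normalized errors `e_t = ||X_t - xbar_t||^2 / R_X`
#' over the most recent `error_window` entries (or over all available
#' entries while fewer exist).
#'
#' @param record a numeric vector of per-step errors (such as the window
#'   state's recorded error history), or a `perceive_step` record, in which
#'   case its window errors are averaged.
#' @param error_window number of recent steps to average over.
#' @return The average error `er_sum`.
#' @export
average_reconstruction_error <- function(record, error_window) {
  err <- if (is.list(record)) record$err else record
  if (length(err) == 0) {
    stop("no per-step errors available", call. = FALSE)
  }
  mean(tail(err, error_window))
}

#' Online perception of a target stream
#'
#' Feeds the target sequence one step at a time through [perceive_step],
#' optionally running the meta-prior controller: once at least
#' `error_window` steps have been observed, the controller updates the
#' regime from `er_sum` after every step, and the resulting meta-priors
#' apply from the next step's inner optimization onward. Without a
#' controller, supply a fixed per-layer `w`.
#'
#' @param net a trained `pvrnn_net`.
#' @param target `pvrnn_trajectory` or `T x n_out` matrix to perceive.
#' @param cfg an [inference_config].
#' @param controller a [controller_config], or `NULL` for fixed meta-priors.
#' @param w per-layer meta-prior vector used when `controller` is `NULL`
#'   (and during the controller warm-up, where the regime is held at FS).
#' @param initial_regime regime at the start of a controller run.
#' @return An object of class `pvrnn_percept`: a per-step `log` data frame
#'   (`t, x, y, xbar, ybar, er_sum, window_mse, kl_l*` (newest step),
#'   `klw_l*` (window mean), `w_l*, state`), the
#'   controller `transitions` data frame, and the final window `state` and
#'   `record`.
#' @export
perceive <- function(net, target, cfg = inference_config(),
                     controller = NULL, w = NULL,
                     initial_regime = "FS") {
  X <- if (inherits(target, "pvrnn_trajectory")) target$values
       else as.matrix(target)
  L <- length(net$specs)
  if (is.null(controller) && is.null(w)) {
    stop("supply either a controller config or a fixed per-layer w",
         call. = FALSE)
  }
  ctrl_state <- if (!is.null(controller)) new_controller_state(initial_regime)
  w_cur <- if (!is.null(controller)) {
    if (identical(initial_regime, "FS")) controller$w_low else controller$w_high
  } else w

  n <- nrow(X)
  rows <- vector("list", n)
  state <- new_window_state(net)
  last_record <- NULL

  run <- function() {
    for (t in seq_len(n)) {
      step <- perceive_step(state, X[t, ], net, w_cur, cfg)
      state <<- step$state
      rec <- step$record
      last_record <<- rec
      if (!is.null(controller) && t >= cfg$error_window) {
        cs <- controller_step(ctrl_state, rec$er_sum, controller, t)
        ctrl_state <<- cs$state
        w_cur <<- cs$w
      }
      k <- nrow(rec$xbar)
      rows[[t]] <<- data.frame(
        t = t, x = X[t, 1], y = X[t, 2],
        xbar = rec$xbar[k, 1], ybar = rec$xbar[k, 2],
        er_sum = rec$er_sum, window_mse = rec$window_mse,
        matrix(rec$kl[, k], 1, dimnames = list(NULL, paste0("kl_l", 1:L))),
        matrix(rowMeans(rec$kl), 1,
               dimnames = list(NULL, paste0("klw_l", 1:L))),
        matrix(w_cur, 1, dimnames = list(NULL, paste0("w_l", 1:L))),
        state = if (is.null(controller)) "fixed" else ctrl_state$regime)
    }
  }
  with_seed(cfg$seed, run())

  structure(list(log = do.call(rbind, rows),
                 transitions = if (is.null(controller)) NULL
                               else transition_log(ctrl_state),
                 state = state, record = last_record,
                 cfg = cfg, controller = controller),
            class = "pvrnn_percept")
}

#' @export
print.pvrnn_percept <- function(x, ...) {
  cat(sprintf("<pvrnn_percept> %d step(s)", nrow(x$log)))
  if (!is.null(x$transitions)) {
    cat(sprintf(", %d regime transition(s)", nrow(x$transitions)))
  }
  cat("\n")
  invisible(x)
}
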