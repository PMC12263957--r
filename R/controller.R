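#' Meta-prior controller configuration
#'
#' The controller switches every layer's meta-prior jointly between a low
#' value (focus state, FS: sensory-driven inference) and a high value
#' (mind-wandering, MW: top-down generation), driven by the average recent
#' reconstruction error `er_sum`. Transition probabilities are sigmoids of
#' the thresholded error scaled by a temperature:
#' `P(FS -> MW) = sigmoid(-(er_sum - thr_low) / temperature)` and
#' `P(MW -> FS) = sigmoid((er_sum - thr_high) / temperature)`.
#'
#' @param w_low,w_high per-layer meta-prior vectors for the FS and MW
#'   regimes (`w_low < w_high` elementwise).
#' @param thr_low,thr_high error thresholds gating FS->MW and MW->FS
#'   (`thr_low < thr_high`), on the per-dimension normalized squared-error
#'   scale.
#' @param temperature sigmoid sharpness (> 0): small values approach a hard
#'   threshold, large values approach a coin flip.
#' @param seed integer seed (used when the controller is run standalone).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(w_low = c(0.01, 0.01), w_high = c(100, 100),
                              thr_low = 0.15, thr_high = 0.40,
                              temperature = 0.01, seed = 1L) {
  stopifnot(length(w_low) == length(w_high), all(w_low < w_high),
            thr_low < thr_high, temperature > 0)
  structure(list(w_low = w_low, w_high = w_high, thr_low = thr_low,
                 thr_high = thr_high, temperature = temperature,
                 seed = as.integer(seed)),
            class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf(paste0("<controller_config> w_low=%s w_high=%s thr=[%.2f, %.2f] ",
                     "temperature=%g\n"),
              paste(x$w_low, collapse = ","),
              paste(x$w_high, collapse = ","), x$thr_low, x$thr_high,
              x$temperature))
  invisible(x)
}

#' Fresh controller state
#'
#' @param regime initial regime, `"FS"` or `"MW"`.
#' @return An object of class `controller_state` with an empty transition
#'   log.
#' @export
new_controller_state <- function(regime = c("FS", "MW")) {
  regime <- match.arg(regime)
  structure(list(regime = regime, transitions = list()),
            class = "controller_state")
}

#' Regime transition probability
#'
#' In FS the probability of switching to MW decreases with the error
#' (`sigmoid(-(er_sum - thr_low) / temperature)`); in MW the probability of
#' switching back to FS increases with it
#' (`sigmoid((er_sum - thr_high) / temperature)`). At `er_sum` equal to the
#' active threshold the probability is exactly 0.5.
#'
#' @param regime `"FS"` or `"MW"`.
#' @param er_sum average recent reconstruction error (>= 0).
#' @param cfg a [controller_config].
#' @return Switching probability in (0, 1).
#' @export
transition_probability <- function(regime, er_sum, cfg) {
  stopifnot(regime %in% c("FS", "MW"))
  if (regime == "FS") {
    plogis(-(er_sum - cfg$thr_low) / cfg$temperature)
  } else {
    plogis((er_sum - cfg$thr_high) / cfg$temperature)
  }
}

#' One controller update
#'
#' Draws `u ~ Uniform(0, 1)` from the current RNG stream and flips the
#' regime iff `u < transition_probability(...)`, logging any flip.
#'
#' @param state a `controller_state`.
#' @param er_sum average recent reconstruction error.
#' @param cfg a [controller_config].
#' @param t current global time step (for the log).
#' @return List with the updated `state`, the per-layer meta-prior vector
#'   `w` matching the (possibly new) regime, the switch probability `p`,
#'   and `flipped`.
#' @export
controller_step <- function(state, er_sum, cfg, t = NA_integer_) {
  p <- transition_probability(state$regime, er_sum, cfg)
  u <- runif(1)
  flipped <- u < p
  if (flipped) {
    to <- if (state$regime == "FS") "MW" else "FS"
    state$transitions[[length(state$transitions) + 1L]] <-
      data.frame(t = t, from = state$regime, to = to, er_sum = er_sum, p = p)
    state$regime <- to
  }
  w <- if (state$regime == "FS") cfg$w_low else cfg$w_high
  list(state = state, w = w, p = p, flipped = flipped)
}

#' Read / write a controller configuration as YAML
#'
#' Fields are serialized under their canonical names (`w_low`, `w_high`,
#' `thr_low`, `thr_high`, `temperature`, `seed`).
#'
#' @param cfg a [controller_config] (for writing).
#' @param path file path.
#' @return `read_controller_config` returns a [controller_config].
#' @export
write_controller_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_controller_config
#' @export
read_controller_config <- function(path) {
  x <- yaml::read_yaml(path)
  controller_config(w_low = as.numeric(x$w_low),
                    w_high = as.numeric(x$w_high),
                    thr_low = x$thr_low, thr_high = x$thr_high,
                    temperature = x$temperature,
                    seed = if (is.null(x$seed)) 1L else x$seed)
}

#' Transition log as a data frame
#'
#' @param state a `controller_state`.
#' @return Data frame with columns `t, from, to, er_sum, p` (zero rows if no
#'   transitions occurred).
#' @export
transition_log <- function(state) {
  if (length(state$transitions) == 0) {
    return(data.frame(t = integer(0), from = character(0), to = character(0),
                      er_sum = numeric(0), p = numeric(0)))
  }
  do.call(rbind, state$transitions)
}
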