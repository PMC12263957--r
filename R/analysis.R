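#' Per-cycle pattern categorization
#'
#' Partitions an output stream into consecutive period-length segments and
#' labels each segment with the template minimizing the phase-aligned mean
#' Euclidean distance (the minimum over all cyclic shifts of the template),
#' so free-phase output such as prior generation is categorized correctly.
#'
#' @param output `T x 2` matrix (or `pvrnn_rollout` / `pvrnn_trajectory`).
#' @param templates list of [cyclic_pattern] templates.
#' @return An object of class `cycle_labels`: per-cycle `labels`,
#'   `match_scores` (cycles x templates distance matrix), and the `period`.
#' @export
categorize_cycles <- function(output, templates) {
  if (inherits(output, "pvrnn_rollout")) output <- output$output
  if (inherits(output, "pvrnn_trajectory")) output <- output$values
  output <- as.matrix(output)
  period <- nrow(templates[[1]]$points)
  if (nrow(output) < period) {
    stop("output must contain at least one full period", call. = FALSE)
  }
  n_cyc <- nrow(output) %/% period
  k <- length(templates)
  # all cyclic shifts of each template, precomputed
  shifted <- lapply(templates, function(tp) {
    lapply(seq_len(period) - 1L, function(s) {
      idx <- ((seq_len(period) - 1L + s) %% period) + 1L
      tp$points[idx, , drop = FALSE]
    })
  })
  scores <- matrix(NA_real_, n_cyc, k)
  for (ci in seq_len(n_cyc)) {
    seg <- output[(ci - 1L) * period + seq_len(period), , drop = FALSE]
    for (j in seq_len(k)) {
      scores[ci, j] <- min(vapply(shifted[[j]], function(tm) {
        mean(sqrt(rowSums((seg - tm)^2)))
      }, numeric(1)))
    }
  }
  ids <- vapply(templates, `[[`, integer(1), "id")
  structure(list(labels = ids[max.col(-scores, ties.method = "first")],
                 match_scores = scores, period = period),
            class = "cycle_labels")
}

#' @export
print.cycle_labels <- function(x, ...) {
  cat(sprintf("<cycle_labels> %d cycle(s): %s\n", length(x$labels),
              paste(utils::head(x$labels, 20), collapse = " ")))
  invisible(x)
}

#' Per-cycle stay/switch statistics
#'
#' Estimates the stay probability as the fraction of consecutive cycle pairs
#' with equal labels, and tabulates switch destinations.
#'
#' @param labels a `cycle_labels` object or an integer vector of per-cycle
#'   labels (>= 2 cycles).
#' @return List with `p_stay_hat`, `p_switch_hat`, `n_pairs`, and
#'   `switch_counts` (a `table` of from -> to switch counts).
#' @export
transition_stats <- function(labels) {
  if (inherits(labels, "cycle_labels")) labels <- labels$labels
  n <- length(labels)
  if (n < 2) stop("need at least 2 cycles", call. = FALSE)
  from <- labels[-n]
  to <- labels[-1]
  stay <- from == to
  list(p_stay_hat = mean(stay), p_switch_hat = mean(!stay),
       n_pairs = n - 1L,
       switch_counts = table(from = from[!stay], to = to[!stay]))
}

#' Temperature sweep of the FS -> MW transition frequency
#'
#' Runs the full perceive-plus-controller loop repeatedly at each
#' temperature (distinct derived seeds per run), counts FS -> MW
#' transitions, and normalizes them per 1,000 time steps.
#'
#' @param net a trained `pvrnn_net`.
#' @param target target stream for the perception runs.
#' @param temps temperatures to sweep.
#' @param n_runs runs per temperature.
#' @param run_len steps per run (target is truncated/required to be at least
#'   this long).
#' @param cfg an [inference_config].
#' @param controller base [controller_config]; its temperature is replaced
#'   per sweep point.
#' @param seed integer master seed; per-run seeds are derived from it.
#' @return An object of class `sweep_result`: `summary` data frame
#'   (`temp, mean, sd, n_runs`) and the raw per-run `counts` matrix of
#'   transitions per 1,000 steps.
#' @export
temperature_sweep <- function(net, target, temps = c(0.01, 0.1, 0.5),
                              n_runs = 3, run_len = 1000,
                              cfg = inference_config(),
                              controller = controller_config(),
                              seed = 1L) {
  X <- if (inherits(target, "pvrnn_trajectory")) target$values
       else as.matrix(target)
  stopifnot(nrow(X) >= run_len)
  X <- X[seq_len(run_len), , drop = FALSE]
  counts <- matrix(NA_real_, n_runs, length(temps))
  for (j in seq_along(temps)) {
    ctrl <- controller
    ctrl$temperature <- temps[j]
    for (r in seq_len(n_runs)) {
      icfg <- cfg
      icfg$seed <- derive_seed(seed, 100L * j + r)
      run <- perceive(net, X, icfg, controller = ctrl)
      tr <- run$transitions
      n_fs_mw <- sum(tr$from == "FS" & tr$to == "MW")
      counts[r, j] <- 1000 * n_fs_mw / run_len
    }
  }
  structure(list(summary = data.frame(temp = temps,
                                      mean = colMeans(counts),
                                      sd = apply(counts, 2, sd),
                                      n_runs = n_runs),
                 counts = counts),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> FS->MW transitions per 1,000 steps\n")
  print(x$summary)
  invisible(x)
}
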