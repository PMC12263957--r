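#' Specification of the synthetic trajectory generator
#'
#' Trajectories are built by probabilistic Markov switching among `K` cyclic
#' 2-D patterns: after one full cycle the same pattern repeats with
#' probability `p_stay`, otherwise the process jumps to one of the other
#' `K - 1` patterns with equal probability. Sparse Gaussian perturbations are
#' then added at randomly spaced points: the intervals between perturbed
#' points are drawn from `Normal(noise_interval_mean, noise_interval_sd)`,
#' rounded to the nearest integer and clamped to a minimum of 1, and the
#' perturbation on each coordinate is `Normal(0, noise_sd)`.
#'
#' @param patterns list of [cyclic_pattern] objects (all with the same period).
#' @param p_stay probability of repeating the current pattern after a cycle.
#' @param noise_interval_mean,noise_interval_sd parameters of the (rounded,
#'   clamped) normal interval distribution between perturbed points.
#' @param noise_sd standard deviation of the additive Gaussian perturbation.
#' @param seed integer seed; all generation is deterministic given the seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(patterns = make_default_patterns(),
                           p_stay = 0.2727,
                           noise_interval_mean = 1,
                           noise_interval_sd = 10,
                           noise_sd = 0.003,
                           seed = 1L) {
  stopifnot(length(patterns) >= 2,
            all(vapply(patterns, inherits, logical(1), "cyclic_pattern")))
  periods <- vapply(patterns, function(p) nrow(p$points), integer(1))
  if (length(unique(periods)) != 1) {
    stop("all patterns must share the same period", call. = FALSE)
  }
  if (p_stay < 0 || p_stay > 1) stop("p_stay must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(patterns = patterns, p_stay = p_stay,
                 noise_interval_mean = noise_interval_mean,
                 noise_interval_sd = noise_interval_sd,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 period = periods[1]),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(paste0("<generator_spec> K=%d patterns, period=%d, ",
                     "p_stay=%.4f, noise_sd=%g, seed=%d\n"),
              length(x$patterns), x$period, x$p_stay, x$noise_sd, x$seed))
  invisible(x)
}

new_trajectory <- function(values, labels, period) {
  n_cycles <- nrow(values) / period
  structure(list(values = values, labels = labels,
                 cycle_boundaries = period * seq_len(n_cycles),
                 period = period),
            class = "pvrnn_trajectory")
}

#' @export
print.pvrnn_trajectory <- function(x, ...) {
  cat(sprintf("<pvrnn_trajectory> T=%d steps (%d cycles of period %d), %d pattern(s)\n",
              nrow(x$values), length(x$cycle_boundaries), x$period,
              length(unique(x$labels))))
  invisible(x)
}

# Markov pattern-id sequence: uniform start, stay w.p. p_stay, else uniform
# over the K - 1 alternatives.
draw_label_chain <- function(k, p_stay, n_cycles) {
  labs <- integer(n_cycles)
  labs[1] <- sample.int(k, 1)
  if (n_cycles > 1) {
    for (i in 2:n_cycles) {
      if (runif(1) < p_stay) {
        labs[i] <- labs[i - 1]
      } else {
        others <- setdiff(seq_len(k), labs[i - 1])
        labs[i] <- others[sample.int(k - 1, 1)]
      }
    }
  }
  labs
}

#' Generate a noiseless switching trajectory
#'
#' Concatenates whole cycles of the spec's patterns, with the active pattern
#' chosen per cycle by the Markov stay/switch rule. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [generator_spec].
#' @param n_cycles number of whole cycles to generate (>= 1).
#' @return A `pvrnn_trajectory` with `n_cycles * period` rows, per-step
#'   pattern labels, and cycle boundary indices.
#' @export
generate_trajectory <- function(spec, n_cycles) {
  stopifnot(inherits(spec, "generator_spec"), n_cycles >= 1)
  k <- length(spec$patterns)
  labs <- with_seed(spec$seed, draw_label_chain(k, spec$p_stay, n_cycles))
  values <- do.call(rbind, lapply(labs, function(i) spec$patterns[[i]]$points))
  new_trajectory(values, rep(labs, each = spec$period), spec$period)
}

#' Add sparse Gaussian perturbations to a trajectory
#'
#' Perturbation points are spaced by intervals drawn from
#' `Normal(noise_interval_mean, noise_interval_sd)`, rounded to the nearest
#' integer and clamped to a minimum of 1; at each such point an independent
#' `Normal(0, noise_sd)` offset is added to both coordinates. With
#' `noise_sd = 0` the trajectory is returned unchanged.
#'
#' @param traj a `pvrnn_trajectory`.
#' @param spec the [generator_spec] holding the noise parameters and seed.
#' @return The perturbed trajectory (labels and boundaries unchanged).
#' @export
add_sparse_noise <- function(traj, spec) {
  stopifnot(inherits(traj, "pvrnn_trajectory"), inherits(spec, "generator_spec"))
  if (spec$noise_sd == 0) return(traj)
  n <- nrow(traj$values)
  traj$values <- with_seed(derive_seed(spec$seed, 1L), {
    gaps <- pmax(1, round(rnorm(n, spec$noise_interval_mean,
                                spec$noise_interval_sd)))
    pos <- cumsum(gaps)
    pos <- pos[pos <= n]
    v <- traj$values
    if (length(pos)) {
      v[pos, ] <- v[pos, ] + matrix(rnorm(2 * length(pos), 0, spec$noise_sd),
                                    ncol = 2)
    }
    v
  })
  traj
}

#' Generate a corpus of independent training trajectories
#'
#' Each sequence is generated (and perturbed) with a sub-seed derived
#' deterministically from `spec$seed`, so the whole corpus is reproducible
#' bit-for-bit.
#'
#' @param spec a [generator_spec].
#' @param n_seqs number of sequences.
#' @param steps steps per sequence; must be a multiple of the period.
#' @return List of `pvrnn_trajectory` objects with attribute `spec`.
#' @export
make_training_corpus <- function(spec, n_seqs, steps) {
  stopifnot(inherits(spec, "generator_spec"), n_seqs >= 1)
  if (steps %% spec$period != 0) {
    stop("steps must be a multiple of the pattern period", call. = FALSE)
  }
  n_cycles <- steps %/% spec$period
  corpus <- lapply(seq_len(n_seqs), function(s) {
    sub <- spec
    sub$seed <- derive_seed(spec$seed, 1000L + s)
    add_sparse_noise(generate_trajectory(sub, n_cycles), sub)
  })
  structure(corpus, spec = spec, class = c("pvrnn_corpus", "list"))
}

#' Write / read a trajectory as delimited text
#'
#' Files carry columns `t, x, y, label` with a header row.
#'
#' @param traj a `pvrnn_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `pvrnn_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = seq_len(nrow(traj$values)),
                   x = traj$values[, 1], y = traj$values[, 2],
                   label = traj$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param period cycle period to assume when reading (default 30).
#' @export
read_trajectory <- function(path, period = 30) {
  df <- read.csv(path)
  new_trajectory(cbind(df$x, df$y), as.integer(df$label), period)
}

#' Write a corpus and its manifest to a directory
#'
#' One CSV per sequence plus a YAML manifest recording the generator settings
#' and the file list.
#'
#' @param corpus result of [make_training_corpus].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(corpus, "spec")
  files <- sprintf("seq_%03d.csv", seq_along(corpus))
  for (i in seq_along(corpus)) {
    write_trajectory(corpus[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    generator = list(
      k = length(spec$patterns), period = spec$period, p_stay = spec$p_stay,
      noise_interval_mean = spec$noise_interval_mean,
      noise_interval_sd = spec$noise_interval_sd,
      noise_sd = spec$noise_sd, seed = spec$seed,
      patterns = lapply(spec$patterns, function(p) {
        list(id = p$id, x = as.numeric(p$points[, 1]),
             y = as.numeric(p$points[, 2]))
      })),
    files = files)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15L)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  g <- manifest$generator
  patterns <- lapply(g$patterns, function(p) {
    cyclic_pattern(cbind(p$x, p$y), p$id)
  })
  spec <- generator_spec(patterns, p_stay = g$p_stay,
                         noise_interval_mean = g$noise_interval_mean,
                         noise_interval_sd = g$noise_interval_sd,
                         noise_sd = g$noise_sd, seed = g$seed)
  corpus <- lapply(manifest$files, function(f) {
    read_trajectory(file.path(dir, f), period = g$period)
  })
  structure(corpus, spec = spec, class = c("pvrnn_corpus", "list"))
}
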