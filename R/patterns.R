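#' Construct a cyclic 2-D pattern
#'
#' A cyclic pattern is one period of a closed 2-D curve sampled at `period`
#' points. Coordinates must lie in `[-1, 1]` so that tanh-range network
#' outputs can represent them.
#'
#' @param points numeric matrix, `period` rows by 2 columns.
#' @param id integer label for the pattern.
#' @return An object of class `cyclic_pattern`.
#' @export
cyclic_pattern <- function(points, id) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 2, nrow(points) >= 4)
  if (max(abs(points)) > 1) {
    stop("pattern coordinates must have magnitude <= 1", call. = FALSE)
  }
  structure(list(points = unname(points), id = as.integer(id)),
            class = "cyclic_pattern")
}

#' @export
print.cyclic_pattern <- function(x, ...) {
  cat(sprintf("<cyclic_pattern> id=%d, period=%d, amplitude range [%.2f, %.2f]\n",
              x$id, nrow(x$points), min(x$points), max(x$points)))
  invisible(x)
}

# One period of a Lissajous curve with per-axis amplitude, frequency, phase.
lissajous <- function(period, ax, ay, fx, fy, phx = 0, phy = 0) {
  th <- 2 * pi * (seq_len(period) - 1) / period
  cbind(ax * sin(fx * th + phx), ay * cos(fy * th + phy))
}

#' Default set of mutually distinguishable cyclic patterns
#'
#' Returns `k` closed 2-D curves sampled at `period` points: a fixed bank of
#' four hand-designed shapes, extended with seeded random Lissajous curves
#' when `k > 4`: a large circle, a flat counter-rotating ellipse, a
#' figure-eight and a small mirrored circle. The bank is deliberately
#' asymmetric (distinct amplitudes and harmonic content) so each pattern is
#' a distinct attractor, with mutual distances large on the scale of the
#' regime-switching error thresholds. All amplitudes
#' are at most 0.9 and any two patterns are well separated (pairwise mean
#' Euclidean distance far above the generator's nominal noise scale).
#'
#' @param k number of patterns (>= 2).
#' @param period samples per cycle (>= 4).
#' @param seed integer seed for the extra patterns drawn when `k > 4`.
#' @return List of [cyclic_pattern] objects with ids `1:k`.
#' @export
make_default_patterns <- function(k = 4, period = 30, seed = 0) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (period < 4) stop("period must be at least 4", call. = FALSE)
  base <- list(
    lissajous(period, 0.80, 0.80, 1, 1),            # circle
    lissajous(period, 0.80, 0.30, 1, 1, phy = pi),  # flat ellipse, reversed y
    lissajous(period, 0.80, 0.70, 1, 2),            # figure-eight
    lissajous(period, 0.45, 0.45, 1, 1, phx = pi)   # small mirrored circle
  )
  shapes <- base[seq_len(min(k, 4))]
  if (k > 4) {
    extra <- with_seed(seed, {
      out <- list()
      tries <- 0
      while (length(out) < k - 4 && tries < 1000 * k) {
        tries <- tries + 1
        cand <- lissajous(period,
                          ax = runif(1, 0.3, 0.9), ay = runif(1, 0.3, 0.9),
                          fx = sample(1:3, 1), fy = sample(1:3, 1),
                          phx = runif(1, 0, 2 * pi), phy = runif(1, 0, 2 * pi))
        sep <- vapply(c(shapes, out), function(s) {
          mean(sqrt(rowSums((s - cand)^2)))
        }, numeric(1))
        if (all(sep > 0.1)) out <- c(out, list(cand))
      }
      if (length(out) < k - 4) {
        stop("could not construct ", k, " well-separated patterns",
             call. = FALSE)
      }
      out
    })
    shapes <- c(shapes, extra)
  }
  lapply(seq_len(k), function(i) cyclic_pattern(shapes[[i]], i))
}

#' Mean Euclidean distance between two cyclic patterns
#'
#' @param p,q `cyclic_pattern` objects or `period x 2` matrices of equal size.
#' @param align if `TRUE`, minimize over cyclic phase shifts of `q`.
#' @return Mean pointwise Euclidean distance (after optional alignment).
#' @export
pattern_distance <- function(p, q, align = FALSE) {
  pm <- if (inherits(p, "cyclic_pattern")) p$points else as.matrix(p)
  qm <- if (inherits(q, "cyclic_pattern")) q$points else as.matrix(q)
  stopifnot(nrow(pm) == nrow(qm))
  if (!align) return(mean(sqrt(rowSums((pm - qm)^2))))
  n <- nrow(pm)
  min(vapply(seq_len(n) - 1L, function(s) {
    idx <- ((seq_len(n) - 1L + s) %% n) + 1L
    mean(sqrt(rowSums((pm - qm[idx, , drop = FALSE])^2)))
  }, numeric(1)))
}
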