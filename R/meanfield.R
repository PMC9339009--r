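#' Parameters of the mean-field stability analysis
#'
#' Bundles the sparseness level and neuron mode used by the overlap
#' fixed-point analysis. In `fixed_activity` mode the firing threshold is
#' adjusted at every step so that exactly a fraction `f` of neurons is
#' active (a global inhibition constraint); in `fixed_threshold` mode the
#' threshold `theta` is held constant and the population activity follows
#' from the dynamics.
#'
#' @param f Sparseness: fraction of neurons active in a memory pattern,
#'   in (0, 0.5).
#' @param mode `"fixed_activity"` (default) or `"fixed_threshold"`.
#' @param theta Firing threshold, used only in `fixed_threshold` mode.
#' @param overlap_retrieval_cut Overlap above which a state counts as a
#'   retrieval of the pattern (default 0.85).
#' @return An object of class `stability_params`.
#' @export
stability_params <- function(f, mode = c("fixed_activity", "fixed_threshold"),
                             theta = NULL, overlap_retrieval_cut = 0.85) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f < 0.5,
            overlap_retrieval_cut > 0, overlap_retrieval_cut < 1)
  if (mode == "fixed_threshold") {
    stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  }
  structure(list(f = f, mode = mode, theta = theta,
                 overlap_retrieval_cut = overlap_retrieval_cut),
            class = "stability_params")
}

#' Upper Gaussian tail probability
#'
#' \eqn{H(x) = \frac{1}{\sqrt{2\pi}} \int_x^\infty e^{-t^2/2}\,dt}, the
#' probability that a standard normal variate exceeds `x`.
#'
#' @param x Numeric vector.
#' @return Tail probabilities in (0, 1), strictly decreasing in `x`.
#' @export
gauss_tail <- function(x) stats::pnorm(x, lower.tail = FALSE)

#' Inverse of the upper Gaussian tail
#'
#' @param p Probabilities in (0, 1).
#' @return `x` such that `gauss_tail(x) == p`.
#' @export
gauss_tail_inv <- function(p) stats::qnorm(p, lower.tail = FALSE)

#' One step of the mean-field overlap dynamics
#'
#' For a state with overlap `m` with a memory pattern of efficacy-to-noise
#' ratio `ratio` = A/Delta, returns the overlap after one synchronous
#' update of the network. In fixed-activity mode this is
#' \deqn{G(m, r) = H(H^{-1}(f(1-m)) - r m) - f(1-m),}
#' where the threshold has been eliminated through the constraint that the
#' population activity stays at `f`. In fixed-threshold mode the update is
#' computed from the conditional activation probabilities of pattern-active
#' and pattern-inactive neurons at threshold `theta`, with the population
#' activity (and hence the effective noise) solved self-consistently; the
#' efficacy and noise must then be passed separately.
#'
#' @param m Overlap in \[0, 1\] (vectorized in fixed-activity mode).
#' @param ratio Efficacy-to-noise ratio A/Delta, >= 0.
#' @param params A [stability_params] object.
#' @param efficacy,delta In fixed-threshold mode, the absolute efficacy A
#'   and interference noise Delta (the `ratio` argument is ignored).
#' @return The updated overlap.
#' @export
overlap_map <- function(m, ratio, params, efficacy = NULL, delta = NULL) {
  if (any(m < 0 | m > 1)) stop("overlap `m` must lie in [0, 1]")
  f <- params$f
  if (params$mode == "fixed_activity") {
    stopifnot(ratio >= 0)
    # clamp away from p = 0: at m = 1 exactly the inactive fraction
    # vanishes and the limit H(-ratio) -> retrieval is the right value
    p <- pmax(f * (1 - m), 1e-300)
    gauss_tail(gauss_tail_inv(p) - ratio * m) - f * (1 - m)
  } else {
    stopifnot(!is.null(efficacy), !is.null(delta))
    vapply(m, function(mm) {
      st <- ft_update(mm, f, efficacy, delta, params$theta, f)
      st[["m"]]
    }, numeric(1), USE.NAMES = FALSE)
  }
}

# Fixed-threshold update: one synchronous sweep of the overlap map at
# fixed threshold. Pattern-active and pattern-inactive neurons fire when
# their Gaussian field (noise `delta`, referenced to a state at the
# pattern sparseness) exceeds theta; the resulting population activity is
# returned as a diagnostic for over-activation.
ft_update <- function(m, y, A, delta, theta, f) {
  fp <- gauss_tail((theta - A * (1 - f) * m) / delta)
  fm <- gauss_tail((theta + A * f * m) / delta)
  c(m = fp - fm, activity = f * fp + (1 - f) * fm)
}

#' Overlap fixed points of the mean-field dynamics
#'
#' Locates all fixed points of [overlap_map] on \[0, 1\] by a dense scan
#' for sign changes followed by bisection, and classifies them by the
#' slope of the map. The zero state is always a fixed point. Above a
#' critical ratio a pair of nonzero fixed points exists: an unstable one
#' `m_unstable` (the basin boundary) and a stable one `m_stable` (the
#' retrieval attractor). At very large ratios the basin boundary merges
#' into the destabilized zero state and is reported as 0.
#'
#' @param ratio Efficacy-to-noise ratio A/Delta.
#' @param params A [stability_params] object (fixed-activity mode).
#' @param n_scan Number of scan points (default 2000).
#' @return A list with `m_zero`, `m_unstable`, `m_stable` (the latter two
#'   `NA` when no nonzero attractor exists) and `zero_stable`.
#' @export
overlap_fixed_points <- function(ratio, params, n_scan = 2000L) {
  stopifnot(ratio >= 0)
  f <- params$f
  g <- function(m) overlap_map(m, ratio, params) - m
  ms <- seq(0, 1, length.out = n_scan)
  gv <- g(ms)
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1L)) {
    if (is.finite(gv[i]) && is.finite(gv[i + 1L]) && gv[i] * gv[i + 1L] < 0) {
      roots <- c(roots, stats::uniroot(g, c(ms[i], ms[i + 1L]), tol = 1e-10)$root)
    }
  }
  # slope of the map at m = 0: the zero state destabilizes when
  # ratio * phi(H^-1(f)) exceeds 1
  zero_stable <- ratio * stats::dnorm(gauss_tail_inv(f)) < 1
  # perfect retrieval: m = 1 is an exact fixed point when the map pushes
  # every interior state upward (no sign change for the scan to find)
  if (abs(gv[n_scan]) < 1e-12 && gv[n_scan - 1L] > 0)
    roots <- c(roots, 1)
  roots <- roots[roots > 1e-8]
  # near the destabilization of the zero state the basin boundary sinks
  # below the linear scan resolution: refine on a log grid
  if (zero_stable && length(roots) == 1L && gv[2] > 0) {
    ml <- 10^seq(-7, log10(ms[2]), length.out = 200L)
    gl <- g(ml)
    i <- which(gl[-length(gl)] * gl[-1L] < 0)
    if (length(i)) {
      roots <- c(stats::uniroot(g, c(ml[i[1L]], ml[i[1L] + 1L]),
                                tol = 1e-12)$root, roots)
    }
  }
  out <- list(m_zero = 0, m_unstable = NA_real_, m_stable = NA_real_,
              zero_stable = zero_stable)
  if (!zero_stable) {
    # basin boundary collapsed onto the zero state
    if (length(roots) >= 1L) {
      out$m_stable <- max(roots)
      out$m_unstable <- 0
    }
  } else if (length(roots) >= 2L) {
    out$m_unstable <- min(roots)
    out$m_stable <- max(roots)
  }
  out
}

#' Raw basin-of-attraction width
#'
#' The mean-field proxy for the basin of attraction size of a memory:
#' the distance `m_stable - m_unstable` between the retrieval attractor
#' and the basin boundary; 0 when no nonzero attractor exists.
#'
#' @inheritParams overlap_fixed_points
#' @return Basin width in \[0, 1\].
#' @export
basin_size_raw <- function(ratio, params, n_scan = 2000L) {
  fp <- overlap_fixed_points(ratio, params, n_scan)
  if (is.na(fp$m_stable) || is.na(fp$m_unstable)) 0 else fp$m_stable - fp$m_unstable
}

#' Critical efficacy-to-noise ratio a(f)
#'
#' The smallest ratio A/Delta at which a memory pattern is a stable
#' attractor (nonzero basin width), located by bisection. The critical
#' efficacy of the model is `A_c = a(f) * Delta`.
#'
#' @param params A [stability_params] object (fixed-activity mode).
#' @param lower,upper Bracketing interval for the bisection.
#' @param tol Bisection tolerance on the ratio.
#' @return The critical ratio `a_f` (> 0).
#' @export
critical_ratio <- function(params, lower = 0.5, upper = 20, tol = 1e-7) {
  stopifnot(params$mode == "fixed_activity")
  if (basin_size_raw(upper, params) <= 0)
    stop("no stable nonzero fixed point up to ratio = ", upper)
  if (basin_size_raw(lower, params) > 0)
    stop("basin already open at ratio = ", lower, "; decrease `lower`")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (basin_size_raw(mid, params) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Closed-form approximation to the critical ratio
#'
#' \eqn{a(f) \approx 1.44 \sqrt{2 \log(1.9 / f)}}, valid in the sparse
#' regime used throughout the package.
#'
#' @param f Sparseness in (0, 0.5).
#' @return Approximate critical ratio.
#' @export
critical_ratio_approx <- function(f) {
  stopifnot(f > 0, f < 0.5)
  1.44 * sqrt(2 * log(1.9 / f))
}

#' Tabulate the normalized basin-size function F
#'
#' Builds the function `F(x)` mapping the efficacy ratio `x = A / A_c` to
#' the normalized basin of attraction size, by computing raw basin widths
#' on a log-spaced grid and normalizing by the large-ratio asymptote so
#' that `F` saturates at 1. `F(x) = 0` for `x < 1` (a memory below the
#' critical efficacy is not an attractor), and `F` rises steeply just
#' above 1. Its product with the maximal rate `lambda` gives the
#' rehearsal rate of a memory.
#'
#' @param params A [stability_params] object (fixed-activity mode).
#' @param x_max Upper end of the tabulated ratio grid (default 50; also the
#'   normalization point).
#' @param n_grid Number of log-spaced grid nodes (default 400).
#' @param a_f Optional precomputed critical ratio (saves the bisection).
#' @return An object of class `basin_table` with fields `x_grid`,
#'   `F_values`, `a_f`, `f`, `mode`, `raw_width`.
#' @export
build_basin_table <- function(params, x_max = 50, n_grid = 400L, a_f = NULL) {
  stopifnot(x_max >= 10)
  if (is.null(a_f)) a_f <- critical_ratio(params)
  xs <- exp(seq(0, log(x_max), length.out = n_grid))
  raw <- vapply(xs * a_f, basin_size_raw, numeric(1), params = params)
  Fv <- raw / raw[length(raw)]
  Fv <- cummax(pmin(Fv, 1))  # enforce monotonicity against grid jitter
  Fv[1] <- 0                 # basin width vanishes at the saddle-node
  structure(list(x_grid = xs, F_values = Fv, a_f = a_f, f = params$f,
                 mode = params$mode, theta = params$theta, raw_width = raw),
            class = "basin_table")
}

#' Evaluate the normalized basin-size function
#'
#' Piecewise-linear interpolation of a [build_basin_table] table: 0 below
#' `x = 1`, 1 beyond the tabulated range.
#'
#' @param table A `basin_table`.
#' @param x Efficacy ratios A/A_c.
#' @return Basin sizes in \[0, 1\].
#' @export
basin_F <- function(table, x) {
  stats::approx(table$x_grid, table$F_values, xout = x,
                yleft = 0, yright = 1, ties = "ordered")$y
}

#' @export
print.basin_table <- function(x, ...) {
  cat("Basin-size table: f =", x$f, " a(f) =", signif(x$a_f, 5),
      " grid", length(x$x_grid), "points on [",
      signif(min(x$x_grid), 3), ",", signif(max(x$x_grid), 3), "]\n")
  invisible(x)
}

#' Write / read a basin table
#'
#' Serializes the grid to CSV (columns `x`, `F`) plus a JSON metadata
#' sidecar (`f`, `a_f`, `mode`, `theta`).
#'
#' @param table A `basin_table`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `write_basin_table` returns `path` invisibly;
#'   `read_basin_table` returns a `basin_table`.
#' @export
write_basin_table <- function(table, path) {
  utils::write.csv(data.frame(x = table$x_grid, F = table$F_values),
                   path, row.names = FALSE)
  meta <- list(f = table$f, a_f = table$a_f, mode = table$mode,
               theta = table$theta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_basin_table
#' @export
read_basin_table <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(x_grid = d$x, F_values = d$F, a_f = meta$a_f, f = meta$f,
                 mode = meta$mode, theta = meta$theta, raw_width = NULL),
            class = "basin_table")
}
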