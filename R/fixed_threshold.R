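#' Mean-field retrieval test at fixed firing threshold
#'
#' Iterates the overlap dynamics for a memory of efficacy `A` at fixed
#' threshold `theta`, starting from the memory state itself (overlap 1,
#' activity f). The population activity is not clamped: it follows from
#' the threshold crossings and is used to detect over-activation, where
#' interference noise recruits pattern-inactive neurons and the state no
#' longer resembles a sparse memory.
#'
#' @param efficacy Memory efficacy A.
#' @param delta Interference noise Delta (at reference activity f).
#' @param params A [stability_params] object in `fixed_threshold` mode.
#' @param max_iter Iteration cap for the overlap dynamics.
#' @return A list with the converged `overlap`, `activity` and the logical
#'   `retrieved` (overlap >= the retrieval cut and bounded activity).
#' @export
fixed_threshold_retrieval <- function(efficacy, delta, params,
                                      max_iter = 300L) {
  stopifnot(params$mode == "fixed_threshold")
  f <- params$f
  m <- 1
  y <- f
  for (i in seq_len(max_iter)) {
    st <- ft_update(m, y, efficacy, delta, params$theta, f)
    m_new <- max(0, min(1, st[["m"]]))
    y_new <- min(1, st[["activity"]])
    if (abs(m_new - m) < 1e-10 && abs(y_new - y) < 1e-10) {
      m <- m_new; y <- y_new
      break
    }
    m <- m_new; y <- y_new
  }
  bounded <- y < 5 * f   # activity comparable to the pattern sparseness
  list(overlap = m, activity = y,
       # the memory state is a stable attractor: the dynamics stays at a
       # substantial overlap without runaway background activation
       stable = m >= 0.3 && bounded,
       retrieved = m >= params$overlap_retrieval_cut && bounded)
}

#' Critical efficacy as a function of noise at fixed threshold
#'
#' Tabulates the map `Delta -> A_c(Delta; theta)`: for each noise level on
#' the grid, the minimal efficacy at which the memory state converges to a
#' stable retrieval (overlap at least the retrieval cut, bounded
#' activity) under fixed-threshold dynamics (bisection on
#' [fixed_threshold_retrieval]). Unlike the fixed-activity case the map is
#' not linear: it has a positive floor `~ theta / (1 - f)` as
#' `Delta -> 0` (the encoding must be strong enough to cross the
#' threshold) and rises abruptly near a critical noise `delta_critical`
#' above which no efficacy yields stable retrieval, due to runaway
#' background activation.
#'
#' @param theta Firing threshold (> 0).
#' @param f Sparseness.
#' @param delta_grid Increasing grid of noise values; defaults to 200
#'   points on \[1e-4, 0.4\].
#' @param A_max Largest efficacy probed (beyond it retrieval is declared
#'   impossible).
#' @param overlap_retrieval_cut Overlap defining retrieval (default 0.85).
#' @return An object of class `threshold_model`: `theta`, `delta_grid`,
#'   `a_c` (with `Inf` above criticality), `delta_critical`.
#' @export
critical_efficacy_fixed_threshold <- function(theta, f,
                                              delta_grid = NULL,
                                              A_max = 50,
                                              overlap_retrieval_cut = 0.85) {
  stopifnot(theta > 0)
  if (is.null(delta_grid))
    delta_grid <- seq(1e-4, 0.4, length.out = 200L)
  params <- stability_params(f, "fixed_threshold", theta = theta,
                             overlap_retrieval_cut = overlap_retrieval_cut)
  # Stability need not be monotone in A near the over-activation
  # catastrophe: strong memories activate all their pattern neurons and
  # tip the background into runaway activation while weaker ones sit
  # marginally below. A noise level whose stable-efficacy set is empty or
  # fragmented is treated as supercritical (all memories lose stability),
  # matching the abrupt rise of A_c at the critical noise.
  A_grid <- exp(seq(log(theta / 4), log(A_max), length.out = 40L))
  ac <- vapply(delta_grid, function(d) {
    ok <- function(A) fixed_threshold_retrieval(A, d, params)$retrieved
    st <- vapply(A_grid, ok, logical(1))
    if (!any(st)) return(Inf)
    first <- which(st)[1]
    if (!all(st[first:length(st)])) return(Inf)   # fragmented: supercritical
    lo <- if (first == 1L) 0 else A_grid[first - 1L]
    hi <- A_grid[first]
    while (hi - lo > 1e-5 * hi) {
      mid <- (lo + hi) / 2
      if (ok(mid)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  # The quiescent (no-memory) state destabilizes when the noise alone
  # pushes the background activation above the target sparseness,
  # H(theta/Delta) > f: beyond that the network over-activates regardless
  # of the retrieved memory's efficacy.
  delta_quiescent <- theta / gauss_tail_inv(f)
  finite <- is.finite(ac)
  delta_critical <- min(delta_quiescent,
                        if (all(finite)) Inf else min(delta_grid[!finite]))
  # beyond the critical noise all memories are treated as unstable, even
  # though formally enormous efficacies could re-stabilize
  ac[delta_grid >= delta_critical] <- Inf
  structure(list(theta = theta, f = f, delta_grid = delta_grid, a_c = ac,
                 delta_critical = delta_critical,
                 overlap_retrieval_cut = overlap_retrieval_cut),
            class = "threshold_model")
}

#' Evaluate a tabulated A_c(Delta) map
#'
#' Linear interpolation of a [critical_efficacy_fixed_threshold] table;
#' `Inf` at noise levels above the critical noise.
#'
#' @param tmodel A `threshold_model`.
#' @param delta Noise values.
#' @return Critical efficacies (possibly `Inf`).
#' @export
threshold_ac <- function(tmodel, delta) {
  finite <- is.finite(tmodel$a_c)
  dg <- tmodel$delta_grid[finite]
  av <- tmodel$a_c[finite]
  out <- stats::approx(dg, av, xout = delta, yleft = av[1], yright = Inf,
                       ties = "ordered")$y
  out[delta >= tmodel$delta_critical] <- Inf
  out
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Fixed-threshold critical-efficacy map: theta =", x$theta,
      " f =", x$f, "\n  A_c floor =", signif(min(x$a_c), 4),
      " delta_critical =", signif(x$delta_critical, 4), "\n")
  invisible(x)
}
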