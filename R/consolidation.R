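#' Configuration of the mean-field consolidation simulation
#'
#' Time is measured in units of the (constant) lag between the arrival of
#' two consecutive memories, so one new memory is encoded per unit time.
#' `tau` is the synaptic decay time in these units; `lam` is the maximal
#' rehearsal rate per unit time, so `lam * tau` is the mean number of
#' rehearsals per decay time for a fully consolidated memory.
#'
#' @param N Number of neurons.
#' @param f Sparseness (default 0.01).
#' @param tau Synaptic decay time.
#' @param lam Maximal rehearsal rate; often set via `lam_tau / tau`.
#' @param b Rehearsal efficacy increment, in (0, 1): each rehearsal is
#'   weaker than the initial Hebbian encoding (amplitude 1).
#' @param dt Integration step; default `0.05 / lam` so the per-step
#'   rehearsal probability stays well below 1 (0.1/tau when `lam = 0`).
#' @param T Total simulated time; default `400 * tau`.
#' @param n_realizations Number of independent realizations.
#' @param seed Base RNG seed; realization r runs under `seed + r - 1`.
#' @param A0_dist Initial-efficacy distribution: `list(kind = "constant",
#'   value = 1)`, `list(kind = "exponential", mean = 1)`, or
#'   `list(kind = "bernoulli", a0 = ..., p = 0.5)` (value `a0` with
#'   probability `p`, else 1).
#' @param snapshot_dt Interval between recorded snapshots (default `tau/4`).
#' @param bin_width Forgetting-curve age bin width (default `tau/2`).
#' @param age_max Largest age tracked in the forgetting curve (default `T`).
#' @return A `sim_config` object.
#' @export
sim_config <- function(N, f = 0.01, tau, lam, b,
                       dt = NULL, T = 400 * tau,
                       n_realizations = 10L, seed = 1L,
                       A0_dist = list(kind = "constant", value = 1),
                       snapshot_dt = tau / 4, bin_width = tau / 2,
                       age_max = T) {
  if (is.null(dt)) dt <- if (lam > 0) 0.05 / lam else 0.1 * tau
  stopifnot(tau > 0, b >= 0, b < 1, lam >= 0, N > 0, T > 0,
            lam * dt <= 0.1 + 1e-12)
  structure(list(N = N, f = f, tau = tau, lam = lam, b = b, dt = dt, T = T,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), A0_dist = A0_dist,
                 snapshot_dt = snapshot_dt, bin_width = bin_width,
                 age_max = age_max),
            class = "sim_config")
}

draw_A0 <- function(dist, n) {
  switch(dist$kind,
         constant = rep(dist$value %||% 1, n),
         exponential = stats::rexp(n, rate = 1 / (dist$mean %||% 1)),
         bernoulli = ifelse(stats::runif(n) < (dist$p %||% 0.5), dist$a0, 1),
         stop("unknown A0 distribution kind: ", dist$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interference noise from the stored efficacies
#'
#' The standard deviation of the crosstalk field contributed by all stored
#' memories: `Delta = sqrt((f/N) * sum(A^2))`.
#'
#' @param efficacies Nonnegative efficacy vector.
#' @param f Sparseness.
#' @param N Number of neurons.
#' @return The noise level Delta.
#' @export
interference_noise <- function(efficacies, f, N) {
  stopifnot(all(efficacies >= 0))
  sqrt(f / N * sum(efficacies^2))
}

#' Rehearsal rate of a memory
#'
#' `lam * F(A / a_c)`: proportional to the memory's normalized basin of
#' attraction size. Zero for memories below the critical efficacy (they
#' are not attractors and cannot be revisited).
#'
#' @param A Efficacy (vectorized).
#' @param a_c Critical efficacy (> 0).
#' @param lam Maximal rehearsal rate.
#' @param basin A [build_basin_table] table.
#' @return Rates per unit time.
#' @export
rehearsal_rate <- function(A, a_c, lam, basin) {
  stopifnot(a_c > 0)
  lam * basin_F(basin, A / a_c)
}

#' One integration step of the efficacy ensemble
#'
#' Reference single-step update mirroring the compiled simulation core:
#' exact exponential decay, then Poisson-thinned rehearsal draws against
#' the basin of the decayed state, then insertion of one new memory at
#' each integer time, then recomputation of Delta and A_c. Useful for
#' inspecting the dynamics; long runs should use [run_simulation].
#'
#' @param state A list with `efficacies`, `birth_times`, `time`, and (once
#'   initialized) `delta`, `a_c`.
#' @param cfg A [sim_config].
#' @param basin A [build_basin_table] table.
#' @param a_f Critical ratio; defaults to `basin$a_f`.
#' @return The updated state.
#' @export
simulate_step <- function(state, cfg, basin, a_f = basin$a_f) {
  dt <- cfg$dt
  t <- state$time + dt
  A <- state$efficacies * exp(-dt / cfg$tau)
  delta <- interference_noise(A, cfg$f, cfg$N)
  a_c <- a_f * delta
  if (length(A)) {
    if (delta <= 0) {
      hit <- A > 0 & stats::runif(length(A)) < cfg$lam * dt
    } else {
      p <- rehearsal_rate(pmax(A, 0), a_c, cfg$lam, basin) * dt
      p[A < a_c] <- 0
      hit <- stats::runif(length(A)) < p
    }
    A[hit] <- A[hit] + cfg$b
  }
  new_arrivals <- state$next_arrival %||% 1
  while (new_arrivals <= t && new_arrivals <= cfg$T) {
    A <- c(A, draw_A0(cfg$A0_dist, 1L))
    state$birth_times <- c(state$birth_times, new_arrivals)
    new_arrivals <- new_arrivals + 1
  }
  delta <- interference_noise(A, cfg$f, cfg$N)
  list(efficacies = A, birth_times = state$birth_times, time = t,
       delta = delta, a_c = a_f * delta, next_arrival = new_arrivals)
}

#' Run the stochastic consolidation simulation
#'
#' Integrates the coupled efficacy dynamics over `[0, T]` for
#' `n_realizations` independent realizations (compiled core), detects the
#' equilibration of the critical efficacy, and aggregates the equilibrium
#' observables: forgetting-curve counts, capacity, consolidation
#' probability, equilibrium A_c and the consolidation fixed point.
#'
#' Equilibrium is declared when the realization-averaged A_c, averaged
#' over consecutive windows of `10 * tau`, changes by less than 2%
#' between windows.
#'
#' @param cfg A [sim_config].
#' @param basin A [build_basin_table] table for `cfg$f`.
#' @param pert Optional [perturbation_spec].
#' @param tmodel Optional [critical_efficacy_fixed_threshold] model; when
#'   supplied the simulation runs in fixed-threshold mode with
#'   `A_c = A_c(Delta; theta)` instead of `a(f) * Delta`.
#' @return An object of class `consol_sim`.
#' @export
run_simulation <- function(cfg, basin, pert = NULL, tmodel = NULL) {
  n_mem <- floor(cfg$T)
  mode <- if (is.null(tmodel)) 0L else 1L
  if (mode == 1L) {
    fin <- is.finite(tmodel$a_c)
    acmap_d <- tmodel$delta_grid[fin]
    acmap_a <- tmodel$a_c[fin]
  } else {
    acmap_d <- acmap_a <- numeric(0)
  }
  p <- pert %||% perturbation_spec("none")
  noise_on <- if (p$kind == "additive_noise") p$t_onset else Inf
  noise_off <- if (p$kind == "additive_noise") (p$t_offset %||% Inf) else Inf
  dil_on <- if (p$kind == "dilution") p$t_onset else Inf

  R <- cfg$n_realizations
  ac_mat <- NULL; above_mat <- NULL; delta_mat <- NULL
  K_pool <- NULL; N_pool <- NULL
  max_eff <- matrix(0, n_mem, R)
  final_A <- vector("list", R)
  snap_t <- NULL
  for (r in seq_len(R)) {
    set.seed(cfg$seed + r - 1L)
    A0 <- draw_A0(cfg$A0_dist, n_mem)
    res <- sim_core(n_mem, A0, cfg$f, cfg$N, cfg$tau, cfg$lam, cfg$b,
                    cfg$dt, cfg$T, basin$a_f,
                    basin$x_grid, basin$F_values,
                    mode, acmap_d, acmap_a,
                    p$D %||% 0, noise_on, noise_off,
                    p$p %||% 0, dil_on,
                    cfg$snapshot_dt, cfg$bin_width, cfg$age_max,
                    1e-6, 10 * cfg$tau)
    if (is.null(ac_mat)) {
      snap_t <- res$snap_t
      ac_mat <- matrix(0, length(snap_t), R)
      above_mat <- matrix(0, length(snap_t), R)
      delta_mat <- matrix(0, length(snap_t), R)
      K_pool <- res$curve_k * 0L
      N_pool <- res$curve_n * 0L
    }
    ac_mat[, r] <- res$snap_ac
    delta_mat[, r] <- res$snap_delta
    above_mat[, r] <- res$snap_above
    K_pool <- K_pool + res$curve_k
    N_pool <- N_pool + res$curve_n
    max_eff[, r] <- res$max_eff
    final_A[[r]] <- res$final_A
  }

  ac_mean <- rowMeans(ac_mat)
  # equilibrium detection uses the interference noise: always finite,
  # while A_c can be +Inf during fixed-threshold blockade episodes
  eq <- detect_equilibrium(snap_t, rowMeans(delta_mat), window = 10 * cfg$tau)
  post <- snap_t >= eq$t_eq
  if (!eq$reached)
    warning("critical efficacy did not equilibrate within T; ",
            "observables use the final 20% of the run")
  ok <- is.finite(ac_mat[post, , drop = FALSE])
  a_c_eq <- mean(ac_mat[post, , drop = FALSE][ok])
  cap <- mean(above_mat[post, , drop = FALSE][ok])
  a_fp <- efficacy_fixed_point(a_c_eq, cfg$b, cfg$lam, cfg$tau, basin)

  # consolidation: a memory counts as consolidated once its efficacy has
  # crossed most (80%) of the gap from A_c to the fixed point
  p_c <- NA_real_
  if (is.finite(a_fp) && a_fp > a_c_eq) {
    thr <- a_c_eq + 0.8 * (a_fp - a_c_eq)
    births <- seq_len(n_mem)
    sel <- births >= eq$t_eq & births <= cfg$T - 5 * cfg$tau
    if (any(sel)) p_c <- mean(max_eff[sel, , drop = FALSE] > thr)
  }

  structure(list(cfg = cfg, basin = basin, pert = pert, tmodel = tmodel,
                 snap_t = snap_t, ac_mat = ac_mat, ac_mean = ac_mean,
                 delta_mat = delta_mat, above_mat = above_mat,
                 curve_k = K_pool, curve_n = N_pool,
                 max_eff = max_eff, final_A = final_A,
                 t_eq = eq$t_eq, equilibrated = eq$reached,
                 summary = list(capacity = cap, p_c = p_c,
                                a_fp = a_fp, a_c_eq = a_c_eq)),
            class = "consol_sim")
}

detect_equilibrium <- function(snap_t, ac, window) {
  n_w <- max(2L, floor(window / (snap_t[2] - snap_t[1])))
  n_full <- floor(length(ac) / n_w)
  if (n_full >= 2L) {
    wm <- vapply(seq_len(n_full), function(i)
      mean(ac[((i - 1L) * n_w + 1L):(i * n_w)]), numeric(1))
    for (i in 2:n_full) {
      if (is.finite(wm[i]) && is.finite(wm[i - 1]) &&
          abs(wm[i] - wm[i - 1]) < 0.02 * abs(wm[i]))
        return(list(t_eq = snap_t[i * n_w], reached = TRUE))
    }
  }
  list(t_eq = stats::quantile(snap_t, 0.8, names = FALSE), reached = FALSE)
}

#' @export
print.consol_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Consolidation simulation: N=%g tau=%g lam*tau=%g b=%g (%d realizations)\n",
    x$cfg$N, x$cfg$tau, x$cfg$lam * x$cfg$tau, x$cfg$b, x$cfg$n_realizations))
  cat(sprintf("  equilibrium A_c = %.4g (t_eq = %.3g tau)\n",
              s$a_c_eq, x$t_eq / x$cfg$tau))
  cat(sprintf("  capacity = %.4g  A_fp = %.4g  p_c = %.3g\n",
              s$capacity, s$a_fp, s$p_c))
  invisible(x)
}

#' Consolidation fixed point of the mean efficacy dynamics
#'
#' Largest nonnegative solution of `A = b * lam * tau * F(A / a_c)`,
#' found by fixed-point iteration from `A = b * lam * tau` (the iteration
#' is monotone decreasing from there, so it converges to the largest
#' solution). Returns 0 when only the zero solution exists, i.e. when the
#' maximal rehearsal drive `b * lam * tau` cannot keep an efficacy above
#' the critical value.
#'
#' @param a_c Critical efficacy (> 0).
#' @param b,lam,tau Model parameters.
#' @param basin A basin table.
#' @return The fixed point `A_fp >= 0`.
#' @export
efficacy_fixed_point <- function(a_c, b, lam, tau, basin) {
  stopifnot(a_c > 0)
  A <- b * lam * tau
  if (A <= a_c) return(0)
  for (i in 1:500) {
    A_new <- b * lam * tau * basin_F(basin, A / a_c)
    if (abs(A_new - A) < 1e-12) { A <- A_new; break }
    A <- A_new
  }
  if (A <= a_c * (1 + 1e-9)) 0 else A
}

#' Pure-forgetting analytics
#'
#' Without rehearsals efficacies decay as `exp(-age/tau)` and the
#' equilibrium interference gives a reference decay time
#' `tau0 = 2N / (f a(f)^2)`. For `tau < tau0` memories younger than the
#' catastrophic age `t0 = (tau/2) log(tau0/tau)` are retrievable and all
#' older ones are lost; `t0` is also the pure-forgetting capacity (one
#' memory arrives per unit time). For `tau >= tau0` the critical efficacy
#' exceeds the encoding strength and no memory is retrievable.
#'
#' @param N,f,tau Model parameters.
#' @param a_f Critical ratio a(f).
#' @return List with `tau0`, `t0`, `capacity` and `retrievable` (FALSE
#'   when global catastrophic forgetting occurs).
#' @export
pure_forgetting_analytics <- function(N, f, tau, a_f) {
  stopifnot(tau > 0)
  tau0 <- 2 * N / (f * a_f^2)
  if (tau >= tau0) {
    list(tau0 = tau0, t0 = 0, capacity = 0, retrievable = FALSE)
  } else {
    t0 <- tau / 2 * log(tau0 / tau)
    list(tau0 = tau0, t0 = t0, capacity = t0, retrievable = TRUE)
  }
}

#' Forgetting curve of a simulation
#'
#' Retrieval probability (fraction of efficacies above A_c) as a function
#' of memory age, pooled over all post-equilibrium snapshots and
#' realizations. Empty bins are dropped.
#'
#' @param sim A [run_simulation] result.
#' @param min_count Minimum pooled sample count per bin.
#' @return A `forgetting_curve` data frame with columns `age`, `age_tau`,
#'   `prob`, `n`.
#' @export
forgetting_curve <- function(sim, min_count = 1L) {
  # condition on the network's normal operating state: fixed-threshold
  # blockade instants (A_c momentarily infinite at the over-activation
  # edge) are measurement gaps, not part of the retention statistics
  post <- sim$snap_t >= sim$t_eq & rowMeans(is.finite(sim$ac_mat)) == 1
  bw <- sim$cfg$bin_width
  # only memories born after equilibration: at snapshot time t, ages up to
  # t - t_eq (earlier cohorts consolidated under a lower A_c and would
  # bias the old-age bins upward)
  n_bins <- ncol(sim$curve_k)
  mask <- outer(sim$snap_t[post] - sim$t_eq, seq_len(n_bins) * bw, `>=`)
  k <- colSums(sim$curve_k[post, , drop = FALSE] * mask)
  n <- colSums(sim$curve_n[post, , drop = FALSE] * mask)
  age <- (seq_along(k) - 0.5) * bw
  keep <- n >= min_count
  out <- data.frame(age = age[keep], age_tau = age[keep] / sim$cfg$tau,
                    prob = k[keep] / n[keep], n = n[keep])
  class(out) <- c("forgetting_curve", "data.frame")
  attr(out, "tau") <- sim$cfg$tau
  out
}

#' Equilibrium memory capacity
#'
#' Time-averaged number of retrievable memories (efficacies strictly
#' above A_c) over the post-equilibrium phase.
#'
#' @param sim A [run_simulation] result.
#' @return The capacity (a count).
#' @export
capacity <- function(sim) sim$summary$capacity

#' Consolidation probability
#'
#' Fraction of memories (born after equilibration, with time left to
#' consolidate) whose efficacy ever climbed into the neighbourhood of the
#' consolidation fixed point.
#'
#' @param sim A [run_simulation] result.
#' @return `p_c` in \[0, 1\] (`NA` when no nonzero fixed point exists).
#' @export
consolidation_probability <- function(sim) sim$summary$p_c

#' Consolidation time from the forgetting-curve tail
#'
#' Fits the exponential tail (ages beyond `tail_from_tau` decay times) of
#' the forgetting curve; the fitted time constant is the consolidation
#' time `tau_c`. With `model = "double_exponential"` the slow component
#' is reported (used when a sizable fraction of memories never
#' consolidates, producing an initial fast decay of the curve).
#'
#' @param sim_or_curve A `consol_sim` or `forgetting_curve`.
#' @param model `"exponential"` or `"double_exponential"`.
#' @param tail_from_tau Fit window start, in units of tau (exponential
#'   fits only; default 5).
#' @return List with `tau_c` (units of tau) and the [fit_exponential_tail]
#'   or [fit_double_exponential] result. For a pure-forgetting run
#'   (`lam = 0`) there is no exponential tail and `tau_c` is `NA` with
#'   `pure_forgetting = TRUE`.
#' @export
consolidation_time <- function(sim_or_curve,
                               model = c("exponential", "double_exponential"),
                               tail_from_tau = 5) {
  model <- match.arg(model)
  if (inherits(sim_or_curve, "consol_sim")) {
    if (sim_or_curve$cfg$lam == 0)
      return(list(tau_c = NA_real_, pure_forgetting = TRUE, fit = NULL))
    curve <- forgetting_curve(sim_or_curve)
  } else curve <- sim_or_curve
  tau <- attr(curve, "tau")
  # bins with fewer than 5 retrieval events sit at the sampling noise
  # floor and would masquerade as an extra slow component; the oldest
  # clean cohorts (born right at the detected equilibration time) carry a
  # residual upward bias from the last percents of A_c drift, so the fit
  # uses the younger half of the observed age range
  curve <- curve[curve$prob * curve$n >= 5, ]
  age_hi <- 0.5 * max(curve$age)
  if (model == "exponential") {
    fit <- fit_exponential_tail(curve, range = c(tail_from_tau * tau, age_hi))
    list(tau_c = fit$params[["tau1"]] / tau, pure_forgetting = FALSE, fit = fit)
  } else {
    fit <- fit_double_exponential(curve, range = c(0, age_hi))
    list(tau_c = fit$params[["tau2"]] / tau, pure_forgetting = FALSE, fit = fit)
  }
}

#' Closed-form approximations to A_c and the capacity
#'
#' In the regime where nearly every memory consolidates (`p_c ~ 1`), the
#' interference is dominated by consolidated memories, giving
#' \deqn{A_c \approx \sqrt{f a(f)^2 p_c \tau_c / N}\; b \lambda \tau,}
#' and eliminating `tau_c` self-consistently yields a power-law capacity
#' \deqn{capacity \approx \tau_c \approx \tau^{1/(1+\lambda\tau/2)}
#'   (N / (f a(f)^2))^{\lambda\tau/(2+\lambda\tau)}.}
#' The N-scaling exponent `lam*tau / (2 + lam*tau)` approaches 1 for
#' large `lam*tau`.
#'
#' @param N,f,tau,lam,b Model parameters.
#' @param a_f Critical ratio.
#' @param p_c,tau_c Consolidation probability and time (`tau_c` in units
#'   of tau) for the A_c estimate; defaults assume full consolidation
#'   with the self-consistent `tau_c`.
#' @return List with `a_c_approx`, `capacity_approx`, `exponent`.
#' @export
capacity_approximation <- function(N, f, tau, lam, b, a_f,
                                   p_c = 1, tau_c = NULL) {
  lt <- lam * tau
  exponent <- lt / (2 + lt)
  capacity_approx <- tau^(1 / (1 + 0.5 * lt)) * (N / (f * a_f^2))^exponent
  if (is.null(tau_c)) tau_c <- capacity_approx / tau
  a_c_approx <- sqrt(f * a_f^2 * p_c * (tau_c * tau) / N) * b * lt
  list(a_c_approx = a_c_approx, capacity_approx = capacity_approx,
       exponent = exponent)
}

#' Equilibrium efficacy distribution
#'
#' Pools the final-state efficacies of all realizations into a log-binned
#' density. The distribution is bimodal: a `p(A) = tau / A` branch below
#' A_c from decaying (forgotten) memories, whose log-log slope is -1, and
#' a consolidated mode around A_fp.
#'
#' @param sim A [run_simulation] result.
#' @param n_bins Number of logarithmic bins.
#' @param fit_range Efficacy range (as fractions of A_c) for the sub-A_c
#'   slope fit.
#' @return List with the binned `density` data frame, `sub_ac_slope`, and
#'   `mode_consolidated` (`NA` when no consolidated mode exists).
#' @export
efficacy_histogram <- function(sim, n_bins = 60L, fit_range = c(0.005, 0.5)) {
  A <- unlist(sim$final_A)
  A <- A[A > 0]
  a_c <- sim$summary$a_c_eq
  br <- exp(seq(log(min(A)), log(max(A) * (1 + 1e-9)), length.out = n_bins + 1L))
  idx <- findInterval(A, br, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  d <- data.frame(mid = sqrt(br[-length(br)] * br[-1]),
                  density = counts / (length(A) * diff(br)),
                  count = counts)
  sel <- d$mid > fit_range[1] * a_c & d$mid < fit_range[2] * a_c & d$density > 0
  slope <- if (sum(sel) >= 3)
    unname(stats::coef(stats::lm(log(density) ~ log(mid), data = d[sel, ]))[2])
  else NA_real_
  above <- d[d$mid > a_c & d$count > 0, ]
  mode_c <- if (nrow(above)) above$mid[which.max(above$density)] else NA_real_
  list(density = d, a_c_eq = a_c, sub_ac_slope = slope,
       mode_consolidated = mode_c)
}
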