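#' Specification of a structural perturbation
#'
#' @param kind `"none"`, `"additive_noise"` (white noise added to the
#'   synaptic dynamics, diffusion coefficient `D`) or `"dilution"`
#'   (random silencing of a fraction `p` of synapses).
#' @param D Diffusion coefficient of the additive synaptic noise.
#' @param p Silenced synapse fraction in \[0, 1).
#' @param t_onset Perturbation onset time.
#' @param t_offset Optional end of a transient perturbation window
#'   (additive noise only); `NULL` means permanent.
#' @param theta Fixed firing threshold in effect during the experiment.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(kind = c("none", "additive_noise", "dilution"),
                              D = 0, p = 0, t_onset = Inf, t_offset = NULL,
                              theta = 0.36) {
  kind <- match.arg(kind)
  stopifnot(D >= 0, p >= 0, p < 1)
  if (!is.null(t_offset)) stopifnot(t_offset > t_onset)
  structure(list(kind = kind, D = D, p = p, t_onset = t_onset,
                 t_offset = t_offset, theta = theta),
            class = "perturbation_spec")
}

#' Field variance under additive synaptic noise
#'
#' After the onset of synaptic white noise with diffusion coefficient
#' `D`, the accumulated noise adds a saturating term to the interference
#' variance:
#' \deqn{\Delta^2(t) = \Delta^2_{mem}(t) +
#'   f \frac{\tau D^2}{2N}\left(1 - e^{-2 (t - t_{on})/\tau}\right).}
#' The prefactor `f` puts the added term in the same normalization as the
#' memory-interference variance `(f/N) sum A^2` (the variance of the
#' local field on the `f N` active inputs).
#'
#' @param delta_sq_base Memory-interference variance `(f/N) sum A^2`.
#' @param D Diffusion coefficient.
#' @param tau Synaptic decay time.
#' @param N Number of neurons.
#' @param f Sparseness.
#' @param t Current time (`>= t_onset`).
#' @param t_onset Noise onset time.
#' @return The total field variance Delta^2.
#' @export
effective_noise_additive <- function(delta_sq_base, D, tau, N, f, t, t_onset) {
  stopifnot(t >= t_onset)
  delta_sq_base +
    f * tau * D^2 / (2 * N) * (1 - exp(-2 * (t - t_onset) / tau))
}

#' Mean-field effect of synaptic dilution
#'
#' Silencing a fraction `p` of synapses scales every memory's retrieval
#' signal by `(1 - p)` and the interference variance by `(1 - p)` (so the
#' noise amplitude by `sqrt(1 - p)`): the signal-to-noise ratio
#' deteriorates by `sqrt(1 - p)`.
#'
#' @param efficacies Efficacy vector.
#' @param delta Interference noise before dilution.
#' @param p Silenced fraction in \[0, 1).
#' @return List with `efficacies_eff` (scaled signal), `delta_eff`.
#' @export
apply_dilution_meanfield <- function(efficacies, delta, p) {
  stopifnot(p >= 0, p < 1)
  list(efficacies_eff = (1 - p) * efficacies,
       delta_eff = sqrt(1 - p) * delta)
}

#' Randomly silence synapses in a full network
#'
#' Applies an elementwise Bernoulli(1-p) mask to the connectivity matrix.
#' The mask is symmetric (`C_ij = C_ji`): a silenced synapse dies on both
#' directions of the symmetric pair, preserving the symmetry of `J` that
#' the attractor dynamics relies on.
#'
#' @param conn A [build_connectivity] object.
#' @param p Silenced fraction.
#' @return A new `connectivity` with the diluted matrix and the mask.
#' @export
dilution_full_network <- function(conn, p) {
  stopifnot(p >= 0, p < 1)
  N <- conn$N
  C <- matrix(1, N, N)
  upper <- upper.tri(C)
  C[upper] <- as.numeric(stats::runif(sum(upper)) >= p)
  C[lower.tri(C)] <- t(C)[lower.tri(C)]  # C_ij = C_ji
  diag(C) <- 0
  structure(list(J = conn$J * C, f = conn$f, N = N, dilution_mask = C),
            class = "connectivity")
}

#' Consolidation dynamics under a structural perturbation
#'
#' Runs the mean-field consolidation simulation in fixed-threshold mode
#' (critical efficacy from the tabulated `A_c(Delta; theta)` map) with the
#' perturbation switched on at `t_onset`, together with a control run on
#' identical seeds, and extracts forgetting curves at a set of delays
#' after the onset plus the perturbed/control capacity ratio.
#'
#' @param cfg A [sim_config]; `T` should leave room for the longest delay
#'   after `pert$t_onset`.
#' @param pert A [perturbation_spec] with finite `t_onset`.
#' @param basin A basin table for `cfg$f`.
#' @param tmodel A [critical_efficacy_fixed_threshold] model for
#'   `pert$theta`; computed on the fly when omitted.
#' @param delays_tau Curve measurement delays after onset, in units of
#'   tau (default 5, 10, 20, 40).
#' @return List with `curves` (one forgetting curve per delay, pooled
#'   over realizations, plus the control at matched times),
#'   `capacity_ratio`, and the two `consol_sim` objects.
#' @export
perturbed_run <- function(cfg, pert, basin, tmodel = NULL,
                          delays_tau = c(5, 10, 20, 40)) {
  stopifnot(is.finite(pert$t_onset))
  if (is.null(tmodel))
    tmodel <- critical_efficacy_fixed_threshold(pert$theta, cfg$f)
  control <- run_simulation(cfg, basin, pert = NULL, tmodel = tmodel)
  perturbed <- run_simulation(cfg, basin, pert = pert, tmodel = tmodel)
  times <- pert$t_onset + delays_tau * cfg$tau
  curves <- lapply(times, function(tt) {
    list(delay_tau = (tt - pert$t_onset) / cfg$tau,
         perturbed = snapshot_curve(perturbed, tt),
         control = snapshot_curve(control, tt))
  })
  post_p <- perturbed$snap_t >= pert$t_onset &
    rowMeans(is.finite(perturbed$ac_mat)) == 1
  post_c <- control$snap_t >= pert$t_onset &
    rowMeans(is.finite(control$ac_mat)) == 1
  cap_ratio <- mean(perturbed$above_mat[post_p, , drop = FALSE]) /
    mean(control$above_mat[post_c, , drop = FALSE])
  list(curves = curves, capacity_ratio = cap_ratio,
       control = control, perturbed = perturbed)
}

# Forgetting curve from the snapshots closest to time `t`, pooled over
# realizations; blockade snapshots (non-finite A_c) are skipped.
snapshot_curve <- function(sim, t, min_count = 1L) {
  usable <- which(rowMeans(is.finite(sim$ac_mat)) == 1)
  i <- usable[which.min(abs(sim$snap_t[usable] - t))]
  k <- sim$curve_k[i, ]
  n <- sim$curve_n[i, ]
  bw <- sim$cfg$bin_width
  age <- (seq_along(k) - 0.5) * bw
  keep <- n >= min_count
  out <- data.frame(age = age[keep], age_tau = age[keep] / sim$cfg$tau,
                    prob = k[keep] / n[keep], n = n[keep])
  class(out) <- c("forgetting_curve", "data.frame")
  attr(out, "tau") <- sim$cfg$tau
  attr(out, "time") <- sim$snap_t[i]
  out
}

#' Capacity-maximizing firing threshold
#'
#' Grid search over thresholds: for each theta, tabulates the
#' fixed-threshold critical-efficacy map, runs the (possibly perturbed)
#' consolidation simulation under common random numbers, and returns the
#' theta with the largest post-equilibration capacity.
#'
#' @param cfg A [sim_config].
#' @param basin A basin table.
#' @param pert Optional [perturbation_spec].
#' @param theta_grid Thresholds to evaluate (default 0.2 to 0.5 by 0.01).
#' @return List with `theta_best`, and a data frame of `theta` versus
#'   `capacity`.
#' @export
optimize_threshold <- function(cfg, basin, pert = NULL,
                               theta_grid = seq(0.2, 0.5, by = 0.01)) {
  caps <- vapply(theta_grid, function(th) {
    tm <- critical_efficacy_fixed_threshold(th, cfg$f)
    p <- pert
    if (!is.null(p)) p$theta <- th
    sim <- run_simulation(cfg, basin, pert = p, tmodel = tm)
    capacity(sim)
  }, numeric(1))
  list(theta_best = theta_grid[which.max(caps)],
       table = data.frame(theta = theta_grid, capacity = caps))
}

#' Diagnostic: efficacy-noise cross-term under additive synaptic noise
#'
#' The analytic treatment of additive noise drops the mixed term coupling
#' the Hebbian efficacies to the accumulated synaptic noise. This
#' diagnostic estimates both contributions to the local-field variance on
#' a small full network and returns the relative magnitude of the mixed
#' term, which should be negligible.
#'
#' @param N Network size for the Monte-Carlo estimate.
#' @param f Sparseness.
#' @param n_mem Number of stored memories.
#' @param noise_sd Standard deviation of the accumulated per-synapse
#'   noise.
#' @param n_draws Monte-Carlo draws.
#' @return List with the relative mixed-term contribution
#'   `relative_mixed` and the two variance components.
#' @export
noise_mixed_term_diagnostic <- function(N = 1000, f = 0.01, n_mem = 50,
                                        noise_sd = 0.05, n_draws = 50) {
  mem <- generate_patterns(n_mem, N, f)
  A <- stats::runif(n_mem, 0.5, 1.5)
  conn <- build_connectivity(mem, A)
  sigma <- mem$patterns[1, ]
  covs <- var_mem <- var_noise <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    E <- matrix(stats::rnorm(N * N, sd = noise_sd), N, N)
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    diag(E) <- 0
    h_mem <- drop(conn$J %*% sigma)
    h_noise <- drop(E %*% sigma)
    var_mem[i] <- stats::var(h_mem)
    var_noise[i] <- stats::var(h_noise)
    covs[i] <- stats::cov(h_mem, h_noise)
  }
  list(relative_mixed = abs(2 * mean(covs)) /
         (mean(var_mem) + mean(var_noise)),
       var_mem = mean(var_mem), var_noise = mean(var_noise))
}
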