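# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fx_params <- function() stability_params(0.01)

fx_af <- function() {
  if (is.null(.fixtures$af)) .fixtures$af <- critical_ratio(fx_params())
  .fixtures$af
}

fx_basin <- function() {
  if (is.null(.fixtures$basin))
    .fixtures$basin <- build_basin_table(fx_params(), a_f = fx_af())
  .fixtures$basin
}

fx_tmodel <- function(theta = 0.36) {
  key <- paste0("tm_", theta)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- critical_efficacy_fixed_threshold(theta, 0.01)
  .fixtures[[key]]
}

# Reference equilibrium run (the lam*tau = 5, b = 0.3 setting), shared by
# the forgetting-curve, capacity and histogram checks.
fx_sim_lt5 <- function() {
  if (is.null(.fixtures$sim_lt5)) {
    cfg <- sim_config(N = 8000, f = 0.01, tau = 160, lam = 5 / 160, b = 0.3,
                      T = 400 * 160, n_realizations = 10L, seed = 1L)
    .fixtures$sim_lt5 <- run_simulation(cfg, fx_basin())
  }
  .fixtures$sim_lt5
}

# Independent Gaussian-tail oracle: direct quadrature of the defining
# integral, plus a bisection inverse. Used to freeze expected values
# without relying on the same special functions as the implementation.
oracle_H <- function(x) {
  vapply(x, function(xx) {
    if (xx < 0) {   # reflect: quadrature over a wide interval misses the mass
      1 - stats::integrate(function(t) exp(-0.5 * t^2) / sqrt(2 * pi),
                           -xx, Inf, rel.tol = 1e-12)$value
    } else {
      stats::integrate(function(t) exp(-0.5 * t^2) / sqrt(2 * pi),
                       xx, Inf, rel.tol = 1e-12)$value
    }
  }, numeric(1))
}

oracle_H_inv <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(x) oracle_H(x) - pp, c(-12, 12),
                   tol = 1e-12)$root, numeric(1))
}
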