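test_that("interference noise: basic values and the pure-forgetting equilibrium level", {
  expect_equal(interference_noise(numeric(0), 0.01, 100), 0)
  expect_equal(interference_noise(rep(0, 5), 0.01, 100), 0)
  expect_equal(interference_noise(1, 0.01, 100), 0.01)
  # efficacies decaying one per unit time: Delta^2 -> f*tau/(2N)
  tau <- 500; N <- 4000; f <- 0.01
  A <- exp(-(seq_len(20 * tau) - 0.5) / tau)
  expect_equal(interference_noise(A, f, N), sqrt(f * tau / (2 * N)),
               tolerance = 0.01)
})

test_that("rehearsal rate is gated by the critical efficacy and saturates at lambda", {
  bt <- fx_basin()
  lam <- 0.05
  expect_equal(rehearsal_rate(0.5 * 0.4, 0.4, lam, bt), 0)
  expect_equal(rehearsal_rate(0.4, 0.4, lam, bt), 0)   # saddle-node: width 0
  expect_equal(rehearsal_rate(40 * 0.4, 0.4, lam, bt), lam, tolerance = 1e-6)
  expect_error(rehearsal_rate(1, 0, lam, bt))
})

test_that("a single step without rehearsals is exact exponential decay", {
  bt <- fx_basin()
  cfg <- sim_config(N = 1000, tau = 50, lam = 0, b = 0.3, T = 100,
                    dt = 0.5, seed = 1)
  st <- list(efficacies = c(1, 0.4), birth_times = c(-10, -5), time = 0,
             next_arrival = Inf)   # suppress arrivals
  set.seed(1)
  st2 <- simulate_step(st, cfg, bt, a_f = fx_af())
  expect_identical(st2$efficacies, c(1, 0.4) * exp(-0.5 / 50))
  # over many steps the closed form is reproduced to machine precision
  for (i in 1:200) st2 <- simulate_step(st2, cfg, bt, a_f = fx_af())
  expect_equal(st2$efficacies, c(1, 0.4) * exp(-st2$time / 50),
               tolerance = 1e-13)
  # Delta is consistent with the state it reports
  expect_equal(st2$delta,
               interference_noise(st2$efficacies, cfg$f, cfg$N),
               tolerance = 1e-12)
})

test_that("memories arrive once per unit time with the configured initial efficacy", {
  bt <- fx_basin()
  cfg <- sim_config(N = 1000, tau = 50, lam = 0, b = 0.3, T = 10,
                    dt = 0.25, seed = 1)
  st <- list(efficacies = numeric(0), birth_times = numeric(0), time = 0)
  set.seed(2)
  for (i in 1:40) st <- simulate_step(st, cfg, bt, a_f = fx_af())
  expect_equal(length(st$efficacies), 10)
  expect_equal(st$birth_times, 1:10)
})

test_that("per-step thinning reproduces homogeneous Poisson counts", {
  bt <- fx_basin()
  lam <- 0.05
  dt <- 0.05 / lam
  rate <- rehearsal_rate(1.2, 0.4, lam, bt)     # pinned ratio A/A_c = 3
  n_steps <- 120L
  mu <- rate * n_steps * dt
  set.seed(7)
  n_trials <- 4000L
  counts <- stats::rbinom(n_trials, n_steps, rate * dt)
  expect_gte(sum(counts), 1e4)
  # chi-square GOF against the Poisson pmf with matched mean
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, kmax + 1L)
  p <- stats::dpois(0:kmax, mu)
  keep <- p * n_trials >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(p[keep], 1 - sum(p[keep]))
  chi <- sum((obs2 - n_trials * p2)^2 / (n_trials * p2))
  pval <- stats::pchisq(chi, df = length(obs2) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("pure-forgetting analytics: reference values and the catastrophic limit", {
  af <- fx_af()
  pf <- pure_forgetting_analytics(8000, 0.01, 2240, af)
  expect_equal(pf$t0 / 2240, 1.73, tolerance = 0.02)
  expect_equal(pf$capacity / 8000, 0.5, tolerance = 0.03)
  tau0 <- pf$tau0
  expect_equal(pure_forgetting_analytics(8000, 0.01, tau0, af)$t0, 0)
  expect_false(pure_forgetting_analytics(8000, 0.01, 2 * tau0, af)$retrievable)
})

test_that("consolidation fixed point: reference value, zero branch, subcritical drive", {
  bt <- fx_basin()
  a_fp <- efficacy_fixed_point(0.4, 0.3, 5 / 160, 160, bt)
  expect_equal(a_fp, 1.5, tolerance = 0.1)
  # drive below the critical efficacy only admits the zero solution
  expect_equal(efficacy_fixed_point(0.5, 0.3, 0.5 / 160, 160, bt), 0)
  # fixed point solves its own equation
  expect_equal(a_fp, 0.3 * 5 * basin_F(bt, a_fp / 0.4), tolerance = 1e-8)
})

test_that("short run: equilibration, capacity/area consistency, monotone curve, determinism", {
  bt <- fx_basin()
  cfg <- sim_config(N = 2000, f = 0.01, tau = 20, lam = 5 / 20, b = 0.3,
                    T = 200 * 20, n_realizations = 3L, seed = 4L)
  sim <- run_simulation(cfg, bt)
  expect_true(sim$equilibrated)
  expect_gt(capacity(sim), 0)
  fc <- forgetting_curve(sim)
  area <- sum(fc$prob) * cfg$bin_width
  expect_lt(abs(area - capacity(sim)) / capacity(sim), 0.1)
  # monotone nonincreasing up to 3 binomial SE per bin
  se <- sqrt(pmax(fc$prob * (1 - fc$prob), 1e-6) / fc$n)
  rises <- diff(fc$prob) - 3 * (se[-1] + se[-length(se)])
  expect_true(all(rises <= 0))
  # p_c in range and near 1 for moderate drive (b*lam*tau = 1.5)
  expect_gte(consolidation_probability(sim), 0.5)
  expect_lte(consolidation_probability(sim), 1)
  sim2 <- run_simulation(cfg, bt)
  expect_identical(sim$ac_mat, sim2$ac_mat)
  expect_identical(sim$curve_k, sim2$curve_k)
  expect_identical(sim$max_eff, sim2$max_eff)
})

test_that("without rehearsals the efficacy distribution has only the 1/A branch", {
  bt <- fx_basin()
  cfg <- sim_config(N = 2000, f = 0.01, tau = 20, lam = 0, b = 0.3,
                    T = 150 * 20, n_realizations = 3L, seed = 5L)
  sim <- run_simulation(cfg, bt)
  h <- efficacy_histogram(sim)
  expect_equal(h$sub_ac_slope, -1, tolerance = 0.15)
  expect_true(is.na(h$mode_consolidated) ||
                h$mode_consolidated < 3 * sim$summary$a_c_eq)
  # pure forgetting: consolidation time undefined, flagged
  ct <- consolidation_time(sim)
  expect_true(ct$pure_forgetting)
  expect_true(is.na(ct$tau_c))
})

test_that("capacity approximation: analytic exponent values and limits", {
  af <- fx_af()
  ca <- capacity_approximation(8000, 0.01, 160, 5 / 160, 0.3, af)
  expect_equal(ca$exponent, 5 / 7, tolerance = 1e-12)
  big <- capacity_approximation(8000, 0.01, 160, 500 / 160, 0.3, af)
  expect_gt(big$exponent, 0.99)
  expect_gt(ca$a_c_approx, 0)
})
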