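test_that("additive-noise variance: onset, saturation, and identity at D=0", {
  base <- 0.02
  expect_equal(effective_noise_additive(base, 6, 160, 8000, 0.01, 100, 100),
               base)
  expect_equal(effective_noise_additive(base, 6, 160, 8000, 0.01, 1e7, 0),
               base + 0.01 * 160 * 36 / 16000, tolerance = 1e-10)
  expect_equal(effective_noise_additive(base, 0, 160, 8000, 0.01, 500, 0),
               base)
  expect_error(effective_noise_additive(base, 6, 160, 8000, 0.01, 1, 10))
})

test_that("mean-field dilution scales signal by (1-p) and noise by sqrt(1-p)", {
  A <- c(1, 2, 0.3)
  d0 <- apply_dilution_meanfield(A, 0.1, 0)
  expect_identical(d0$efficacies_eff, A)
  expect_identical(d0$delta_eff, 0.1)
  d <- apply_dilution_meanfield(A, 0.1, 0.75)
  expect_equal(d$efficacies_eff, 0.25 * A)
  expect_equal(d$delta_eff, 0.05)
})

test_that("full-network dilution: symmetric mask with the right silencing fraction", {
  set.seed(11)
  mem <- generate_patterns(20, 400, 0.05, exact_count = TRUE)
  conn <- build_connectivity(mem, rep(1, 20))
  expect_identical(dilution_full_network(conn, 0)$J, conn$J)
  dil <- dilution_full_network(conn, 0.3)
  C <- dil$dilution_mask
  expect_identical(C, t(C))
  off <- C[upper.tri(C)]
  p_hat <- 1 - mean(off)
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / length(off)))
  expect_true(all(dil$J[C == 0] == 0))
  near <- dilution_full_network(conn, 0.99)
  expect_lt(mean(near$J != 0), 0.03)
})

test_that("masked-field statistics match the diluted signal and noise scalings", {
  set.seed(12)
  N <- 2000; f <- 0.01; n_mem <- 120; p <- 0.5
  k <- round(f * N)
  zm <- numeric(6)
  v_ratio <- numeric(6)
  for (r in 1:6) {
    mem <- generate_patterns(n_mem, N, f, exact_count = TRUE)
    A <- c(1, stats::runif(n_mem - 1, 0.2, 1.2))
    conn <- dilution_full_network(build_connectivity(mem, A), p)
    sigma <- mem$patterns[1, ]
    h <- drop(conn$J %*% sigma)
    on <- sigma == 1
    pred_mean <- (1 - p) * (1 - f) * A[1] * (k - 1) / k
    pred_var <- (1 - p) * f / N * sum(A[-1]^2)
    # the mask thins the signal inputs: binomial noise
    # (A(1-f)/k)^2 (k-1) p (1-p) per neuron on top of the interference
    se <- sqrt(((A[1] * (1 - f) / k)^2 * (k - 1) * p * (1 - p) +
                  pred_var) / k)
    zm[r] <- (mean(h[on]) - pred_mean) / se
    v_ratio[r] <- stats::var(h[!on]) / pred_var
  }
  expect_lt(abs(mean(zm)) / sqrt(1 / 6), 3)
  expect_lt(abs(mean(v_ratio) - 1), 4 * sqrt(2 / (n_mem * 6)))
})

test_that("the efficacy-noise cross term is negligible", {
  set.seed(13)
  d <- noise_mixed_term_diagnostic(N = 800, n_mem = 40, n_draws = 30)
  expect_lt(d$relative_mixed, 0.05)
})

test_that("null perturbations reproduce the control bitwise", {
  bt <- fx_basin()
  tm <- fx_tmodel(0.36)
  cfg <- sim_config(N = 2000, f = 0.01, tau = 20, lam = 10 / 20, b = 0.25,
                    T = 60 * 20, n_realizations = 2L, seed = 21L)
  ctl <- run_simulation(cfg, bt, tmodel = tm)
  d0 <- run_simulation(cfg, bt, tmodel = tm,
                       pert = perturbation_spec("additive_noise", D = 0,
                                                t_onset = 30 * 20))
  p0 <- run_simulation(cfg, bt, tmodel = tm,
                       pert = perturbation_spec("dilution", p = 0,
                                                t_onset = 30 * 20))
  expect_identical(ctl$ac_mat, d0$ac_mat)
  expect_identical(ctl$curve_k, d0$curve_k)
  expect_identical(ctl$max_eff, d0$max_eff)
  expect_identical(ctl$ac_mat, p0$ac_mat)
  expect_identical(ctl$curve_k, p0$curve_k)
})

test_that("a transient noise window ends with recovered encoding of new memories", {
  bt <- fx_basin()
  tau <- 20
  cfg <- sim_config(N = 2000, f = 0.01, tau = tau, lam = 5 / tau, b = 0.3,
                    T = 90 * tau, n_realizations = 4L, seed = 22L)
  ctl <- run_simulation(cfg, bt)
  pert <- perturbation_spec("additive_noise", D = 6, t_onset = 55 * tau,
                            t_offset = 60 * tau)
  tr <- run_simulation(cfg, bt, pert = pert)
  t_probe <- (60 + 10) * tau
  cc <- memconsol:::snapshot_curve(ctl, t_probe)
  cp <- memconsol:::snapshot_curve(tr, t_probe)
  young_c <- cc$prob[cc$age_tau <= 3]
  young_p <- cp$prob[cp$age_tau <= 3]
  se <- sqrt(mean(young_c) * (1 - mean(young_c) + 1e-9) /
               sum(cc$n[cc$age_tau <= 3]))
  expect_gte(mean(young_p), mean(young_c) - 3 * se - 0.05)
})

test_that("threshold optimization returns the capacity-maximizing grid point", {
  bt <- fx_basin()
  cfg <- sim_config(N = 2000, f = 0.01, tau = 20, lam = 10 / 20, b = 0.25,
                    T = 60 * 20, n_realizations = 2L, seed = 23L)
  res <- optimize_threshold(cfg, bt, theta_grid = c(0.30, 0.36, 0.44))
  expect_true(res$theta_best %in% c(0.30, 0.36, 0.44))
  expect_equal(nrow(res$table), 3L)
  expect_true(all(res$table$capacity >= 0))
  expect_equal(res$table$capacity[res$table$theta == res$theta_best],
               max(res$table$capacity))
})
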