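test_that("pattern generation: sparseness statistics and edge cases", {
  set.seed(1)
  expect_true(all(generate_patterns(5, 100, 0)$patterns == 0))
  mem <- generate_patterns(200, 2000, 0.01)
  counts <- rowSums(mem$patterns)
  expect_equal(mean(counts), 20, tolerance = 0.1 * 20)
  # per-pattern active fraction within 3 binomial SD of f
  expect_true(all(abs(counts - 20) <= 3 * sqrt(2000 * 0.01 * 0.99) + 1))
  exact <- generate_patterns(50, 2000, 0.01, exact_count = TRUE)
  expect_true(all(rowSums(exact$patterns) == 20))
})

test_that("centered overlaps of unrelated patterns scatter at the binomial scale", {
  set.seed(2)
  N <- 2000; f <- 0.01
  mem <- generate_patterns(200, N, f)
  ov <- sapply(1:100, function(i)
    overlap(mem$patterns[2 * i, ], mem$patterns[2 * i - 1, ], f))
  expect_lt(abs(mean(ov)), 3 / sqrt(100) * stats::sd(ov) + 0.01)
  # sd of the overlap estimator ~ 1/sqrt(N f (1-f)) for activity-f states
  expect_equal(stats::sd(ov), 1 / sqrt(N * f * (1 - f)), tolerance = 0.35)
})

test_that("connectivity: symmetry, zero diagonal, signal normalization", {
  set.seed(3)
  mem <- generate_patterns(30, 500, 0.05, exact_count = TRUE)
  expect_true(all(build_connectivity(mem, rep(0, 30))$J == 0))
  A <- stats::runif(30, 0.2, 1.5)
  conn <- build_connectivity(mem, A)
  expect_identical(conn$J, t(conn$J))
  expect_true(all(diag(conn$J) == 0))
  expect_error(build_connectivity(mem, A[-1]), "one efficacy per pattern")
  # single stored memory: field on its active neurons ~ (1-f) * A * M
  mem1 <- generate_patterns(1, 2000, 0.01, exact_count = TRUE)
  c1 <- build_connectivity(mem1, 1)
  h <- drop(c1$J %*% mem1$patterns[1, ])
  expect_equal(mean(h[mem1$patterns[1, ] == 1]), 1 - 0.01, tolerance = 0.06)
})

test_that("field statistics near a stored pattern match the mean-field signal and noise", {
  set.seed(4)
  N <- 2000; f <- 0.01; n_mem <- 120
  k <- round(f * N)
  zs_mean <- numeric(8)
  v_ratio <- numeric(8)
  for (r in 1:8) {
    mem <- generate_patterns(n_mem, N, f, exact_count = TRUE)
    A <- c(0.9, stats::runif(n_mem - 1, 0.2, 1.2))
    conn <- build_connectivity(mem, A)
    sigma <- mem$patterns[1, ]
    h <- drop(conn$J %*% sigma)
    on <- sigma == 1
    # zero self-coupling: an active neuron misses its own contribution
    pred_mean <- A[1] * (1 - f) * (k - 1) / k
    pred_var <- f / N * sum(A[-1]^2)
    zs_mean[r] <- (mean(h[on]) - pred_mean) / sqrt(pred_var / k)
    v_ratio[r] <- stats::var(h[!on]) / pred_var
  }
  expect_lt(abs(mean(zs_mean)) / (1 + sqrt(1 / 8)), 3)
  # crosstalk factors are shared across neurons, so the single-realization
  # variance estimate fluctuates at the sqrt(2/n_mem) scale
  expect_lt(abs(mean(v_ratio) - 1), 3 * sqrt(2 / (n_mem * 8)))
})

test_that("fixed-activity updates conserve the activation count and retrieve stored patterns", {
  set.seed(5)
  N <- 1000; f <- 0.02
  mem <- generate_patterns(10, N, f, exact_count = TRUE)
  conn <- build_connectivity(mem, rep(1, 10))
  st <- as.numeric(stats::runif(N) < f)
  for (i in 1:5) {
    st <- step_fixed_activity(st, conn, f)
    expect_equal(sum(st), round(f * N))
  }
  # degenerate J: still exactly fN active
  conn0 <- build_connectivity(mem, rep(0, 10))
  expect_equal(sum(step_fixed_activity(st, conn0, f)), round(f * N))
  # a dominant stored memory is a fixed point
  r <- test_retrieval(mem$patterns[1, ], conn)
  expect_true(r$retrievable)
  expect_gt(r$overlap, 0.95)
})

test_that("fixed-threshold update: all-off at huge threshold", {
  set.seed(6)
  mem <- generate_patterns(5, 500, 0.05, exact_count = TRUE)
  conn <- build_connectivity(mem, rep(1, 5))
  st <- step_fixed_threshold(mem$patterns[1, ], conn, 1e6)
  expect_true(all(st == 0))
})

test_that("overlap: perfect retrieval, random state, anti-correlated state", {
  set.seed(7)
  f <- 0.2; N <- 20
  pattern <- c(rep(1, 4), rep(0, 16))
  expect_equal(overlap(pattern, pattern, f), 1)
  anti <- c(rep(0, 4), rep(1, 4), rep(0, 12))   # active only off-pattern
  expect_equal(overlap(anti, pattern, f), 4 * (0 - f) / (N * f * (1 - f)))
  expect_lt(overlap(anti, pattern, f), 0)
  mem <- generate_patterns(2, 4000, 0.01)
  expect_lt(abs(overlap(mem$patterns[1, ], mem$patterns[2, ], 0.01)), 0.25)
})

test_that("synchronous two-cycles are detected and scored by the better state", {
  conn <- structure(list(J = matrix(c(0, 1, 1, 0), 2), f = 0.5, N = 2),
                    class = "connectivity")
  r <- memconsol:::run_to_convergence(c(1, 0), conn, c(1, 0), 0.5,
                                      mode = "fixed_threshold", theta = 0.5)
  expect_true(r$converged)
  expect_lte(r$sweeps, 5)
})

test_that("retrieval fails below the critical efficacy and basin size grows with efficacy", {
  set.seed(8)
  N <- 2000; f <- 0.01; af <- fx_af()
  n_bg <- 150
  mem <- generate_patterns(n_bg + 1, N, f, exact_count = TRUE)
  A_bg <- rep(1, n_bg)
  delta <- sqrt(f / N * sum(A_bg^2))
  sub <- build_connectivity(mem, c(0.5 * af * delta, A_bg))
  expect_false(test_retrieval(mem$patterns[1, ], sub)$retrievable)
  bas <- sapply(c(0.6, 2.2, 4.5), function(x) {
    conn <- build_connectivity(mem, c(x * af * delta, A_bg))
    measure_basin_size(mem$patterns[1, ], conn, n_reps = 3)
  })
  expect_equal(bas[1], 0)
  expect_true(all(diff(bas) >= 0))
  expect_gt(bas[3], 0.2)
  # a lone stored memory owns most of the state space
  mem1 <- generate_patterns(1, N, f, exact_count = TRUE)
  lone <- build_connectivity(mem1, 1)
  expect_gt(measure_basin_size(mem1$patterns[1, ], lone, n_reps = 2), 0.8)
})

test_that("network forgetting curve: pure-decay ensemble steps from one to zero", {
  set.seed(9)
  N <- 2000; f <- 0.01; af <- fx_af()
  tau <- round(2240 / 74009.5 * pure_forgetting_analytics(N, f, 1, af)$tau0)
  ages <- seq(0.5, 2.3 * tau, by = 1)
  eff <- exp(-ages / tau)
  cv <- network_forgetting_curve(eff, ages, N, f, bin_width = tau / 4,
                                 probes_per_bin = 6)
  expect_gte(mean(cv$prob[cv$age < 0.8 * tau]), 0.9)
  expect_lte(mean(cv$prob[cv$age > 2 * tau]), 0.1)
  # zero efficacies: nothing retrievable
  cv0 <- network_forgetting_curve(rep(0, 200), seq_len(200), 1000, f,
                                  bin_width = 50, probes_per_bin = 4)
  expect_true(all(cv0$prob == 0))
  expect_error(network_forgetting_curve(rep(1, 100), 1:100, 500, f,
                                        bin_width = 10, max_patterns = 50),
               "cap")
})
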