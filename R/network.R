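#' Generate sparse binary memory patterns
#'
#' Each pattern is an i.i.d. Bernoulli(f) binary vector over the N
#' neurons.
#'
#' @param n_patterns Number of patterns.
#' @param N Number of neurons.
#' @param f Sparseness.
#' @param exact_count If `TRUE`, every pattern has exactly `round(f N)`
#'   active units (a random subset) instead of a binomial count. The
#'   fixed-activity retrieval dynamics clamps the network activation at
#'   `round(f N)`, so binomial count fluctuations place a ceiling below 1
#'   on the overlap a pattern can reach that has nothing to do with
#'   interference; retrieval and basin experiments therefore use
#'   count-matched patterns.
#' @return A `memory_set`: list with `patterns` (n_patterns x N 0/1
#'   matrix) and `f`.
#' @export
generate_patterns <- function(n_patterns, N, f, exact_count = FALSE) {
  stopifnot(n_patterns >= 1, N >= 1, f >= 0, f <= 1)
  if (exact_count) {
    k <- round(f * N)
    patterns <- matrix(0, n_patterns, N)
    for (i in seq_len(n_patterns))
      patterns[i, sample.int(N, k)] <- 1
  } else {
    patterns <- matrix(
      as.numeric(stats::runif(n_patterns * N) < f), n_patterns, N)
  }
  structure(list(patterns = patterns, f = f, N = N), class = "memory_set")
}

#' Build the synaptic connectivity matrix
#'
#' Weighted sum of centered Hebbian outer products,
#' `J = (1 / (N f (1-f))) * sum_l A_l (xi_l - f)(xi_l - f)^T`,
#' with zero self-coupling. The centering removes the mean activity
#' component; the normalization puts the retrieval signal of a pattern
#' with efficacy A at `A (1-f)` on its active neurons.
#'
#' @param memories A [generate_patterns] memory set.
#' @param efficacies One efficacy per pattern.
#' @return A `connectivity` object with the symmetric matrix `J`.
#' @export
build_connectivity <- function(memories, efficacies) {
  P <- memories$patterns
  if (length(efficacies) != nrow(P))
    stop("need one efficacy per pattern (", nrow(P), "), got ",
         length(efficacies))
  f <- memories$f; N <- ncol(P)
  Pc <- P - f
  J <- crossprod(Pc * sqrt(efficacies)) / (N * f * (1 - f))
  # crossprod needs nonnegative weights; general efficacies use the slower
  # explicit form
  if (any(efficacies < 0))
    J <- t(Pc) %*% (efficacies * Pc) / (N * f * (1 - f))
  diag(J) <- 0
  structure(list(J = J, f = f, N = N), class = "connectivity")
}

#' One synchronous update at fixed activity
#'
#' Computes the local fields `h = J sigma` and activates the `round(f N)`
#' neurons with the largest fields (a global-inhibition constraint that
#' clamps the population activity to the memory sparseness). Field ties
#' are broken uniformly at random using the current RNG stream.
#'
#' @param state Binary activation vector.
#' @param conn A [build_connectivity] object.
#' @param f Sparseness.
#' @return The updated binary state (exactly `round(f N)` active units).
#' @export
step_fixed_activity <- function(state, conn, f) {
  N <- length(state)
  h <- drop(conn$J %*% state)
  k <- round(f * N)
  ord <- order(h + stats::runif(N, 0, 1e-12 * (1 + max(abs(h)))),
               decreasing = TRUE)
  out <- numeric(N)
  out[ord[seq_len(k)]] <- 1
  out
}

#' One synchronous update at fixed threshold
#'
#' `sigma_i <- Theta(h_i - theta)` for all neurons simultaneously.
#'
#' @param state Binary activation vector.
#' @param conn A [build_connectivity] object.
#' @param theta Firing threshold.
#' @return The updated binary state.
#' @export
step_fixed_threshold <- function(state, conn, theta) {
  as.numeric(drop(conn$J %*% state) > theta)
}

#' Overlap between a network state and a memory pattern
#'
#' The centered, normalized correlation
#' `M = (1 / (N f (1-f))) * sum_j (xi_j - f) sigma_j`, equal to
#' `f_plus - f_minus` (the difference between the activation rates of
#' pattern-active and pattern-inactive neurons). 1 for a perfect
#' retrieval, ~0 for an unrelated state at activity f.
#'
#' @param state Binary activation vector.
#' @param pattern Binary memory pattern.
#' @param f Sparseness used at pattern generation.
#' @return The overlap M.
#' @export
overlap <- function(state, pattern, f) {
  stopifnot(length(state) == length(pattern))
  sum((pattern - f) * state) / (length(pattern) * f * (1 - f))
}

# Iterate synchronous updates until the state repeats with period 1 or 2
# (symmetric synchronous dynamics can settle on a 2-cycle); returns the
# visited state with the larger overlap.
run_to_convergence <- function(state, conn, pattern, f,
                               mode = c("fixed_activity", "fixed_threshold"),
                               theta = NULL, max_sweeps = 50L) {
  mode <- match.arg(mode)
  prev <- state
  prev2 <- NULL
  converged <- FALSE
  for (s in seq_len(max_sweeps)) {
    cur <- if (mode == "fixed_activity") step_fixed_activity(prev, conn, f)
           else step_fixed_threshold(prev, conn, theta)
    if (identical(cur, prev) ||
        (!is.null(prev2) && identical(cur, prev2))) {
      converged <- TRUE
      break
    }
    prev2 <- prev
    prev <- cur
  }
  cand <- list(cur, prev)
  ovs <- vapply(cand, overlap, numeric(1), pattern = pattern, f = f)
  best <- which.max(ovs)
  list(state = cand[[best]], overlap = ovs[best], converged = converged,
       sweeps = s)
}

#' Test retrieval of a stored pattern
#'
#' Initializes the network at the pattern, iterates the binary dynamics
#' to convergence (period-1 or period-2 repetition, up to `max_sweeps`
#' synchronous sweeps) and declares the memory retrievable when the final
#' overlap is at least `cut`.
#'
#' @param pattern Binary pattern vector.
#' @param conn A [build_connectivity] object.
#' @param mode `"fixed_activity"` or `"fixed_threshold"`.
#' @param theta Threshold for fixed-threshold mode.
#' @param cut Retrieval overlap cut (default 0.85).
#' @param max_sweeps Sweep cap; non-convergence is reported in the result.
#' @return List with `retrievable`, `overlap`, `converged`.
#' @export
test_retrieval <- function(pattern, conn,
                           mode = c("fixed_activity", "fixed_threshold"),
                           theta = NULL, cut = 0.85, max_sweeps = 50L) {
  mode <- match.arg(mode)
  r <- run_to_convergence(pattern, conn, pattern, conn$f, mode, theta,
                          max_sweeps)
  list(retrievable = r$overlap >= cut, overlap = r$overlap,
       converged = r$converged)
}

# Flip k active units off and k inactive units on (activity-conserving
# perturbation of a pattern).
flip_pattern <- function(pattern, k) {
  on <- which(pattern == 1)
  off <- which(pattern == 0)
  k <- min(k, length(on), length(off))
  out <- pattern
  if (k > 0) {
    out[sample(on, k)] <- 0
    out[sample(off, k)] <- 1
  }
  out
}

#' Monte-Carlo basin-of-attraction size of a stored pattern
#'
#' Perturbs the pattern by flipping `k` active units off and `k` inactive
#' units on (conserving the total activation `f N`), runs the dynamics to
#' convergence, and finds the largest `k` for which the final overlap
#' still reaches the retrieval cut: a coarse upward scan followed by
#' bisection, averaged over `n_reps` flip realizations. The normalized
#' basin size is the number of flipped units `2 k_max` over the maximal
#' number of flips `2 f N` (at `k = f N` every active unit has been
#' exchanged, the maximal perturbation).
#'
#' @param pattern Binary pattern vector.
#' @param conn A [build_connectivity] object.
#' @param mode `"fixed_activity"` or `"fixed_threshold"`.
#' @param theta Threshold for fixed-threshold mode.
#' @param cut Retrieval overlap cut (default 0.85).
#' @param n_reps Number of flip realizations averaged.
#' @return Normalized basin size in \[0, 1\] (0 when even the unperturbed
#'   pattern is not recovered).
#' @export
measure_basin_size <- function(pattern, conn,
                               mode = c("fixed_activity", "fixed_threshold"),
                               theta = NULL, cut = 0.85, n_reps = 5L) {
  mode <- match.arg(mode)
  f <- conn$f
  fN <- as.integer(round(f * length(pattern)))
  ok0 <- run_to_convergence(pattern, conn, pattern, f, mode, theta)$overlap >= cut
  if (!ok0) return(0)
  ok_at <- function(k) {
    st <- flip_pattern(pattern, k)
    run_to_convergence(st, conn, pattern, f, mode, theta)$overlap >= cut
  }
  kmax <- vapply(seq_len(n_reps), function(rep) {
    step <- max(1L, fN %/% 20L)
    k_ok <- 0L
    k <- step
    while (k <= fN && ok_at(k)) { k_ok <- k; k <- k + step }
    if (k_ok == fN) return(fN)
    lo <- as.integer(k_ok); hi <- min(as.integer(k), fN)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (ok_at(mid)) lo <- mid else hi <- mid
    }
    lo
  }, integer(1))
  mean(2 * kmax) / (2 * fN)
}

#' Full-network forgetting curve
#'
#' Given efficacies by age (for instance a snapshot of a mean-field
#' consolidation run), draws fresh random patterns, builds the
#' connectivity matrix, and tests retrieval of a subsample of memories per
#' age bin. This is the direct network counterpart of the mean-field
#' forgetting curve.
#'
#' @param efficacies Efficacy vector, one per stored memory.
#' @param ages Memory ages (same length).
#' @param N Number of neurons.
#' @param f Sparseness.
#' @param mode,theta,cut Retrieval settings, as in [test_retrieval].
#' @param bin_width Age bin width.
#' @param probes_per_bin Number of memories tested per age bin.
#' @param max_patterns Safety cap on the number of stored patterns.
#' @return A `forgetting_curve` data frame (`age`, `prob`, `n`,
#'   `mean_overlap`).
#' @export
network_forgetting_curve <- function(efficacies, ages, N, f,
                                     mode = "fixed_activity", theta = NULL,
                                     cut = 0.85, bin_width,
                                     probes_per_bin = 10L,
                                     max_patterns = 20000L) {
  stopifnot(length(efficacies) == length(ages))
  if (length(efficacies) > max_patterns)
    stop("T * N too large: ", length(efficacies), " patterns exceed cap ",
         max_patterns)
  mem <- generate_patterns(length(efficacies), N, f, exact_count = TRUE)
  conn <- build_connectivity(mem, efficacies)
  bins <- split(seq_along(ages), floor(ages / bin_width))
  rows <- lapply(bins, function(idx) {
    probe <- if (length(idx) > probes_per_bin) sample(idx, probes_per_bin)
             else idx
    res <- vapply(probe, function(i)
      test_retrieval(mem$patterns[i, ], conn, mode, theta, cut)$overlap,
      numeric(1))
    data.frame(age = mean(ages[probe]), prob = mean(res >= cut),
               n = length(probe), mean_overlap = mean(res))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age), ]
  rownames(out) <- NULL
  class(out) <- c("forgetting_curve", "data.frame")
  out
}
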