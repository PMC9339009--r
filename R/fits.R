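#' Exponential fit to the tail of a retention curve
#'
#' Unweighted least squares of `log(prob)` against age on the requested
#' range: `prob = c * exp(-age / tau1)`. A non-decaying (constant or
#' rising) curve is flagged as degenerate with an infinite time constant.
#'
#' @param curve A `forgetting_curve` data frame (`age`, `prob`).
#' @param range Age interval `c(lo, hi)` used for the fit.
#' @param min_points Minimum number of positive-probability points.
#' @return A `fit_result`: `model`, `params` (`c`, `tau1`), `r_squared`,
#'   `fit_range`, `degenerate`.
#' @export
fit_exponential_tail <- function(curve, range = c(0, Inf), min_points = 10L) {
  d <- curve[curve$age >= range[1] & curve$age <= range[2] & curve$prob > 0, ]
  if (nrow(d) < min_points)
    stop("insufficient points for exponential fit: ", nrow(d), " < ",
         min_points)
  fit <- stats::lm(log(prob) ~ age, data = d)
  co <- stats::coef(fit)
  # non-decaying: less than one part in 1e6 of decay across the fit range
  degenerate <- co[2] * diff(range(d$age)) > -1e-6
  structure(list(model = "exponential",
                 params = c(c = unname(exp(co[1])),
                            tau1 = if (degenerate) Inf else unname(-1 / co[2])),
                 r_squared = summary(fit)$r.squared,
                 fit_range = range(d$age), degenerate = degenerate,
                 n_points = nrow(d)),
            class = "fit_result")
}

#' Double-exponential fit to a retention curve
#'
#' Nonlinear least squares of
#' `prob = c1 * exp(-age/tau1) + c2 * exp(-age/tau2)` with `tau1 < tau2`,
#' fitted on log-probabilities with multi-start initialization
#' (Levenberg-Marquardt). When the two components merge or one amplitude
#' vanishes the result is flagged as effectively single-exponential.
#'
#' @param curve A `forgetting_curve` data frame.
#' @param range Age interval used for the fit.
#' @param min_points Minimum number of positive-probability points.
#' @param n_starts Number of multi-start initializations.
#' @return A `fit_result` with `params` (`c1`, `tau1`, `c2`, `tau2`).
#' @export
fit_double_exponential <- function(curve, range = c(0, Inf),
                                   min_points = 15L, n_starts = 8L) {
  d <- curve[curve$age >= range[1] & curve$age <= range[2] & curve$prob > 0, ]
  if (nrow(d) < min_points)
    stop("insufficient points for double-exponential fit: ", nrow(d),
         " < ", min_points)
  span <- max(d$age) - min(d$age)
  # initial slow constant from the last third, fast from the first third
  best <- NULL
  for (s in seq_len(n_starts)) {
    fac <- 2^(s - n_starts / 2)
    t1 <- span / 20 * fac
    t2 <- span / 1.5 * fac
    start <- list(lc1 = log(max(d$prob) / 2), lt1 = log(t1),
                  lc2 = log(max(d$prob) / 2), lt2 = log(t2))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        log(prob) ~ log(exp(lc1 - age / exp(lt1)) + exp(lc2 - age / exp(lt2))),
        data = d, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("double-exponential fit did not converge")
  co <- stats::coef(best$fit)
  c1 <- exp(co[["lc1"]]); t1 <- exp(co[["lt1"]])
  c2 <- exp(co[["lc2"]]); t2 <- exp(co[["lt2"]])
  if (t1 > t2) { tmp <- c(c1, t1); c1 <- c2; t1 <- t2; c2 <- tmp[1]; t2 <- tmp[2] }
  tss <- sum((log(d$prob) - mean(log(d$prob)))^2)
  merged <- t2 / t1 < 1.5 || c1 < 1e-3 * c2 || c2 < 1e-3 * c1
  structure(list(model = "double_exponential",
                 params = c(c1 = c1, tau1 = t1, c2 = c2, tau2 = t2),
                 r_squared = 1 - best$rss / tss,
                 fit_range = range(d$age), degenerate = merged,
                 n_points = nrow(d)),
            class = "fit_result")
}

#' Power-law fit to a retention curve
#'
#' Least squares of `log(prob)` against `log(age)`:
#' `prob = c * age^(-slope)`, with the decay exponent reported positive.
#'
#' @param curve A `forgetting_curve` data frame.
#' @param range Age interval used for the fit.
#' @param min_points Minimum number of positive-probability points.
#' @return A `fit_result` with `params` (`c`, `slope`).
#' @export
fit_power_law <- function(curve, range = c(0, Inf), min_points = 5L) {
  d <- curve[curve$age >= range[1] & curve$age <= range[2] &
               curve$prob > 0 & curve$age > 0, ]
  if (nrow(d) < min_points)
    stop("insufficient points for power-law fit: ", nrow(d), " < ",
         min_points)
  fit <- stats::lm(log(prob) ~ log(age), data = d)
  co <- stats::coef(fit)
  structure(list(model = "power_law",
                 params = c(c = unname(exp(co[1])), slope = unname(-co[2])),
                 r_squared = summary(fit)$r.squared,
                 fit_range = range(d$age), degenerate = co[2] >= 0,
                 n_points = nrow(d)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit:", x$model, " R^2 =", signif(x$r_squared, 4), "\n  params:",
      paste(names(x$params), signif(x$params, 5), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Capacity scaling with network size
#'
#' Runs the consolidation simulation across a grid of network sizes
#' (all other parameters fixed) and fits `log(capacity) ~ log(N)`. The
#' fitted exponent is compared with the analytic prediction
#' `lam*tau / (2 + lam*tau)`.
#'
#' @param N_grid Network sizes (>= 4 values spanning at least a decade
#'   recommended).
#' @param cfg_template A [sim_config] whose `N` is replaced per run.
#' @param basin A basin table.
#' @return List with `exponent`, `exponent_theory`, `capacities` data
#'   frame, `fit`, and per-N `errors` (failures are isolated).
#' @export
capacity_scaling_experiment <- function(N_grid, cfg_template, basin) {
  stopifnot(length(N_grid) >= 2)
  errors <- list()
  caps <- vapply(N_grid, function(N) {
    cfg <- cfg_template
    cfg$N <- N
    tryCatch(capacity(run_simulation(cfg, basin)),
             error = function(e) {
               errors[[as.character(N)]] <<- conditionMessage(e)
               NA_real_
             })
  }, numeric(1))
  d <- data.frame(N = N_grid, capacity = caps)
  ok <- is.finite(caps) & caps > 0
  if (sum(ok) < 2) stop("capacity scan failed on nearly all N")
  fit <- stats::lm(log(capacity) ~ log(N), data = d[ok, ])
  lt <- cfg_template$lam * cfg_template$tau
  list(exponent = unname(stats::coef(fit)[2]),
       exponent_theory = lt / (2 + lt),
       capacities = d, fit = fit, errors = errors)
}
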