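# Benchmark drivers: tracking error metrics, the particles-needed-versus-
# dimension scaling study with linear/exponential curve fits, and the
# multisensory tracking demonstration.

#' Time-averaged mean squared tracking error
#'
#' Mean over post-burn-in steps of the squared Euclidean error
#' `||xhat_t - x_t||^2`.  For the reference linear model the optimal value
#' is the trace of the steady-state Riccati covariance (0.5 per dimension).
#'
#' @param estimates steps x n matrix of posterior means.
#' @param truth steps x n matrix of true hidden states.
#' @param burn_in fraction of initial steps discarded (default 0.1).
#' @return scalar MSE.
#' @export
time_averaged_mse <- function(estimates, truth, burn_in = 0.1) {
  estimates <- as.matrix(estimates); truth <- as.matrix(truth)
  stopifnot(all(dim(estimates) == dim(truth)), burn_in >= 0, burn_in < 1)
  steps <- nrow(truth)
  keep <- seq.int(floor(burn_in * steps) + 1L, steps)
  mean(rowSums((estimates[keep, , drop = FALSE] -
                truth[keep, , drop = FALSE])^2))
}

#' Optimal steady-state MSE of a model family
#'
#' Linear family: analytic Riccati trace, `d * P*`.  Bimodal family: no
#' closed form; estimated once at `d = 1` with a large-N bootstrap particle
#' filter and extrapolated by per-dimension additivity (the family is a
#' product of independent scalar problems by construction).
#'
#' @param family `"linear"` or `"bimodal"`.
#' @param d hidden dimension.
#' @param drift OU drift for the linear family.
#' @param sigma_y2 observation noise variance per dimension.
#' @param opt_pf_n particle count of the reference filter for the bimodal
#'   family (default 10000).
#' @param T,dt,seed simulation settings for the bimodal reference runs.
#' @param reps number of reference runs averaged (bimodal).
#' @return scalar optimal MSE for dimension `d`.
#' @export
mse_opt <- function(family = c("linear", "bimodal"), d, drift = -0.75,
                    sigma_y2 = NULL, opt_pf_n = 10000L, T = 100, dt = 0.01,
                    seed = 1L, reps = 2L) {
  family <- match.arg(family)
  if (is.null(sigma_y2)) sigma_y2 <- if (family == "bimodal") 0.1 else 1
  if (family == "linear")
    return(d * riccati_steady(drift, q = 1, c = 1, r = sigma_y2))
  m1 <- model_zoo("bimodal_d", d = 1L, sigma_y2 = sigma_y2)
  per_dim <- mean(vapply(seq_len(reps), function(r) {
    rec <- simulate_ssm(m1, T = T, dt = dt, seed = derive_seed(seed, 100L + r))
    pf <- run_bootstrap_pf(m1, rec, N = opt_pf_n,
                           seed = derive_seed(seed, 200L + r))
    time_averaged_mse(pf$xhat, rec$x)
  }, 0))
  d * per_dim
}

#' MSE ratio of a filter on a model family
#'
#' Runs one filter on freshly simulated data and reports its time-averaged
#' MSE divided by the optimal MSE.  The workhorse behind
#' [particles_needed()] and [scaling_experiment()].
#'
#' @param filter_kind `"npf"`, `"enkbf"`, or `"pf"`.
#' @param model an `"ssm"` from the zoo (`linear_d` / `bimodal_d`).
#' @param N particle count.
#' @param mse_opt_value optimal MSE normalizer for this model.
#' @param T,dt simulation horizon and step.
#' @param seed master seed (simulation and filter draw separate streams).
#' @param burn_in burn-in fraction.
#' @return scalar ratio `MSE / MSE_opt`.
#' @export
filter_mse_ratio <- function(filter_kind, model, N, mse_opt_value,
                             T = 200, dt = 0.01, seed = 1L, burn_in = 0.1) {
  rec <- simulate_ssm(model, T = T, dt = dt, seed = seed)
  est <- switch(filter_kind,
    npf   = run_filter(model, rec, N = N, gain = "empirical",
                       method = "npf", seed = seed)$xhat,
    enkbf = run_filter(model, rec, N = N, gain = "empirical",
                       method = "enkbf", seed = seed)$xhat,
    pf    = run_bootstrap_pf(model, rec, N = N, seed = seed)$xhat,
    kalman = run_kalman_bucy(model, rec)$xhat,
    stop("unknown filter kind: ", filter_kind))
  time_averaged_mse(est, rec$x, burn_in) / mse_opt_value
}

#' Smallest particle count reaching a target MSE ratio
#'
#' Searches for the smallest `N` whose mean MSE ratio (over seeds) falls
#' below `ratio_threshold`, by doubling from `n_min` until the threshold is
#' met and then bisecting.  The exact Kalman filter needs no particles and
#' returns 1 by convention.
#'
#' @param filter_kind `"npf"`, `"enkbf"`, `"pf"`, or `"kalman"`.
#' @param model an `"ssm"` object.
#' @param mse_opt_value optimal MSE normalizer.
#' @param ratio_threshold target ratio (> 1; default 1.5).
#' @param seeds vector of seeds averaged at each `N`.
#' @param n_min,n_max search bounds; if the threshold is not reached by
#'   `n_max` the sentinel `NA` is returned with a warning.
#' @param T,dt simulation settings per run.
#' @return list with `n_star` (or `NA`), `evaluated` (data.frame of N and
#'   mean ratio).
#' @export
particles_needed <- function(filter_kind, model, mse_opt_value,
                             ratio_threshold = 1.5, seeds = 1:3,
                             n_min = 2L, n_max = 4096L, T = 200, dt = 0.01) {
  stopifnot(ratio_threshold > 1)
  if (filter_kind == "kalman")
    return(list(n_star = 1L, evaluated = data.frame(N = 1L, ratio = 1)))
  evaluated <- list()
  ratio_at <- function(N) {
    r <- mean(vapply(seeds, function(s)
      filter_mse_ratio(filter_kind, model, N, mse_opt_value,
                       T = T, dt = dt, seed = s), 0))
    evaluated[[length(evaluated) + 1L]] <<- data.frame(N = N, ratio = r)
    r
  }
  N <- as.integer(n_min)
  r <- ratio_at(N)
  while (r >= ratio_threshold && N < n_max) {
    N <- min(2L * N, as.integer(n_max))
    r <- ratio_at(N)
  }
  if (r >= ratio_threshold) {
    warning(sprintf("%s: threshold %.2f not reached by N = %d",
                    filter_kind, ratio_threshold, N))
    return(list(n_star = NA_integer_,
                evaluated = do.call(rbind, evaluated)))
  }
  lo <- max(as.integer(N / 2), 1L); hi <- N   # lo fails (or untested), hi passes
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) / 2)
    if (ratio_at(mid) < ratio_threshold) hi <- mid else lo <- mid
  }
  list(n_star = hi, evaluated = do.call(rbind, evaluated))
}

#' Fit linear and exponential scaling laws to particles-needed points
#'
#' Least-squares fits of `N(d) = a d + b` and
#' `N(d) = c0 exp(c1 d) + c2 d + c3` to the particles-needed curve, with
#' residual sums of squares and an AIC comparison of the two forms.  The
#' exponential fit profiles the rate `c1` over a grid (the remaining
#' coefficients are linear given `c1`), then polishes with [stats::optim()].
#'
#' @param d vector of dimensions (>= 4 points for the linear form, >= 5
#'   for the exponential).
#' @param N particles-needed values at `d` (sentinel `NA`s are dropped).
#' @return object of class `"scaling_fit"`: list with `linear`
#'   (`a`, `b`, `rss`, `aic`), `exponential` (`c0..c3`, `rss`, `aic`),
#'   `preferred` (`"linear"` or `"exponential"`), and the points used.
#' @export
fit_scaling <- function(d, N) {
  keep <- is.finite(d) & is.finite(N)
  d <- d[keep]; N <- N[keep]
  if (length(d) < 4L) stop("need >= 4 points for the linear fit")
  lin <- stats::lm(N ~ d)
  rss_lin <- sum(stats::residuals(lin)^2)
  npts <- length(d)
  aic_of <- function(rss, k) npts * log(max(rss, 1e-12) / npts) + 2 * k
  out <- list(
    d = d, N = N,
    linear = list(a = unname(stats::coef(lin)[2L]),
                  b = unname(stats::coef(lin)[1L]),
                  rss = rss_lin, aic = aic_of(rss_lin, 2L)))
  if (length(d) >= 5L) {
    # profile over the exponential rate c1; c0, c2, c3 are linear given c1
    prof <- function(c1) {
      X <- cbind(exp(c1 * d), d, 1)
      fit <- stats::lm.fit(X, N)
      list(coef = fit$coefficients, rss = sum(fit$residuals^2))
    }
    grid <- seq(0.005, 0.5, by = 0.005)
    rsses <- vapply(grid, function(c1) prof(c1)$rss, 0)
    c1 <- grid[which.min(rsses)]
    opt <- stats::optim(c1, function(p) prof(p)$rss, method = "Brent",
                        lower = 1e-4, upper = 1)
    best <- prof(opt$par)
    out$exponential <- list(c0 = unname(best$coef[1L]), c1 = opt$par,
                            c2 = unname(best$coef[2L]),
                            c3 = unname(best$coef[3L]),
                            rss = best$rss, aic = aic_of(best$rss, 4L))
    out$preferred <- if (out$exponential$aic < out$linear$aic)
      "exponential" else "linear"
  }
  structure(out, class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit>  linear N = %.3g d + %.3g (RSS %.3g)\n",
              x$linear$a, x$linear$b, x$linear$rss))
  if (!is.null(x$exponential))
    cat(sprintf("  exponential N = %.3g e^(%.3g d) %+.3g d %+.3g (RSS %.3g)\n  preferred: %s\n",
                x$exponential$c0, x$exponential$c1, x$exponential$c2,
                x$exponential$c3, x$exponential$rss, x$preferred))
  invisible(x)
}

#' Multisensory tracking demonstration
#'
#' Runs the double-well tracking example with a linear visual and a
#' sigmoidal auditory channel: simulates the scene, filters with the
#' unweighted particle filter (empirical gain), records per-branch
#' certainties and the per-channel gain traces, and benchmarks the MSE
#' against a weighted bootstrap particle filter on the same record.
#'
#' @param sigma_v2,sigma_a2 sensory noise variances (default 0.1 each).
#' @param N particle count (default 1000).
#' @param T,dt horizon and step.
#' @param seed master seed.
#' @param pf_N benchmark bootstrap-PF particle count (default 10000).
#' @param branch_halfwidth half-width of the two branch intervals centered
#'   at -1 and +1 (default 0.25).
#' @return list with the simulation record, the filter run (gain and
#'   certainty traces included), `mse_npf`, `mse_pf`, and time-averaged
#'   per-channel gains `W_mean`.
#' @export
frog_experiment <- function(sigma_v2 = 0.1, sigma_a2 = 0.1, N = 1000L,
                            T = 100, dt = 0.01, seed = 1L, pf_N = 10000L,
                            branch_halfwidth = 0.25) {
  model <- model_zoo("frog", sigma_v2 = sigma_v2, sigma_a2 = sigma_a2)
  rec <- simulate_ssm(model, T = T, dt = dt, seed = seed)
  branches <- rbind(left  = c(-1 - branch_halfwidth, -1 + branch_halfwidth),
                    right = c(1 - branch_halfwidth, 1 + branch_halfwidth))
  run <- run_filter(model, rec, N = N, gain = "empirical", seed = seed,
                    branches = branches)
  pf <- run_bootstrap_pf(model, rec, N = pf_N, seed = seed)
  list(model = model, record = rec, npf = run,
       mse_npf = time_averaged_mse(run$xhat, rec$x),
       mse_pf = time_averaged_mse(pf$xhat, rec$x),
       W_mean = stats::setNames(as.numeric(run$W_mean),
                                c("visual", "auditory")),
       branches = branches)
}

#' Time-averaged sensory gains across a noise grid
#'
#' Sweeps one channel's noise variance and reports the time-averaged
#' empirical gains of both channels, demonstrating that a channel's gain
#' decreases as its noise grows.
#'
#' @param vary `"auditory"` or `"visual"`: which channel's variance sweeps.
#' @param grid noise variances to sweep (default `c(0.01, 0.1, 1)`).
#' @param other_sigma2 fixed variance of the other channel.
#' @param N,T,dt,seed run settings.
#' @return data.frame with columns `sigma2`, `W_visual`, `W_auditory`.
#' @export
frog_gain_sweep <- function(vary = c("auditory", "visual"),
                            grid = c(0.01, 0.1, 1), other_sigma2 = 0.1,
                            N = 500L, T = 50, dt = 0.01, seed = 1L) {
  vary <- match.arg(vary)
  rows <- lapply(grid, function(s2) {
    model <- if (vary == "auditory")
      model_zoo("frog", sigma_v2 = other_sigma2, sigma_a2 = s2)
    else model_zoo("frog", sigma_v2 = s2, sigma_a2 = other_sigma2)
    rec <- simulate_ssm(model, T = T, dt = dt, seed = seed)
    run <- run_filter(model, rec, N = N, gain = "empirical", seed = seed)
    data.frame(sigma2 = s2, W_visual = run$W_mean[1L, 1L],
               W_auditory = run$W_mean[1L, 2L])
  })
  do.call(rbind, rows)
}

#' Particles-versus-dimension scaling study
#'
#' For each filter and each dimension in `d_grid`, finds the particles
#' needed to reach `MSE < ratio_threshold * MSE_opt` and fits linear and
#' exponential scaling laws to the resulting curves.
#'
#' @param family `"linear"` or `"bimodal"`.
#' @param filters subset of `c("npf", "enkbf", "pf")`.
#' @param d_grid hidden dimensions (default `c(2, 5, 10, 20, 40, 80)`).
#' @param ratio_threshold target MSE ratio (default 1.5).
#' @param seeds seeds per (filter, d, N) cell.
#' @param n_max particle budget per cell.
#' @param T,dt per-run settings.
#' @param sigma_y2 observation noise per dimension.
#' @param opt_pf_n reference-PF size for the bimodal optimum.
#' @return list per filter: `curve` (data.frame d, n_star), `fit`
#'   (a `"scaling_fit"` when enough finite points), `evaluated` tables.
#' @export
scaling_experiment <- function(family = c("linear", "bimodal"),
                               filters = c("npf", "enkbf", "pf"),
                               d_grid = c(2L, 5L, 10L, 20L, 40L, 80L),
                               ratio_threshold = 1.5, seeds = 1:3,
                               n_max = 4096L, T = 200, dt = 0.01,
                               sigma_y2 = NULL, opt_pf_n = 10000L) {
  family <- match.arg(family)
  if (is.null(sigma_y2)) sigma_y2 <- if (family == "bimodal") 0.1 else 1
  zoo_name <- if (family == "linear") "linear_d" else "bimodal_d"
  opt1 <- mse_opt(family, d = 1L, sigma_y2 = sigma_y2,
                  opt_pf_n = opt_pf_n, T = min(T, 100), dt = dt)
  out <- list()
  for (fk in filters) {
    rows <- list(); evals <- list()
    for (d in d_grid) {
      model <- model_zoo(zoo_name, d = d, sigma_y2 = sigma_y2)
      pn <- particles_needed(fk, model, mse_opt_value = opt1 * d,
                             ratio_threshold = ratio_threshold,
                             seeds = seeds, n_max = n_max, T = T, dt = dt)
      rows[[length(rows) + 1L]] <- data.frame(d = d, n_star = pn$n_star)
      evals[[length(evals) + 1L]] <- cbind(d = d, pn$evaluated)
    }
    curve <- do.call(rbind, rows)
    fit <- if (sum(is.finite(curve$n_star)) >= 4L)
      fit_scaling(curve$d, curve$n_star) else NULL
    out[[fk]] <- list(curve = curve, fit = fit,
                      evaluated = do.call(rbind, evals))
  }
  attr(out, "mse_opt_per_dim") <- opt1
  out
}
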