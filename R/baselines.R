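# Reference filters used for benchmarking the unweighted particle filter:
# the exact Kalman-Bucy filter for linear models, the weighted bootstrap
# particle filter with systematic resampling, and the constant-structure
# ensemble Kalman-Bucy (feedback-particle-filter) update.

#' Steady-state Riccati variance of a scalar linear filtering problem
#'
#' For `dx = a x dt + sqrt(q) dw`, `dy = c x dt + sqrt(r) du` the
#' stationary posterior variance solves `0 = 2 a P + q - P^2 c^2 / r`; the
#' positive root is returned.  It equals the optimal steady-state MSE of
#' the filter.
#'
#' @param a drift coefficient.
#' @param q process noise variance.
#' @param c observation coefficient.
#' @param r observation noise variance.
#' @return the positive root `P*`.
#' @export
riccati_steady <- function(a, q = 1, c = 1, r = 1) {
  stopifnot(q >= 0, r > 0, c != 0)
  (a + sqrt(a^2 + q * c^2 / r)) * r / c^2
}

#' One Kalman-Bucy update step
#'
#' Euler discretization of the continuous-time Kalman filter for the linear
#' model `f(x) = A x`, `g(x) = C x`:
#' `K = P C^T Sigma_y^{-1}`;
#' `xhat <- xhat + A xhat dt + K (dy - C xhat dt)`;
#' `P <- P + (A P + P A^T + Sigma_x - K Sigma_y K^T) dt` (re-symmetrized).
#'
#' @param state list with `mean` (n-vector) and `cov` (n x n).
#' @param dy observation increment (m-vector).
#' @param A,C system matrices.
#' @param model an `"ssm"` object supplying the noise covariances.
#' @param dt step size.
#' @return updated state list (with gain `K` attached).
#' @export
kalman_bucy_step <- function(state, dy, A, C, model, dt) {
  P <- state$cov
  K <- P %*% t(C) %*% model$sigma_y_inv
  mean2 <- state$mean + A %*% state$mean * dt +
    K %*% (as.numeric(dy) - C %*% state$mean * dt)
  P2 <- P + (A %*% P + P %*% t(A) + model$sigma_x -
             K %*% model$sigma_y %*% t(K)) * dt
  P2 <- (P2 + t(P2)) / 2
  list(mean = as.numeric(mean2), cov = P2, K = K)
}

#' Run the Kalman-Bucy filter over a simulated record
#'
#' @param model a linear `"ssm"` (built with `linear = list(A, C)`, e.g.
#'   `model_zoo("linear_d")`).
#' @param record an `"ssm_sim"` object.
#' @param x0 initial mean (default zero).
#' @param P0 initial covariance (default stationary prior covariance for
#'   the OU family, else identity).
#' @return list with `xhat` (steps x n), `P_final`, `K_final`.
#' @export
run_kalman_bucy <- function(model, record, x0 = NULL, P0 = NULL) {
  if (is.null(model$linear))
    stop("Kalman-Bucy filter requires a linear model (f = Ax, g = Cx)")
  A <- model$linear$A; C <- model$linear$C
  n <- model$n
  if (is.null(x0)) x0 <- rep(0, n)
  if (is.null(P0)) {
    P0 <- if (all(diag(A) < 0) && all(A == diag(diag(A), n)))
      diag(diag(model$sigma_x) / (-2 * diag(A)), n) else diag(1, n)
  }
  state <- list(mean = x0, cov = as_cov(P0, n, "P0"))
  steps <- length(record$times)
  xhat <- matrix(NA_real_, steps, n)
  for (i in seq_len(steps)) {
    xhat[i, ] <- state$mean
    state <- kalman_bucy_step(state, record$dy[i, ], A, C, model, record$dt)
  }
  list(times = record$times, xhat = xhat, P_final = state$cov,
       K_final = state$K)
}

#' Effective sample size of a weight vector
#'
#' `ESS = 1 / sum(w^2)` for normalized weights; equals `N` for uniform
#' weights and 1 for a degenerate ensemble.
#'
#' @param w normalized weights.
#' @return scalar in `[1, N]`.
#' @export
ess <- function(w) 1 / sum(w^2)

#' Systematic resampling
#'
#' Draws `N` indices with a single uniform offset against the cumulative
#' weights (low-variance resampling).
#'
#' @param w normalized weights.
#' @param u optional uniform offset in `[0,1)`; default drawn from the
#'   current RNG.
#' @return integer vector of `length(w)` particle indices.
#' @export
systematic_resample <- function(w, u = stats::runif(1L)) {
  N <- length(w)
  pts <- (u + seq_len(N) - 1L) / N
  findInterval(pts, cumsum(w), left.open = TRUE) + 1L
}

#' One bootstrap particle filter step
#'
#' Propagates particles by the prior SDE (Euler-Maruyama), multiplies each
#' weight by the Gaussian likelihood of the observation increment
#' `N(dy; g(z) dt, Sigma_y dt)`, renormalizes (in log space), and applies
#' systematic resampling when `ESS < resample_threshold * N`.
#'
#' @param ens list with `z` (`N x n`) and `logw` (length-N log weights).
#' @param dy observation increment (m-vector).
#' @param model an `"ssm"` object.
#' @param dt step size.
#' @param resample_threshold ESS fraction below which to resample
#'   (default 0.5); `0` disables resampling.
#' @return updated ensemble list; `$degenerate` flags a weight underflow
#'   (all weights reset to uniform), `$resampled` whether resampling fired.
#' @export
bootstrap_pf_step <- function(ens, dy, model, dt, resample_threshold = 0.5) {
  z <- ens$z
  N <- nrow(z); n <- model$n
  noise <- if (all(model$sigma_x == 0)) 0 else
    sqrt(dt) * (matrix(stats::rnorm(N * n), N, n) %*% t(model$sigma_x_sqrt))
  z <- z + model$f(z) * dt + noise
  r <- sweep(-model$g(z) * dt, 2L, as.numeric(dy), "+")
  logw <- ens$logw - 0.5 * rowSums((r %*% model$sigma_y_inv) * r) / dt
  degenerate <- FALSE
  lse <- logsumexp(logw)
  if (!is.finite(lse)) {
    warning("all particle weights underflowed; resetting to uniform")
    logw <- rep(0, N); lse <- log(N); degenerate <- TRUE
  }
  logw <- logw - lse
  w <- exp(logw)
  resampled <- FALSE
  if (resample_threshold > 0 && ess(w) < resample_threshold * N) {
    idx <- systematic_resample(w)
    z <- z[idx, , drop = FALSE]
    logw <- rep(-log(N), N)
    resampled <- TRUE
  }
  list(z = z, logw = logw, degenerate = degenerate, resampled = resampled)
}

#' Run the weighted bootstrap particle filter over a record
#'
#' @inheritParams run_filter
#' @param resample_threshold ESS fraction triggering systematic resampling
#'   (default 0.5; `0` disables resampling).
#' @return list with `xhat` (steps x n posterior means), `ess` (per-step
#'   effective sample size, recorded before resampling), `n_resample`,
#'   `n_degenerate`.
#' @export
run_bootstrap_pf <- function(model, record, N, seed = 1L,
                             resample_threshold = 0.5) {
  stopifnot(inherits(model, "ssm"), inherits(record, "ssm_sim"))
  steps <- length(record$times)
  set.seed(derive_seed(seed, 2L))
  ens <- list(z = init_ensemble(model, N), logw = rep(-log(N), N))
  xhat <- matrix(NA_real_, steps, model$n)
  ess_trace <- numeric(steps)
  n_res <- 0L; n_deg <- 0L
  for (i in seq_len(steps)) {
    w <- exp(ens$logw)
    xhat[i, ] <- colSums(ens$z * w)
    ess_trace[i] <- ess(w)
    ens <- bootstrap_pf_step(ens, record$dy[i, ], model, record$dt,
                             resample_threshold)
    n_res <- n_res + ens$resampled
    n_deg <- n_deg + ens$degenerate
  }
  list(times = record$times, xhat = xhat, ess = ess_trace,
       n_resample = n_res, n_degenerate = n_deg, N = N, seed = seed)
}

#' One ensemble Kalman-Bucy particle update
#'
#' Identical to [npf_step()] except that the innovation uses the averaged
#' prediction: `dn^(k) = dy - (g(z^(k)) + <g>) / 2 * dt`.  This is the
#' constant-gain feedback-particle-filter update; with a collapsed ensemble
#' (`g(z^(k)) = <g>` for all k) it coincides with the plain update exactly.
#'
#' @inheritParams npf_step
#' @param dy observation increment (m-vector).
#' @return updated `N x n` particle matrix.
#' @export
enkbf_step <- function(z, dy, model, W, dt, xi = NULL) {
  gz <- model$g(z)
  dn <- novelty(z, dy, model, dt, gz = gz) +
    sweep(gz, 2L, colMeans(gz)) * (dt / 2)
  npf_step(z, dn, model, W, dt, xi = xi)
}
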