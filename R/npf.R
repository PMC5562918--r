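# Unweighted (neural) particle filter.
#
# N equally weighted particles z^(k) are propagated by the prior drift and
# corrected by a gain-weighted innovation,
#   dz^(k) = f(z^(k)) dt + W_t (dy - g(z^(k)) dt) + Sigma_x^{1/2} dOmega^(k),
# so the ensemble itself represents the filtering posterior and expectations
# are plain averages over particles.  The gain W_t (n x m) plays the role of
# the Kalman gain; by default it is estimated each step from the ensemble
# cross-covariance between states and predicted observations.

#' Initialize an unweighted particle ensemble
#'
#' Particles are drawn i.i.d. from the prior stationary density when the
#' hidden state is scalar (or a product of independent scalar double-well /
#' OU dimensions flagged by the model zoo); the fallback is standard normal.
#'
#' @param model an `"ssm"` object.
#' @param N number of particles (`N >= 1`).
#' @return an `N x n` matrix of particle states.
#' @export
init_ensemble <- function(model, N) {
  stopifnot(N >= 1)
  n <- model$n
  if (n == 1L && !all(model$sigma_x == 0)) {
    sd1 <- try(stationary_density(model), silent = TRUE)
    if (!inherits(sd1, "try-error"))
      return(matrix(sample_stationary(sd1, N), N, 1L))
  }
  if (grepl("^bimodal_d", model$name)) {
    # independent double-well marginals
    m1 <- model_zoo("frog", channels = "visual")
    sd1 <- stationary_density(m1)
    return(matrix(sample_stationary(sd1, N * n), N, n))
  }
  if (grepl("^linear_d", model$name)) {
    a <- model$linear$A[1L, 1L]
    return(matrix(stats::rnorm(N * n, sd = sqrt(1 / (-2 * a))), N, n))
  }
  matrix(stats::rnorm(N * n), N, n)
}

#' Empirical gain from the particle ensemble
#'
#' The gain is the population (1/N-normalized) cross-covariance between
#' particle states and their predicted observations, right-multiplied by the
#' inverse observation noise:
#' `W = [ mean(z g(z)^T) - mean(z) mean(g(z))^T ] Sigma_y^{-1}`.
#' With a single particle (or an ensemble collapsed to a point) the
#' covariance is degenerate and the gain is exactly zero.
#'
#' @param z `N x n` particle matrix.
#' @param model an `"ssm"` object.
#' @param gz optional precomputed `g(z)` (`N x m`), to avoid recomputation
#'   inside filter loops.
#' @return the `n x m` gain matrix.
#' @export
empirical_gain <- function(z, model, gz = model$g(z)) {
  N <- nrow(z)
  if (N == 1L) return(matrix(0, model$n, model$m))
  zc <- sweep(z, 2L, colMeans(z))
  gc <- sweep(gz, 2L, colMeans(gz))
  (crossprod(zc, gc) / N) %*% model$sigma_y_inv
}

#' Per-particle innovation (novelty) increments
#'
#' The innovation compares the observed increment with each particle's own
#' prediction: `dn^(k) = dy - g(z^(k)) dt`.  Deterministic given its inputs.
#'
#' @param z `N x n` particle matrix.
#' @param dy observation increment (m-vector).
#' @param model an `"ssm"` object.
#' @param dt step size.
#' @param gz optional precomputed `g(z)`.
#' @return `N x m` matrix of innovation increments.
#' @export
novelty <- function(z, dy, model, dt, gz = model$g(z)) {
  stopifnot(dt > 0)
  sweep(-gz * dt, 2L, as.numeric(dy), "+")
}

#' One particle update step
#'
#' Advances every particle by the prior drift plus the gain-weighted
#' innovation plus fresh process noise:
#' `z <- z + f(z) dt + (W dn)^T + Sigma_x^{1/2} sqrt(dt) xi`.
#' With `W = 0` and `sigma_x = 0` this is deterministic Euler on `f`.
#'
#' @param z `N x n` particle matrix.
#' @param dn `N x m` innovation matrix (see [novelty()]).
#' @param model an `"ssm"` object.
#' @param W `n x m` gain matrix.
#' @param dt step size.
#' @param xi optional pre-drawn `N x n` standard normal matrix (for common
#'   random number experiments); default draws from the current RNG.
#' @return updated `N x n` particle matrix.
#' @export
npf_step <- function(z, dn, model, W, dt, xi = NULL) {
  stopifnot(dt > 0, all(is.finite(W)))
  N <- nrow(z)
  noise <- if (all(model$sigma_x == 0)) 0 else {
    if (is.null(xi)) xi <- matrix(stats::rnorm(N * model$n), N, model$n)
    sqrt(dt) * (xi %*% t(model$sigma_x_sqrt))
  }
  z2 <- z + model$f(z) * dt + dn %*% t(W) + noise
  if (!all(is.finite(z2))) {
    bad <- which(!stats::complete.cases(z2))[1L]
    stop(sprintf("particle %d diverged (non-finite state)", bad))
  }
  z2
}

#' Posterior expectation from an unweighted ensemble
#'
#' `E[phi(x) | Y] ~ mean_k phi(z^(k))`; the identity map yields the
#' posterior mean.  Invariant under particle permutations.
#'
#' @param z `N x n` particle matrix.
#' @param phi function mapping an `N x n` matrix to an `N x p` matrix (or an
#'   N-vector); default identity.
#' @return p-vector of expectations.
#' @export
posterior_expectation <- function(z, phi = identity) {
  v <- phi(z)
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  stopifnot(all(is.finite(v)))
  colMeans(v)
}

#' Fraction of particles inside a box
#'
#' Certainty assigned to a spatial region, measured as the relative number
#' of particles whose state lies inside the axis-aligned box
#' `[lo_i, hi_i]` in every dimension.
#'
#' @param z `N x n` particle matrix.
#' @param lo,hi box bounds (n-vectors or scalars recycled).
#' @return fraction in `[0, 1]`.
#' @export
region_certainty <- function(z, lo, hi) {
  stopifnot(all(lo <= hi))
  inside <- rep(TRUE, nrow(z))
  for (j in seq_len(ncol(z)))
    inside <- inside & z[, j] >= rep_len(lo, ncol(z))[j] &
                       z[, j] <= rep_len(hi, ncol(z))[j]
  mean(inside)
}

#' Run an unweighted particle filter over a simulated record
#'
#' Time-steps the ensemble through all observation increments of `record`.
#' Per step, the gain is computed from the *pre-update* ensemble
#' (`empirical` mode) or held at `W0` (`fixed`) or adapted online by
#' likelihood-gradient updates (`learned`; delegates to [run_learning()]),
#' then every particle receives its innovation-corrected Euler update.
#'
#' `method = "enkbf"` runs the ensemble Kalman-Bucy variant, identical
#' except that the innovation uses the averaged prediction
#' `dy - (g(z^(k)) + <g>)/2 dt` (see [enkbf_step()]).
#'
#' @param model an `"ssm"` object (must match the record's `m` and `dt`).
#' @param record an `"ssm_sim"` object.
#' @param N number of particles.
#' @param gain one of `"empirical"`, `"fixed"`, `"learned"`.
#' @param method `"npf"` (default) or `"enkbf"`.
#' @param W0 gain matrix for `gain = "fixed"` (and initial gain for
#'   `"learned"`).
#' @param seed RNG seed for particle initialization and diffusion.
#' @param eta_W learning rate for `gain = "learned"`.
#' @param keep_particles logical; store the full particle trace (only
#'   sensible for small problems).
#' @param branches optional 2-column matrix of `[lo, hi]` scalar intervals;
#'   per-step [region_certainty()] is recorded for each row (scalar models).
#' @return list of class `"npf_run"` with `xhat` (steps x n posterior
#'   means), `xvar` (steps x n posterior marginal variances), `W_mean`
#'   (time-averaged gain), `W_trace` (steps x n*m, only when `n*m <= 16`),
#'   `certainty` (steps x nrow(branches)), `z_final`, and (optionally)
#'   `particles`.
#' @export
run_filter <- function(model, record, N, gain = c("empirical", "fixed",
                                                  "learned"),
                       method = c("npf", "enkbf"), W0 = NULL, seed = 1L,
                       eta_W = 1e-3, keep_particles = FALSE,
                       branches = NULL) {
  gain <- match.arg(gain)
  method <- match.arg(method)
  stopifnot(inherits(model, "ssm"), inherits(record, "ssm_sim"))
  if (ncol(record$dy) != model$m)
    stop("record observation dimension does not match model")
  if (gain == "learned")
    return(run_learning(model, record, N, which = "W", seed = seed,
                        eta_W = eta_W, W0 = W0)$filter)
  steps <- length(record$times)
  n <- model$n; m <- model$m; dt <- record$dt
  set.seed(derive_seed(seed, 1L))
  z <- init_ensemble(model, N)
  if (gain == "fixed") {
    stopifnot(!is.null(W0))
    W0 <- matrix(W0, n, m)
  }
  xhat <- matrix(NA_real_, steps, n)
  xvar <- matrix(NA_real_, steps, n)
  trace_W <- n * m <= 16L
  W_trace <- if (trace_W) matrix(NA_real_, steps, n * m) else NULL
  W_sum <- matrix(0, n, m)
  cert <- if (!is.null(branches))
    matrix(NA_real_, steps, nrow(branches)) else NULL
  particles <- if (keep_particles) array(NA_real_, c(steps, N, n)) else NULL
  stoch <- !all(model$sigma_x == 0)
  for (i in seq_len(steps)) {
    gz <- model$g(z)
    W <- if (gain == "fixed") W0 else empirical_gain(z, model, gz = gz)
    dn <- novelty(z, record$dy[i, ], model, dt, gz = gz)
    if (method == "enkbf") {
      # innovation against the averaged prediction (g(z^(k)) + <g>)/2:
      # dn^(k) = dy - g dt + (g(z^(k)) - <g>) dt/2
      dn <- dn + sweep(gz, 2L, colMeans(gz)) * (dt / 2)
    }
    xhat[i, ] <- colMeans(z)
    xvar[i, ] <- colMeans(z^2) - xhat[i, ]^2
    W_sum <- W_sum + W
    if (trace_W) W_trace[i, ] <- as.numeric(W)
    if (!is.null(cert)) for (b in seq_len(nrow(branches)))
      cert[i, b] <- region_certainty(z, branches[b, 1L], branches[b, 2L])
    if (keep_particles) particles[i, , ] <- z
    xi <- if (stoch) matrix(stats::rnorm(N * n), N, n) else NULL
    z <- npf_step(z, dn, model, W, dt, xi = xi)
  }
  structure(list(times = record$times, xhat = xhat, xvar = xvar,
                 W_mean = W_sum / steps, W_trace = W_trace,
                 certainty = cert, z_final = z, particles = particles,
                 N = N, gain = gain, method = method, seed = seed),
            class = "npf_run")
}

#' @export
print.npf_run <- function(x, ...) {
  cat(sprintf("<npf_run>  %s/%s gain, N = %d, %d steps, n = %d\n",
              x$method, x$gain, x$N, nrow(x$xhat), ncol(x$xhat)))
  invisible(x)
}
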