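# Online parameter learning for the unweighted particle filter.
#
# Parameters are learned by stochastic gradient ascent on the observation
# log-likelihood
#   L_t = int <g>^T Sigma_y^{-1} dy  -  1/2 <g>^T Sigma_y^{-1} <g> dt,
# where <g> is the particle estimate of the predicted observation drift.
# The gradient of <g> with respect to a parameter has an explicit part and
# an implicit part through the particle states (the "filter derivative"),
# which is tracked by forward sensitivity propagation: each particle
# carries d z^(k)/d theta, advanced by differentiating the particle update
# along the particle's own (frozen) noise path.
#
# Scope: scalar hidden state (n = 1).  The learnable generative parameter
# is the weight vector J of a linear observation model g(x) = J x (one
# entry per channel); the gain W (1 x m) can be learned for arbitrary
# observation maps via the model's Jacobian dg.

#' Log-likelihood increment of one observation step
#'
#' `dL = <g>^T Sigma_y^{-1} dy - 1/2 <g>^T Sigma_y^{-1} <g> dt`.
#' Summed over steps this is the running observation log-likelihood (up to
#' a theta-independent constant).
#'
#' @param g_hat posterior estimate of the observation drift (m-vector).
#' @param dy observation increment (m-vector).
#' @param model an `"ssm"` object (supplies `Sigma_y^{-1}`).
#' @param dt step size.
#' @return scalar increment.
#' @export
loglik_increment <- function(g_hat, dy, model, dt) {
  g_hat <- as.numeric(g_hat); dy <- as.numeric(dy)
  q <- model$sigma_y_inv %*% g_hat
  sum(dy * q) - 0.5 * sum(g_hat * q) * dt
}

#' Initialize a learner state
#'
#' Bundles the current parameter estimates, learning rates, running
#' log-likelihood, and the per-particle sensitivity states (initialized to
#' zero) used by the filter derivative.
#'
#' @param model an `"ssm"` with scalar hidden state.
#' @param N particle count.
#' @param J initial generative weight estimate (m-vector) or `NULL` when J
#'   is not learned.
#' @param W initial gain (m-vector, the single row of the 1 x m gain).
#' @param eta_J,eta_W learning rates per unit time (>= 0; 0 freezes the
#'   parameter exactly).
#' @return object of class `"npf_learner"`.
#' @export
learner_state <- function(model, N, J = NULL, W = rep(0, model$m),
                          eta_J = 1e-3, eta_W = 1e-3) {
  stopifnot(model$n == 1L, N >= 1, eta_J >= 0, eta_W >= 0)
  m <- model$m
  if (!is.null(J)) stopifnot(length(J) == m)
  stopifnot(length(W) == m)
  structure(list(
    J = J, W = as.numeric(W), eta_J = eta_J, eta_W = eta_W,
    sJ = if (!is.null(J)) matrix(0, N, m) else NULL,
    sW = matrix(0, N, m), L = 0, N = N, m = m
  ), class = "npf_learner")
}

# Observation drift and its state-derivative per particle.
# For learned J: g_a(z) = J_a z, g'_a = J_a.  Otherwise the model's g/dg.
.obs_eval <- function(state, z, model) {
  if (!is.null(state$J)) {
    list(gz = outer(z, state$J),
         gp = matrix(state$J, length(z), state$m, byrow = TRUE))
  } else {
    zm <- matrix(z, ncol = 1L)
    if (is.null(model$dg))
      stop("gain learning for a nonlinear observation needs model$dg")
    gp <- t(vapply(z, function(zi) as.numeric(model$dg(zi)),
                   numeric(state$m)))
    if (state$m == 1L) gp <- matrix(gp, ncol = 1L)
    list(gz = model$g(zm), gp = gp)
  }
}

#' Maximum-likelihood update of the generative weight J
#'
#' One online gradient-ascent step
#' `J <- J + eta_J * (d<g>/dJ)^T Sigma_y^{-1} (dy - <g> dt)` where the
#' gradient `d<g>_a/dJ_b = 1{a=b} <z> + J_a mean(sJ_b)` combines the
#' explicit dependence with the sensitivity-propagated filter derivative.
#' The J-sensitivities are then advanced along the tangent recursion
#' (holding each particle's noise path fixed).
#'
#' @param state an [learner_state()] with non-`NULL` `J`.
#' @param z particle states (N-vector; scalar hidden state).
#' @param dy observation increment (m-vector).
#' @param model an `"ssm"` object.
#' @param dt step size.
#' @return updated learner state.
#' @export
ml_param_update <- function(state, z, dy, model, dt) {
  stopifnot(inherits(state, "npf_learner"), !is.null(state$J))
  if (is.null(attr(state, "model_env"))) state <- .bind_model(state, model)
  z <- as.numeric(z)
  ob <- .obs_eval(state, z, model)
  gbar <- colMeans(ob$gz)
  innov <- as.numeric(dy) - gbar * dt
  grad_gJ <- diag(mean(z), state$m) + crossprod(ob$gp, state$sJ) / length(z)
  deltaJ <- state$eta_J * as.numeric(t(grad_gJ) %*%
                                     (model$sigma_y_inv %*% innov))
  if (!all(is.finite(deltaJ))) stop("non-finite parameter gradient")
  state$sJ <- .advance_sJ(state, z, ob, dt)
  state$J <- state$J + deltaJ
  state
}

#' Hebbian update of the generative weight (small-noise limit)
#'
#' Local approximation of the likelihood gradient for a linear observation
#' model: `J <- J + eta * (dy - J xhat dt) xhat^T`.  Exact no-op when the
#' residual or the presynaptic estimate vanishes.
#'
#' @param J current weight (m x n matrix or m-vector for scalar states).
#' @param dy observation increment (m-vector).
#' @param x_hat posterior mean (n-vector).
#' @param dt step size.
#' @param eta learning rate.
#' @return updated J of the same shape.
#' @export
hebbian_update <- function(J, dy, x_hat, dt, eta) {
  Jm <- if (is.null(dim(J))) matrix(J, ncol = length(x_hat)) else J
  resid <- as.numeric(dy) - Jm %*% x_hat * dt
  out <- Jm + eta * resid %*% t(x_hat)
  if (is.null(dim(J))) as.numeric(out) else out
}

#' Maximum-likelihood update of the gain W
#'
#' One gradient-ascent step on the per-entry gain sensitivities:
#' `W_b <- W_b + eta_W * (d<g>/dW_b)^T Sigma_y^{-1} (dy - <g> dt)` with
#' `d<g>_a/dW_b = mean(g'_a(z^(k)) sW_b^(k))` (W enters `<g>` only through
#' the particle states, so the first update from zero sensitivities is
#' exactly zero).  The W-sensitivities are then advanced.
#'
#' @inheritParams ml_param_update
#' @return updated learner state.
#' @export
gain_update <- function(state, z, dy, model, dt) {
  stopifnot(inherits(state, "npf_learner"))
  if (is.null(attr(state, "model_env"))) state <- .bind_model(state, model)
  z <- as.numeric(z)
  ob <- .obs_eval(state, z, model)
  gbar <- colMeans(ob$gz)
  innov <- as.numeric(dy) - gbar * dt
  grad_gW <- crossprod(ob$gp, state$sW) / length(z)
  deltaW <- state$eta_W * as.numeric(t(grad_gW) %*%
                                     (model$sigma_y_inv %*% innov))
  if (!all(is.finite(deltaW))) stop("non-finite gain gradient")
  state$sW <- .advance_sW(state, z, dy, ob, model, dt)
  state$W <- state$W + deltaW
  state
}

# Tangent recursion for dz/dJ_b, differentiating
#   z' = z + f(z) dt + sum_a W_a (dy_a - g_a(z) dt) + noise
# with the noise path held fixed:
#   sJ_b' = sJ_b (1 + (f'(z) - sum_a W_a g'_a(z)) dt) - W_b z dt
.advance_sJ <- function(state, z, ob, dt) {
  fp <- .drift_prime(z, attr(state, "model_env"))
  wg <- as.numeric(ob$gp %*% state$W)        # sum_a W_a g'_a(z^(k))
  decay <- 1 + (fp - wg) * dt
  state$sJ * decay - outer(z, state$W) * dt
}

# Tangent recursion for dz/dW_b:
#   sW_b' = sW_b (1 + (f'(z) - sum_a W_a g'_a(z)) dt) + dn_b
.advance_sW <- function(state, z, dy, ob, model, dt) {
  fp <- .drift_prime(z, attr(state, "model_env"))
  wg <- as.numeric(ob$gp %*% state$W)
  decay <- 1 + (fp - wg) * dt
  dn <- sweep(-ob$gz * dt, 2L, as.numeric(dy), "+")
  state$sW * decay + dn
}

# f'(z) per particle, from the env stashed on the learner by run_learning
# (falls back to a central difference if no analytic Jacobian is set).
.drift_prime <- function(z, env) {
  if (is.null(env) || is.null(env$df_diag)) {
    f <- env$f
    h <- 1e-5
    (as.numeric(f(matrix(z + h, ncol = 1L))) -
     as.numeric(f(matrix(z - h, ncol = 1L)))) / (2 * h)
  } else env$df_diag(z)
}

# Attach the drift derivative machinery of `model` to a learner.
.bind_model <- function(state, model) {
  env <- new.env(parent = emptyenv())
  env$f <- model$f
  env$df_diag <- if (!is.null(model$df))
    function(z) vapply(z, function(zi) model$df(zi)[1L, 1L], 0) else NULL
  attr(state, "model_env") <- env
  state
}

#' Filter and learn parameters online
#'
#' Interleaves unweighted particle filtering with per-step online parameter
#' updates.  Each step: (1) posterior drift estimate `<g>` and parameter
#' gradients from the *pre-update* ensemble; (2) gradient updates of J
#' (maximum likelihood or Hebbian) and/or W; (3) particle update with the
#' pre-update parameters; (4) tangent recursion of the sensitivities.
#' The two-timescale assumption (learning much slower than filtering)
#' means `eta_J`, `eta_W` should be small relative to `1/dt`.
#'
#' @param model an `"ssm"` with scalar hidden state.  When J is learned the
#'   observation model is treated as linear, `g(x) = J x`, and the model's
#'   own `g` is ignored in favor of the current estimate.
#' @param record an `"ssm_sim"` observation record.
#' @param N particle count.
#' @param which which parameters to learn: `"J"`, `"W"` or `"both"`.
#' @param rule learning rule for J: `"ml"` (gradient with filter
#'   derivative) or `"hebb"` (local small-noise approximation).
#' @param eta_J,eta_W learning rates per unit time.
#' @param J0 initial J estimate (m-vector; required when learning J).
#' @param W0 initial gain (m-vector; default zero).
#' @param seed RNG seed.
#' @return list of class `"npf_learn_run"` with `J_trace`, `W_trace`
#'   (steps x m), `sJ_trace`, `sW_trace` (per-step ensemble-mean
#'   sensitivities, for diagnostics), `L_trace` (running log-likelihood),
#'   `filter` (an `"npf_run"`-shaped list with `xhat`, `xvar`), and the
#'   final `learner`.
#' @export
run_learning <- function(model, record, N, which = c("J", "W", "both"),
                         rule = c("ml", "hebb"), eta_J = 1e-3,
                         eta_W = 1e-3, J0 = NULL, W0 = NULL, seed = 1L) {
  which <- match.arg(which)
  rule <- match.arg(rule)
  stopifnot(inherits(model, "ssm"), model$n == 1L,
            inherits(record, "ssm_sim"))
  m <- model$m; dt <- record$dt
  steps <- length(record$times)
  learn_J <- which %in% c("J", "both")
  learn_W <- which %in% c("W", "both")
  if (learn_J && is.null(J0)) stop("learning J requires an initial J0")
  if (is.null(W0)) W0 <- rep(0, m)
  state <- learner_state(model, N,
                         J = if (learn_J) as.numeric(J0) else NULL,
                         W = as.numeric(W0),
                         eta_J = if (learn_J) eta_J else 0,
                         eta_W = if (learn_W) eta_W else 0)
  state <- .bind_model(state, model)
  set.seed(derive_seed(seed, 3L))
  z <- as.numeric(init_ensemble(model, N))
  J_trace <- if (learn_J) matrix(NA_real_, steps, m) else NULL
  W_trace <- matrix(NA_real_, steps, m)
  sJ_trace <- if (learn_J) matrix(NA_real_, steps, m) else NULL
  sW_trace <- matrix(NA_real_, steps, m)
  L_trace <- numeric(steps)
  xhat <- matrix(NA_real_, steps, 1L)
  xvar <- matrix(NA_real_, steps, 1L)
  sx <- sqrt(as.numeric(model$sigma_x))
  for (i in seq_len(steps)) {
    dy <- record$dy[i, ]
    ob <- .obs_eval(state, z, model)
    gbar <- colMeans(ob$gz)
    xhat[i, ] <- mean(z)
    xvar[i, ] <- mean(z^2) - mean(z)^2
    if (learn_J) { J_trace[i, ] <- state$J
                   sJ_trace[i, ] <- colMeans(state$sJ) }
    W_trace[i, ] <- state$W
    sW_trace[i, ] <- colMeans(state$sW)
    state$L <- state$L + loglik_increment(gbar, dy, model, dt)
    L_trace[i] <- state$L
    # parameter gradients from the pre-update ensemble
    J_old <- state$J; W_old <- state$W
    if (learn_J) {
      if (rule == "ml") {
        state <- ml_param_update(state, z, dy, model, dt)
      } else {
        state$J <- hebbian_update(state$J, dy, mean(z), dt, state$eta_J)
        state$sJ <- .advance_sJ(state, z, ob, dt)   # kept current anyway
      }
    }
    if (learn_W) state <- gain_update(state, z, dy, model, dt)
    # particle update with the pre-update parameters
    dn <- sweep(-ob$gz * dt, 2L, as.numeric(dy), "+")
    fz <- as.numeric(model$f(matrix(z, ncol = 1L)))
    z <- z + fz * dt + as.numeric(dn %*% W_old) +
      sx * sqrt(dt) * stats::rnorm(length(z))
    if (!all(is.finite(z)))
      stop(sprintf("learning run diverged at step %d", i))
  }
  structure(list(
    times = record$times, J_trace = J_trace, W_trace = W_trace,
    sJ_trace = sJ_trace, sW_trace = sW_trace, L_trace = L_trace,
    filter = structure(list(times = record$times, xhat = xhat, xvar = xvar,
                            W_mean = matrix(colMeans(W_trace), 1L, m),
                            W_trace = W_trace, certainty = NULL,
                            z_final = matrix(z, ncol = 1L), particles = NULL,
                            N = N, gain = "learned", method = "npf",
                            seed = seed), class = "npf_run"),
    learner = state, rule = rule, which = which, seed = seed
  ), class = "npf_learn_run")
}

#' @export
print.npf_learn_run <- function(x, ...) {
  cat(sprintf("<npf_learn_run>  learn %s by %s, N = %d, %d steps\n",
              x$which, x$rule, x$filter$N, length(x$times)))
  if (!is.null(x$J_trace))
    cat(sprintf("  final J: %s\n",
                paste(signif(x$J_trace[nrow(x$J_trace), ], 4),
                      collapse = ", ")))
  invisible(x)
}
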