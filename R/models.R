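# State-space diffusion models and their Euler-Maruyama simulator.
#
# A model is the generative pair
#   dx_t = f(x_t) dt + Sigma_x^{1/2} dw_t          (hidden state, R^n)
#   dy_t = g(x_t) dt + Sigma_y^{1/2} du_t          (observations, R^m)
# Observations are handled as increments dy throughout: the filters only
# ever consume increments, and storing increments avoids catastrophic
# cancellation in cumulative paths.

#' Construct a state-space diffusion model
#'
#' Defines the generative pair of Itô SDEs for a hidden diffusion `x_t`
#' (dimension `n`) observed through noisy increment observations `dy_t`
#' (dimension `m`).
#'
#' `f` and `g` must be vectorized over states: they take an `N x n` matrix
#' (rows are states) and return an `N x n` (resp. `N x m`) matrix.  Use
#' [rowwise_fn()] to wrap a plain one-state-at-a-time function.
#'
#' @param n hidden dimension (positive integer).
#' @param m observation dimension (positive integer).
#' @param f drift map; matrix-in, matrix-out (see Details).
#' @param sigma_x hidden noise covariance (n x n; scalar and vector
#'   shorthand for diagonal matrices accepted).  Positive semi-definite.
#' @param g observation map; matrix-in, matrix-out.
#' @param sigma_y observation noise covariance (m x m).  Must be strictly
#'   positive definite: its inverse enters the gain, the likelihood and all
#'   learning rules.
#' @param df optional Jacobian of `f` at a single state (n x n matrix
#'   valued function of an n-vector); used by sensitivity propagation.
#' @param dg optional Jacobian of `g` at a single state (m x n).
#' @param linear optional list `list(A =, C =)` declaring `f(x) = A x`,
#'   `g(x) = C x`; required by the Kalman-Bucy filter.
#' @param name model label used in printing and output metadata.
#' @return an object of class `"ssm"`.
#' @seealso [model_zoo()], [simulate_ssm()], [stationary_density()]
#' @export
state_space_model <- function(n, m, f, sigma_x, g, sigma_y,
                              df = NULL, dg = NULL, linear = NULL,
                              name = "custom") {
  stopifnot(n >= 1, m >= 1, is.function(f), is.function(g))
  n <- as.integer(n); m <- as.integer(m)
  sigma_x <- as_cov(sigma_x, n, "sigma_x", strict = FALSE)
  sigma_y <- as_cov(sigma_y, m, "sigma_y", strict = TRUE)
  model <- structure(list(
    n = n, m = m, f = f, g = g,
    sigma_x = sigma_x, sigma_y = sigma_y,
    sigma_x_sqrt = cov_sqrt(sigma_x),
    sigma_y_sqrt = cov_sqrt(sigma_y),
    sigma_y_inv = solve(sigma_y),
    df = df, dg = dg, linear = linear, name = name
  ), class = "ssm")
  probe <- matrix(0, 1, n)
  fx <- model$f(probe); gx <- model$g(probe)
  if (!is.matrix(fx) || !all(dim(fx) == c(1L, n)) || !all(is.finite(fx)))
    stop("'f' must map an N x n matrix to a finite N x n matrix")
  if (!is.matrix(gx) || !all(dim(gx) == c(1L, m)) || !all(is.finite(gx)))
    stop("'g' must map an N x n matrix to a finite N x m matrix")
  model
}

#' @export
print.ssm <- function(x, ...) {
  cat(sprintf("<ssm '%s'>  hidden dim n = %d, observed dim m = %d%s\n",
              x$name, x$n, x$m,
              if (!is.null(x$linear)) " (linear)" else ""))
  invisible(x)
}

#' Vectorize a one-state function over rows
#'
#' Convenience wrapper turning a function of a single state vector into the
#' matrix-in/matrix-out form required by [state_space_model()].
#'
#' @param fn function taking an n-vector and returning a p-vector.
#' @param p output dimension.
#' @return function mapping `N x n` matrices to `N x p` matrices.
#' @export
rowwise_fn <- function(fn, p) {
  function(x) {
    out <- t(apply(x, 1L, fn))
    if (p == 1L) out <- matrix(out, ncol = 1L)
    out
  }
}

#' Simulate a state-space model by Euler-Maruyama
#'
#' Integrates the hidden SDE with the fixed-step Euler-Maruyama scheme
#' `x_{t+dt} = x_t + f(x_t) dt + Sigma_x^{1/2} sqrt(dt) xi` and generates
#' observation increments `dy_t = g(x_t) dt + Sigma_y^{1/2} sqrt(dt) zeta`
#' with independent standard normal `xi`, `zeta`.  Runs are bit-reproducible
#' under a fixed seed.
#'
#' @param model an [state_space_model()] object.
#' @param T total duration (time units); `T >= dt`.
#' @param dt step size; default 0.01 time units.
#' @param x0 initial hidden state (n-vector).  Default: a draw from the
#'   stationary density when `n == 1` and it exists, else the origin.
#' @param seed RNG seed (integer).
#' @return an object of class `"ssm_sim"`: list with `times` (grid
#'   `t_i = i dt`, length `steps`), `x` (`steps x n` hidden states), `dy`
#'   (`steps x m` observation increments over `[t_i, t_i + dt)`), plus
#'   `dt` and `seed`.
#' @export
simulate_ssm <- function(model, T, dt = 0.01, x0 = NULL, seed = 1L) {
  stopifnot(inherits(model, "ssm"), dt > 0, T >= dt)
  steps <- as.integer(round(T / dt))
  n <- model$n; m <- model$m
  set.seed(derive_seed(seed, 0L))
  if (is.null(x0)) {
    x0 <- rep(0, n)
    if (n == 1L && !all(model$sigma_x == 0)) {
      sd1 <- try(stationary_density(model), silent = TRUE)
      if (!inherits(sd1, "try-error")) x0 <- sample_stationary(sd1, 1L)
    }
  }
  stopifnot(length(x0) == n, all(is.finite(x0)))
  x <- matrix(NA_real_, steps, n)
  x[1L, ] <- x0
  xi <- matrix(stats::rnorm(steps * n), steps, n)
  noise_x <- if (all(model$sigma_x == 0)) matrix(0, steps, n)
             else sqrt(dt) * (xi %*% t(model$sigma_x_sqrt))
  cur <- matrix(x0, 1L, n)
  for (i in seq_len(steps - 1L)) {
    drift <- model$f(cur)
    cur <- cur + drift * dt + noise_x[i, , drop = FALSE]
    if (!all(is.finite(cur)))
      stop(sprintf("simulation diverged at step %d (non-finite state)", i + 1L))
    x[i + 1L, ] <- cur
  }
  gx <- model$g(x)
  if (!all(is.finite(gx)))
    stop(sprintf("simulation diverged: non-finite observation drift at step %d",
                 which(!stats::complete.cases(gx))[1L]))
  zeta <- matrix(stats::rnorm(steps * m), steps, m)
  dy <- gx * dt + sqrt(dt) * (zeta %*% t(model$sigma_y_sqrt))
  structure(list(times = (seq_len(steps) - 1L) * dt, x = x, dy = dy,
                 dt = dt, seed = as.integer(seed), model_name = model$name),
            class = "ssm_sim")
}

#' @export
print.ssm_sim <- function(x, ...) {
  cat(sprintf("<ssm_sim '%s'>  %d steps, dt = %g, n = %d, m = %d, seed = %d\n",
              x$model_name, length(x$times), x$dt, ncol(x$x), ncol(x$dy),
              x$seed))
  invisible(x)
}

#' Stationary density of a scalar diffusion
#'
#' For a one-dimensional model `dx = f(x) dt + sqrt(sigma_x) dw` the
#' stationary density is `p(x) proportional to exp((2/sigma_x) * F(x))` with
#' `F` an antiderivative of `f`.  Computed by trapezoid quadrature on a grid
#' and normalized to integrate to one.
#'
#' @param model a scalar (`n == 1`) [state_space_model()] with
#'   `sigma_x > 0`.
#' @param grid evaluation grid (increasing numeric vector); default 2001
#'   points on `[-5, 5]`.
#' @return object of class `"ssm_density"`: list with `x` (grid), `d`
#'   (density values), `cdf` and `quantile` (interpolating functions).
#' @export
stationary_density <- function(model, grid = seq(-5, 5, length.out = 2001L)) {
  stopifnot(inherits(model, "ssm"), model$n == 1L)
  s <- as.numeric(model$sigma_x)
  if (s <= 0) stop("stationary density requires sigma_x > 0")
  fx <- as.numeric(model$f(matrix(grid, ncol = 1L)))
  logp <- (2 / s) * cumtrapz(grid, fx)
  logp <- logp - max(logp)
  # diverging tails: the log-density must fall off at both grid ends
  edge <- max(logp[1L], logp[length(logp)])
  if (edge > log(1e-3))
    stop("density does not decay on the grid; non-integrable or grid too narrow")
  d <- exp(logp)
  z <- sum(diff(grid) * (d[-1] + d[-length(d)]) / 2)
  if (!is.finite(z) || z <= 0) stop("density normalization failed")
  d <- d / z
  cdfv <- cumtrapz(grid, d)
  cdfv <- cdfv / cdfv[length(cdfv)]
  keep <- !duplicated(cdfv)
  structure(list(
    x = grid, d = d,
    cdf = stats::approxfun(grid, cdfv, yleft = 0, yright = 1),
    quantile = stats::approxfun(cdfv[keep], grid[keep], rule = 2)
  ), class = "ssm_density")
}

#' Draw i.i.d. samples from a tabulated stationary density
#'
#' Inverse-CDF sampling from an [stationary_density()] object.  Uses the
#' current RNG state (seed management is the caller's job).
#'
#' @param density an `"ssm_density"` object.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_stationary <- function(density, n) {
  stopifnot(inherits(density, "ssm_density"))
  density$quantile(stats::runif(n))
}

#' Built-in model zoo
#'
#' Ready-made models used throughout the package:
#'
#' * `"frog"` — scalar double-well hidden dynamics
#'   `dx = 3 x (1 - x^2) dt + dw` (bimodal stationary density with modes at
#'   -1 and +1) observed through a linear "visual" channel
#'   `dv = J x dt + sigma_v dbeta` and/or a sigmoidal "auditory" channel
#'   `da = tanh(2 x) dt + sigma_a dgamma`.  `channels` selects
#'   `"both"` (m = 2, default), `"visual"` or `"auditory"`.
#' * `"linear_d"` — `d` independent Ornstein-Uhlenbeck dimensions
#'   `dx_i = a x_i dt + dw_i` with `a = -0.75`, identity observation and
#'   unit noise covariances; the optimal (Kalman) steady-state MSE is
#'   exactly 0.5 per dimension.
#' * `"bimodal_d"` — `d` independent copies of the double-well dynamics
#'   with identity observation.
#'
#' @param name one of `"frog"`, `"linear_d"`, `"bimodal_d"`.
#' @param d hidden dimension for the `_d` families.
#' @param sigma_v2,sigma_a2 sensory noise variances of the frog channels
#'   (default 0.1 each).
#' @param channels frog sensory channels (see above).
#' @param J generative weight of the frog's visual channel (default 1).
#' @param drift OU drift coefficient for `"linear_d"` (default -0.75).
#' @param sigma_y2 per-dimension observation noise variance for the `_d`
#'   families.  Defaults: 1 for `"linear_d"` (pins the optimal MSE at 0.5
#'   per dimension), 0.1 for `"bimodal_d"` (the sensory-noise level of the
#'   scalar double-well example, of which this family is the
#'   high-dimensional product).
#' @return an `"ssm"` object.
#' @export
model_zoo <- function(name = c("frog", "linear_d", "bimodal_d"), d = 1L,
                      sigma_v2 = 0.1, sigma_a2 = 0.1,
                      channels = c("both", "visual", "auditory"), J = 1,
                      drift = -0.75, sigma_y2 = NULL) {
  name <- match.arg(name)
  if (is.null(sigma_y2)) sigma_y2 <- if (name == "bimodal_d") 0.1 else 1
  dwell <- function(x) 3 * x * (1 - x^2)
  dwell_jac_diag <- function(x) 3 - 9 * x^2
  switch(name,
    frog = {
      channels <- match.arg(channels)
      if (sigma_v2 <= 0 || sigma_a2 <= 0)
        stop("sensory noise variances must be positive")
      gdefs <- list(
        visual   = list(g = function(x) J * x, dg = function(x) J,
                        s2 = sigma_v2),
        auditory = list(g = function(x) tanh(2 * x),
                        dg = function(x) 2 / cosh(2 * x)^2, s2 = sigma_a2)
      )
      use <- if (channels == "both") c("visual", "auditory") else channels
      m <- length(use)
      gfun <- function(x) {
        out <- matrix(0, nrow(x), m)
        for (j in seq_len(m)) out[, j] <- gdefs[[use[j]]]$g(x[, 1L])
        out
      }
      dgfun <- function(x) {
        matrix(vapply(use, function(u) gdefs[[u]]$dg(x[1L]), 0), ncol = 1L)
      }
      state_space_model(
        n = 1L, m = m, f = function(x) dwell(x), sigma_x = 1,
        g = gfun, sigma_y = diag(vapply(use, function(u) gdefs[[u]]$s2, 0),
                                 m),
        df = function(x) matrix(dwell_jac_diag(x[1L]), 1L, 1L), dg = dgfun,
        name = paste0("frog_", channels))
    },
    linear_d = {
      if (sigma_y2 <= 0) stop("sigma_y2 must be positive")
      d <- as.integer(d)
      a <- drift
      state_space_model(
        n = d, m = d, f = function(x) a * x, sigma_x = diag(1, d),
        g = function(x) x, sigma_y = diag(sigma_y2, d),
        df = function(x) diag(a, d), dg = function(x) diag(1, d),
        linear = list(A = diag(a, d), C = diag(1, d)),
        name = sprintf("linear_d%d", d))
    },
    bimodal_d = {
      if (sigma_y2 <= 0) stop("sigma_y2 must be positive")
      d <- as.integer(d)
      state_space_model(
        n = d, m = d, f = function(x) dwell(x), sigma_x = diag(1, d),
        g = function(x) x, sigma_y = diag(sigma_y2, d),
        df = function(x) diag(dwell_jac_diag(x), d),
        dg = function(x) diag(1, d),
        name = sprintf("bimodal_d%d", d))
    })
}

#' Write a simulation record to delimited text
#'
#' Serializes an [simulate_ssm()] record as CSV (columns `t`, `x_1..x_n`,
#' `dy_1..dy_m`) with a JSON metadata sidecar (`<path>.json`).
#'
#' @param record an `"ssm_sim"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ssm_sim <- function(record, path) {
  stopifnot(inherits(record, "ssm_sim"))
  n <- ncol(record$x); m <- ncol(record$dy)
  df <- data.frame(t = record$times, record$x, record$dy)
  names(df) <- c("t", paste0("x_", seq_len(n)), paste0("dy_", seq_len(m)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model = record$model_name, dt = record$dt,
               seed = record$seed, steps = length(record$times),
               n = n, m = m)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a simulation record written by [write_ssm_sim()]
#'
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return an `"ssm_sim"` object.
#' @export
read_ssm_sim <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  structure(list(
    times = df$t,
    x = as.matrix(df[, paste0("x_", seq_len(meta$n)), drop = FALSE]),
    dy = as.matrix(df[, paste0("dy_", seq_len(meta$m)), drop = FALSE]),
    dt = meta$dt, seed = meta$seed, model_name = meta$model
  ), class = "ssm_sim")
}
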