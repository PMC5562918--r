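test_that("log-likelihood increment is exact and rotation invariant", {
  m <- ou_model()
  expect_equal(loglik_increment(0, dy = 0.7, m, dt = 0.1), 0)
  expect_equal(loglik_increment(1, dy = 0.2, m, dt = 0.1), 0.15)

  # quadratic form is invariant under a joint rotation of g, dy, Sigma_y
  theta <- 0.83
  Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Sy <- diag(c(0.5, 2))
  m2 <- state_space_model(1, 2, function(x) -x,
                          sigma_x = 1, g = function(x) cbind(x, x),
                          sigma_y = Sy)
  m2r <- state_space_model(1, 2, function(x) -x,
                           sigma_x = 1, g = function(x) cbind(x, x),
                           sigma_y = Q %*% Sy %*% t(Q))
  gh <- c(0.3, -1.2); dy <- c(0.05, 0.2)
  expect_equal(loglik_increment(Q %*% gh, Q %*% dy, m2r, dt = 0.1),
               loglik_increment(gh, dy, m2, dt = 0.1))

  # additivity over contiguous segments is summation by construction
  incs <- c(loglik_increment(1, 0.1, m, 0.1), loglik_increment(0.5, -0.1, m, 0.1))
  expect_equal(sum(incs), incs[1] + incs[2])
})

test_that("ML weight update matches explicit-term arithmetic", {
  m <- ou_model(r = 0.1)   # sigma_y^2 = 0.1
  st <- learner_state(m, N = 4, J = 1, W = 0.5, eta_J = 0.01, eta_W = 0)
  z <- rep(0.5, 4)         # <z> = 0.5, zero sensitivities
  st2 <- ml_param_update(st, z, dy = 0.1, m, dt = 0.1)
  # delta J = eta * <z> * sigma^-2 * (dy - J <z> dt) = 0.01*0.5*10*0.05
  expect_equal(st2$J, 1 + 0.0025)

  # frozen learning rate is an exact no-op on the parameter
  st0 <- learner_state(m, N = 4, J = 1, W = 0.5, eta_J = 0, eta_W = 0)
  expect_equal(ml_param_update(st0, z, dy = 0.1, m, dt = 0.1)$J, 1)
})

test_that("Hebbian update matches its local arithmetic", {
  expect_equal(hebbian_update(1, dy = 0.2, x_hat = 0.1, dt = 0.1, eta = 1),
               1.019)
  expect_equal(hebbian_update(1, dy = 0.01, x_hat = 0.1, dt = 0.1, eta = 1),
               1)                       # dy = J xhat dt: zero residual
  expect_equal(hebbian_update(2, dy = 5, x_hat = 0, dt = 0.1, eta = 1), 2)
})

test_that("gain gradient needs one step to build sensitivity", {
  m <- ou_model(r = 0.1)
  st <- learner_state(m, N = 3, J = NULL, W = 0.8, eta_J = 0, eta_W = 0.05)
  z <- c(-0.2, 0.1, 0.6)
  st1 <- gain_update(st, z, dy = 0.3, m, dt = 0.1)
  expect_equal(st1$W, 0.8)              # zero sensitivities: no first move
  expect_true(any(st1$sW != 0))         # but sensitivities now nonzero
  st2 <- gain_update(st1, z, dy = 0.3, m, dt = 0.1)
  expect_false(isTRUE(all.equal(st2$W, 0.8)))
})

test_that("tangent sensitivities equal common-random-number finite differences", {
  m <- model_zoo("frog", channels = "visual", J = 1, sigma_v2 = 0.1)
  rec <- simulate_ssm(m, T = 0.3, dt = 0.01, seed = 4)
  h <- 1e-4
  run_at <- function(J0, W0) run_learning(m, rec, N = 50, which = "both",
                                          rule = "ml", eta_J = 0, eta_W = 0,
                                          J0 = J0, W0 = W0, seed = 9)
  rc <- run_at(1, 1.5)
  fdJ <- (mean(run_at(1 + h, 1.5)$filter$z_final) -
          mean(run_at(1 - h, 1.5)$filter$z_final)) / (2 * h)
  expect_equal(mean(rc$learner$sJ), fdJ, tolerance = 1e-4)
  fdW <- (mean(run_at(1, 1.5 + h)$filter$z_final) -
          mean(run_at(1, 1.5 - h)$filter$z_final)) / (2 * h)
  expect_equal(mean(rc$learner$sW), fdW, tolerance = 1e-4)
})

test_that("zero learning rates freeze the trajectories exactly", {
  m <- model_zoo("frog", channels = "visual", J = 1, sigma_v2 = 0.1)
  rec <- simulate_ssm(m, T = 2, dt = 0.01, seed = 6)
  r <- run_learning(m, rec, N = 30, which = "both", rule = "ml",
                    eta_J = 0, eta_W = 0, J0 = 0.4, W0 = 1.2, seed = 6)
  expect_equal(unique(r$J_trace[, 1L]), 0.4)
  expect_equal(unique(r$W_trace[, 1L]), 1.2)
  r2 <- run_learning(m, rec, N = 30, which = "both", rule = "ml",
                     eta_J = 0, eta_W = 0, J0 = 0.4, W0 = 1.2, seed = 6)
  expect_identical(r$filter$xhat, r2$filter$xhat)  # seed determinism
})

test_that("online ML moves the weight estimate toward the truth", {
  m <- model_zoo("frog", channels = "visual", J = 1, sigma_v2 = 0.1)
  rec <- simulate_ssm(m, T = 80, dt = 0.01, seed = 14)
  r <- run_learning(m, rec, N = 100, which = "both", rule = "ml",
                    eta_J = 0.02, eta_W = 0.1, J0 = 0.2, W0 = 0.5, seed = 14)
  expect_gt(last_fraction_mean(r$J_trace[, 1L]), 0.6)
})

test_that("Hebbian and ML rules agree at small observation noise", {
  s2 <- 0.01
  m <- model_zoo("frog", channels = "visual", J = 1, sigma_v2 = s2)
  rec <- simulate_ssm(m, T = 120, dt = 0.01, seed = 8)
  rml <- run_learning(m, rec, N = 100, which = "both", rule = "ml",
                      eta_J = 0.02, eta_W = 0.1, J0 = 0.2, W0 = 0.5,
                      seed = 8)
  rhb <- run_learning(m, rec, N = 100, which = "both", rule = "hebb",
                      eta_J = 0.02 / s2, eta_W = 0.1, J0 = 0.2, W0 = 0.5,
                      seed = 8)
  jm <- last_fraction_mean(rml$J_trace[, 1L])
  jh <- last_fraction_mean(rhb$J_trace[, 1L])
  expect_lt(abs(jm - jh), 0.15)
  expect_lt(abs(jh - 1), 0.15)

  # the two per-step updates stay positively proportional at every noise
  # level (the filter-derivative term rescales, but does not flip, the
  # local Hebbian direction)
  for (s2 in c(1, 0.1, 0.01)) {
    mm <- model_zoo("frog", channels = "visual", J = 1, sigma_v2 = s2)
    rr <- simulate_ssm(mm, T = 40, dt = 0.01, seed = 8)
    r <- run_learning(mm, rr, N = 100, which = "both", rule = "ml",
                      eta_J = 0, eta_W = 0.1, J0 = 1, W0 = 0.5, seed = 8)
    zb <- r$filter$xhat[, 1L]; sj <- r$sJ_trace[, 1L]
    innov <- rr$dy[, 1L] - zb * rr$dt
    dml <- (zb + sj) * innov
    dhb <- zb * innov
    expect_gt(sum(dml * dhb) / sum(dhb^2), 0)
  }
})

test_that("likelihood is highest near the generating parameter", {
  m <- model_zoo("frog", channels = "visual", J = 1, sigma_v2 = 0.1)
  rec <- simulate_ssm(m, T = 60, dt = 0.01, seed = 21)
  L_at <- function(J0) {
    r <- run_learning(m, rec, N = 100, which = "both", rule = "ml",
                      eta_J = 0, eta_W = 0.1, J0 = J0, W0 = 0.5, seed = 21)
    r$L_trace[length(r$L_trace)]
  }
  expect_gt(L_at(1.0), L_at(0.5))
  expect_gt(L_at(1.0), L_at(1.5))
})
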