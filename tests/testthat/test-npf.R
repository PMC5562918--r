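test_that("empirical gain matches hand-computed and brute-force values", {
  # two-point ensemble, linear readout: population var 1, sigma_y^2 = 0.1
  m <- det_model(r = 0.1)
  z <- matrix(c(-1, 1), 2, 1)
  expect_equal(empirical_gain(z, m), matrix(10, 1, 1))

  # sigmoidal readout: cov(z, tanh 2z) on {0, 2} is tanh(4)/2
  ma <- det_model(g = function(x) tanh(2 * x), r = 0.1)
  za <- matrix(c(0, 2), 2, 1)
  expect_equal(empirical_gain(za, ma), matrix(10 * tanh(4) / 2, 1, 1),
               tolerance = 1e-12)

  # degenerate ensembles carry zero gain
  expect_equal(empirical_gain(matrix(0.7, 5, 1), m), matrix(0, 1, 1))
  expect_equal(empirical_gain(matrix(0.7, 1, 1), m), matrix(0, 1, 1))

  # brute-force double sum agrees on random multivariate ensembles
  set.seed(99)
  mm <- state_space_model(
    n = 2L, m = 3L, f = function(x) -x, sigma_x = diag(1, 2),
    g = function(x) cbind(x[, 1], tanh(x[, 2]), x[, 1] * 0.5 + x[, 2]),
    sigma_y = diag(c(1, 0.5, 2)))
  for (rep in 1:5) {
    z <- matrix(rnorm(8 * 2), 8, 2)
    expect_equal(empirical_gain(z, mm), gain_bruteforce(z, mm),
                 tolerance = 1e-12)
  }
})

test_that("novelty is the exact per-particle residual", {
  m <- det_model()
  z <- matrix(0.5, 1, 1)
  expect_equal(novelty(z, dy = 0.05, m, dt = 0.1), matrix(0, 1, 1))
  ma <- det_model(g = function(x) tanh(2 * x))
  expect_equal(novelty(matrix(0, 1, 1), dy = 0.2, ma, dt = 0.1),
               matrix(0.2, 1, 1))
  # perfect prediction for every particle
  z <- matrix(c(0.1, -0.4, 2), 3, 1)
  dn <- novelty(z, dy = 0, m, dt = 0.3)
  expect_equal(dn, -z * 0.3)
})

test_that("particle update honors its algebraic limits", {
  m <- det_model()
  z <- matrix(c(-1, 0, 2), 3, 1)
  dn0 <- matrix(0, 3, 1)
  expect_equal(npf_step(z, dn0, m, W = matrix(0, 1, 1), dt = 0.1), z)

  # drift fixed point stays put with zero gain and zero noise
  mdw <- det_model(f = function(x) 3 * x * (1 - x^2))
  expect_equal(npf_step(matrix(1, 1, 1), matrix(0, 1, 1), mdw,
                        W = matrix(0, 1, 1), dt = 0.1), matrix(1, 1, 1))

  # pure gain response: z' = z + W dn
  expect_equal(npf_step(matrix(0, 1, 1), matrix(0.1, 1, 1), m,
                        W = matrix(10, 1, 1), dt = 0.1), matrix(1, 1, 1))

  expect_error(npf_step(matrix(1e308, 1, 1), matrix(1e308, 1, 1), m,
                        W = matrix(1e308, 1, 1), dt = 0.1), "diverged")
})

test_that("posterior expectations and region certainty are exact averages", {
  z <- matrix(c(-1, 0, 1), 3, 1)
  expect_equal(posterior_expectation(z), 0)
  expect_equal(posterior_expectation(matrix(c(-1, 1), 2, 1),
                                     phi = function(z) z^2), 1)
  expect_equal(posterior_expectation(matrix(c(0.2, 0.4, 0.6), 3, 1)), 0.4)

  z4 <- matrix(c(-1.1, -0.9, 1.0, 1.05), 4, 1)
  expect_equal(region_certainty(z4, -1.25, -0.75), 0.5)
  expect_equal(region_certainty(z4, -10, 10), 1)
  expect_equal(region_certainty(z4, 0, 0), 0)     # measure-zero box
  expect_equal(region_certainty(z4, 1.0, 1.0), 0.25)  # exact hit counts
})

test_that("ensemble statistics are permutation invariant", {
  m <- model_zoo("frog")
  set.seed(5)
  for (rep in 1:5) {
    z <- matrix(rnorm(40), 40, 1)
    perm <- sample(40)
    zp <- z[perm, , drop = FALSE]
    expect_equal(empirical_gain(zp, m), empirical_gain(z, m))
    expect_equal(posterior_expectation(zp), posterior_expectation(z))
    expect_equal(region_certainty(zp, 0.75, 1.25),
                 region_certainty(z, 0.75, 1.25))
  }
})

test_that("run_filter reduces to deterministic Euler in the noiseless limit", {
  m <- det_model(f = function(x) -x)
  rec <- simulate_ssm(m, T = 1, dt = 0.01, x0 = 1, seed = 2)
  run <- run_filter(m, rec, N = 3, gain = "fixed", W0 = 0, seed = 2)
  z0 <- run$xhat[1L, 1L]
  expect_equal(run$xhat[, 1L], z0 * (1 - 0.01)^(seq_len(100) - 1L),
               tolerance = 1e-12)
})

test_that("filter tracks the Kalman-Bucy solution on the linear model", {
  m <- model_zoo("linear_d", d = 1)
  rec <- simulate_ssm(m, T = 30, dt = 0.01, seed = 13)
  kb <- run_kalman_bucy(m, rec)
  run <- run_filter(m, rec, N = 3000, seed = 13)
  expect_lt(mean(abs(run$xhat - kb$xhat)), 0.1)
  # the plain-innovation ensemble equilibrates at ITS analytic gain fixed
  # point, the root of 2V^2/r - 2aV - q = 0 (below the Kalman gain P*/r)
  V_npf <- (-1.5 + sqrt(1.5^2 + 8)) / 4
  expect_equal(run$W_mean[1L, 1L], V_npf, tolerance = 0.05 * V_npf)
})

test_that("inter-particle variance shrinks as observation noise vanishes", {
  vars <- vapply(c(1, 0.1, 0.01), function(s2) {
    m <- model_zoo("frog", sigma_v2 = s2, sigma_a2 = s2)
    rec <- simulate_ssm(m, T = 10, dt = 0.01, seed = 17)
    run <- run_filter(m, rec, N = 300, seed = 17)
    mean(run$xvar[-seq_len(100), 1L])
  }, 0)
  expect_true(all(diff(vars) < 0))
})

test_that("zero gain reproduces the prior stationary density", {
  m <- model_zoo("frog")
  rec <- simulate_ssm(m, T = 5, dt = 0.01, seed = 19)
  run <- run_filter(m, rec, N = 2000, gain = "fixed",
                    W0 = matrix(0, 1, 2), seed = 19)
  D <- ks_distance(run$z_final[, 1L], stationary_density(m))
  expect_lt(D, 0.05)
})

test_that("auditory gain reflects noise level and posterior location", {
  # gain decreases with the channel's noise (Fig-3b-style sweep)
  sweep <- frog_gain_sweep(vary = "auditory", grid = c(0.01, 0.1, 1),
                           N = 300, T = 20, seed = 23)
  expect_true(all(diff(sweep$W_auditory) < 0))

  # sigmoid slope: posterior mass near 0 makes audition more informative
  m <- model_zoo("frog")
  set.seed(31)
  z_center <- matrix(rnorm(4000, 0, 0.3), ncol = 1)
  z_branch <- matrix(rnorm(4000, 1, 0.3), ncol = 1)
  expect_gt(empirical_gain(z_center, m)[1L, 2L],
            empirical_gain(z_branch, m)[1L, 2L])
})
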