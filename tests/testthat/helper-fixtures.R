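# Shared fixtures: tiny models and deterministic ensembles built in code.

# scalar OU model dx = a x dt + sqrt(q) dw, dy = x dt + sqrt(r) du
ou_model <- function(a = -0.75, q = 1, r = 1) {
  state_space_model(
    n = 1L, m = 1L, f = function(x) a * x, sigma_x = q,
    g = function(x) x, sigma_y = r,
    df = function(x) matrix(a, 1, 1), dg = function(x) matrix(1, 1, 1),
    linear = list(A = matrix(a, 1, 1), C = matrix(1, 1, 1)),
    name = "ou_test")
}

# deterministic scalar model (no process noise) for exact-arithmetic tests
det_model <- function(f = function(x) 0 * x, g = function(x) x, r = 1) {
  state_space_model(n = 1L, m = 1L, f = f, sigma_x = 0, g = g, sigma_y = r,
                    name = "det_test")
}

# brute-force double-sum version of the empirical gain (independent oracle)
gain_bruteforce <- function(z, model) {
  N <- nrow(z)
  gz <- model$g(z)
  s1 <- matrix(0, ncol(z), ncol(gz))
  for (k in seq_len(N)) s1 <- s1 + tcrossprod(z[k, ], gz[k, ])
  s2 <- matrix(0, ncol(z), ncol(gz))
  for (k in seq_len(N)) for (l in seq_len(N))
    s2 <- s2 + tcrossprod(z[k, ], gz[l, ])
  (s1 / N - s2 / N^2) %*% model$sigma_y_inv
}

# Kolmogorov-Smirnov distance of samples against a tabulated density's cdf
ks_distance <- function(x, density) {
  x <- sort(x)
  n <- length(x)
  cdf <- density$cdf(x)
  max(abs(cdf - seq_len(n) / n), abs(cdf - (seq_len(n) - 1L) / n))
}

last_fraction_mean <- function(v, frac = 0.2) {
  n <- length(v)
  mean(v[seq.int(floor((1 - frac) * n) + 1L, n)])
}
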