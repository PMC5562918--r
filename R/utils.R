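#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive a component sub-seed from a master seed
#'
#' Each logical component of a run (simulation, each filter, learner) draws
#' from its own RNG stream so that adding a component to a run does not
#' perturb the noise seen by the others.  Streams are derived
#' deterministically from the master seed and a small stream index.
#'
#' @param seed master seed (integer).
#' @param stream stream index (non-negative integer).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 48271 * (stream + 1)) %% 2147483629)
}

# Validate and canonicalize a covariance matrix; scalars are promoted to
# diagonal matrices.  `strict` demands positive definiteness (the inverse is
# needed), otherwise positive semi-definiteness suffices.
as_cov <- function(x, d, name, strict = FALSE) {
  if (is.null(dim(x))) {
    if (length(x) == 1L) x <- diag(as.numeric(x), d)
    else if (length(x) == d) x <- diag(as.numeric(x), d)
    else stop(sprintf("'%s' must be %dx%d (or scalar/diagonal)", name, d, d))
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(d, d)))
    stop(sprintf("'%s' must be %dx%d", name, d, d))
  if (!isTRUE(all.equal(x, t(x), tolerance = 1e-8)))
    stop(sprintf("'%s' must be symmetric", name))
  ev <- eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (strict && min(ev) <= 1e-12 * max(abs(ev), 1))
    stop(sprintf("'%s' must be strictly positive definite", name))
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(sprintf("'%s' must be positive semi-definite", name))
  (x + t(x)) / 2
}

# Symmetric matrix square root (covariances may be singular, so chol() is
# not enough); tiny negative eigenvalues from roundoff are clipped.
cov_sqrt <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Cumulative trapezoid integral of y over x (same length as x, starts at 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Polynomial rolling hash of a character vector, as 8 hex digits; used only
# to stamp a resolved run configuration into output metadata.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
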