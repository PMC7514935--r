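# Independent oracles used across the test files.

# KL divergence between two Beta densities by adaptive quadrature,
# independent of both the digamma identity and the grid path.
kl_quadrature <- function(p, q) {
  f <- function(x) {
    dbeta(x, p$alpha, p$beta) *
      (dbeta(x, p$alpha, p$beta, log = TRUE) -
         dbeta(x, q$alpha, q$beta, log = TRUE))
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

# Beta-Binomial pmf by quadrature of Binomial(n, theta) against the Beta
# density, independent of the log-Beta-function path.
beta_binomial_pmf_quadrature <- function(n, shape) {
  vapply(0:n, function(s) {
    stats::integrate(function(th) {
      dbinom(s, n, th) * dbeta(th, shape$alpha, shape$beta)
    }, 0, 1, rel.tol = 1e-10)$value
  }, numeric(1))
}

# draw moderate random Beta shape pairs (overlapping supports) for
# property sweeps
random_shape_pairs <- function(k, seed = 42) {
  set.seed(seed)
  purrr::map(seq_len(k), function(i) {
    conc <- runif(2, 4, 60)
    loc <- runif(1, 0.2, 0.8) + c(0, runif(1, -0.1, 0.1))
    loc <- pmin(pmax(loc, 0.05), 0.95)
    list(p = beta_shape(loc[1] * conc[1], (1 - loc[1]) * conc[1]),
         q = beta_shape(loc[2] * conc[2], (1 - loc[2]) * conc[2]))
  })
}
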