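#' Discretize a Beta density into equal-width bin masses
#'
#' Partitions `[0, 1]` into `bins` equal-width bins and assigns each bin its
#' exact Beta probability mass, `pbeta(right) - pbeta(left)`. CDF increments
#' telescope, so the masses sum to one even when a shape parameter is below 1
#' and the density is unbounded at an endpoint; the endpoints themselves are
#' never evaluated (midpoints lie strictly inside (0, 1)).
#'
#' @param shape A [beta_shape()].
#' @param bins Number of bins, at least 2. Default 2000, the resolution used
#'   throughout the package's criteria and study defaults.
#' @return A `density_grid`: list with `midpoints` (bin centers) and
#'   `probabilities` (bin masses).
#' @examples
#' g <- discretize_beta(beta_shape(1, 1), bins = 4)
#' g$probabilities  # 0.25 0.25 0.25 0.25
#' @export
discretize_beta <- function(shape, bins = 2000) {
  stopifnot(inherits(shape, "beta_shape"),
            length(bins) == 1L, bins >= 2, bins == round(bins))
  bins <- as.integer(bins)
  edges <- seq(0, 1, length.out = bins + 1L)
  probs <- diff(pbeta(edges, shape$alpha, shape$beta))
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  new_density_grid(midpoints = mids, probabilities = probs,
                   log_probabilities = drop(log_mass_matrix(
                     shape$alpha, shape$beta, matrix(probs, ncol = 1L), mids)))
}

# Stable log bin masses. Bins whose CDF increment is representable just take
# log(mass); bins that underflow (the analytic mass is positive but below
# double precision) fall back to the midpoint rule on the log density,
# log f(mid) + log h, which is very accurate in deep tails where the log
# density is nearly linear across a bin. alpha/beta: one entry per column
# of the mass matrix P.
log_mass_matrix <- function(alpha, beta, P, mids) {
  LP <- log(pmax(P, 1e-250))
  tiny <- P < 1e-250
  if (any(tiny)) {
    h <- mids[2L] - mids[1L]
    LD <- outer(log(mids), alpha - 1, `*`) +
      outer(log1p(-mids), beta - 1, `*`) -
      rep(lbeta(alpha, beta), each = length(mids)) + log(h)
    LP[tiny] <- LD[tiny]
  }
  LP
}

new_density_grid <- function(midpoints, probabilities,
                             log_probabilities = NULL) {
  structure(list(midpoints = midpoints, probabilities = probabilities,
                 log_probabilities = log_probabilities),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d equal-width bins on (0, 1); total mass %.15g\n",
              length(x$midpoints), sum(x$probabilities)))
  invisible(x)
}

#' @export
as_tibble.density_grid <- function(x, ...) {
  tibble::tibble(midpoint = x$midpoints, probability = x$probabilities)
}

# masses for all posteriors Beta(alpha + s, beta + n - s), s = 0..n, as a
# bins x (n + 1) matrix (columns indexed by s + 1). Single vectorized pbeta
# call; this is the study's hot path.
posterior_grid_matrix <- function(shape, n, bins) {
  edges <- seq(0, 1, length.out = bins + 1L)
  s <- 0:n
  a <- shape$alpha + s
  b <- shape$beta + n - s
  cdf <- matrix(pbeta(rep(edges, each = n + 1L), a, b),
                nrow = n + 1L, ncol = bins + 1L)
  P <- t(cdf[, -1L, drop = FALSE] - cdf[, -(bins + 1L), drop = FALSE])
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  attr(P, "log") <- log_mass_matrix(a, b, P, mids)
  P
}

# masses for many Beta shapes at once: bins x length(alpha) matrix
shape_grid_matrix <- function(alpha, beta, bins) {
  k <- length(alpha)
  edges <- seq(0, 1, length.out = bins + 1L)
  cdf <- matrix(pbeta(rep(edges, each = k), alpha, beta),
                nrow = k, ncol = bins + 1L)
  P <- t(cdf[, -1L, drop = FALSE] - cdf[, -(bins + 1L), drop = FALSE])
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  attr(P, "log") <- log_mass_matrix(alpha, beta, P, mids)
  P
}
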