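#' Beta shape parameters
#'
#' Constructs a validated pair of Beta shape parameters. The pair can be read
#' either as the usual `(alpha, beta)` shapes or through the
#' location/concentration reparameterization used throughout the package:
#' location `alpha / (alpha + beta)` (where the prior puts its mass) and
#' concentration `alpha + beta` (how precise the belief is).
#'
#' @param alpha,beta Positive Beta shape parameters.
#' @return An object of class `beta_shape`: a named list with elements
#'   `alpha` and `beta`.
#' @examples
#' prior <- beta_shape(2, 3)
#' shape_location(prior)       # 0.4
#' shape_concentration(prior)  # 5
#' @export
beta_shape <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L)
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("`alpha` and `beta` must be finite and > 0", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_shape")
}

#' @export
print.beta_shape <- function(x, ...) {
  cat(sprintf("<beta_shape> Beta(%g, %g)  location %.4g, concentration %g\n",
              x$alpha, x$beta, shape_location(x), shape_concentration(x)))
  invisible(x)
}

#' @rdname beta_shape
#' @param location Prior location in (0, 1).
#' @param concentration Prior concentration (> 0).
#' @export
beta_shape_lc <- function(location, concentration) {
  stopifnot(length(location) == 1L, length(concentration) == 1L)
  if (!is.finite(location) || location <= 0 || location >= 1) {
    stop("`location` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.finite(concentration) || concentration <= 0) {
    stop("`concentration` must be > 0", call. = FALSE)
  }
  beta_shape(location * concentration, concentration - location * concentration)
}

#' @rdname beta_shape
#' @param shape A `beta_shape`.
#' @export
shape_location <- function(shape) shape$alpha / (shape$alpha + shape$beta)

#' @rdname beta_shape
#' @export
shape_concentration <- function(shape) shape$alpha + shape$beta

#' Binomial data as a sufficient statistic
#'
#' A binomial dataset enters every Beta posterior only through the number of
#' trials `n` and successes `s`, so the pair is all the package ever needs.
#'
#' @param n Number of trials (non-negative integer).
#' @param s Number of successes, `0 <= s <= n`.
#' @return An object of class `binomial_sample`.
#' @examples
#' binomial_sample(100, 50)
#' @export
binomial_sample <- function(n, s) {
  stopifnot(length(n) == 1L, length(s) == 1L)
  n <- as.numeric(n); s <- as.numeric(s)
  if (!is.finite(n) || n < 0 || n != round(n)) {
    stop("`n` must be a non-negative integer", call. = FALSE)
  }
  if (!is.finite(s) || s < 0 || s > n || s != round(s)) {
    stop("`s` must be an integer with 0 <= s <= n", call. = FALSE)
  }
  structure(list(n = n, s = s), class = "binomial_sample")
}

#' @export
print.binomial_sample <- function(x, ...) {
  cat(sprintf("<binomial_sample> %g successes out of %g trials\n", x$s, x$n))
  invisible(x)
}

#' Conjugate posterior update
#'
#' For a Beta(`alpha`, `beta`) prior and binomial data `(n, s)` the posterior
#' is Beta(`alpha + s`, `beta + n - s`).
#'
#' @param prior A [beta_shape()].
#' @param data A [binomial_sample()].
#' @return A `beta_shape` holding the posterior.
#' @examples
#' posterior_update(beta_shape(2, 3), binomial_sample(10, 4))  # Beta(6, 9)
#' @export
posterior_update <- function(prior, data) {
  stopifnot(inherits(prior, "beta_shape"), inherits(data, "binomial_sample"))
  beta_shape(prior$alpha + data$s, prior$beta + data$n - data$s)
}

#' Beta-Binomial prior predictive pmf
#'
#' Marginal probability of each success count `s = 0, ..., n` when
#' `theta ~ Beta(alpha, beta)` and `y | theta ~ Binomial(n, theta)`.
#' Computed in log space so large `n` and concentrations do not overflow,
#' then normalized.
#'
#' @param n Number of trials.
#' @param shape A [beta_shape()] for the mixing Beta.
#' @return Numeric vector of `n + 1` probabilities (index `s + 1` is
#'   `P(S = s)`), summing to one.
#' @examples
#' beta_binomial_pmf(10, beta_shape(1, 1))  # discrete uniform on 0..10
#' @export
beta_binomial_pmf <- function(n, shape) {
  stopifnot(inherits(shape, "beta_shape"), length(n) == 1L, n >= 1, n == round(n))
  s <- 0:n
  lp <- lchoose(n, s) + lbeta(shape$alpha + s, shape$beta + n - s) -
    lbeta(shape$alpha, shape$beta)
  m <- max(lp)
  p <- exp(lp - m)
  p / sum(p)
}

#' Closed-form Kullback-Leibler divergence between two Beta distributions
#'
#' The exponential-family identity
#' `KL(p || q) = ln B(a2,b2) - ln B(a1,b1) + (a1-a2) psi(a1) + (b1-b2) psi(b1)
#'  + (a2-a1+b2-b1) psi(a1+b1)` with `psi` the digamma function. Serves as the
#' analytic oracle for the discretized numeric path.
#'
#' @param p,q [beta_shape()] objects; `p` is the reference (first) argument.
#' @return Non-negative divergence in nats; zero iff `p == q`.
#' @examples
#' kl_beta(beta_shape(2, 2), beta_shape(1, 1))  # log(6) - 5/3
#' @export
kl_beta <- function(p, q) {
  stopifnot(inherits(p, "beta_shape"), inherits(q, "beta_shape"))
  a1 <- p$alpha; b1 <- p$beta; a2 <- q$alpha; b2 <- q$beta
  lbeta(a2, b2) - lbeta(a1, b1) +
    (a1 - a2) * digamma(a1) + (b1 - b2) * digamma(b1) +
    (a2 - a1 + b2 - b1) * digamma(a1 + b1)
}

#' Closed-form Renyi divergence between two Beta distributions
#'
#' `D_order(p || q) = (order - 1)^-1 * ln[ B(a3, b3) /
#' (B(a1,b1)^order * B(a2,b2)^(1-order)) ]` with
#' `a3 = order*a1 + (1-order)*a2` (and `b3` analogously). Defined only when
#' `a3 > 0` and `b3 > 0`; converges to [kl_beta()] as `order -> 1`.
#'
#' @inheritParams kl_beta
#' @param order Divergence order, `> 0` and `!= 1`.
#' @return Finite real divergence in nats.
#' @examples
#' renyi_beta(beta_shape(2, 2), beta_shape(1, 1), order = 0.5)
#' @export
renyi_beta <- function(p, q, order) {
  stopifnot(inherits(p, "beta_shape"), inherits(q, "beta_shape"),
            length(order) == 1L, is.finite(order))
  if (order <= 0 || order == 1) {
    stop("`order` must be > 0 and != 1", call. = FALSE)
  }
  a3 <- order * p$alpha + (1 - order) * q$alpha
  b3 <- order * p$beta + (1 - order) * q$beta
  if (a3 <= 0 || b3 <= 0) {
    stop(sprintf(
      "Renyi divergence undefined for these shapes/order (mixed shape %.3g, %.3g)",
      a3, b3), call. = FALSE)
  }
  (lbeta(a3, b3) - order * lbeta(p$alpha, p$beta) -
     (1 - order) * lbeta(q$alpha, q$beta)) / (order - 1)
}

#' Draw reproducible binomial samples
#'
#' Seeded wrapper around [stats::rbinom()] used by the replicate study; the
#' caller's random state is left untouched.
#'
#' @param n Trials per sample.
#' @param theta Success probability in (0, 1).
#' @param count Number of samples to draw.
#' @param seed Integer seed.
#' @return A tibble with columns `n` and `s`, one row per sample.
#' @export
sample_binomial <- function(n, theta, count, seed) {
  stopifnot(count >= 1, theta > 0, theta < 1, n >= 1)
  s <- local_seed_eval(seed, stats::rbinom(count, size = n, prob = theta))
  tibble::tibble(n = rep(as.numeric(n), count), s = as.numeric(s))
}

# run expr under a temporary RNG state; restores (or removes) .Random.seed
local_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-cell child seeds below 2^31, documented in run_replicates()
child_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 + 2654435761 * as.numeric(index)) %%
               2147483647)
}
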