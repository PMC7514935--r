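#' Data Agreement Criterion
#'
#' Ratio of two distances from the benchmark posterior (the posterior obtained
#' by updating a non-informative benchmark prior, by default Beta(1, 1), with
#' the data): the numerator is the distance to the expert prior, the
#' denominator the distance to the benchmark prior itself. A ratio above 1
#' means the oblivious benchmark agrees with the data better than the expert
#' does, and a prior-data conflict is flagged (strictly `dac > threshold`).
#'
#' @param expert Expert prior, a [beta_shape()].
#' @param data A [binomial_sample()] with `n >= 1`.
#' @param measure Distance measure name from [distance_measures()].
#' @param benchmark Benchmark prior (default Beta(1, 1)).
#' @param bins Discretization resolution (default 2000).
#' @param order Renyi order, used only for `measure = "renyi"`.
#' @param threshold Conflict threshold on the ratio (default 1).
#' @return A `dac_result`; see [dac_result()].
#' @examples
#' dac(beta_shape(20, 80), binomial_sample(100, 50))
#' @export
dac <- function(expert, data, measure = "kullback_leibler",
                benchmark = beta_shape(1, 1), bins = 2000, order = 0.5,
                threshold = 1) {
  stopifnot(inherits(expert, "beta_shape"), inherits(data, "binomial_sample"),
            inherits(benchmark, "beta_shape"))
  if (data$n < 1) {
    stop("degenerate benchmark: with n = 0 the benchmark posterior equals the benchmark prior",
         call. = FALSE)
  }
  post <- discretize_beta(posterior_update(benchmark, data), bins)
  num <- prob_distance(post, discretize_beta(expert, bins), measure, order)
  den <- prob_distance(post, discretize_beta(benchmark, bins), measure, order)
  dac_result(num, den, measure = measure, threshold = threshold)
}

#' Construct a DAC result
#'
#' Packages the two distances of the Data Agreement Criterion into a result
#' object, computing the ratio and the strict conflict flag. Exposed so the
#' flag arithmetic can be applied to distances obtained elsewhere.
#'
#' @param numerator Distance from the benchmark posterior to the expert prior.
#' @param denominator Distance from the benchmark posterior to the benchmark
#'   prior; must exceed `1e-12` (data that do not move the benchmark give no
#'   usable reference scale).
#' @param measure,threshold Metadata stored on the result.
#' @return A list of class `dac_result` with elements `numerator`,
#'   `denominator`, `dac`, `conflict`, `measure`, `threshold`.
#' @examples
#' dac_result(0.89, 1.26)  # ratio 0.706, no conflict
#' @export
dac_result <- function(numerator, denominator, measure = NA_character_,
                       threshold = 1) {
  if (!is.finite(denominator) || denominator < 1e-12) {
    stop("degenerate benchmark: denominator distance below tolerance",
         call. = FALSE)
  }
  ratio <- numerator / denominator
  structure(list(numerator = numerator, denominator = denominator,
                 dac = ratio, conflict = ratio > threshold,
                 measure = measure, threshold = threshold),
            class = "dac_result")
}

#' @export
print.dac_result <- function(x, ...) {
  cat(sprintf("<dac_result> %s\n", if (is.na(x$measure)) "" else x$measure))
  cat(sprintf("  numerator   %.6g\n  denominator %.6g\n  dac         %.6g\n",
              x$numerator, x$denominator, x$dac))
  cat(sprintf("  verdict: %s (threshold %g)\n",
              if (x$conflict) "prior-data conflict" else "no prior-data conflict",
              x$threshold))
  invisible(x)
}

#' Prior-to-posterior discrepancy for the surprise criterion
#'
#' The distance from the expert's posterior to the expert's own prior -- the
#' discrepancy whose prior-predictive tail probability defines the Nott-style
#' conflict check. Depends on the data only through the sufficient statistic.
#'
#' @inheritParams dac
#' @return A single non-negative number (0 when `n = 0`).
#' @export
nott_discrepancy <- function(expert, data, measure = "kullback_leibler",
                             bins = 2000, order = 0.5) {
  stopifnot(inherits(expert, "beta_shape"), inherits(data, "binomial_sample"))
  if (data$n == 0) return(0)
  prob_distance(discretize_beta(posterior_update(expert, data), bins),
                discretize_beta(expert, bins), measure, order)
}

#' Prior-predictive surprise p-value
#'
#' Computes `p = P(D(Y) >= D(y_obs))` where `D` is the prior-to-posterior
#' discrepancy ([nott_discrepancy()]) and `Y` is drawn from the expert's
#' Beta-Binomial prior predictive. Because the discrepancy depends on the data
#' only through the success count, the default backend enumerates all `n + 1`
#' outcomes exactly; the Monte Carlo backend draws from the prior predictive
#' and caches the discrepancy per distinct outcome. Ties count toward the
#' p-value (inclusive `>=`), which makes the discrete p conservative and
#' `p = 1` attainable. Conflict is flagged when `p <= threshold`.
#'
#' @inheritParams dac
#' @param n Number of trials.
#' @param s_obs Observed success count, `0 <= s_obs <= n`.
#' @param method `"exact"` (enumeration, default) or `"mc"`.
#' @param draws Monte Carlo draws (only for `method = "mc"`).
#' @param seed Seed for the Monte Carlo backend.
#' @param threshold Conflict threshold on the p-value (default 0.05).
#' @return A list of class `nott_result` with the observed discrepancy, the
#'   p-value, the backend used, the number of draws (0 for exact) and the
#'   conflict flag.
#' @examples
#' nott_p(beta_shape(2, 2), n = 10, s_obs = 10)
#' @export
nott_p <- function(expert, n, s_obs, measure = "kullback_leibler",
                   bins = 2000, order = 0.5, method = c("exact", "mc"),
                   draws = 1e5, seed = 1L, threshold = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(expert, "beta_shape"), s_obs >= 0, s_obs <= n)
  if (n == 0) {
    return(new_nott_result(0, 1, "exact", 0L, threshold))
  }
  if (method == "exact") {
    Dmap <- nott_discrepancy_map(expert, n, measure, bins, order)
    pmf <- beta_binomial_pmf(n, expert)
    d_obs <- Dmap[s_obs + 1L]
    p <- sum(pmf[Dmap >= d_obs])
    new_nott_result(d_obs, p, "exact", 0L, threshold)
  } else {
    if (draws < 1) stop("`draws` must be >= 1", call. = FALSE)
    pmf <- beta_binomial_pmf(n, expert)
    ys <- local_seed_eval(seed, sample.int(n + 1L, draws, replace = TRUE,
                                           prob = pmf) - 1L)
    need <- sort(unique(c(ys, s_obs)))
    # discrepancy evaluated once per distinct outcome, not per draw
    Dsub <- nott_discrepancy_map(expert, n, measure, bins, order,
                                 s_values = need)
    lookup <- stats::setNames(Dsub, need)
    d_obs <- lookup[[as.character(s_obs)]]
    p <- mean(lookup[as.character(ys)] >= d_obs)
    new_nott_result(d_obs, p, "monte_carlo", as.integer(draws), threshold)
  }
}

# D(s) for s in s_values (default all 0..n): distance from the expert
# posterior at outcome s to the expert prior, vectorized over s
nott_discrepancy_map <- function(expert, n, measure, bins, order = 0.5,
                                 s_values = 0:n) {
  eg <- discretize_beta(expert, bins)
  P <- shape_grid_matrix(expert$alpha + s_values, expert$beta + n - s_values,
                         bins)
  drop(dist_block(P, eg$probabilities, measure, order = order,
                  rows_first = TRUE, lq = eg$log_probabilities))
}

new_nott_result <- function(d_obs, p, method, draws, threshold) {
  structure(list(observed_discrepancy = d_obs, p_value = p, method = method,
                 draws = draws, conflict = p <= threshold,
                 threshold = threshold),
            class = "nott_result")
}

#' @export
print.nott_result <- function(x, ...) {
  cat("<nott_result>\n")
  cat(sprintf("  observed discrepancy %.6g\n  p-value              %.6g  (%s%s)\n",
              x$observed_discrepancy, x$p_value, x$method,
              if (x$draws > 0) sprintf(", %d draws", x$draws) else ""))
  cat(sprintf("  verdict: %s (p <= %g flags conflict)\n",
              if (x$conflict) "prior-data conflict" else "no prior-data conflict",
              x$threshold))
  invisible(x)
}

#' Run both conflict criteria over a table of cases
#'
#' Data-frame-first driver: one row per case with columns `alpha`, `beta`
#' (expert prior), `n`, `s` (data) and optionally `measure` (default
#' Kullback-Leibler). Appends the DAC ratio, the exact surprise p-value and
#' both conflict flags.
#'
#' @param cases A data frame with columns `alpha`, `beta`, `n`, `s` and
#'   optionally `measure`.
#' @inheritParams dac
#' @param p_threshold Conflict threshold for the p-value.
#' @return The input as a tibble with columns `dac`, `dac_conflict`,
#'   `nott_p`, `nott_conflict` appended.
#' @examples
#' tibble::tibble(alpha = c(2, 20), beta = c(2, 80), n = 100, s = 50) |>
#'   conflict_check()
#' @export
conflict_check <- function(cases, measure = "kullback_leibler",
                           benchmark = beta_shape(1, 1), bins = 2000,
                           threshold = 1, p_threshold = 0.05) {
  stopifnot(is.data.frame(cases),
            all(c("alpha", "beta", "n", "s") %in% names(cases)))
  cases <- tibble::as_tibble(cases)
  if (!"measure" %in% names(cases)) cases$measure <- measure
  res <- purrr::pmap(cases[c("alpha", "beta", "n", "s", "measure")],
    function(alpha, beta, n, s, measure) {
      expert <- beta_shape(alpha, beta)
      d <- dac(expert, binomial_sample(n, s), measure, benchmark, bins,
               threshold = threshold)
      np <- nott_p(expert, n, s, measure, bins, threshold = p_threshold)
      tibble::tibble(dac = d$dac, dac_conflict = d$conflict,
                     nott_p = np$p_value, nott_conflict = np$conflict)
    })
  dplyr::bind_cols(cases, dplyr::bind_rows(res))
}
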