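#' Registry of distance measures
#'
#' The twelve measures compared in the simulation study, in the study's
#' canonical order (total variation first, then Hellinger, Kolmogorov,
#' Euclidean, Manhattan, Sorensen, intersection, harmonic mean, Bhattacharyya,
#' divergence, Jeffreys, Jensen-Shannon), followed by the Kullback-Leibler
#' divergence and the Renyi family. Intersection and harmonic mean are
#' similarities in their native form and are registered as `1 - similarity`
#' so that larger always means more conflict.
#'
#' @param study_only If `TRUE`, return only the twelve study measures.
#' @return A tibble with columns `name`, `symmetric`,
#'   `derived_from_similarity` and `order` (`NA` except for `renyi`).
#' @examples
#' distance_measures(study_only = TRUE)$name
#' @export
distance_measures <- function(study_only = FALSE) {
  reg <- tibble::tibble(
    name = c("total_variation", "hellinger", "kolmogorov", "euclidean",
             "manhattan", "sorensen", "intersection", "harmonic_mean",
             "bhattacharyya", "divergence", "jeffreys", "jensen_shannon",
             "kullback_leibler", "renyi"),
    symmetric = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    derived_from_similarity = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                                FALSE, FALSE),
    order = c(rep(NA_real_, 13L), 0.5)
  )
  if (study_only) reg[seq_len(12L), ] else reg
}

study_measure_names <- function() distance_measures(study_only = TRUE)$name

# floor used under logarithms and ratio denominators; Beta bin masses are
# analytically positive, only floating-point underflow produces zeros here
.eps <- 1e-300

#' Distance between two discretized densities
#'
#' Evaluates any registry measure on a pair of densities sharing one binning.
#' All measures operate on the bin-probability vectors with natural
#' logarithms; for the asymmetric measures (`kullback_leibler`, `renyi`) the
#' first argument is the reference distribution (in the criteria: the
#' posterior). Bins where both masses underflow to zero contribute nothing;
#' a single-sided zero under a logarithm or in a ratio denominator is floored
#' at `1e-300`.
#'
#' An alternative `mode = "density"` evaluates the same formulas on
#' approximate density values (mass / bin width) instead of the normalized
#' masses. The two conventions agree up to scale for the homogeneous measures
#' but genuinely differ for the dimensionful ones (Euclidean, Manhattan,
#' divergence); the mode exists so both conventions can be compared, and the
#' study uses `"probability"` throughout.
#'
#' @param p,q [discretize_beta()] grids (or bare probability vectors of equal
#'   length) on identical binnings; `p` is the reference for asymmetric
#'   measures.
#' @param measure A registry name from [distance_measures()].
#' @param order Renyi order (used only for `measure = "renyi"`).
#' @param mode `"probability"` (default) or `"density"`.
#' @return A single non-negative number; zero when `p == q`.
#' @examples
#' p <- discretize_beta(beta_shape(2, 2))
#' q <- discretize_beta(beta_shape(1, 1))
#' prob_distance(p, q, "total_variation")  # about sqrt(3)/9
#' @export
prob_distance <- function(p, q, measure, order = 0.5,
                          mode = c("probability", "density")) {
  mode <- match.arg(mode)
  measure <- match.arg(measure, distance_measures()$name)
  pv <- grid_probs(p); qv <- grid_probs(q)
  if (length(pv) != length(qv) ||
      (inherits(p, "density_grid") && inherits(q, "density_grid") &&
       !isTRUE(all.equal(p$midpoints, q$midpoints, tolerance = 0)))) {
    stop("grid mismatch: `p` and `q` must share identical binnings",
         call. = FALSE)
  }
  lpv <- if (inherits(p, "density_grid")) p$log_probabilities
  lqv <- if (inherits(q, "density_grid")) q$log_probabilities
  if (mode == "density") {
    b <- length(pv)
    pv <- pv * b
    qv <- qv * b
    if (!is.null(lpv)) lpv <- lpv + log(b)
    if (!is.null(lqv)) lqv <- lqv + log(b)
  }
  out <- unname(drop(dist_block(matrix(pv, ncol = 1L), qv, measure,
                                order = order, rows_first = TRUE,
                                LP = if (!is.null(lpv)) matrix(lpv, ncol = 1L),
                                lq = lqv)))
  if (!is.finite(out)) {
    bad <- which(!is.finite(log(pmax(pv, .eps)) - log(pmax(qv, .eps))) |
                   (pv == 0 & qv == 0))
    stop(sprintf("non-finite %s distance (offending bins: %s)", measure,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

grid_probs <- function(x) {
  if (inherits(x, "density_grid")) x$probabilities
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a density_grid or a numeric probability vector",
            call. = FALSE)
}

# Vectorized distance kernel. P: bins x k matrix of densities (one per
# column), q: single density vector on the same bins. Computes the requested
# measures between every column of P and q. `rows_first = TRUE` means the
# columns of P are the first (reference) argument of asymmetric measures;
# FALSE means q is. LP/lq are stable log masses (see log_mass_matrix());
# when absent, logs are floored at 1e-300. Returns a k x length(measures)
# matrix.
dist_block <- function(P, q, measures, order = 0.5, rows_first = TRUE,
                       LP = attr(P, "log"), lq = NULL) {
  k <- ncol(P)
  if (is.null(LP)) LP <- log(pmax(P, .eps))
  if (is.null(lq)) lq <- log(pmax(q, .eps))
  out <- matrix(NA_real_, nrow = k, ncol = length(measures),
                dimnames = list(NULL, measures))
  D <- P - q
  A <- abs(D)
  colA <- .colSums(A, nrow(A), k)
  need <- function(...) any(measures %in% c(...))

  if (need("total_variation")) out[, colnames(out) == "total_variation"] <- colA / 2
  if (need("manhattan")) out[, colnames(out) == "manhattan"] <- colA
  if (need("sorensen")) {
    out[, colnames(out) == "sorensen"] <- colA / .colSums(P + q, nrow(P), k)
  }
  if (need("euclidean")) {
    out[, colnames(out) == "euclidean"] <- sqrt(.colSums(D * D, nrow(D), k))
  }
  if (need("kolmogorov")) {
    cs <- apply(D, 2L, function(col) max(abs(cumsum(col))))
    out[, colnames(out) == "kolmogorov"] <- cs
  }
  if (need("hellinger", "bhattacharyya")) {
    # geometric-mean sum through the stable logs so deep-tail bins whose
    # linear mass underflows still contribute their analytic share;
    # sum (sqrt p - sqrt q)^2 expands to sum p + sum q - 2 bc
    bc <- .colSums(exp(0.5 * (LP + lq)), nrow(P), k)
    if (need("hellinger")) {
      h2 <- .colSums(P, nrow(P), k) + sum(q) - 2 * bc
      out[, colnames(out) == "hellinger"] <- sqrt(2 * pmax(h2, 0))
    }
    if (need("bhattacharyya")) {
      out[, colnames(out) == "bhattacharyya"] <- -log(bc)
    }
  }
  if (need("intersection")) {
    out[, colnames(out) == "intersection"] <- 1 - .colSums(pmin(P, q), nrow(P), k)
  }
  if (need("harmonic_mean", "divergence", "jensen_shannon")) {
    S <- pmax(P + q, .eps)
    if (need("harmonic_mean")) {
      out[, colnames(out) == "harmonic_mean"] <- 1 - 2 * .colSums(P * q / S, nrow(P), k)
    }
    if (need("divergence")) {
      R <- D / S  # divide before squaring: S^2 can underflow, |D/S| <= 1
      out[, colnames(out) == "divergence"] <- 2 * .colSums(R * R, nrow(P), k)
    }
    if (need("jensen_shannon")) {
      lM <- log(pmax(S, .eps) / 2)
      out[, colnames(out) == "jensen_shannon"] <-
        0.5 * .colSums(P * (LP - lM), nrow(P), k) +
        0.5 * .colSums(q * (lq - lM), nrow(P), k)
    }
  }
  if (need("kullback_leibler", "jeffreys", "renyi")) {
    LR <- LP - lq
    if (need("jeffreys")) {
      out[, colnames(out) == "jeffreys"] <- .colSums(D * LR, nrow(D), k)
    }
    if (need("kullback_leibler")) {
      kl <- if (rows_first) .colSums(P * LR, nrow(P), k)
            else .colSums(q * -LR, nrow(P), k)
      out[, colnames(out) == "kullback_leibler"] <- kl
    }
    if (need("renyi")) {
      integ <- if (rows_first) exp(order * LP + (1 - order) * lq)
               else exp(order * lq + (1 - order) * LP)
      out[, colnames(out) == "renyi"] <- log(.colSums(integ, nrow(P), k)) / (order - 1)
    }
  }
  # distances are non-negative analytically; clamp the rounding dust at zero
  sym <- measures != "renyi"
  out[, sym] <- pmax(out[, sym, drop = FALSE], 0)
  out
}
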