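#' Simulation-study configuration
#'
#' Collects every knob of the simulation study with the study's canonical
#' defaults: a population success probability of 0.5; sample sizes 50, 100 and
#' 200; an expert-prior grid crossing locations 0.05, 0.07, ..., 0.95 with
#' concentrations 10, 12, ..., 200 (46 x 96 cells); replicate sweeps restricted
#' to locations 0.2-0.5 and concentrations 50/100/200 with 1000 replicate
#' samples per cell; all twelve registry measures; a Beta(1, 1) benchmark.
#'
#' @param theta_true Population success probability.
#' @param n_values Sample sizes under study.
#' @param locations,concentrations Expert-prior grid axes (location strictly
#'   inside (0, 1), concentration positive). The expert shape in a cell is
#'   `alpha = location * concentration`, `beta = concentration - alpha`.
#' @param replicate_locations,replicate_concentrations Cells of the
#'   replicate-sampling sweep.
#' @param replicates Replicate samples per cell.
#' @param measures Distance measure names (default the twelve study measures).
#' @param bins Discretization resolution (default 2000, matching
#'   [discretize_beta()]).
#' @param seed Master seed; per-cell child seeds are derived from it.
#' @param dac_threshold,p_threshold Conflict thresholds.
#' @param fixed_sample_s Named list/vector mapping `n` to the success count of
#'   the fixed sample used by [run_fixed_sample_grid()]; defaults to
#'   `s = n / 2`, the modal outcome at `theta_true = 0.5`.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(theta_true = 0.5,
                         n_values = c(50, 100, 200),
                         locations = seq(0.05, 0.95, by = 0.02),
                         concentrations = seq(10, 200, by = 2),
                         replicate_locations = c(0.2, 0.3, 0.4, 0.5),
                         replicate_concentrations = c(50, 100, 200),
                         replicates = 1000,
                         measures = study_measure_names(),
                         bins = 2000,
                         seed = 1L,
                         dac_threshold = 1,
                         p_threshold = 0.05,
                         fixed_sample_s = NULL) {
  stopifnot(theta_true > 0, theta_true < 1,
            all(locations > 0), all(locations < 1),
            all(concentrations > 0),
            all(replicate_locations > 0), all(replicate_locations < 1),
            all(replicate_concentrations > 0),
            replicates >= 1, bins >= 2,
            all(n_values >= 1), all(n_values == round(n_values)))
  bad <- setdiff(measures, distance_measures()$name)
  if (length(bad) > 0) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(fixed_sample_s)) {
    fixed_sample_s <- stats::setNames(as.list(round(n_values / 2)),
                                      as.character(n_values))
  }
  structure(list(theta_true = theta_true, n_values = n_values,
                 locations = locations, concentrations = concentrations,
                 replicate_locations = replicate_locations,
                 replicate_concentrations = replicate_concentrations,
                 replicates = replicates, measures = measures, bins = bins,
                 seed = as.integer(seed), dac_threshold = dac_threshold,
                 p_threshold = p_threshold,
                 fixed_sample_s = fixed_sample_s),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<study_config> theta %g; n {%s}; %d x %d prior grid; %d replicate cells",
    " x %d reps; %d measures; %d bins; seed %d\n"),
    x$theta_true, paste(x$n_values, collapse = ", "),
    length(x$locations), length(x$concentrations),
    length(x$replicate_locations) * length(x$replicate_concentrations),
    x$replicates, length(x$measures), x$bins, x$seed))
  invisible(x)
}

#' Evaluate both criteria on the full prior grid for one fixed sample
#'
#' For a single dataset (by default `s = n / 2` successes out of `n`), sweeps
#' every combination of expert-prior location and concentration in the
#' configuration and records, for every distance measure, the DAC ratio and
#' the exact prior-predictive surprise p-value together with their conflict
#' flags. These are the decision grids whose `dac = 1` and `p = 0.05` level
#' sets separate conflict from no-conflict regions.
#'
#' The implementation exploits sufficiency and vectorization: one CDF sweep
#' yields all `n + 1` expert posteriors of a cell at once, and all measures
#' are evaluated in one pass per cell.
#'
#' @param config A [study_config()].
#' @param n Sample size, one of `config$n_values`.
#' @return A tibble of class `bbc_grid` in long format with columns
#'   `n, cell_s, location, concentration, measure, criterion, statistic,
#'   conflict` (criterion `"dac"` carries the ratio, `"nott"` the p-value).
#' @export
run_fixed_sample_grid <- function(config, n) {
  stopifnot(inherits(config, "study_config"), n %in% config$n_values)
  s_obs <- as.numeric(config$fixed_sample_s[[as.character(n)]])
  data <- binomial_sample(n, s_obs)
  bins <- config$bins
  measures <- config$measures
  cells <- tidyr::expand_grid(location = config$locations,
                              concentration = config$concentrations)
  alpha <- cells$location * cells$concentration
  beta <- cells$concentration - alpha

  # --- DAC: one benchmark posterior against every expert prior -------------
  bench <- beta_shape(1, 1)
  postg <- discretize_beta(posterior_update(bench, data), bins)
  benchg <- discretize_beta(bench, bins)
  den <- drop(dist_block(matrix(benchg$probabilities, ncol = 1L),
                         postg$probabilities, measures, rows_first = FALSE,
                         LP = matrix(benchg$log_probabilities, ncol = 1L),
                         lq = postg$log_probabilities))
  ncell <- nrow(cells)
  dac_stat <- matrix(NA_real_, ncell, length(measures))
  for (idx in split(seq_len(ncell), ceiling(seq_len(ncell) / 512))) {
    Q <- shape_grid_matrix(alpha[idx], beta[idx], bins)
    num <- dist_block(Q, postg$probabilities, measures, rows_first = FALSE,
                      lq = postg$log_probabilities)
    dac_stat[idx, ] <- sweep(num, 2L, den, `/`)
  }

  # --- Nott: exact enumeration per cell ------------------------------------
  nott_stat <- matrix(NA_real_, ncell, length(measures))
  for (i in seq_len(ncell)) {
    expert <- beta_shape(alpha[i], beta[i])
    eg <- discretize_beta(expert, bins)
    P <- posterior_grid_matrix(expert, n, bins)
    D <- dist_block(P, eg$probabilities, measures, rows_first = TRUE,
                    lq = eg$log_probabilities)
    pmf <- beta_binomial_pmf(n, expert)
    ge <- D >= matrix(D[s_obs + 1L, ], nrow(D), ncol(D), byrow = TRUE)
    nott_stat[i, ] <- colSums(pmf * ge)
  }

  long <- function(stat, criterion, conflict) {
    tidyr::expand_grid(cells, measure = measures) |>
      dplyr::mutate(n = n, cell_s = s_obs, criterion = criterion,
                    statistic = as.vector(t(stat)),
                    conflict = as.vector(t(conflict))) |>
      dplyr::select("n", "cell_s", "location", "concentration", "measure",
                    "criterion", "statistic", "conflict")
  }
  out <- dplyr::bind_rows(
    long(dac_stat, "dac", dac_stat > config$dac_threshold),
    long(nott_stat, "nott", nott_stat <= config$p_threshold)
  )
  class(out) <- c("bbc_grid", class(out))
  attr(out, "config") <- config
  out
}

#' Replicate-sampling conflict rates
#'
#' For every combination of sample size, replicate location and replicate
#' concentration, draws `config$replicates` binomial samples from the
#' population (`theta_true`), applies both criteria with every measure to each
#' sample, and reports per-cell conflict counts -- the data behind
#' stacked-histogram summaries of how often each measure flags conflict.
#'
#' Both criteria depend on a sample only through its success count, so each
#' cell computes every criterion once per distinct count and weights by the
#' empirical frequency: at most `n + 1` criterion evaluations per cell per
#' measure regardless of the number of replicates. Child seeds are derived
#' from the master seed as
#' `(seed + 2654435761 * cell_index) mod 2147483647`, with `cell_index` the
#' row number in the expanded (n x location x concentration) design, so any
#' subset of cells reproduces in isolation.
#'
#' @param config A [study_config()].
#' @return A tibble of class `bbc_replicates` with columns
#'   `n, location, concentration, measure, criterion, conflicts, replicates,
#'   no_conflict_rate`, plus an attribute `cell_summary`: the per-cell mean
#'   no-conflict rate across measures (see [replicate_cell_summary()]).
#' @export
run_replicates <- function(config) {
  stopifnot(inherits(config, "study_config"))
  bins <- config$bins
  measures <- config$measures
  design <- tidyr::expand_grid(n = config$n_values,
                               location = config$replicate_locations,
                               concentration = config$replicate_concentrations)
  bench <- beta_shape(1, 1)

  # benchmark posteriors and DAC denominators depend only on n: cache them
  bench_cache <- new.env(parent = emptyenv())
  bench_for <- function(n) {
    key <- as.character(n)
    if (is.null(bench_cache[[key]])) {
      Pb <- posterior_grid_matrix(bench, n, bins)
      bg <- discretize_beta(bench, bins)
      den <- dist_block(Pb, bg$probabilities, measures, rows_first = TRUE,
                        lq = bg$log_probabilities)  # (n+1) x m
      bench_cache[[key]] <- list(Pb = Pb, den = den)
    }
    bench_cache[[key]]
  }

  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    n <- design$n[i]
    expert <- beta_shape_lc(design$location[i], design$concentration[i])
    counts <- tabulate(
      local_seed_eval(child_seed(config$seed, i),
                      stats::rbinom(config$replicates, n, config$theta_true)) + 1L,
      nbins = n + 1L)

    eg <- discretize_beta(expert, bins)
    bc <- bench_for(n)

    # DAC per distinct outcome: benchmark posterior rows vs expert prior
    num <- dist_block(bc$Pb, eg$probabilities, measures, rows_first = TRUE,
                      lq = eg$log_probabilities)
    dac_mat <- num / bc$den
    dac_confl <- dac_mat > config$dac_threshold

    # Nott exact p per distinct outcome
    P <- posterior_grid_matrix(expert, n, bins)
    D <- dist_block(P, eg$probabilities, measures, rows_first = TRUE,
                    lq = eg$log_probabilities)
    pmf <- beta_binomial_pmf(n, expert)
    p_mat <- apply(D, 2L, function(d) {
      vapply(d, function(d0) sum(pmf[d >= d0]), numeric(1))
    })
    nott_confl <- p_mat <= config$p_threshold

    tibble::tibble(
      n = n, location = design$location[i],
      concentration = design$concentration[i],
      measure = rep(measures, 2L),
      criterion = rep(c("dac", "nott"), each = length(measures)),
      conflicts = unname(c(colSums(counts * dac_confl),
                           colSums(counts * nott_confl))),
      replicates = config$replicates
    )
  })

  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(no_conflict_rate = 1 - .data$conflicts / .data$replicates)
  class(out) <- c("bbc_replicates", class(out))
  attr(out, "config") <- config
  attr(out, "cell_summary") <- replicate_cell_summary(out)
  out
}

#' Per-cell mean no-conflict rate
#'
#' Averages the no-conflict rate over measures within each
#' (n, location, concentration, criterion) cell -- the per-cell summary
#' percentage printed alongside each stacked histogram of a replicate study.
#'
#' @param result A `bbc_replicates` tibble from [run_replicates()].
#' @return Tibble with one row per cell and criterion.
#' @export
replicate_cell_summary <- function(result) {
  result |>
    dplyr::group_by(.data$n, .data$location, .data$concentration,
                    .data$criterion) |>
    dplyr::summarise(mean_no_conflict_rate = mean(.data$no_conflict_rate),
                     .groups = "drop")
}

#' Rank measures by lenience on a decision grid
#'
#' Counts, per measure, the prior-grid cells flagged as *no* conflict by the
#' given criterion and sorts descending: the first measure is the most
#' lenient (largest no-conflict area), the last the most stringent. Ties are
#' broken alphabetically.
#'
#' @param result A `bbc_grid` from [run_fixed_sample_grid()].
#' @param criterion `"dac"` or `"nott"`.
#' @return Tibble with columns `measure` and `no_conflict_cells`.
#' @export
lenience_ranking <- function(result, criterion = c("dac", "nott")) {
  criterion <- match.arg(criterion)
  if (nrow(result) == 0) stop("empty study result", call. = FALSE)
  result |>
    dplyr::filter(.data$criterion == !!criterion) |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(no_conflict_cells = sum(!.data$conflict),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$no_conflict_cells), .data$measure)
}

#' Consensus partition of a decision grid
#'
#' Labels every prior-grid cell by whether all measures agree on conflict
#' (`all_conflict`), all agree on no conflict (`none_conflict`), or disagree
#' (`disagreement`). The disagreement count is the scalar summary of how
#' sensitive a criterion is to the choice of distance measure.
#'
#' @inheritParams lenience_ranking
#' @return Tibble with columns `location`, `concentration`, `label`.
#' @export
consensus_partition <- function(result, criterion = c("dac", "nott")) {
  criterion <- match.arg(criterion)
  result |>
    dplyr::filter(.data$criterion == !!criterion) |>
    dplyr::group_by(.data$location, .data$concentration) |>
    dplyr::summarise(label = if (all(.data$conflict)) "all_conflict"
                     else if (!any(.data$conflict)) "none_conflict"
                     else "disagreement",
                     .groups = "drop")
}
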