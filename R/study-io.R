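#' Write and read study results as CSV
#'
#' Study results are serialized as RFC-4180 CSV (header row, UTF-8, '.'
#' decimal) with the fixed header
#' `n,cell_s,location,concentration,measure,criterion,statistic,conflict`.
#' Numeric fields are written with 17 significant digits so a read-back
#' reconstructs the doubles exactly. Replicate summaries reuse the header
#' with `cell_s = NA`, `statistic` carrying the conflict count and
#' `conflict = NA` (the flag applies per sample, not per summary row).
#'
#' @param result A `bbc_grid` or `bbc_replicates` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(result, path) {
  df <- as_study_records(result)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

as_study_records <- function(result) {
  if (inherits(result, "bbc_replicates")) {
    tibble::tibble(n = result$n, cell_s = NA_real_,
                   location = result$location,
                   concentration = result$concentration,
                   measure = result$measure, criterion = result$criterion,
                   statistic = result$conflicts, conflict = NA)
  } else {
    tibble::as_tibble(result)[, c("n", "cell_s", "location", "concentration",
                                  "measure", "criterion", "statistic",
                                  "conflict")]
  }
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  # base strtod parsing: correctly-rounded doubles, so 17-digit fields
  # round-trip bit-for-bit
  df <- utils::read.csv(path, colClasses = c(
    n = "numeric", cell_s = "numeric", location = "numeric",
    concentration = "numeric", measure = "character",
    criterion = "character", statistic = "numeric", conflict = "logical"))
  tibble::as_tibble(df)
}

#' Summaries and manifest for a study run
#'
#' `study_summary()` condenses grid and replicate results into the quantities
#' a report needs: lenience rankings, consensus-partition counts per
#' criterion, and per-cell replicate conflict rates.
#' `run_manifest()` records tool version, the fully materialized
#' configuration, the master seed, a timestamp and the emitted files, so a
#' run can be reproduced byte-for-byte (modulo the timestamp).
#'
#' @param grids List of `bbc_grid` results (possibly empty).
#' @param reps A `bbc_replicates` result or `NULL`.
#' @return `study_summary()`: a nested list ready for JSON serialization.
#' @export
study_summary <- function(grids = list(), reps = NULL) {
  out <- list()
  if (length(grids) > 0) {
    out$lenience <- purrr::map(grids, function(g) list(
      n = g$n[1],
      dac = lenience_ranking(g, "dac"),
      nott = lenience_ranking(g, "nott")
    ))
    out$consensus <- purrr::map(grids, function(g) list(
      n = g$n[1],
      dac = as.list(table(consensus_partition(g, "dac")$label)),
      nott = as.list(table(consensus_partition(g, "nott")$label))
    ))
  }
  if (!is.null(reps)) {
    out$replicate_rates <- reps
    out$replicate_cell_means <- replicate_cell_summary(reps)
  }
  out
}

#' @rdname study_summary
#' @param config The `study_config` used.
#' @param files Character vector of emitted result files.
#' @param path If non-`NULL`, the manifest is also written there as JSON.
#' @return `run_manifest()`: the manifest list.
#' @export
run_manifest <- function(config, files, path = NULL) {
  man <- list(
    tool = "bbconflict",
    version = as.character(utils::packageVersion("bbconflict")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    files = files
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(man)
}

#' Load a study configuration from YAML
#'
#' Missing keys fall back to the [study_config()] defaults; unknown keys are
#' fatal (no silent defaults for misspellings).
#'
#' @param path YAML file whose keys are `study_config()` argument names. An
#'   empty or absent file yields the full default configuration.
#' @return A `study_config`.
#' @export
read_study_config <- function(path = NULL) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(vals$fixed_sample_s)) {
    vals$fixed_sample_s <- as.list(vals$fixed_sample_s)
  }
  do.call(study_config, vals)
}
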