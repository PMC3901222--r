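#' Pipeline configuration
#'
#' Exactly one input source: a per-rat cohort (tibble or CSV path) or a
#' group-summary table used either to simulate a cohort or to build profiles
#' directly from the printed medians (`summary_mode = "median"`).
#'
#' @param cohort A cohort tibble or CSV path (exclusive with `summary`).
#' @param summary A group-summary tibble (exclusive with `cohort`).
#' @param summary_mode With a summary input: `"median"` builds profiles
#'   directly from printed medians; `"simulate"` draws a synthetic cohort
#'   first.
#' @param max_missing_frac Rat-removal threshold (default 0.30).
#' @param cluster A [cluster_config()].
#' @param svd_tol,svd_energy_floor Passed to [svd_patterns()].
#' @param models Named list of [regressor_spec()]s for the selection stage
#'   (ignored in median mode, which has no per-rat data).
#' @param budget `"auto"` (number of independent patterns) or a fixed
#'   integer.
#' @param statistic Group statistic for profiles (`"mean"` or `"median"`).
#' @param seed Master seed; every stage seed is derived from it by stable
#'   hashing of the stage name.
#' @return A list of class `burndex_config`.
#' @export
pipeline_config <- function(cohort = NULL, summary = NULL,
                            summary_mode = c("median", "simulate"),
                            max_missing_frac = 0.30,
                            cluster = cluster_config(),
                            svd_tol = 1e-2, svd_energy_floor = 0.02,
                            models = list(linear = regressor_spec("linear"),
                                          mlp = regressor_spec("mlp")),
                            budget = "auto",
                            statistic = c("mean", "median"),
                            seed = 1L) {
  if (is.null(cohort) == is.null(summary)) {
    abort("provide exactly one input source: cohort or summary")
  }
  structure(list(cohort = cohort, summary = summary,
                 summary_mode = match.arg(summary_mode),
                 max_missing_frac = max_missing_frac, cluster = cluster,
                 svd_tol = svd_tol, svd_energy_floor = svd_energy_floor,
                 models = models, budget = budget,
                 statistic = match.arg(statistic), seed = as.integer(seed)),
            class = "burndex_config")
}

#' Run the full indicator-identification pipeline
#'
#' Executes mask -> filter -> impute -> profiles -> k scan/choice ->
#' clustering -> SVD pattern count (variable budget) -> wrapper selection and
#' model comparison -> index training, and returns a manifest of every stage
#' output with the seeds used. With a summary input in median mode the
#' per-rat stages are skipped and the manifest stops after the pattern
#' analysis (plus the budget), since no rat-level data exist to regress on.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `burndex_manifest`.
#' @export
#' @examples
#' cfg <- pipeline_config(summary = burndex_summary(), summary_mode = "median")
#' man <- run_pipeline(cfg)
#' man$k_star
#' man$budget
run_pipeline <- function(config) {
  stopifnot(inherits(config, "burndex_config"))
  seed <- config$seed
  manifest <- list(seed = seed, stages = character(0))
  note <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
  }

  ## ---- input + preprocessing ----
  if (!is.null(config$summary) && config$summary_mode == "median") {
    profiles <- profiles_from_summary(config$summary)
    manifest$input <- "summary (printed medians)"
    cohort <- NULL
    note("profiles_from_summary")
  } else {
    cohort <- if (!is.null(config$summary)) {
      gen_cohort(simulation_spec(config$summary,
                                 seed = derive_seed(seed, "simulate")))
    } else if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      validate_cohort(config$cohort)
    }
    manifest$input <- if (!is.null(config$summary)) "summary (simulated cohort)"
      else "cohort"
    masked <- mask_outliers(cohort)
    manifest$mask_report <- preprocess_report(masked)
    note("mask_outliers")
    kept <- filter_rats(masked, config$max_missing_frac)
    manifest$filter_report <- preprocess_report(kept)
    note("filter_rats")
    cohort <- impute_group_median(kept)
    manifest$impute_report <- preprocess_report(cohort)
    note("impute_group_median")
    profiles <- group_profiles(cohort, statistic = config$statistic)
    note("group_profiles")
  }
  manifest$n_profiles <- length(unique(profiles$variable))

  ## ---- clustering ----
  ccfg <- config$cluster
  ccfg$seed <- derive_seed(seed, "cluster")
  scan <- scan_k(profiles, ccfg)
  manifest$scan <- tibble::as_tibble(scan)
  k_star <- choose_k(scan)
  manifest$k_star <- k_star
  clustering <- kmeans_profiles(profiles, k_star, ccfg)
  manifest$clustering <- glance(clustering)
  manifest$assignment <- tidy(clustering)
  note("clustering")

  ## ---- pattern analysis ----
  cm <- centroid_matrix(profiles, clustering$assignment)
  patterns <- svd_patterns(cm, tol = config$svd_tol,
                           energy_floor = config$svd_energy_floor)
  manifest$patterns <- glance(patterns)
  manifest$singular_values <- patterns$singular_values
  manifest$cross_vessel <- withCallingHandlers(
    cross_vessel_membership(clustering$assignment),
    warning = function(w) {
      manifest$cross_vessel_note <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  manifest$census <- membership_census(clustering$assignment)
  budget <- if (identical(config$budget, "auto")) patterns$n_independent
    else as.integer(config$budget)
  manifest$budget <- budget
  note("pattern_analysis")

  ## ---- selection + index (per-rat data only) ----
  if (!is.null(cohort)) {
    comparison <- compare_models(config$models, cohort, budget,
                                 seed = derive_seed(seed, "selection"))
    manifest$comparison <- dplyr::select(comparison, -"selection")
    best <- comparison$selection[[nrow(comparison)]]
    index <- train_index(best$model, cohort, best$variables)
    manifest$index <- glance(index)
    manifest$index_model <- index
    note("severity_index")
  }

  class(manifest) <- "burndex_manifest"
  manifest
}

#' @export
print.burndex_manifest <- function(x, ...) {
  cat("burndex pipeline manifest (seed ", x$seed, ")\n", sep = "")
  cat("  input:", x$input, "\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  profiles:", x$n_profiles, "  k* =", x$k_star,
      "  budget =", x$budget, "\n")
  if (!is.null(x$comparison)) {
    cat("  best model:", x$comparison$kind[nrow(x$comparison)], "(",
        x$comparison$variables[nrow(x$comparison)], ")\n")
  }
  invisible(x)
}

#' Write a manifest to a JSON file
#'
#' Tabular stage outputs are serialized as data frames; model objects are
#' omitted (the manifest records their summaries and seeds, which fully
#' determine re-execution via [run_pipeline()]).
#'
#' @param manifest A `burndex_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[setdiff(names(manifest), "index_model")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Printed model predictions of the published severity index
#'
#' The published per-rat predictions of the final neural-network index
#' (trained on all 21 retained rats) for the 2-, 3-, 4- and 5-variable
#' models, transcribed as printed, with the actual %TBSA of each rat.
#' Useful for validating the relative-absolute-error metric.
#'
#' @return A 21-row tibble: `instance`, `actual_tbsa`, `pred_2var` ..
#'   `pred_5var`.
#' @export
burndex_index_predictions <- function() {
  path <- system.file("extdata", "table5_predictions.csv",
                      package = "burndex", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    instance = readr::col_integer(),
    .default = readr::col_double()), progress = FALSE)
}
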