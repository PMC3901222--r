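#' Load a group-summary table (median and IQR per burn group)
#'
#' Reads a CSV of per-variable group summaries: one row per
#' (analyte, vessel) series with the median and interquartile range for each
#' burn group (sham, 20% and 40% TBSA) and, optionally, a published cluster
#' label. The packaged fixture transcribing the study's printed summary table
#' is available via [burndex_summary()].
#'
#' @param path Path to a summary CSV with columns `analyte`, `vessel`,
#'   `paper_cluster`, `median_sham`, `iqr_sham`, `median_20`, `iqr_20`,
#'   `median_40`, `iqr_40` (and optionally `source_row`).
#' @return A tibble with one row per (analyte, vessel) series.
#' @export
#' @examples
#' summ <- burndex_summary()
#' nrow(summ) # 165 series: 55 analytes x 3 vessels
load_summary_fixture <- function(path) {
  if (!file.exists(path)) abort(paste0("summary file not found: ", path))
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    analyte = readr::col_character(),
    vessel = readr::col_character(),
    paper_cluster = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE))
  if (nrow(df) == 0L) abort(paste0("empty summary file: ", path))
  required <- c("analyte", "vessel", "paper_cluster",
                "median_sham", "iqr_sham", "median_20", "iqr_20",
                "median_40", "iqr_40")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("summary file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_vessel <- which(!df$vessel %in% setdiff(COMPARTMENTS, "FLUX"))
  if (length(bad_vessel)) {
    abort(paste0("unknown vessel '", df$vessel[bad_vessel[1]],
                 "' on summary row ", bad_vessel[1]))
  }
  dup <- which(duplicated(df[, c("analyte", "vessel")]))
  if (length(dup)) {
    abort(paste0("duplicate (analyte, vessel) key on summary row ", dup[1],
                 ": ", df$analyte[dup[1]], " / ", df$vessel[dup[1]]))
  }
  iqr_cols <- c("iqr_sham", "iqr_20", "iqr_40")
  for (cl in iqr_cols) {
    bad <- which(!is.finite(df[[cl]]) | df[[cl]] < 0)
    if (length(bad)) {
      abort(paste0("negative or missing ", cl, " on summary row ", bad[1],
                   " (", df$analyte[bad[1]], " / ", df$vessel[bad[1]], ")"))
    }
  }
  med_cols <- c("median_sham", "median_20", "median_40")
  for (cl in med_cols) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad)) {
      abort(paste0("missing ", cl, " on summary row ", bad[1]))
    }
  }
  dplyr::as_tibble(df)
}

#' Packaged transcription of the published group-summary table
#'
#' The printed per-variable summary (median ± IQR for each burn group, plus
#' the published cluster label) transcribed as printed, including its label
#' irregularities; `source_row` indexes the printed row order so any
#' discrepancy is auditable.
#'
#' @return A 165-row tibble (55 analytes x {HA, PV, SHVC}).
#' @export
burndex_summary <- function() {
  load_summary_fixture(system.file("extdata", "table1_summary.csv",
                                   package = "burndex", mustWork = TRUE))
}

#' Reshape a group-summary table to long form
#'
#' One row per (analyte, vessel, dose level) with `median` and `iqr` columns;
#' dose levels are the %TBSA values 0 (sham), 20 and 40.
#'
#' @param summary A summary tibble as returned by [load_summary_fixture()].
#' @return A long tibble with columns `analyte`, `vessel`, `tbsa`, `median`,
#'   `iqr`.
#' @export
summary_long <- function(summary) {
  lv <- tibble::tibble(
    suffix = c("sham", "20", "40"),
    tbsa = c(0, 20, 40)
  )
  purrr::map_dfr(seq_len(nrow(lv)), function(i) {
    tibble::tibble(
      analyte = summary$analyte,
      vessel = summary$vessel,
      tbsa = lv$tbsa[i],
      median = summary[[paste0("median_", lv$suffix[i])]],
      iqr = summary[[paste0("iqr_", lv$suffix[i])]]
    )
  }) |>
    dplyr::arrange(.data$analyte, .data$vessel, .data$tbsa)
}

#' Read a per-rat cohort table
#'
#' Cohort CSVs have a `rat_id` column, a `tbsa` column holding the %TBSA burn
#' group (0 for sham), and one numeric column per measurement series named
#' `analyte@vessel` (e.g. `VLDL@HA`). Empty cells are missing values.
#'
#' @param path Path to a cohort CSV.
#' @return A tibble with `rat_id` (character), `tbsa` (numeric) and one
#'   numeric column per measurement series; missing cells are `NA`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    rat_id = readr::col_character(),
    .default = readr::col_double()
  ), na = "", progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("non-numeric cell in ", path, " at row ", probs$row[1],
                 ", column ", probs$col[1], ": ", probs$actual[1]))
  }
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param table A cohort tibble.
#' @export
write_cohort <- function(table, path) {
  table <- validate_cohort(table)
  readr::write_csv(table, path, na = "")
  invisible(path)
}

validate_cohort <- function(table) {
  if (!all(c("rat_id", "tbsa") %in% names(table))) {
    abort("cohort table must have 'rat_id' and 'tbsa' columns")
  }
  dup <- which(duplicated(table$rat_id))
  if (length(dup)) {
    abort(paste0("duplicate rat_id: ", table$rat_id[dup[1]]))
  }
  if (any(!is.finite(table$tbsa)) || any(table$tbsa < 0)) {
    abort("tbsa must be non-negative and non-missing for every rat")
  }
  cols <- measurement_cols(table)
  if (length(cols)) {
    keys <- split_var_key(cols)
    bad <- which(!keys$compartment %in% COMPARTMENTS)
    if (length(bad)) {
      abort(paste0("unknown compartment suffix in column '", cols[bad[1]],
                   "' (expected one of ", paste(COMPARTMENTS, collapse = ", "),
                   ")"))
    }
    not_num <- cols[!vapply(table[cols], is.numeric, logical(1))]
    if (length(not_num)) {
      abort(paste0("non-numeric measurement column: ", not_num[1]))
    }
  }
  tibble::as_tibble(table)
}
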