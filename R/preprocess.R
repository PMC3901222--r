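#' Mask outliers by the group median +/- 2 IQR fence
#'
#' Within each (variable, %TBSA group), cells outside
#' `[median - 2*IQR, median + 2*IQR]` are set to missing. The median and IQR
#' are computed on the pre-masking values; all other cells are unchanged.
#' With zero IQR the fence collapses to the median, so any non-median value
#' is masked (a warning notes affected variables).
#'
#' @param table A cohort tibble.
#' @param quartile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation on sorted data).
#' @return The masked cohort tibble. The `report` attribute holds a tibble of
#'   masked-cell counts per (variable, group); read it with
#'   [preprocess_report()].
#' @export
#' @examples
#' tab <- tibble::tibble(rat_id = sprintf("r%d", 1:5), tbsa = 0,
#'                       `X@HA` = c(1, 2, 3, 4, 100))
#' masked <- mask_outliers(tab)
#' masked$`X@HA` # 100 is beyond the fence [-1, 7]
mask_outliers <- function(table, quartile_type = 7) {
  table <- validate_cohort(table)
  cols <- measurement_cols(table)
  rep_rows <- list()
  zero_iqr_masked <- character(0)
  for (cl in cols) {
    for (lv in unique(table$tbsa)) {
      idx <- which(table$tbsa == lv)
      x <- table[[cl]][idx]
      obs <- x[!is.na(x)]
      if (length(obs) == 0L) next
      med <- median(obs)
      q <- quantile(obs, c(0.25, 0.75), type = quartile_type, names = FALSE)
      iqr <- q[2] - q[1]
      out <- !is.na(x) & (x < med - 2 * iqr | x > med + 2 * iqr)
      if (any(out)) {
        if (iqr == 0) zero_iqr_masked <- c(zero_iqr_masked, cl)
        table[[cl]][idx[out]] <- NA_real_
        rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
          variable = cl, tbsa = lv, n_masked = sum(out))
      }
    }
  }
  if (length(zero_iqr_masked)) {
    warn(paste0("zero-IQR group(s) with non-median values; fence collapsed ",
                "to the median for: ",
                paste(unique(zero_iqr_masked), collapse = ", ")))
  }
  report <- if (length(rep_rows)) dplyr::bind_rows(rep_rows) else
    tibble::tibble(variable = character(0), tbsa = numeric(0),
                   n_masked = integer(0))
  attr(table, "report") <- list(stage = "mask_outliers", masked = report,
                                quartile_type = quartile_type)
  table
}

#' Remove rats with excessive missingness
#'
#' Rats whose missing fraction over the concentration columns (derived flux
#' columns are excluded) is strictly greater than `max_missing_frac` are
#' removed; survivor order is preserved.
#'
#' @param table A cohort tibble.
#' @param max_missing_frac Removal threshold (default 0.30; a rat at exactly
#'   30% missing is kept).
#' @return The filtered cohort tibble with a `report` attribute listing the
#'   removed rats and their missingness fractions.
#' @export
filter_rats <- function(table, max_missing_frac = 0.30) {
  table <- validate_cohort(table)
  cols <- concentration_cols(table)
  if (length(cols) == 0L) abort("cohort has no measurement columns")
  frac <- rowMeans(is.na(as.matrix(table[cols])))
  drop <- frac > max_missing_frac
  if (all(drop)) abort("empty cohort after filtering")
  report <- tibble::tibble(rat_id = table$rat_id[drop],
                           missing_frac = frac[drop])
  out <- table[!drop, , drop = FALSE]
  attr(out, "report") <- list(stage = "filter_rats", removed = report,
                              max_missing_frac = max_missing_frac)
  out
}

#' Impute missing cells with the group median
#'
#' Each missing cell is replaced by the median of the observed values of that
#' variable within the same %TBSA group. Observed cells are unchanged;
#' re-imputation is a fixpoint.
#'
#' @param table A cohort tibble.
#' @return The imputed cohort tibble (no missing measurement cells remain)
#'   with a `report` attribute of imputation counts.
#' @export
impute_group_median <- function(table) {
  table <- validate_cohort(table)
  cols <- measurement_cols(table)
  rep_rows <- list()
  for (cl in cols) {
    for (lv in unique(table$tbsa)) {
      idx <- which(table$tbsa == lv)
      x <- table[[cl]][idx]
      nas <- is.na(x)
      if (!any(nas)) next
      obs <- x[!nas]
      if (length(obs) == 0L) {
        abort(paste0("cannot impute '", cl, "' in group tbsa=", lv,
                     ": all values missing"))
      }
      table[[cl]][idx[nas]] <- median(obs)
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        variable = cl, tbsa = lv, n_imputed = sum(nas))
    }
  }
  report <- if (length(rep_rows)) dplyr::bind_rows(rep_rows) else
    tibble::tibble(variable = character(0), tbsa = numeric(0),
                   n_imputed = integer(0))
  attr(table, "report") <- list(stage = "impute_group_median",
                                imputed = report)
  table
}

#' Read the audit report attached by a preprocessing stage
#'
#' @param table A cohort tibble returned by a preprocessing function.
#' @return The stage's report list, or `NULL` if none is attached.
#' @export
preprocess_report <- function(table) attr(table, "report")

#' Net liver flux of a metabolite
#'
#' The liver's net release (positive) or uptake (negative), computed as the
#' difference between efflux and influxes -- each the product of a vessel
#' concentration and its blood flow rate -- normalized to liver weight. The
#' outflow rate is taken as the sum of the two inflow rates.
#'
#' `flux = (conc_shvc * (Q_pv + Q_ha) - conc_pv * Q_pv - conc_ha * Q_ha) / W`
#'
#' @param conc_ha,conc_pv,conc_shvc Concentrations in the hepatic artery,
#'   portal vein and suprahepatic vena cava (any shared assay unit).
#' @param flow_ha,flow_pv Blood flow rates (mL/min); strictly positive.
#' @param liver_weight Liver mass (g); strictly positive.
#' @return Net flux per gram of liver (amount/min/g); vectorized.
#' @export
#' @examples
#' compute_flux(0, 0, 10, flow_ha = 5, flow_pv = 20, liver_weight = 10) # 25
compute_flux <- function(conc_ha, conc_pv, conc_shvc,
                         flow_ha, flow_pv, liver_weight) {
  if (any(liver_weight <= 0, na.rm = TRUE)) {
    abort("liver_weight must be strictly positive")
  }
  if (any(c(flow_ha, flow_pv) <= 0, na.rm = TRUE)) {
    abort("flow rates must be strictly positive")
  }
  (conc_shvc * (flow_pv + flow_ha) - conc_pv * flow_pv - conc_ha * flow_ha) /
    liver_weight
}

#' Derive per-rat liver flux columns for every analyte measured in all three
#' vessels
#'
#' Adds one `analyte@FLUX` column per analyte that has HA, PV and SHVC
#' concentration columns, using the rat's measured flow rates and liver
#' weight. Intended to run after imputation so no flux is built from missing
#' concentrations.
#'
#' @param table An imputed cohort tibble.
#' @param liver_weight Per-rat liver weights (g): a single value or a vector
#'   named by `rat_id`. Defaults to the `liver_weight_g` attribute if
#'   present.
#' @param flow_ha_col,flow_pv_col Names of the flow-rate columns.
#' @return The cohort with appended `@FLUX` columns.
#' @export
add_flux_columns <- function(table,
                             liver_weight = attr(table, "liver_weight_g"),
                             flow_ha_col = "Flow Rate@HA",
                             flow_pv_col = "Flow Rate@PV") {
  table <- validate_cohort(table)
  if (is.null(liver_weight)) abort("liver_weight is required")
  if (!is.null(names(liver_weight))) {
    liver_weight <- unname(liver_weight[table$rat_id])
  }
  if (!all(c(flow_ha_col, flow_pv_col) %in% names(table))) {
    abort("flow rate columns not found in cohort")
  }
  keys <- split_var_key(measurement_cols(table))
  by_analyte <- split(keys$compartment, keys$analyte)
  full <- names(by_analyte)[vapply(by_analyte, function(v)
    all(c("HA", "PV", "SHVC") %in% v), logical(1))]
  full <- setdiff(full, "Flow Rate")
  for (an in full) {
    table[[var_key(an, "FLUX")]] <- compute_flux(
      table[[var_key(an, "HA")]], table[[var_key(an, "PV")]],
      table[[var_key(an, "SHVC")]],
      flow_ha = table[[flow_ha_col]], flow_pv = table[[flow_pv_col]],
      liver_weight = liver_weight)
  }
  table
}

# Affine map sending min -> -1 and max -> +1; constant profiles map to 0.
normalize_profile <- function(v) {
  r <- range(v)
  if (!all(is.finite(r))) abort("profile contains non-finite values")
  if (r[1] == r[2]) return(rep(0, length(v)))
  2 * (v - r[1]) / (r[2] - r[1]) - 1
}

#' Dose-response profiles of a cohort
#'
#' For each measurement series, the per-group statistic (mean by default, the
#' study's choice; median available for summary-driven reproduction) across
#' ascending %TBSA levels, normalized to `[-1, 1]` by the affine map sending
#' the profile minimum to -1 and maximum to +1. A constant profile maps to
#' all zeros.
#'
#' @param table An imputed cohort tibble with at least two dose levels.
#' @param statistic `"mean"` or `"median"`.
#' @return A long tibble: `variable`, `analyte`, `compartment`, `tbsa`,
#'   `raw`, `normalized`.
#' @export
group_profiles <- function(table, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  table <- validate_cohort(table)
  levels <- sort(unique(table$tbsa))
  if (length(levels) < 2) abort("at least two dose levels are required")
  fun <- if (statistic == "mean") mean else median
  cols <- measurement_cols(table)
  keys <- split_var_key(cols)
  purrr::map_dfr(seq_along(cols), function(j) {
    raw <- vapply(levels, function(lv)
      fun(table[[cols[j]]][table$tbsa == lv]), numeric(1))
    tibble::tibble(variable = cols[j], analyte = keys$analyte[j],
                   compartment = keys$compartment[j], tbsa = levels,
                   raw = raw, normalized = normalize_profile(raw))
  })
}

#' Dose-response profiles from a group-summary table
#'
#' Applies the `[-1, 1]` profile normalization directly to the printed group
#' medians -- the closest reproducible proxy when per-rat data are
#' unavailable.
#'
#' @param summary A group-summary tibble.
#' @return A long profile tibble as in [group_profiles()].
#' @export
profiles_from_summary <- function(summary) {
  long <- summary_long(summary)
  long |>
    dplyr::group_by(.data$analyte, .data$vessel) |>
    dplyr::arrange(.data$tbsa, .by_group = TRUE) |>
    dplyr::mutate(variable = var_key(.data$analyte[1], .data$vessel[1]),
                  raw = .data$median,
                  normalized = normalize_profile(.data$median)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$variable, .data$analyte,
                     compartment = .data$vessel, .data$tbsa, .data$raw,
                     .data$normalized)
}

#' Profile matrix (variables x dose levels)
#'
#' @param profiles A long profile tibble.
#' @param value Which column to spread (default `"normalized"`).
#' @return A numeric matrix, one row per variable (rownames are
#'   `analyte@compartment` keys), columns in ascending dose order.
#' @export
profile_matrix <- function(profiles, value = "normalized") {
  wide <- profiles |>
    dplyr::select("variable", "tbsa", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "tbsa", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$variable
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}
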