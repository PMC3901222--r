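#' Specify a synthetic cohort calibrated to a group-summary table
#'
#' The generator draws each cell from a normal distribution centred on the
#' group median with sd = IQR/1.349 (the normal-theory IQR-to-sd conversion),
#' truncated at zero for non-negative analytes, then injects missing cells and
#' planted outliers at the requested rates. Only group medians and IQRs are
#' published for the study cohort, so this family is the simplest model
#' consistent with the printed summaries.
#'
#' @param summary A group-summary tibble ([load_summary_fixture()]).
#' @param group_sizes Named numeric vector of rats per %TBSA level; default
#'   matches the study design (12 sham, 12 at 20%, 13 at 40%).
#' @param missing_rate Probability a cell is recorded as missing.
#' @param outlier_rate Probability a cell is replaced by a planted extreme
#'   value.
#' @param outlier_scale Planted outliers sit `outlier_scale` IQRs beyond the
#'   2xIQR outlier fence, on a random side, so the masking rule is exercised
#'   on both tails.
#' @param nonneg Truncate draws at zero (concentrations cannot be negative).
#' @param liver_weight_mean,liver_weight_sd Mean and sd (g) of simulated liver
#'   weights, attached as the `liver_weight_g` attribute (the study prints no
#'   liver weights; these defaults are the generator's own).
#' @param seed RNG seed; fixes the entire output.
#' @return A list of class `burndex_simspec`.
#' @export
simulation_spec <- function(summary,
                            group_sizes = c(`0` = 12, `20` = 12, `40` = 13),
                            missing_rate = 0.05,
                            outlier_rate = 0.02,
                            outlier_scale = 3,
                            nonneg = TRUE,
                            liver_weight_mean = 10,
                            liver_weight_sd = 1,
                            seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            all(group_sizes >= 1), liver_weight_mean > 0)
  if (is.null(names(group_sizes))) {
    abort("group_sizes must be named by %TBSA level, e.g. c(`0`=12, `20`=12, `40`=13)")
  }
  structure(list(summary = summary, group_sizes = group_sizes,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 outlier_scale = outlier_scale, nonneg = nonneg,
                 liver_weight_mean = liver_weight_mean,
                 liver_weight_sd = liver_weight_sd, seed = as.integer(seed)),
            class = "burndex_simspec")
}

# Truncated-at-zero normal draw via rejection; sd = 0 collapses to the mean.
rtnorm0 <- function(n, mean, sd, nonneg) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  if (nonneg) {
    bad <- which(x < 0)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] < 0]
      guard <- guard + 1L
    }
    if (length(bad)) x[bad] <- 0 # pathological mean << 0; clamp
  }
  x
}

#' Generate a synthetic per-rat cohort from group summaries
#'
#' @param spec A [simulation_spec()].
#' @return A cohort tibble (`rat_id`, `tbsa`, one column per series). The
#'   `truth` attribute holds the injected-outlier and missingness masks (long
#'   tibble: `rat_id`, `variable`, `is_outlier`, `is_missing`); the
#'   `liver_weight_g` attribute holds one simulated liver weight per rat.
#' @export
#' @examples
#' summ <- burndex_summary()
#' cohort <- gen_cohort(simulation_spec(summ, seed = 7))
#' dim(cohort)
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "burndex_simspec"))
  long <- summary_long(spec$summary)
  levels_avail <- sort(unique(long$tbsa))
  levels_want <- as.numeric(names(spec$group_sizes))
  missing_lv <- setdiff(levels_want, levels_avail)
  if (length(missing_lv)) {
    abort(paste0("summary lacks group level(s): ",
                 paste(missing_lv, collapse = ", ")))
  }
  set.seed(spec$seed)
  keys <- var_key(spec$summary$analyte, spec$summary$vessel)
  n_total <- sum(spec$group_sizes)
  rat_id <- sprintf("rat%02d", seq_len(n_total))
  tbsa <- rep(levels_want, times = spec$group_sizes)

  vals <- matrix(NA_real_, nrow = n_total, ncol = length(keys),
                 dimnames = list(NULL, keys))
  out_mask <- matrix(FALSE, n_total, length(keys), dimnames = list(NULL, keys))
  na_mask <- matrix(FALSE, n_total, length(keys), dimnames = list(NULL, keys))

  for (j in seq_along(keys)) {
    st <- long[long$analyte == spec$summary$analyte[j] &
                 long$vessel == spec$summary$vessel[j], ]
    for (lv in levels_want) {
      rows <- which(tbsa == lv)
      med <- st$median[st$tbsa == lv]
      iqr <- st$iqr[st$tbsa == lv]
      x <- rtnorm0(length(rows), med, iqr / 1.349, spec$nonneg)
      is_out <- runif(length(rows)) < spec$outlier_rate
      if (any(is_out)) {
        # just beyond the 2xIQR fence plus outlier_scale x IQR; degenerate
        # IQR = 0 falls back to a unit-or-median-sized offset so the planted
        # point still violates the fence
        offs <- (2 + spec$outlier_scale) * iqr
        if (iqr == 0) offs <- max(1, abs(med))
        side <- sample(c(-1, 1), sum(is_out), replace = TRUE)
        if (spec$nonneg) side[med + side * offs < 0] <- 1
        x[is_out] <- med + side * offs
      }
      is_na <- runif(length(rows)) < spec$missing_rate
      x[is_na] <- NA_real_
      vals[rows, j] <- x
      out_mask[rows, j] <- is_out & !is_na
      na_mask[rows, j] <- is_na
    }
  }

  cohort <- dplyr::bind_cols(
    tibble::tibble(rat_id = rat_id, tbsa = tbsa),
    tibble::as_tibble(vals)
  )
  truth <- tibble::tibble(
    rat_id = rep(rat_id, times = length(keys)),
    variable = rep(keys, each = n_total),
    is_outlier = as.vector(out_mask),
    is_missing = as.vector(na_mask)
  )
  attr(cohort, "truth") <- truth
  attr(cohort, "liver_weight_g") <- setNames(
    abs(rnorm(n_total, spec$liver_weight_mean, spec$liver_weight_sd)), rat_id)
  cohort
}

#' The four canonical dose-response archetypes
#'
#' Normalized 3-vectors over the dose levels (0, 20, 40 %TBSA) matching the
#' four cluster centroid shapes recovered from the published summaries:
#' monotone increase, peak at the intermediate dose, dip at the intermediate
#' dose with a late spike, and monotone decrease.
#'
#' @return A named list of numeric 3-vectors in `[-1, 1]`.
#' @export
default_archetypes <- function() {
  list(
    up = c(-1, 0.35, 1),
    peak = c(-0.9, 1, -1),
    dip = c(0.15, -1, 1),
    down = c(1, -0.75, -1)
  )
}

#' Specify an archetype cohort with known pattern labels
#'
#' @param patterns Named list of normalized dose-response 3-vectors (default
#'   [default_archetypes()]).
#' @param n_per_pattern Number of variables carrying each pattern (>= 2, or
#'   recovery is undefined).
#' @param noise_sd Per-cell Gaussian noise sd on the profile scale.
#' @return A list of class `burndex_archspec` with an `assignment` tibble
#'   mapping each variable to its pattern.
#' @export
archetype_spec <- function(patterns = default_archetypes(),
                           n_per_pattern = 10,
                           noise_sd = 0.1) {
  stopifnot(length(patterns) >= 1, noise_sd >= 0)
  if (n_per_pattern < 2) {
    abort("n_per_pattern must be >= 2 (pattern recovery is undefined otherwise)")
  }
  rng <- vapply(patterns, function(p) all(is.finite(p)) && length(p) == 3 &&
                  all(abs(p) <= 1), logical(1))
  if (!all(rng)) abort("patterns must be 3-vectors with entries in [-1, 1]")
  assignment <- tibble::tibble(
    variable = var_key(
      sprintf("%s_%02d", rep(names(patterns), each = n_per_pattern),
              rep(seq_len(n_per_pattern), times = length(patterns))),
      "HA"),
    pattern = rep(names(patterns), each = n_per_pattern)
  )
  structure(list(patterns = patterns, assignment = assignment,
                 noise_sd = noise_sd),
            class = "burndex_archspec")
}

#' Generate a cohort whose variables follow known dose-response archetypes
#'
#' Each variable's group means follow its assigned pattern scaled by
#' `effect_scale`, plus Gaussian noise; used to test that clustering recovers
#' planted structure.
#'
#' @param arch An [archetype_spec()].
#' @param n_per_group Rats per dose level.
#' @param effect_scale Multiplier on the pattern amplitude (0 = no signal).
#' @param seed RNG seed.
#' @param levels Dose levels (default `c(0, 20, 40)`).
#' @return A cohort tibble with a `pattern_truth` attribute (the generating
#'   assignment).
#' @export
gen_archetype_cohort <- function(arch, n_per_group = 7, effect_scale = 1,
                                 seed = 1L, levels = c(0, 20, 40)) {
  stopifnot(inherits(arch, "burndex_archspec"), n_per_group >= 1)
  set.seed(as.integer(seed))
  n_total <- n_per_group * length(levels)
  tbsa <- rep(levels, each = n_per_group)
  vars <- arch$assignment$variable
  vals <- matrix(NA_real_, n_total, length(vars),
                 dimnames = list(NULL, vars))
  for (j in seq_along(vars)) {
    pat <- arch$patterns[[arch$assignment$pattern[j]]]
    mu <- pat[match(tbsa, levels)] * effect_scale
    vals[, j] <- rnorm(n_total, mu, arch$noise_sd)
  }
  cohort <- dplyr::bind_cols(
    tibble::tibble(rat_id = sprintf("rat%02d", seq_len(n_total)), tbsa = tbsa),
    tibble::as_tibble(vals)
  )
  attr(cohort, "pattern_truth") <- arch$assignment
  cohort
}

#' Generate a cohort with a planted two-variable severity signal
#'
#' Emulates the published group summaries while isolating a known,
#' recoverable predictive signal. The planted variables keep their printed
#' per-group medians (so they carry the printed dose-response shapes: a
#' monotone decrease and a step-down at the highest dose) with their
#' dispersion set so the smallest non-zero gap between adjacent group
#' medians equals `effect_d` within-group standard deviations -- a strong,
#' well-defined planted effect. Every other variable is made exactly null:
#' its group medians are replaced by the variable's pooled median and its
#' group IQRs by the pooled IQR, so all dose groups share one distribution
#' (with per-group IQRs kept, zero-truncation of near-zero analytes would
#' leak dispersion differences into group means). Selection experiments then
#' have an unambiguous ground truth.
#'
#' @param summary A group-summary tibble.
#' @param planted Character vector of `analyte@vessel` keys to leave
#'   informative (default: the two headline indicators).
#' @param effect_d Standardized effect size of the planted signal: the
#'   smallest non-zero adjacent-group median gap of a planted variable, in
#'   units of its within-group sd (default 3).
#' @param ... Passed on to [simulation_spec()] (e.g. `group_sizes`, `seed`).
#' @return A cohort tibble; the `planted` attribute names the signal
#'   variables.
#' @export
gen_planted_cohort <- function(summary,
                               planted = c("Very low density lipoprotein (VLDL)@HA",
                                           "Acetoacetate@SHVC"),
                               effect_d = 3, ...) {
  keys <- var_key(summary$analyte, summary$vessel)
  miss <- setdiff(planted, keys)
  if (length(miss)) {
    abort(paste0("planted variable(s) not in summary: ",
                 paste(miss, collapse = ", ")))
  }
  null_summary <- summary
  flat <- !keys %in% planted
  med <- cbind(summary$median_sham, summary$median_20, summary$median_40)
  pooled <- apply(med, 1, median)
  iqr <- cbind(summary$iqr_sham, summary$iqr_20, summary$iqr_40)
  pooled_iqr <- apply(iqr, 1, median)
  null_summary$median_sham[flat] <- pooled[flat]
  null_summary$median_20[flat] <- pooled[flat]
  null_summary$median_40[flat] <- pooled[flat]
  null_summary$iqr_sham[flat] <- pooled_iqr[flat]
  null_summary$iqr_20[flat] <- pooled_iqr[flat]
  null_summary$iqr_40[flat] <- pooled_iqr[flat]
  for (i in which(!flat)) {
    gaps <- abs(diff(med[i, ]))
    gaps <- gaps[gaps > 0]
    if (!length(gaps)) {
      abort(paste0("planted variable has a constant profile: ", keys[i]))
    }
    iqr <- 1.349 * min(gaps) / effect_d
    null_summary$iqr_sham[i] <- iqr
    null_summary$iqr_20[i] <- iqr
    null_summary$iqr_40[i] <- iqr
  }
  spec <- simulation_spec(null_summary, missing_rate = 0, outlier_rate = 0, ...)
  cohort <- gen_cohort(spec)
  attr(cohort, "planted") <- planted
  cohort
}
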