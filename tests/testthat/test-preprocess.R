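test_that("outlier masking applies the median +/- 2 IQR fence per group", {
  # hand-computed with type-7 quartiles: {1,2,3,4,100} -> median 3,
  # Q1 2, Q3 4, fence [-1, 7] -> only 100 masked
  tab <- tibble::tibble(rat_id = sprintf("r%d", 1:5), tbsa = 0,
                        `X@HA` = c(1, 2, 3, 4, 100))
  masked <- mask_outliers(tab)
  expect_equal(masked$`X@HA`, c(1, 2, 3, 4, NA))
  rep <- preprocess_report(masked)
  expect_equal(rep$masked$n_masked, 1L)

  # all-equal group: nothing masked
  tab2 <- tibble::tibble(rat_id = sprintf("r%d", 1:4), tbsa = 0,
                         `X@HA` = rep(7, 4))
  expect_equal(mask_outliers(tab2)$`X@HA`, rep(7, 4))

  # zero IQR with deviating values: fence collapses to the median
  tab3 <- tibble::tibble(rat_id = sprintf("r%d", 1:5), tbsa = 0,
                         `X@HA` = c(5, 5, 5, 5, 9))
  expect_warning(m3 <- mask_outliers(tab3), "zero-IQR")
  expect_equal(m3$`X@HA`, c(5, 5, 5, 5, NA))
})

test_that("masking of generator-injected outliers approaches completeness", {
  summ <- burndex_summary()[seq(1, 120, by = 6), ]
  spec <- simulation_spec(summ, group_sizes = c(`0` = 50, `20` = 50, `40` = 50),
                          missing_rate = 0, outlier_rate = 0.04, seed = 11)
  cohort <- gen_cohort(spec)
  truth <- attr(cohort, "truth")
  masked <- suppressWarnings(mask_outliers(cohort))
  out <- truth[truth$is_outlier, ]
  caught <- vapply(seq_len(nrow(out)), function(r) {
    is.na(masked[[out$variable[r]]][masked$rat_id == out$rat_id[r]])
  }, logical(1))
  expect_gte(mean(caught), 0.95)
})

test_that("rat filtering uses a strict 30% missingness threshold", {
  n_cols <- 165
  vals <- matrix(1, 3, n_cols)
  vals[1, 1:50] <- NA  # 50/165 = 30.3% -> removed
  vals[2, 1:49] <- NA  # 49/165 = 29.7% -> kept
  colnames(vals) <- sprintf("v%03d@HA", seq_len(n_cols))
  tab <- dplyr::bind_cols(tibble::tibble(rat_id = c("a", "b", "c"), tbsa = 0),
                          tibble::as_tibble(vals))
  kept <- filter_rats(tab)
  expect_equal(kept$rat_id, c("b", "c"))
  rep <- preprocess_report(kept)
  expect_equal(rep$removed$rat_id, "a")
  expect_equal(rep$removed$missing_frac, 50 / 165)

  # exactly 30%: kept (strict inequality)
  vals2 <- matrix(1, 2, 10)
  vals2[1, 1:3] <- NA
  colnames(vals2) <- sprintf("v%02d@HA", 1:10)
  tab2 <- dplyr::bind_cols(tibble::tibble(rat_id = c("a", "b"), tbsa = 0),
                           tibble::as_tibble(vals2))
  expect_equal(filter_rats(tab2)$rat_id, c("a", "b"))

  # fully observed table passes through unchanged
  tab3 <- toy_cohort()[, 1:3]
  expect_equal(filter_rats(tab3), tab3, ignore_attr = TRUE)

  # flux columns are excluded from the missingness fraction
  tab4 <- tibble::tibble(rat_id = c("a", "b"), tbsa = 0,
                         `X@HA` = c(1, 1), `X@FLUX` = c(NA_real_, NA_real_))
  expect_equal(filter_rats(tab4)$rat_id, c("a", "b"))

  tab5 <- tibble::tibble(rat_id = "a", tbsa = 0, `X@HA` = NA_real_)
  expect_error(filter_rats(tab5), "empty cohort")
})

test_that("group-median imputation fills every gap and is idempotent", {
  tab <- tibble::tibble(rat_id = sprintf("r%d", 1:4), tbsa = 0,
                        `X@HA` = c(2, 4, 9, NA))
  imp <- impute_group_median(tab)
  expect_equal(imp$`X@HA`, c(2, 4, 9, 4))
  expect_equal(impute_group_median(imp)$`X@HA`, imp$`X@HA`)

  # observed cells unchanged; no missing cells remain on a mixed table
  cohort <- gen_cohort(simulation_spec(burndex_summary()[1:20, ],
                                       missing_rate = 0.1, seed = 2))
  imp2 <- impute_group_median(cohort)
  expect_false(anyNA(as.matrix(imp2[, -(1:2)])))
  obs <- !is.na(as.matrix(cohort[, -(1:2)]))
  expect_equal(as.matrix(imp2[, -(1:2)])[obs], as.matrix(cohort[, -(1:2)])[obs])

  tab_bad <- tibble::tibble(rat_id = c("a", "b"), tbsa = c(0, 0),
                            `X@HA` = c(NA_real_, NA_real_))
  expect_error(impute_group_median(tab_bad), "X@HA")
})

test_that("liver flux follows the mass-balance arithmetic", {
  # conservation: equal concentrations in and out -> zero net flux
  expect_equal(compute_flux(3, 3, 3, flow_ha = 5, flow_pv = 17,
                            liver_weight = 8), 0)
  # direct arithmetic: 10 * (20 + 5) / 10
  expect_equal(compute_flux(0, 0, 10, flow_ha = 5, flow_pv = 20,
                            liver_weight = 10), 25)
  # homogeneity in the flows
  f1 <- compute_flux(1, 2, 4, flow_ha = 3, flow_pv = 7, liver_weight = 5)
  f2 <- compute_flux(1, 2, 4, flow_ha = 6, flow_pv = 14, liver_weight = 5)
  expect_equal(f2, 2 * f1)
  expect_error(compute_flux(1, 1, 1, 1, 1, liver_weight = 0), "positive")
})

test_that("flux columns derive from vessel triples after imputation", {
  tab <- tibble::tibble(
    rat_id = c("a", "b"), tbsa = c(0, 20),
    `Flow Rate@HA` = c(0.5, 0.6), `Flow Rate@PV` = c(20, 21),
    `Flow Rate@SHVC` = c(20.5, 21.6),
    `Glucose@HA` = c(0, 1), `Glucose@PV` = c(0, 1), `Glucose@SHVC` = c(10, 1),
    `Urea@HA` = c(1, 1), `Urea@PV` = c(1, 1)) # incomplete triple: skipped
  out <- add_flux_columns(tab, liver_weight = c(a = 10, b = 5))
  expect_true("Glucose@FLUX" %in% names(out))
  expect_false("Urea@FLUX" %in% names(out))
  expect_false("Flow Rate@FLUX" %in% names(out))
  expect_equal(out$`Glucose@FLUX`[1],
               compute_flux(0, 0, 10, 0.5, 20, 10))
  expect_equal(out$`Glucose@FLUX`[2], 0)
})

test_that("profile normalization maps group statistics onto [-1, 1]", {
  tab <- tibble::tibble(rat_id = sprintf("r%d", 1:6),
                        tbsa = c(0, 0, 20, 20, 40, 40),
                        `A@HA` = c(1, 1, 2, 2, 3, 3),
                        `B@HA` = c(5, 5, 5, 5, 5, 5))
  prof <- group_profiles(tab)
  expect_equal(prof$normalized[prof$variable == "A@HA"], c(-1, 0, 1))
  expect_equal(prof$normalized[prof$variable == "B@HA"], c(0, 0, 0))

  # fixture medians: VLDL@HA (13, 6, 5) -> (1, -0.75, -1)
  prof_s <- profiles_from_summary(burndex_summary())
  vldl <- prof_s[prof_s$variable == "Very low density lipoprotein (VLDL)@HA", ]
  expect_equal(vldl$raw, c(13, 6, 5))
  expect_equal(vldl$normalized, c(1, -0.75, -1))

  # units invariance: positive affine rescaling leaves profiles unchanged
  tab2 <- tab
  tab2$`A@HA` <- tab2$`A@HA` * 37.2 + 11
  expect_equal(group_profiles(tab2)$normalized, prof$normalized)

  # median mode matches the summary-driven route on generated data
  cohort <- gen_cohort(simulation_spec(burndex_summary()[1:8, ], seed = 1,
                                       missing_rate = 0, outlier_rate = 0))
  pm <- group_profiles(cohort, statistic = "median")
  expect_true(all(pm$normalized >= -1 & pm$normalized <= 1))
})

test_that("the profile matrix is keyed by variable and ordered by dose", {
  prof <- profiles_from_summary(burndex_summary())
  X <- profile_matrix(prof)
  expect_equal(dim(X), c(165, 3))
  expect_equal(colnames(X), c("0", "20", "40"))
  expect_true(all(X >= -1 & X <= 1))
  expect_equal(unname(X["Very low density lipoprotein (VLDL)@HA", ]),
               c(1, -0.75, -1))
})
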