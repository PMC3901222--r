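test_that("relative absolute error matches its definition and edge cases", {
  y <- c(0, 10, 20)
  expect_equal(rae(y, y), 0)                      # perfect
  expect_equal(rae(rep(mean(y), 3), y), 100)      # baseline predictor
  expect_error(rae(c(1, 2), c(5, 5)), "constant") # zero denominator
  # accuracy identity on random reports
  set.seed(1)
  for (rep in 1:10) {
    p <- rnorm(10); a <- rnorm(10)
    expect_equal(100 - rae(p, a), 100 - 100 * sum(abs(p - a)) /
                   sum(abs(mean(a) - a)))
  }
})

test_that("the published index predictions reproduce their printed errors", {
  t5 <- burndex_index_predictions()
  expect_equal(nrow(t5), 21)
  expect_equal(unname(table(t5$actual_tbsa)), rep(7L, 3), ignore_attr = TRUE)
  expect_equal(round(rae(t5$pred_2var, t5$actual_tbsa), 2), 8.49)
  expect_equal(round(rae(t5$pred_3var, t5$actual_tbsa), 2), 2.54)
  expect_equal(round(rae(t5$pred_4var, t5$actual_tbsa), 2), 4.10)
})

test_that("each regressor learns a realizable target", {
  set.seed(2)
  n <- 40
  x1 <- runif(n, 0, 10); x2 <- runif(n, 0, 10)
  data <- tibble::tibble(rat_id = sprintf("r%d", 1:n),
                         tbsa = 2 * x1 + 5,
                         `x1@HA` = x1, `x2@HA` = x2)
  for (kind in c("linear", "mlp", "svr", "model_tree")) {
    idx <- train_index(regressor_spec(kind, seed = 3), data, c("x1@HA", "x2@HA"))
    expect_lt(idx$training_rae, 25)
    # prediction is pure: same rat twice gives the same value
    p1 <- predict(idx, data[3, ])
    p2 <- predict(idx, data[3, ])
    expect_identical(p1, p2)
  }
  # the linear family is exactly realizable
  lin <- train_index(regressor_spec("linear"), data, c("x1@HA", "x2@HA"))
  expect_lt(lin$training_rae, 1e-8)

  # the RBF network's unsupervised centres track the input distribution, so
  # give it a single-feature step target its two bases can represent
  step_data <- tibble::tibble(rat_id = sprintf("r%d", 1:n),
                              tbsa = ifelse(x1 > 5, 20, 0), `x1@HA` = x1)
  rbf <- train_index(regressor_spec("rbf_network", seed = 3), step_data,
                     "x1@HA")
  expect_lt(rbf$training_rae, 30)
  expect_identical(predict(rbf, step_data[2, ]), predict(rbf, step_data[2, ]))
})

test_that("cross-validation scores a realizable linear target above 99%", {
  set.seed(5)
  n <- 30
  x <- runif(n, 0, 10)
  data <- tibble::tibble(rat_id = sprintf("r%d", 1:n), tbsa = 3 * x - 1,
                         `x@HA` = x)
  cv <- cross_validate(regressor_spec("linear"), data, "x@HA", seed = 1)
  expect_gt(cv$accuracy_mean, 99)
  expect_equal(nrow(tidy(cv)), 5)
  # determinism under an identical seed
  cv2 <- cross_validate(regressor_spec("linear"), data, "x@HA", seed = 1)
  expect_identical(tidy(cv), tidy(cv2))
})

test_that("pure-noise targets earn near-zero cross-validated accuracy", {
  accs <- vapply(1:20, function(seed) {
    set.seed(seed + 300)
    n <- 30
    data <- tibble::tibble(rat_id = sprintf("r%d", 1:n),
                           tbsa = sample(rep(c(0, 20, 40), each = 10)),
                           `x@HA` = rnorm(n), `z@HA` = rnorm(n))
    cross_validate(regressor_spec("linear"), data, c("x@HA", "z@HA"),
                   seed = seed)$accuracy_mean
  }, numeric(1))
  expect_lte(mean(accs), 20)
})

test_that("cross-validated accuracy does not beat training accuracy on average", {
  diffs <- vapply(1:20, function(seed) {
    set.seed(seed + 700)
    n <- 24
    x <- runif(n, 0, 10)
    data <- tibble::tibble(rat_id = sprintf("r%d", 1:n),
                           tbsa = 2 * x + rnorm(n, 0, 8),
                           `x@HA` = x, `z@HA` = rnorm(n))
    cv <- cross_validate(regressor_spec("linear"), data, c("x@HA", "z@HA"),
                         seed = seed)
    idx <- train_index(regressor_spec("linear"), data, c("x@HA", "z@HA"))
    (100 - idx$training_rae) - cv$accuracy_mean
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("wrapper selection recovers a planted pair among noise variables", {
  planted <- c("signal_lin@HA", "signal_step@SHVC")
  hits <- vapply(1:10, function(seed) {
    data <- planted_selection_cohort(n_noise = 48, seed = seed)
    sel <- select_variables(regressor_spec("linear"), data, budget = 2,
                            seed = seed)
    setequal(sel$variables, planted)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("selection is deterministic and honours degenerate budgets", {
  data <- planted_selection_cohort(n_noise = 10, n_per_group = 5, seed = 3)
  s1 <- select_variables(regressor_spec("linear"), data, budget = 2, seed = 7)
  s2 <- select_variables(regressor_spec("linear"), data, budget = 2, seed = 7)
  expect_identical(s1$variables, s2$variables)
  expect_identical(tidy(s1$cv), tidy(s2$cv))

  all_vars <- burndex:::measurement_cols(data)
  s3 <- select_variables(regressor_spec("linear"), data,
                         budget = length(all_vars), seed = 1)
  expect_setequal(s3$variables, all_vars)
  expect_equal(nrow(s3$log), 0)
  expect_error(select_variables(regressor_spec("linear"), data, budget = 0),
               "budget")
  expect_error(select_variables(regressor_spec("linear"), data,
                                budget = length(all_vars) + 1), "candidate")
})

test_that("model comparison ranks by accuracy regardless of input order", {
  data <- planted_selection_cohort(n_noise = 6, n_per_group = 7, seed = 2)
  specs <- list(tree = regressor_spec("model_tree"),
                linear = regressor_spec("linear"))
  cmp <- compare_models(specs, data, budget = 2, seed = 4)
  expect_equal(nrow(cmp), 2)
  expect_true(all(diff(cmp$accuracy_mean) >= 0))
  cmp_rev <- compare_models(rev(specs), data, budget = 2, seed = 4)
  expect_equal(cmp$kind, cmp_rev$kind)
  expect_equal(cmp$accuracy_mean, cmp_rev$accuracy_mean)

  single <- compare_models(list(regressor_spec("linear")), data, budget = 2,
                           seed = 4)
  expect_equal(nrow(single), 1)
})

test_that("the budget sweep exposes gains from genuinely useful variables", {
  set.seed(9)
  n <- 30
  x1 <- runif(n, 0, 10); x2 <- runif(n, 0, 10); x3 <- runif(n, 0, 10)
  data <- tibble::tibble(rat_id = sprintf("r%d", 1:n),
                         tbsa = x1 + x2 + x3 + rnorm(n, 0, 0.5),
                         `x1@HA` = x1, `x2@HA` = x2, `x3@HA` = x3,
                         `n1@HA` = rnorm(n), `n2@HA` = rnorm(n))
  sweep <- budget_sweep(regressor_spec("linear"), data, budgets = 2:3,
                        seed = 5)
  expect_equal(nrow(sweep), 2)
  expect_gte(sweep$accuracy_mean[sweep$budget == 3],
             sweep$accuracy_mean[sweep$budget == 2])
})

test_that("the trained index reaches the printed error regime on 21 rats", {
  cohort <- gen_planted_cohort(burndex_summary(),
                               group_sizes = c(`0` = 7, `20` = 7, `40` = 7),
                               seed = 12)
  planted <- attr(cohort, "planted")
  idx <- train_index(regressor_spec("mlp", seed = 12), cohort, planted)
  expect_lt(idx$training_rae, 15)
  preds <- predict(idx, cohort)
  expect_equal(length(preds), 21)
  expect_true(all(is.finite(preds)))
})
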