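#' Relative absolute error
#'
#' `RAE = 100 * sum(|prediction - actual|) / sum(|baseline - actual|)` --
#' the summed absolute error as a percentage of the error of always
#' predicting the baseline (by default the mean of the actuals). The
#' companion accuracy figure is `100 - RAE`.
#'
#' @param predictions,actuals Equal-length numeric vectors.
#' @param baseline Reference prediction; defaults to `mean(actuals)`. In
#'   cross-validation the training-fold mean is used.
#' @return RAE in percent (>= 0; unbounded above).
#' @export
#' @examples
#' rae(c(1, 2, 3), c(1, 2, 3)) # perfect -> 0
rae <- function(predictions, actuals, baseline = mean(actuals)) {
  if (length(predictions) != length(actuals) || length(actuals) < 1) {
    abort("predictions and actuals must be equal-length, non-empty")
  }
  if (!is.finite(baseline)) abort("baseline must be finite")
  den <- sum(abs(baseline - actuals))
  if (den == 0) abort("constant actuals: RAE baseline denominator is zero")
  100 * sum(abs(predictions - actuals)) / den
}

#' Specify a regression model for the severity index
#'
#' @param kind One of `"linear"` (ordinary least squares),
#'   `"mlp"` (single-hidden-layer perceptron via nnet: logistic hidden
#'   units, identity output, standardized inputs), `"rbf_network"`
#'   (normalized Gaussian radial basis functions on k-means centres with a
#'   ridge readout), `"svr"` (linear-kernel support vector regression via
#'   e1071) or `"model_tree"` (variance-reduction splits with linear leaf
#'   models).
#' @param seed Seed for any randomized element of training.
#' @param ... Hyperparameter overrides: `hidden` (mlp units, default
#'   `ceiling((p+1)/2)`), `maxit` (500), `decay` (1e-4), `centers` (rbf, 2),
#'   `ridge` (1e-6), `cost` (svr, 1), `epsilon` (1e-3), `minbucket` (model
#'   tree, 4).
#' @return An object of class `burndex_regressor`.
#' @export
regressor_spec <- function(kind = c("linear", "mlp", "rbf_network", "svr",
                                    "model_tree"),
                           seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- list(hidden = NULL, maxit = 500L, decay = 1e-4,
                   centers = 2L, ridge = 1e-6,
                   cost = 1, epsilon = 1e-3, minbucket = 4L)
  params <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "burndex_regressor")
}

as_x_matrix <- function(data, variables) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) {
    abort(paste0("variables not in data: ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(data[variables])
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("model inputs must be finite numeric (impute first)")
  }
  X
}

scale_info <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
apply_scale <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

fit_regressor <- function(spec, X, y) {
  stopifnot(inherits(spec, "burndex_regressor"))
  p <- ncol(X)
  fit <- switch(spec$kind,
    linear = {
      qrx <- qr(cbind(1, X))
      beta <- qr.coef(qrx, y)
      beta[is.na(beta)] <- 0
      list(beta = beta)
    },
    mlp = {
      sc <- scale_info(X)
      hidden <- spec$params$hidden %||% ceiling((p + 1) / 2)
      set.seed(derive_seed(spec$seed, "mlp"))
      net <- nnet::nnet(apply_scale(X, sc), y, size = hidden, linout = TRUE,
                        maxit = spec$params$maxit, decay = spec$params$decay,
                        trace = FALSE)
      list(net = net, sc = sc)
    },
    rbf_network = {
      sc <- scale_info(X)
      Xs <- apply_scale(X, sc)
      k <- min(spec$params$centers, nrow(unique(as.data.frame(Xs))))
      set.seed(derive_seed(spec$seed, "rbf"))
      km <- lloyd_once(Xs, k)
      centers <- km$centroids
      # basis width: RMS within-cluster spread, floored (WEKA-style)
      sigma <- max(sqrt(km$within_ss / nrow(Xs)), 0.1)
      Phi <- rbf_design(Xs, centers, sigma)
      lambda <- spec$params$ridge
      w <- solve(crossprod(Phi) + lambda * diag(ncol(Phi)), crossprod(Phi, y))
      list(centers = centers, sigma = sigma, w = w, sc = sc)
    },
    svr = {
      set.seed(derive_seed(spec$seed, "svr"))
      list(svm = e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                            cost = spec$params$cost,
                            epsilon = spec$params$epsilon, scale = TRUE))
    },
    model_tree = {
      list(tree = grow_model_tree(X, y, minbucket = spec$params$minbucket))
    }
  )
  structure(list(kind = spec$kind, fit = fit, variables = colnames(X)),
            class = "burndex_fit")
}

predict_regressor <- function(object, X) {
  X <- X[, object$variables, drop = FALSE]
  f <- object$fit
  switch(object$kind,
    linear = as.numeric(cbind(1, X) %*% f$beta),
    mlp = as.numeric(predict(f$net, apply_scale(X, f$sc))),
    rbf_network = as.numeric(rbf_design(apply_scale(X, f$sc), f$centers,
                                        f$sigma) %*% f$w),
    svr = as.numeric(predict(f$svm, X)),
    model_tree = predict_model_tree(f$tree, X)
  )
}

# Normalized Gaussian design matrix: bases sum to one across centres.
rbf_design <- function(X, centers, sigma) {
  D2 <- point_center_dist2(X, centers)
  G <- exp(-D2 / (2 * sigma^2))
  rs <- rowSums(G)
  rs[rs == 0] <- 1
  G / rs
}

# Minimal M5-style model tree: greedy variance-reduction splits on single
# variables, linear least-squares models in the leaves (leaf mean when the
# leaf is too small to support a regression).
grow_model_tree <- function(X, y, minbucket = 4, depth = 0, max_depth = 10) {
  n <- nrow(X)
  make_leaf <- function() {
    if (n >= ncol(X) + 2) {
      qrx <- qr(cbind(1, X))
      beta <- qr.coef(qrx, y)
      beta[is.na(beta)] <- 0
      list(type = "leaf", beta = beta)
    } else {
      list(type = "leaf", beta = c(mean(y), rep(0, ncol(X))))
    }
  }
  if (n < 2 * minbucket || depth >= max_depth || var(y) == 0) {
    return(make_leaf())
  }
  sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  best <- list(gain = 0)
  total <- sse(y)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    cuts <- (head(xs, -1) + tail(xs, -1)) / 2
    for (cut in cuts) {
      left <- X[, j] <= cut
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      gain <- total - sse(y[left]) - sse(y[!left])
      if (gain > best$gain) best <- list(gain = gain, j = j, cut = cut)
    }
  }
  if (best$gain <= 1e-12) return(make_leaf())
  left <- X[, best$j] <= best$cut
  list(type = "node", j = best$j, cut = best$cut,
       left = grow_model_tree(X[left, , drop = FALSE], y[left], minbucket,
                              depth + 1, max_depth),
       right = grow_model_tree(X[!left, , drop = FALSE], y[!left], minbucket,
                               depth + 1, max_depth))
}

predict_model_tree <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- tree
    while (node$type == "node") {
      node <- if (X[i, node$j] <= node$cut) node$left else node$right
    }
    as.numeric(c(1, X[i, ]) %*% node$beta)
  }, numeric(1))
}

#' Repeated k-fold cross-validated relative accuracy
#'
#' For each repetition a fresh random partition into `folds` folds is drawn
#' and the model is retrained with fresh seeds on each training split.
#' Held-out absolute errors are pooled over the folds of a repetition, and
#' the RAE denominator uses each fold's training-set mean as the baseline.
#' The report gives per-repetition RAE and accuracy (`100 - RAE`) and their
#' mean and sd across repetitions.
#'
#' @param spec A [regressor_spec()].
#' @param data A cohort tibble with the `tbsa` target.
#' @param variables Character vector of predictor columns.
#' @param folds Number of folds (default 10).
#' @param reps Number of repetitions (default 5).
#' @param seed Seed controlling partitions and model seeds.
#' @return An object of class `burndex_cv`.
#' @export
cross_validate <- function(spec, data, variables, folds = 10, reps = 5,
                           seed = 1L) {
  X <- as_x_matrix(data, variables)
  y <- data$tbsa
  n <- length(y)
  if (n < folds) abort("need at least as many rats as folds")
  per_rep <- vapply(seq_len(reps), function(r) {
    set.seed(derive_seed(seed, paste0("cv_rep", r)))
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    num <- 0
    den <- 0
    for (f in seq_len(folds)) {
      test <- fold_id == f
      if (all(test)) abort("fold with no training instances")
      rspec <- spec
      rspec$seed <- derive_seed(seed, paste0("fit_r", r, "f", f))
      fit <- fit_regressor(rspec, X[!test, , drop = FALSE], y[!test])
      pred <- predict_regressor(fit, X[test, , drop = FALSE])
      num <- num + sum(abs(pred - y[test]))
      den <- den + sum(abs(mean(y[!test]) - y[test]))
    }
    if (den == 0) abort("constant training targets in every fold")
    100 * num / den
  }, numeric(1))
  reps_tbl <- tibble::tibble(rep = seq_len(reps), rae = per_rep,
                             accuracy = 100 - per_rep)
  structure(list(
    kind = spec$kind, variables = variables, folds = folds, reps = reps,
    seed = seed, repetitions = reps_tbl,
    accuracy_mean = mean(reps_tbl$accuracy),
    accuracy_sd = sd(reps_tbl$accuracy),
    rae_mean = mean(reps_tbl$rae)
  ), class = "burndex_cv")
}

#' @export
print.burndex_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold CV of %s on {%s}\n", x$reps, x$folds, x$kind,
              paste(x$variables, collapse = ", ")))
  cat(sprintf("  relative accuracy: %.2f +/- %.2f (RAE %.2f%%)\n",
              x$accuracy_mean, x$accuracy_sd, x$rae_mean))
  invisible(x)
}

#' @export
tidy.burndex_cv <- function(x, ...) x$repetitions

#' @export
glance.burndex_cv <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_variables = length(x$variables),
                 folds = x$folds, reps = x$reps,
                 accuracy_mean = x$accuracy_mean,
                 accuracy_sd = x$accuracy_sd, rae_mean = x$rae_mean)
}

#' Genetic-algorithm parameters for wrapper selection
#'
#' @param pop_size Population size (default 20).
#' @param generations Number of generations (default 20).
#' @param crossover_rate Single-point crossover probability (default 0.6).
#' @param mutation_rate Per-bit mutation probability; default
#'   `1 / n_candidates`.
#' @param init_rate Per-bit inclusion probability of the initial population
#'   (default 0.5). The union of the final population forms the pool the
#'   best-first stage searches, so a dense initialization keeps candidate
#'   coverage broad even when the genetic phase drifts.
#' @param elitism Number of elites copied unchanged (default 1).
#' @param cv_reps,cv_folds Cross-validation effort used for the fitness
#'   function (defaults 5 and 10, matching the study's five 10-fold
#'   cross-validations; lower `cv_reps` trades selection reliability for
#'   speed).
#' @param stale_limit Best-first search stops after this many consecutive
#'   non-improving expansions (default 5).
#' @param pool Which variables the best-first stage may use: `"seen"`
#'   (default; every variable the genetic phase evaluated in any
#'   individual) or `"population"` (only variables surviving in the final
#'   population -- a narrower, more aggressive pruning that can drop
#'   informative variables by drift).
#' @return A list of class `burndex_gaparams`.
#' @export
ga_params <- function(pop_size = 20, generations = 20, crossover_rate = 0.6,
                      mutation_rate = NULL, init_rate = NULL, elitism = 1,
                      cv_reps = 5, cv_folds = 10, stale_limit = 5,
                      pool = c("seen", "population")) {
  structure(list(pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, init_rate = init_rate,
                 elitism = elitism,
                 cv_reps = cv_reps, cv_folds = cv_folds,
                 stale_limit = stale_limit, pool = match.arg(pool)),
            class = "burndex_gaparams")
}

#' Wrapper variable selection: genetic algorithm + best-first ranking
#'
#' A genetic algorithm over variable bitmasks, with cross-validated relative
#' accuracy as the fitness, identifies a strong variable pool; a forward
#' best-first search with backtracking (stopping after `stale_limit`
#' non-improving expansions) then ranks within that pool and returns exactly
#' `budget` variables. All randomness is derived from `seed`; identical
#' seeds give identical selections.
#'
#' @param spec A [regressor_spec()] used to score candidate subsets.
#' @param data A cohort tibble with the `tbsa` target.
#' @param budget Number of variables to select.
#' @param candidates Candidate columns (default: all measurement columns).
#' @param ga A [ga_params()].
#' @param seed Master seed for the search.
#' @return An object of class `burndex_selection`: `variables` (ordered),
#'   `cv` (full 5 x 10-fold report on the final set), `log` (evaluated
#'   subsets), `model`.
#' @export
select_variables <- function(spec, data, budget,
                             candidates = measurement_cols(data),
                             ga = ga_params(), seed = 1L) {
  if (budget < 1) abort("budget must be >= 1")
  if (budget > length(candidates)) abort("budget exceeds candidate count")
  final_cv <- function(vars) {
    cross_validate(spec, data, vars, folds = min(ga$cv_folds, nrow(data)),
                   reps = 5, seed = derive_seed(seed, "final_cv"))
  }
  if (budget == length(candidates)) {
    return(structure(list(model = spec, variables = candidates,
                          cv = final_cv(candidates),
                          log = tibble::tibble(phase = character(0),
                                               subset = character(0),
                                               fitness = numeric(0)),
                          budget = budget, seed = seed),
                     class = "burndex_selection"))
  }

  n_cand <- length(candidates)
  mut_rate <- ga$mutation_rate %||% (1 / n_cand)
  cache <- new.env(parent = emptyenv())
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  fitness <- function(idx, phase) {
    idx <- sort(idx)
    if (length(idx) == 0L) return(-Inf)
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cv <- cross_validate(spec, data, candidates[idx],
                         folds = min(ga$cv_folds, nrow(data)),
                         reps = ga$cv_reps,
                         seed = derive_seed(seed, "fitness"))
    val <- cv$accuracy_mean
    cache[[key]] <- val
    log_env$rows[[length(log_env$rows) + 1L]] <-
      tibble::tibble(phase = phase, subset = key, fitness = val)
    val
  }

  ## --- genetic algorithm over bitmasks ---
  set.seed(derive_seed(seed, "ga"))
  init_rate <- ga$init_rate %||% 0.5
  ensure_nonempty <- function(bits) {
    if (!any(bits)) bits[sample.int(n_cand, 1)] <- TRUE
    bits
  }
  pop <- lapply(seq_len(ga$pop_size), function(i)
    ensure_nonempty(runif(n_cand) < init_rate))
  best_bits <- NULL
  best_fit <- -Inf
  seen <- rep(FALSE, n_cand)
  for (gen in seq_len(ga$generations)) {
    for (b in pop) seen <- seen | b
    fits <- vapply(pop, function(b) fitness(which(b), "ga"), numeric(1))
    ord <- order(fits, decreasing = TRUE)
    if (fits[ord[1]] > best_fit) {
      best_fit <- fits[ord[1]]
      best_bits <- pop[[ord[1]]]
    }
    if (gen == ga$generations) break
    elite <- pop[ord[seq_len(ga$elitism)]]
    tournament <- function() {
      ij <- sample.int(ga$pop_size, 2)
      pop[[ij[which.max(fits[ij])]]]
    }
    children <- list()
    while (length(children) < ga$pop_size - ga$elitism) {
      p1 <- tournament()
      p2 <- tournament()
      child <- if (runif(1) < ga$crossover_rate && n_cand > 1) {
        cut <- sample.int(n_cand - 1, 1)
        c(p1[seq_len(cut)], p2[(cut + 1):n_cand])
      } else p1
      flip <- runif(n_cand) < mut_rate
      child[flip] <- !child[flip]
      children[[length(children) + 1L]] <- ensure_nonempty(child)
    }
    pop <- c(elite, children)
  }

  ## --- pool for the ranking stage ---
  pool <- switch(ga$pool %||% "seen",
    seen = which(seen),
    population = {
      freq <- colSums(do.call(rbind, pop))
      union(which(best_bits), which(freq > 0))
    },
    abort("unknown pool mode"))
  if (length(pool) < budget) {
    pool <- c(pool, setdiff(seq_len(n_cand), pool))[seq_len(budget)]
  }

  ## --- best-first forward search with backtracking, capped at budget ---
  open <- list(list(idx = integer(0), fit = -Inf))
  closed <- character(0)
  best_state <- NULL   # best state of exactly `budget` variables
  best_any <- -Inf
  stale <- 0L
  while (length(open) > 0 && stale < ga$stale_limit) {
    scores <- vapply(open, `[[`, numeric(1), "fit")
    at <- which.max(scores)
    node <- open[[at]]
    open[[at]] <- NULL
    if (length(node$idx) >= budget) next # leaf: nothing to expand
    key <- paste(sort(node$idx), collapse = ",")
    if (key %in% closed) next
    closed <- c(closed, key)
    improved <- FALSE
    for (v in setdiff(pool, node$idx)) {
      child_idx <- c(node$idx, v)
      fit <- fitness(child_idx, "best_first")
      if (fit > best_any) {
        best_any <- fit
        improved <- TRUE
      }
      if (length(child_idx) == budget &&
          (is.null(best_state) || fit > best_state$fit)) {
        best_state <- list(idx = child_idx, fit = fit)
      }
      open[[length(open) + 1L]] <- list(idx = child_idx, fit = fit)
    }
    stale <- if (improved) 0L else stale + 1L
  }
  if (is.null(best_state)) {
    # search stalled before reaching the budget: complete greedily
    idx <- integer(0)
    while (length(idx) < budget) {
      cand <- setdiff(pool, idx)
      fits <- vapply(cand, function(v) fitness(c(idx, v), "greedy_fill"),
                     numeric(1))
      idx <- c(idx, cand[which.max(fits)])
    }
    best_state <- list(idx = idx, fit = max(fits))
  }

  selected <- candidates[best_state$idx]
  structure(list(model = spec, variables = selected,
                 cv = final_cv(selected),
                 log = dplyr::bind_rows(log_env$rows),
                 budget = budget, seed = seed),
            class = "burndex_selection")
}

#' @export
print.burndex_selection <- function(x, ...) {
  cat("Wrapper variable selection (", x$model$kind, ", budget ", x$budget,
      ")\n", sep = "")
  cat("  selected:", paste(x$variables, collapse = ", "), "\n")
  cat(sprintf("  CV relative accuracy: %.2f +/- %.2f\n",
              x$cv$accuracy_mean, x$cv$accuracy_sd))
  invisible(x)
}

#' @export
tidy.burndex_selection <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$variables), variable = x$variables)
}

#' @export
glance.burndex_selection <- function(x, ...) {
  tibble::tibble(kind = x$model$kind, budget = x$budget,
                 variables = paste(x$variables, collapse = "; "),
                 accuracy_mean = x$cv$accuracy_mean,
                 accuracy_sd = x$cv$accuracy_sd)
}

#' Compare regression models under a fixed variable budget
#'
#' Runs [select_variables()] for each model and tabulates the results,
#' sorted by ascending cross-validated accuracy.
#'
#' @param specs A list of [regressor_spec()] objects.
#' @param data A cohort tibble.
#' @param budget Variable budget shared by all models.
#' @param ... Passed to [select_variables()].
#' @return A tibble (one row per model) with the full selection objects in
#'   the `selection` list-column.
#' @export
compare_models <- function(specs, data, budget, ...) {
  if (length(specs) < 1) abort("at least one model is required")
  sels <- purrr::map(specs, function(sp)
    select_variables(sp, data, budget, ...))
  out <- purrr::map_dfr(sels, glance)
  out$selection <- sels
  dplyr::arrange(out, .data$accuracy_mean)
}

#' Accuracy as a function of the variable budget
#'
#' @param spec A [regressor_spec()].
#' @param data A cohort tibble.
#' @param budgets Budgets to evaluate (default 2..5).
#' @param ... Passed to [select_variables()].
#' @return A tibble, one row per budget, with selections in a list-column.
#'   Accuracy need not be monotone in the budget (overfitting).
#' @export
budget_sweep <- function(spec, data, budgets = 2:5, ...) {
  sels <- purrr::map(budgets, function(b)
    select_variables(spec, data, b, ...))
  out <- purrr::map_dfr(sels, glance)
  out$selection <- sels
  out
}

#' Train the final severity index on all data
#'
#' @param spec A [regressor_spec()].
#' @param data An imputed cohort tibble.
#' @param variables Predictor columns of the index.
#' @return An object of class `burndex_index` with a [predict()] method.
#'   Predictions are unclipped real %TBSA values (may be slightly negative).
#' @export
train_index <- function(spec, data, variables) {
  X <- as_x_matrix(data, variables)
  y <- data$tbsa
  fit <- fit_regressor(spec, X, y)
  pred <- predict_regressor(fit, X)
  structure(list(model = spec, variables = variables, fit = fit,
                 training_rae = rae(pred, y),
                 n_train = length(y)),
            class = "burndex_index")
}

#' @export
predict.burndex_index <- function(object, newdata, ...) {
  predict_regressor(object$fit, as_x_matrix(newdata, object$variables))
}

#' @export
print.burndex_index <- function(x, ...) {
  cat("Burn-severity index (", x$model$kind, ") on ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  cat(sprintf("  training RAE: %.2f%% (n = %d)\n", x$training_rae, x$n_train))
  invisible(x)
}

#' @export
glance.burndex_index <- function(x, ...) {
  tibble::tibble(kind = x$model$kind,
                 variables = paste(x$variables, collapse = "; "),
                 training_rae = x$training_rae,
                 training_accuracy = 100 - x$training_rae,
                 n_train = x$n_train)
}
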