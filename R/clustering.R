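#' Clustering configuration
#'
#' @param k_range Candidate numbers of clusters (default 2..8).
#' @param replicates Random restarts per k; the best restart by
#'   within-cluster sum of squares is kept. The study reports that cluster
#'   centroids changed negligibly between clustering runs; 100 restarts
#'   reproduce that run-to-run stability on the packaged profiles (the
#'   study's reported floor of >10 leaves visible restart noise).
#' @param seed RNG seed; restart initializations derive from it.
#' @param silhouette_gain_threshold Relative mean-silhouette gain below which
#'   adding clusters is considered marginal (default 0.05; the study treated
#'   a 2.2% gain as marginal).
#' @param metric Distance used for silhouettes: `"euclidean"` (default) or
#'   `"sqeuclidean"`.
#' @return A list of class `burndex_clusterconfig`.
#' @export
cluster_config <- function(k_range = 2:8, replicates = 100, seed = 1L,
                           silhouette_gain_threshold = 0.05,
                           metric = c("euclidean", "sqeuclidean")) {
  stopifnot(replicates >= 1, all(k_range >= 1))
  structure(list(k_range = sort(unique(as.integer(k_range))),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 silhouette_gain_threshold = silhouette_gain_threshold,
                 metric = match.arg(metric)),
            class = "burndex_clusterconfig")
}

# Lloyd's algorithm with random-distinct-row initialization and farthest-point
# reseeding of empty clusters. X: n x d matrix. Returns assignment, centroids,
# within-cluster sum of squared distances.
lloyd_once <- function(X, k, iter_max = 200) {
  n <- nrow(X)
  C <- X[sample(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    D2 <- point_center_dist2(X, C)
    a <- max.col(-D2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(a))
    if (length(empty)) {
      dmin <- apply(D2, 1, min)
      for (j in empty) {
        # reseed from the farthest point whose cluster can spare it
        dmin[tabulate(a, k)[a] <= 1] <- -Inf
        far <- which.max(dmin)
        a[far] <- j
        dmin[far] <- -Inf
      }
    }
    if (identical(a, assign_old)) break
    assign_old <- a
    v <- vapply(seq_len(k), function(j)
      colMeans(X[a == j, , drop = FALSE]), numeric(ncol(X)))
    C <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  }
  D2 <- point_center_dist2(X, C)
  wss <- sum(D2[cbind(seq_len(n), a)])
  list(assignment = a, centroids = C, within_ss = wss)
}

# squared Euclidean distances between rows of X and rows of C
point_center_dist2 <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

#' K-means clustering of dose-response profiles
#'
#' Euclidean k-means (Lloyd iterations) initialized from random distinct
#' profiles, run `replicates` times; the restart with the smallest
#' within-cluster sum of squared distances is kept. Empty clusters are
#' reseeded from the point farthest from its centroid. Fully deterministic
#' given the config seed.
#'
#' @param profiles A long profile tibble ([group_profiles()],
#'   [profiles_from_summary()]) or a numeric matrix of profiles.
#' @param k Number of clusters.
#' @param config A [cluster_config()].
#' @return An object of class `burndex_clustering`: `k`, `assignment` tibble
#'   (`variable`, `cluster`, `silhouette`), `centroids` (k x levels matrix),
#'   `within_ss`, `mean_silhouette`.
#' @export
kmeans_profiles <- function(profiles, k, config = cluster_config()) {
  X <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (k > nrow(unique(as.data.frame(X)))) {
    abort("k exceeds the number of distinct profiles")
  }
  set.seed(derive_seed(config$seed, paste0("kmeans_k", k)))
  best <- NULL
  for (r in seq_len(config$replicates)) {
    fit <- lloyd_once(X, k)
    if (is.null(best) || fit$within_ss < best$within_ss) best <- fit
  }
  sil <- if (k >= 2) {
    silhouette_values(X, best$assignment, metric = config$metric)
  } else {
    rep(NA_real_, nrow(X))
  }
  structure(list(
    k = k,
    assignment = tibble::tibble(variable = rownames(X) %||%
                                  as.character(seq_len(nrow(X))),
                                cluster = best$assignment,
                                silhouette = sil),
    centroids = best$centroids,
    within_ss = best$within_ss,
    mean_silhouette = if (k >= 2) mean(sil) else NA_real_,
    config = config
  ), class = "burndex_clustering")
}

#' @export
print.burndex_clustering <- function(x, ...) {
  cat("K-means clustering of dose-response profiles\n")
  cat("  k =", x$k, "  within_ss =", signif(x$within_ss, 6),
      "  mean silhouette =", signif(x$mean_silhouette, 4), "\n")
  cat("  cluster sizes:", paste(tabulate(x$assignment$cluster, x$k),
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.burndex_clustering <- function(x, ...) x$assignment

#' @export
glance.burndex_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, within_ss = x$within_ss,
                 mean_silhouette = x$mean_silhouette)
}

#' Silhouette values
#'
#' The standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where
#' `a(i)` is the mean distance of point i to its own cluster's other members
#' and `b(i)` the smallest mean distance to another cluster. Members of
#' singleton clusters score 0 (declared convention).
#'
#' @param x A numeric matrix (rows = points) or long profile tibble.
#' @param assignment Integer cluster assignment, one entry per point.
#' @param metric `"euclidean"` (default) or `"sqeuclidean"`.
#' @return Numeric vector of silhouettes in `[-1, 1]`.
#' @export
silhouette_values <- function(x, assignment,
                              metric = c("euclidean", "sqeuclidean")) {
  metric <- match.arg(metric)
  X <- if (is.matrix(x)) x else profile_matrix(x)
  if (length(assignment) != nrow(X)) {
    abort("assignment length must match the number of profiles")
  }
  if (length(unique(assignment)) < 2) {
    abort("silhouettes require at least two clusters")
  }
  D <- as.matrix(stats::dist(X))
  if (metric == "sqeuclidean") D <- D^2
  n <- nrow(X)
  ks <- sort(unique(assignment))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    own <- own[own != i]
    if (length(own) == 0L) { s[i] <- 0; next }
    a_i <- mean(D[i, own])
    b_i <- min(vapply(setdiff(ks, assignment[i]),
                      function(j) mean(D[i, assignment == j]), numeric(1)))
    m <- max(a_i, b_i)
    s[i] <- if (m == 0) 0 else (b_i - a_i) / m
  }
  s
}

#' Scan candidate numbers of clusters
#'
#' Runs [kmeans_profiles()] at every k in the config's range and collects the
#' elbow curve (within-cluster sum of squares) and the mean silhouette of the
#' best restart at each k.
#'
#' @param profiles Long profile tibble or matrix.
#' @param config A [cluster_config()].
#' @return A tibble of class `burndex_kscan`: `k`, `within_ss`,
#'   `mean_silhouette`.
#' @export
scan_k <- function(profiles, config = cluster_config()) {
  X <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  res <- purrr::map_dfr(config$k_range, function(k) {
    glance(kmeans_profiles(X, k, config))
  })
  inc <- which(diff(res$within_ss) > 1e-8)
  if (length(inc)) {
    warn(paste0("within_ss increased between k=", res$k[inc[1]], " and k=",
                res$k[inc[1] + 1], "; consider more replicates"))
  }
  class(res) <- c("burndex_kscan", class(res))
  attr(res, "config") <- config
  res
}

#' Choose the number of clusters from a k-scan
#'
#' Formalizes the tandem elbow/silhouette rule: the chosen k is the smallest
#' k at which the mean-silhouette curve turns from rising to flat -- the
#' relative gain into k, `(s(k) - s(k-1)) / s(k-1)`, is at least `threshold`
#' while the forward gain, `(s(k+1) - s(k)) / s(k)`, falls below it -- and
#' the clustering error is still decreasing. A silhouette peak after a
#' substantial rise qualifies automatically (its forward gain is negative).
#' If no k qualifies (e.g. the curve falls from the start, or rises slowly
#' everywhere) the scan's silhouette argmax is returned with a warning.
#' Ties break toward smaller k.
#'
#' @param scan A [scan_k()] result (at least 3 k values).
#' @param threshold Relative-gain threshold; defaults to the scan config's
#'   `silhouette_gain_threshold`.
#' @return The chosen k (integer).
#' @export
choose_k <- function(scan, threshold = NULL) {
  if (nrow(scan) < 3) abort("scan must cover at least 3 values of k")
  cfg <- attr(scan, "config")
  threshold <- threshold %||% cfg$silhouette_gain_threshold %||% 0.05
  s <- scan$mean_silhouette
  k <- scan$k
  w <- scan$within_ss
  for (i in 2:(length(k) - 1)) {
    if (s[i - 1] <= 0 || s[i] <= 0) next # no meaningful separation yet
    prev_gain <- (s[i] - s[i - 1]) / s[i - 1]
    fwd_gain <- (s[i + 1] - s[i]) / s[i]
    if (w[i] < w[i - 1] && prev_gain >= threshold && fwd_gain < threshold) {
      return(k[i])
    }
  }
  warn("no silhouette elbow found; returning silhouette argmax")
  k[which.max(s)]
}

#' Elbow and silhouette curves for a k-scan
#'
#' @param scan A [scan_k()] result.
#' @return A ggplot with one panel per criterion.
#' @export
plot_kscan <- function(scan) {
  long <- tidyr::pivot_longer(tibble::as_tibble(scan), -"k",
                              names_to = "criterion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of clusters",
                  y = NULL,
                  title = "Cluster-number selection: elbow and silhouette") +
    ggplot2::theme_minimal()
}

#' Centroid dose-response patterns of a clustering
#'
#' @param clustering A `burndex_clustering`.
#' @param profiles The profile tibble the clustering was fitted on.
#' @return A ggplot of member profiles (thin) and centroids (thick) per
#'   cluster.
#' @export
plot_centroids <- function(clustering, profiles) {
  assign_tbl <- clustering$assignment
  df <- dplyr::left_join(profiles, assign_tbl, by = "variable")
  cent <- df |>
    dplyr::group_by(.data$cluster, .data$tbsa) |>
    dplyr::summarise(normalized = median(.data$normalized), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tbsa, y = .data$normalized)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$variable),
                       alpha = 0.2, colour = "grey40") +
    ggplot2::geom_line(data = cent, colour = "firebrick", linewidth = 1.2) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "%TBSA", y = "normalized response",
                  title = "Dose-response clusters and centroid patterns") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.burndex_kscan <- function(object, ...) plot_kscan(object)
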