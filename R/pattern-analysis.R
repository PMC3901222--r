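#' Cluster-centroid matrix
#'
#' One column per cluster, one row per dose level; each entry is the cluster
#' median of its members' normalized responses at that level.
#'
#' @param profiles A long profile tibble.
#' @param assignment A tibble with `variable` and `cluster` columns (e.g.
#'   `tidy()` of a clustering, or the published labels).
#' @return A levels x k numeric matrix with entries in `[-1, 1]`; column
#'   names are the cluster ids.
#' @export
centroid_matrix <- function(profiles, assignment) {
  df <- dplyr::inner_join(profiles, assignment[, c("variable", "cluster")],
                          by = "variable")
  clusters <- sort(unique(assignment$cluster))
  empty <- clusters[!clusters %in% df$cluster]
  if (length(empty)) {
    abort(paste0("empty cluster(s): ", paste(empty, collapse = ", ")))
  }
  levels <- sort(unique(df$tbsa))
  m <- vapply(clusters, function(cl) {
    vapply(levels, function(lv)
      median(df$normalized[df$cluster == cl & df$tbsa == lv]), numeric(1))
  }, numeric(length(levels)))
  dimnames(m) <- list(levels, clusters)
  m
}

#' Count independent dose-response patterns by SVD
#'
#' Singular value decomposition of the (uncentred) centroid matrix. A
#' pattern counts as independent when its singular value is non-negligible:
#' greater than `tol` in absolute terms and carrying more than `energy_floor`
#' of the squared-singular-value mass (patterns below that share are within
#' the margin of error of the clustering). Retained singular values within
#' `tol` of each other are merged greedily top-down and counted once.
#'
#' @param cm A centroid matrix ([centroid_matrix()]).
#' @param tol Absolute nonzero threshold on singular values (default 1e-2).
#' @param energy_floor Minimum share of squared-singular-value mass for a
#'   pattern to count (default 0.02).
#' @param total How explained fractions are computed: `"energy"` (squared
#'   singular values, default) or `"linear"` (plain singular values).
#' @return An object of class `burndex_patterns`: `singular_values`
#'   (descending), `n_independent`, `explained_fraction` (cumulative, by
#'   component), `dominant_clusters` (ids with the largest loadings on the
#'   top components).
#' @export
svd_patterns <- function(cm, tol = 1e-2, energy_floor = 0.02,
                         total = c("energy", "linear")) {
  total <- match.arg(total)
  if (!all(is.finite(cm))) abort("centroid matrix must be finite")
  dec <- svd(cm)
  sv <- dec$d
  mass <- if (total == "energy") sv^2 else sv
  share <- if (sum(mass) == 0) rep(0, length(sv)) else mass / sum(mass)
  keep <- which(sv > tol & share > energy_floor)
  # merge retained values that are indistinct (within tol), top-down
  n_ind <- 0L
  last <- Inf
  for (i in keep) {
    if (last - sv[i] > tol) n_ind <- n_ind + 1L
    last <- sv[i]
  }
  # clusters carrying the most energy in the top singular subspace
  dominant <- if (n_ind > 0) {
    top <- seq_len(min(n_ind, length(sv)))
    wt <- colSums((sv[top] * t(dec$v[, top, drop = FALSE]))^2)
    ids <- colnames(cm) %||% as.character(seq_len(ncol(cm)))
    ids[order(wt, decreasing = TRUE)][top]
  } else character(0)
  structure(list(
    singular_values = sv,
    n_independent = n_ind,
    explained_fraction = cumsum(share),
    dominant_clusters = unique(dominant),
    tol = tol, energy_floor = energy_floor, total = total
  ), class = "burndex_patterns")
}

#' @export
print.burndex_patterns <- function(x, ...) {
  cat("Independent dose-response patterns (SVD of cluster centroids)\n")
  cat("  singular values:", paste(signif(x$singular_values, 5),
                                  collapse = ", "), "\n")
  cat("  independent patterns:", x$n_independent, "\n")
  cat(sprintf("  top-%d explained fraction: %.2f%%\n", x$n_independent,
              100 * x$explained_fraction[max(x$n_independent, 1)]))
  if (length(x$dominant_clusters)) {
    cat("  dominant clusters:", paste(x$dominant_clusters, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.burndex_patterns <- function(x, ...) {
  tibble::tibble(component = seq_along(x$singular_values),
                 singular_value = x$singular_values,
                 explained_fraction = x$explained_fraction)
}

#' @export
glance.burndex_patterns <- function(x, ...) {
  tibble::tibble(n_independent = x$n_independent,
                 top_explained_fraction =
                   x$explained_fraction[max(x$n_independent, 1)])
}

#' Analytes whose cluster changes between liver inlets and outlet
#'
#' Flags analytes assigned to the same cluster in both liver inflows
#' (hepatic artery and portal vein) but to a different cluster in the outflow
#' (suprahepatic vena cava) -- an indicator of altered liver handling under
#' increasing burn. Analytes missing any of the three vessels are skipped
#' with a warning.
#'
#' @param assignment A tibble with `variable` and `cluster` columns using
#'   `analyte@vessel` keys.
#' @return A tibble: `analyte`, `cluster_ha`, `cluster_pv`, `cluster_shvc`.
#' @export
cross_vessel_membership <- function(assignment) {
  keys <- split_var_key(assignment$variable)
  df <- tibble::tibble(analyte = keys$analyte,
                       compartment = keys$compartment,
                       cluster = assignment$cluster) |>
    dplyr::filter(.data$compartment %in% c("HA", "PV", "SHVC")) |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "cluster")
  for (v in c("HA", "PV", "SHVC")) if (!v %in% names(df)) df[[v]] <- NA
  incomplete <- df$analyte[!stats::complete.cases(df[, c("HA", "PV", "SHVC")])]
  if (length(incomplete)) {
    warn(paste0("skipping analyte(s) missing a vessel: ",
                paste(incomplete, collapse = "; ")))
  }
  df |>
    dplyr::filter(!is.na(.data$HA), !is.na(.data$PV), !is.na(.data$SHVC)) |>
    dplyr::filter(.data$HA == .data$PV, .data$SHVC != .data$HA) |>
    dplyr::transmute(.data$analyte, cluster_ha = .data$HA,
                     cluster_pv = .data$PV, cluster_shvc = .data$SHVC)
}

#' Cluster-membership census by compartment
#'
#' @param assignment A tibble with `variable` and `cluster` columns.
#' @return A contingency tibble of counts, one row per cluster plus a totals
#'   row, one column per compartment plus a `total` column.
#' @export
membership_census <- function(assignment) {
  keys <- split_var_key(assignment$variable)
  df <- tibble::tibble(cluster = assignment$cluster,
                       compartment = keys$compartment)
  counts <- df |>
    dplyr::count(.data$cluster, .data$compartment) |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$cluster)
  comp_cols <- setdiff(names(counts), "cluster")
  counts$total <- rowSums(counts[comp_cols])
  totals <- dplyr::summarise(counts, cluster = NA_integer_,
                             dplyr::across(dplyr::all_of(c(comp_cols, "total")),
                                           sum))
  dplyr::bind_rows(counts, totals)
}
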