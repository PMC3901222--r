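# Independent oracles and small data builders shared across tests.

# Brute-force silhouette: textbook double-loop formula over an explicit
# distance matrix, written independently of the package implementation.
brute_silhouette <- function(X, assignment) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(assignment == assignment[i]), i)
    if (length(same) == 0) { out[i] <- 0; next }
    a <- mean(D[i, same])
    b <- Inf
    for (cl in setdiff(unique(assignment), assignment[i])) {
      b <- min(b, mean(D[i, assignment == cl]))
    }
    out[i] <- (b - a) / max(a, b)
  }
  out
}

# Exhaustive k-means oracle: global minimum of the within-cluster sum of
# squared distances over every assignment of n points to k labels.
brute_kmeans_wss <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  grid <- rep(list(seq_len(k)), n)
  all_assign <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(all_assign))) {
    a <- as.integer(all_assign[r, ])
    if (length(unique(a)) < k) next
    wss <- 0
    for (cl in seq_len(k)) {
      pts <- X[a == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, wss)
  }
  best
}

# Small cohort with known content: 5 rats, 2 groups, 2 measurement columns.
toy_cohort <- function() {
  tibble::tibble(
    rat_id = sprintf("r%d", 1:6),
    tbsa = c(0, 0, 0, 20, 20, 20),
    `Glucose@HA` = c(10, 11, 12, 20, 21, 22),
    `Glucose@PV` = c(5, 6, NA, 8, 9, 10)
  )
}

# Quantile of a normal truncated at zero -- the generator's oracle family.
tnorm0_q <- function(p, mean, sd) {
  if (sd == 0) return(mean)
  alpha <- pnorm(0, mean, sd)
  qnorm(alpha + p * (1 - alpha), mean, sd)
}

# Cohort for selection tests: 2 complementary informative variables (one
# separates sham from burned, the other flags the top dose) among pure-noise
# candidates, so both are needed and the pair is uniquely best.
planted_selection_cohort <- function(n_noise = 48, n_per_group = 10,
                                     noise_sd = 1, seed = 1) {
  set.seed(seed)
  tbsa <- rep(c(0, 20, 40), each = n_per_group)
  n <- length(tbsa)
  info1 <- ifelse(tbsa > 0, 10, 0) + rnorm(n, 0, noise_sd)   # burn vs sham
  info2 <- ifelse(tbsa == 40, 10, 0) + rnorm(n, 0, noise_sd) # top dose flag
  noise <- matrix(rnorm(n * n_noise), n, n_noise)
  colnames(noise) <- sprintf("noise%02d@HA", seq_len(n_noise))
  dplyr::bind_cols(
    tibble::tibble(rat_id = sprintf("r%02d", seq_len(n)), tbsa = tbsa,
                   `signal_lin@HA` = info1, `signal_step@SHVC` = info2),
    tibble::as_tibble(noise)
  )
}

paper_assignment <- function() {
  summ <- burndex_summary()
  tibble::tibble(variable = paste0(summ$analyte, "@", summ$vessel),
                 cluster = summ$paper_cluster)
}
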