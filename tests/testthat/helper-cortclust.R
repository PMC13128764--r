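# Shared fixtures and independent oracles, all built in code.

# Deterministic sample with EXACT mean and sd (for moment-matched groups).
exact_moment_sample <- function(n, mean, sd) {
  z <- stats::qnorm(stats::ppoints(n))
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# Exhaustive-search oracle: minimum complete-data WCSS over every assignment
# of n rows to at most k clusters (feasible for n <= 8).
best_partition_wcss <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 8)
  assign <- rep(1L, n)
  best <- Inf
  repeat {
    w <- 0
    for (g in unique(assign)) {
      rows <- X[assign == g, , drop = FALSE]
      w <- w + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    best <- min(best, w)
    # odometer increment over k^n assignments
    i <- 1L
    while (i <= n && assign[i] == k) {
      assign[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Well-separated 3-cluster complete matrix used by several tests.
separated_matrix <- function(n_per = 6, t = 4, gap = 50, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, gap, 2 * gap), 3, t)
    X <- do.call(rbind, lapply(1:3, function(g) {
      matrix(stats::rnorm(n_per * t, centers[g, 1], sd), n_per, t)
    }))
    rownames(X) <- sprintf("P%02d", seq_len(nrow(X)))
    X
  })
}

# Tiny long-format measurement table on the 6-hourly grid.
toy_measurements <- function(values, hours = seq(6, by = 6,
                                                 length.out = length(values)),
                             id = "P1") {
  tibble::tibble(patient_id = id, hours = hours, cortisol = values)
}
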