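test_that("a single cluster on complete data gives column means and fit 0", {
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2)
  f <- kpod(X, 1, n_restarts = 2, seed = 1)
  expect_equal(unname(f$centroids[1, ]), colMeans(X))
  expect_equal(f$fit, 0)
  expect_equal(f$wcss, f$tss)
})

test_that("fit integrity matches the hand-computed toy example", {
  X <- matrix(c(0, 0, 0, 2, 10, 0, 10, 2), 4, 2, byrow = TRUE)
  fi <- fit_integrity(X, c(1, 1, 2, 2))
  expect_equal(fi$tss, 104)
  expect_equal(fi$wcss, 4)
  expect_equal(fi$fit, 25 / 26)
  expect_false(fi$degenerate)

  # singleton clusters: wcss 0, fit 1
  fi1 <- fit_integrity(X, 1:4)
  expect_equal(fi1$wcss, 0)
  expect_equal(fi1$fit, 1)

  # all values identical: degenerate, fit defined as 1
  fid <- fit_integrity(matrix(5, 3, 2), c(1, 1, 2))
  expect_true(fid$degenerate)
  expect_equal(fid$fit, 1)
})

test_that("k-POD recovers the enumeration-oracle partition on a 6x2 matrix", {
  X <- matrix(c(0, 0, 0.1, 0, 10, 10, 10.1, 10, 20, 0, 20, 0.1),
              6, 2, byrow = TRUE)
  f <- kpod(X, 3, n_restarts = 10, seed = 4)
  expect_equal(f$wcss, best_partition_wcss(X, 3), tolerance = 1e-9)
  part <- split(seq_len(6), f$assignments)
  expect_setequal(
    lapply(unname(part), as.integer),
    list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  )

  # delete one cell: same partition, and at the fixed point the completed
  # value equals the assigned centroid coordinate
  Xm <- X
  Xm[1, 2] <- NA
  fm <- kpod(Xm, 3, n_restarts = 10, seed = 4)
  partm <- split(seq_len(6), fm$assignments)
  expect_setequal(
    lapply(unname(partm), as.integer),
    list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  )
  g <- fm$assignments[1]
  expect_equal(unname(fm$completed[1, 2]),
               unname(fm$completed_centroids[g, 2]), tolerance = 1e-9)
})

test_that("best-of-restarts matches exhaustive-partition WCSS on small matrices", {
  hits <- 0
  trials <- 60
  for (i in seq_len(trials)) {
    X <- withr::with_seed(1000 + i, {
      n <- sample(4:8, 1)
      matrix(rnorm(n * 3), n, 3)
    })
    k <- if (nrow(X) > 4) sample(2:3, 1) else 2
    f <- kpod(X, k, n_restarts = 15, seed = i)
    oracle <- best_partition_wcss(X, k)
    if (abs(f$wcss - oracle) <= 1e-9) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.95)
})

test_that("the completed-data objective is non-increasing within every restart", {
  X <- separated_matrix(n_per = 8, sd = 5, seed = 2)
  X[sample(length(X), 15)] <- NA
  X[rowSums(!is.na(X)) == 0, 1] <- 0 # keep every row observed somewhere
  f <- kpod(X, 3, n_restarts = 10, seed = 6)
  for (tr in f$objective_traces) {
    expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("the recovered partition survives 20% MCAR deletion", {
  ok <- 0
  trials <- 20
  for (i in seq_len(trials)) {
    X <- separated_matrix(n_per = 6, t = 6, gap = 40, sd = 2, seed = 100 + i)
    full <- kpod(X, 3, n_restarts = 10, seed = i)
    Xm <- X
    del <- withr::with_seed(200 + i, sample(length(X), round(0.2 * length(X))))
    Xm[del] <- NA
    drop_rows <- rowSums(!is.na(Xm)) == 0
    Xm[drop_rows, 1] <- X[drop_rows, 1]
    fm <- kpod(Xm, 3, n_restarts = 10, seed = i)
    if (rand_index(full$assignments, fm$assignments) == 1) ok <- ok + 1
  }
  expect_gte(ok / trials, 0.9)
})

test_that("fit lies in [0, 1] across random inputs and missingness levels", {
  for (i in 1:10) {
    X <- withr::with_seed(i, {
      X <- matrix(rnorm(60), 12, 5)
      X[sample(60, 12)] <- NA
      X[rowSums(!is.na(X)) == 0, 1] <- 0
      X
    })
    f <- kpod(X, sample(1:4, 1), n_restarts = 5, seed = i)
    expect_gte(f$fit, 0)
    expect_lte(f$fit, 1)
    expect_lte(f$wcss, f$tss + 1e-9)
  }
})

test_that("kpod is deterministic given a seed and validates its inputs", {
  X <- separated_matrix(seed = 3)
  X[2, 1] <- NA
  a <- kpod(X, 3, n_restarts = 5, seed = 11)
  b <- kpod(X, 3, n_restarts = 5, seed = 11)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$fit, b$fit)

  expect_error(kpod(X, nrow(X) + 1, seed = 1), "exceeds")
  Xbad <- X
  Xbad[1, ] <- NA
  expect_error(kpod(Xbad, 2, seed = 1), "observed cell")
})

test_that("tidiers expose assignments, centroids and model summary", {
  co <- generate_cohort(30, seed = 13)
  f <- kpod(co, 3, n_restarts = 5, seed = 13)
  td <- tidy(f)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$size), 30)
  expect_true(all(c("h6", "h36") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$k, 3)
  au <- augment(f)
  expect_equal(nrow(au), 30)
  expect_s3_class(au$.cluster, "factor")
})
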