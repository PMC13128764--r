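test_that("Welch t-test handles identity, summaries and degenerate input", {
  same <- welch_t(list(mean = 5, sd = 2, n = 10), list(mean = 5, sd = 2, n = 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # reference age summaries: two-sided Welch p ~ 0.59
  age <- welch_t(list(mean = 45.1, sd = 15.2, n = 77),
                 list(mean = 43.1, sd = 13.3, n = 17))
  expect_equal(age$p_value, 0.58954, tolerance = 1e-4)

  degen <- welch_t(list(mean = 3, sd = 0, n = 5), list(mean = 3, sd = 0, n = 5))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  expect_error(welch_t(list(mean = 1, sd = 1, n = 1),
                       list(mean = 1, sd = 1, n = 5)), "n >= 2")
})

test_that("raw and summary entry points agree and match stats::t.test", {
  x <- exact_moment_sample(12, 10, 3)
  y <- exact_moment_sample(20, 12, 5)
  raw <- welch_t(x, y)
  summ <- welch_t(list(mean = mean(x), sd = sd(x), n = 12),
                  list(mean = mean(y), sd = sd(y), n = 20))
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  ref <- stats::t.test(x, y)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(raw$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Welch p decreases when both samples double at fixed moments", {
  ps <- vapply(c(10, 20, 40, 80), function(n) {
    welch_t(list(mean = 10, sd = 4, n = n),
            list(mean = 11, sd = 4, n = n))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("one-way ANOVA: identity, summary agreement, and oracle check", {
  eq <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  gs <- withr::with_seed(9, list(rnorm(8), rnorm(12, 1), rnorm(6, 2)))
  raw <- oneway_anova(gs)
  summ <- oneway_anova_summary(
    vapply(gs, mean, 1), vapply(gs, sd, 1), lengths(gs)
  )
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  ref <- stats::oneway.test(
    values ~ g,
    data = data.frame(values = unlist(gs),
                      g = rep(seq_along(gs), lengths(gs))),
    var.equal = TRUE
  )
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(raw$p_value, ref$p.value, tolerance = 1e-10)

  degen <- oneway_anova(list(c(2, 2), c(2, 2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("summary-statistic ANOVA on the reference age moments", {
  a <- oneway_anova_summary(c(46.7, 54.2, 40.6), c(15.3, 10.8, 14.8),
                            c(23, 15, 39))
  # closed-form value from the printed moments
  expect_equal(a$statistic, 5.120759, tolerance = 1e-5)
  expect_equal(a$p_value, 0.0082624, tolerance = 1e-4)
  # oracle: classic ANOVA on exact-moment samples gives the same answer
  gs <- Map(exact_moment_sample, c(23, 15, 39),
            c(46.7, 54.2, 40.6), c(15.3, 10.8, 14.8))
  ref <- oneway_anova(gs)
  expect_equal(a$p_value, ref$p_value, tolerance = 1e-8)
})

test_that("chi-square on the reference sex-by-remission counts and edge cases", {
  tab <- matrix(c(32, 45, 8, 9), 2, 2, byrow = TRUE)
  ct <- chisq_2xk(tab)
  expect_equal(round(ct$p_value, 4), 0.8854)
  expect_equal(ct$statistic, 0.0208, tolerance = 1e-2)

  prop <- chisq_2xk(matrix(c(10, 20, 20, 40), 2, 2, byrow = TRUE))
  expect_equal(prop$p_value, 1)

  zero <- chisq_2xk(matrix(c(0, 0, 5, 7), 2, 2, byrow = TRUE))
  expect_true(zero$degenerate)
  expect_true(is.na(zero$p_value))
})

test_that("Yates-corrected p is never below the uncorrected Pearson p", {
  for (i in 1:25) {
    tab <- withr::with_seed(i, matrix(rpois(4, 8) + 1, 2, 2))
    py <- chisq_2xk(tab, correct = TRUE)$p_value
    pp <- chisq_2xk(tab, correct = FALSE)$p_value
    expect_gte(py, pp - 1e-12)
  }
})

test_that("chi-square p agrees with a fixed-margin Monte-Carlo oracle", {
  tab <- matrix(4 * c(9, 4, 7, 5, 8, 3), 2, 3, byrow = TRUE)
  res <- chisq_2xk(tab) # 2x3: plain Pearson
  mc <- withr::with_seed(42, {
    sims <- stats::r2dtable(20000, rowSums(tab), colSums(tab))
    stat <- function(m) {
      e <- outer(rowSums(m), colSums(m)) / sum(m)
      sum((m - e)^2 / e)
    }
    obs <- stat(tab)
    mean(vapply(sims, stat, numeric(1)) >= obs - 1e-12)
  })
  expect_equal(res$p_value, mc, tolerance = 0.02)
})

test_that("BH step-up matches a brute-force rank oracle and p.adjust", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    best <- 0
    for (i in seq_len(m)) {
      if (p[ord[i]] <= i / m * q) best <- i
    }
    sig <- rep(FALSE, m)
    if (best > 0) sig[ord[seq_len(best)]] <- TRUE
    sig
  }
  for (i in 1:20) {
    p <- withr::with_seed(i, runif(25)^sample(1:3, 1))
    got <- bh_adjust(p, 0.05)
    expect_identical(got$significant, bh_oracle(p, 0.05))
    expect_identical(got$significant,
                     stats::p.adjust(p, "BH") <= 0.05)
  }
})

test_that("BH bookkeeping: the 58-test battery threshold and empty case", {
  # 20 passing ranks out of 58 tests at q = 0.05 -> alpha = 0.0172
  p <- c(rep(0.0001, 20), rep(0.99, 38))
  got <- bh_adjust(p, 0.05)
  expect_equal(got$n_significant, 20)
  expect_equal(got$adjusted_alpha, 0.05 * 20 / 58)
  expect_equal(round(got$adjusted_alpha, 4), 0.0172)

  none <- bh_adjust(rep(1, 10), 0.05)
  expect_false(any(none$significant))
  expect_equal(none$adjusted_alpha, 0.005)
  expect_error(bh_adjust(numeric(0)), "non-empty")
})

test_that("the test battery counts its tests and is relabel-invariant", {
  co <- generate_cohort(60, seed = 33)
  dat <- dplyr::mutate(co$covariates, grp = rep(c("a", "b", "c"), 20))
  bat <- test_battery(
    dat, "grp",
    continuous = c("age", "length_of_stay"),
    categorical = c("male", "macroadenoma")
  )
  expect_equal(attr(bat, "m"), sum(!is.na(bat$p_value)))
  expect_equal(nrow(bat), 4)

  dat2 <- dplyr::mutate(
    dat, grp = c(a = "z", b = "y", c = "x")[grp]
  )
  bat2 <- test_battery(
    dat2, "grp",
    continuous = c("age", "length_of_stay"),
    categorical = c("male", "macroadenoma")
  )
  expect_equal(bat$p_value, bat2$p_value, tolerance = 1e-12)

  # extra p-values are counted in m and in the threshold
  bat3 <- test_battery(
    dat, "grp", continuous = "age",
    extra_p = c(t6 = 0.001, t12 = 0.5)
  )
  expect_equal(attr(bat3, "m"), 3)
})
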