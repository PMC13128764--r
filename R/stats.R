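#' Welch's unequal-variance t-test
#'
#' Two-sample unpaired t-test without the pooled-variance assumption, with
#' the Welch-Satterthwaite degrees of freedom. Accepts either raw value
#' vectors or `list(mean =, sd =, n =)` summaries; raw input is reduced to
#' its moments, so the two entry points agree exactly.
#'
#' @param a,b Numeric vectors, or lists/named vectors with `mean`, `sd`,
#'   `n`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `degenerate`, and a `groups` list-column with per-group `n`, `mean`,
#'   `sd`.
#' @examples
#' welch_t(list(mean = 45.1, sd = 15.2, n = 77), list(mean = 43.1, sd = 13.3, n = 17))
#' @export
welch_t <- function(a, b) {
  a <- as_summary(a)
  b <- as_summary(b)
  if (a$n < 2 || b$n < 2) abort("Each group needs n >= 2.")
  if (a$sd < 0 || b$sd < 0) abort("SDs must be non-negative.")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  degenerate <- (va + vb) == 0
  if (degenerate) {
    stat <- 0
    df <- a$n + b$n - 2
    p <- 1
  } else {
    stat <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    p <- 2 * pt(-abs(stat), df)
  }
  test_row(
    "welch_t", stat, df, p, degenerate,
    groups = tibble::tibble(
      group = c("a", "b"),
      n = c(a$n, b$n), mean = c(a$mean, b$mean), sd = c(a$sd, b$sd)
    )
  )
}

#' One-way analysis of variance
#'
#' `oneway_anova()` takes raw per-group value vectors;
#' `oneway_anova_summary()` takes per-group moments. The raw entry point
#' reduces to the summary computation (the classic F statistic depends on
#' the data only through per-group means, SDs and sizes), so the two agree
#' exactly.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return A one-row tibble as in [welch_t()] (with `df1`/`df2`).
#' @examples
#' oneway_anova_summary(
#'   means = c(46.7, 54.2, 40.6), sds = c(15.3, 10.8, 14.8), ns = c(23, 15, 39)
#' )
#' @export
oneway_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) abort("Need at least two groups.")
  if (any(lengths(groups) < 2)) abort("Each group needs >= 2 values.")
  oneway_anova_summary(
    means = vapply(groups, mean, numeric(1)),
    sds = vapply(groups, sd, numeric(1)),
    ns = lengths(groups)
  )
}

#' @rdname oneway_anova
#' @param means,sds,ns Per-group means, SDs and sizes.
#' @export
oneway_anova_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  if (length(means) < 2) abort("Need at least two groups.")
  if (any(ns < 2)) abort("Each group needs n >= 2.")
  if (any(sds < 0)) abort("SDs must be non-negative.")
  N <- sum(ns)
  k <- length(means)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  degenerate <- ssw <= 0 && ssb <= 0
  if (degenerate) {
    stat <- 0
    p <- 1
  } else if (ssw <= 0) {
    stat <- Inf
    p <- 0
  } else {
    stat <- (ssb / df1) / (ssw / df2)
    p <- pf(stat, df1, df2, lower.tail = FALSE)
  }
  test_row(
    "anova", stat, c(df1 = df1, df2 = df2), p, degenerate,
    groups = tibble::tibble(
      group = as.character(seq_len(k)), n = as.integer(ns),
      mean = as.numeric(means), sd = as.numeric(sds)
    )
  )
}

#' Chi-square test for a 2-by-k contingency table
#'
#' Pearson's chi-square on counts; 2-by-2 tables use the Yates continuity
#' correction (the convention for small clinical tables), larger tables the
#' plain Pearson statistic. Expected counts are returned for inspection. A
#' zero row or column margin makes the test undefined and is flagged.
#'
#' @param counts A matrix of non-negative integer counts (>= 2 rows and
#'   columns).
#' @param correct `NULL` (auto: Yates iff 2x2), or TRUE/FALSE to force.
#' @return A one-row tibble as in [welch_t()], with the expected-count
#'   matrix in the `expected` list-column.
#' @examples
#' chisq_2xk(matrix(c(32, 45, 8, 9), 2, byrow = TRUE)) # p = 0.8854
#' @export
chisq_2xk <- function(counts, correct = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("`counts` must be at least 2x2.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    out <- test_row("chi_square", NA_real_, NA_real_, NA_real_, TRUE,
                    groups = NULL)
    out$expected <- list(NULL)
    return(out)
  }
  correct <- correct %||% all(dim(counts) == 2)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  out <- test_row(
    "chi_square", unname(ct$statistic), unname(ct$parameter), ct$p.value,
    FALSE,
    groups = tibble::tibble(
      group = colnames(counts) %||% as.character(seq_len(ncol(counts))),
      n = colSums(counts),
      count = counts[1, ],
      proportion = counts[1, ] / colSums(counts)
    )
  )
  out$expected <- list(ct$expected)
  out
}

test_row <- function(kind, statistic, df, p, degenerate, groups) {
  tb <- tibble::tibble(
    test = kind,
    statistic = unname(statistic),
    df1 = if (length(df) == 2) df[[1]] else unname(df),
    df2 = if (length(df) == 2) df[[2]] else NA_real_,
    p_value = unname(p),
    degenerate = degenerate
  )
  tb$groups <- list(groups)
  tb
}

as_summary <- function(x) {
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    return(list(mean = x$mean, sd = x$sd, n = x$n))
  }
  x <- x[!is.na(x)]
  list(mean = mean(x), sd = sd(x), n = length(x))
}

#' Benjamini-Hochberg step-up correction
#'
#' The standard step-up procedure controlling the false discovery rate:
#' sort the m p-values ascending, find the largest rank i with
#' `p(i) <= (i/m) * q`, and declare the i smallest significant. The single
#' working threshold `(i/m) * q` is returned as `adjusted_alpha` -- the
#' per-comparison alpha a battery of m tests is effectively held to (for
#' m = 58 tests at q = 0.05 with 20 passing ranks this is 0.05 * 20/58 =
#' 0.0172). When no rank passes, `adjusted_alpha` is the smallest critical
#' value `q/m` and nothing is flagged.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target false-discovery rate (default 0.05).
#' @return A list: `significant` (logical, input order), `adjusted_alpha`,
#'   `n_significant`, `rank_passed`, and `critical_values` `(i/m)q` in sorted
#'   order.
#' @examples
#' bh_adjust(c(0.001, 0.02, 0.04, 0.9))
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) abort("`p` must be non-empty.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must be in [0, 1].")
  if (!is_scalar_number(q) || q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  m <- length(p)
  ord <- order(p)
  crit <- (seq_len(m) / m) * q
  passing <- which(p[ord] <= crit)
  i <- if (length(passing)) max(passing) else 0L
  significant <- rep(FALSE, m)
  if (i > 0) significant[ord[seq_len(i)]] <- TRUE
  list(
    significant = significant,
    adjusted_alpha = if (i > 0) crit[i] else crit[1],
    n_significant = i,
    rank_passed = i,
    critical_values = crit
  )
}

# Per-comparison significance threshold under a named policy:
# "bh", "bonferroni", or "fixed:<alpha>".
alpha_threshold <- function(p, policy = "bh", q = 0.05) {
  if (startsWith(policy, "fixed:")) {
    return(as.numeric(sub("^fixed:", "", policy)))
  }
  switch(policy,
    bh = bh_adjust(p, q)$adjusted_alpha,
    bonferroni = q / length(p),
    abort(sprintf("Unknown alpha policy '%s'.", policy))
  )
}

#' Run the full between-group comparison battery
#'
#' Compares groups on a set of continuous variables (Welch t-test for two
#' groups, one-way ANOVA for more) and categorical variables (chi-square on
#' the group-by-level table), then applies a multiple-testing policy across
#' the whole battery. This is the engine behind demographic/tumor/treatment
#' comparison tables: group summaries, raw p-values and significance flags
#' under a single corrected threshold.
#'
#' @param data Tibble with one row per patient.
#' @param group Name of the grouping column (2+ levels).
#' @param continuous,categorical Character vectors of column names.
#' @param alpha_policy `"bh"` (Benjamini-Hochberg, default),
#'   `"bonferroni"`, or `"fixed:<alpha>"`.
#' @param q Target FDR / family-wise level for the correction.
#' @param extra_p Optional named numeric vector of additional p-values
#'   (e.g. per-timepoint trajectory tests) counted in the same battery.
#' @return An object of class `test_battery`: a tibble with one row per
#'   test (`variable`, `test`, `statistic`, `df1`, `df2`, `p_value`,
#'   `degenerate`, `groups`, `significant`) with attributes `m`, `q`,
#'   `alpha_policy`, `adjusted_alpha`.
#' @examples
#' cohort <- generate_cohort(30, seed = 5)
#' test_battery(
#'   dplyr::mutate(cohort$covariates, grp = rep(c("x", "y"), 15)),
#'   group = "grp", continuous = "age", categorical = "male"
#' )
#' @export
test_battery <- function(data, group,
                         continuous = character(0),
                         categorical = character(0),
                         alpha_policy = "bh", q = 0.05,
                         extra_p = NULL) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("`group` must have at least two levels.")
  rows <- list()
  for (v in continuous) {
    vals <- split(data[[v]], g)
    row <- if (nlevels(g) == 2) {
      welch_t(vals[[1]], vals[[2]])
    } else {
      oneway_anova(vals)
    }
    row$groups[[1]]$group <- levels(g)
    row$variable <- v
    rows[[length(rows) + 1]] <- row
  }
  for (v in categorical) {
    f <- if (is.logical(data[[v]])) {
      factor(data[[v]], levels = c(FALSE, TRUE))
    } else {
      factor(data[[v]])
    }
    tab <- table(f, g)
    row <- chisq_2xk(unclass(tab))
    row$variable <- v
    rows[[length(rows) + 1]] <- row
  }
  battery <- dplyr::bind_rows(rows) |>
    dplyr::relocate("variable")
  p_all <- c(battery$p_value, unname(extra_p))
  names(p_all) <- c(battery$variable, names(extra_p))
  ok <- !is.na(p_all)
  adj_alpha <- alpha_threshold(p_all[ok], alpha_policy, q)
  battery$significant <- !is.na(battery$p_value) &
    battery$p_value <= adj_alpha
  structure(
    battery,
    m = sum(ok),
    q = q,
    alpha_policy = alpha_policy,
    adjusted_alpha = adj_alpha,
    extra_p = extra_p,
    class = c("test_battery", class(battery))
  )
}

#' @export
print.test_battery <- function(x, ...) {
  cat(sprintf(
    "<test_battery> m = %d tests, policy = %s, adjusted alpha = %.4f\n",
    attr(x, "m"), attr(x, "alpha_policy"), attr(x, "adjusted_alpha")
  ))
  NextMethod()
}
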