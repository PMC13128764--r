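#' Per-timepoint comparison of cortisol across clusters
#'
#' At each grid timepoint, runs a one-way ANOVA on the observed cortisol
#' values grouped by cluster assignment, reporting per-group n/mean/SD next
#' to the p-value. Clusters contributing fewer than 2 observed values at a
#' timepoint are excluded from that timepoint's test; if fewer than 2
#' clusters remain the test is skipped and flagged.
#'
#' @inheritParams kpod
#' @param assignments Cluster index per row of `x` (named or in row order).
#' @return A tibble with one row per timepoint: `hours`, `n_groups`, `n`,
#'   `statistic`, `df1`, `df2`, `p_value`, `skipped`, and a `groups`
#'   list-column of per-cluster summaries.
#' @examples
#' cohort <- generate_cohort(30, seed = 11)
#' fit <- kpod(cohort, 3, n_restarts = 5, seed = 11)
#' compare_timepoints(cohort, fit$assignments)
#' @export
compare_timepoints <- function(x, assignments) {
  xm <- as_matrix_input(x)
  values <- xm$values
  assignments <- as.integer(assignments)
  if (length(assignments) != nrow(values)) {
    abort("`assignments` must cover every row of `x`.")
  }
  if (length(unique(assignments)) < 2) {
    abort("Need at least two non-empty clusters.")
  }
  purrr::map_dfr(seq_along(xm$hours), function(j) {
    col <- values[, j]
    ok <- !is.na(col)
    grp <- split(col[ok], assignments[ok])
    summaries <- tibble::tibble(
      cluster = as.integer(names(grp)),
      n = lengths(grp),
      mean = vapply(grp, mean, numeric(1)),
      sd = vapply(grp, function(v) if (length(v) > 1) sd(v) else NA_real_,
                  numeric(1))
    )
    usable <- grp[lengths(grp) >= 2]
    out <- tibble::tibble(
      hours = xm$hours[j],
      n_groups = length(usable),
      n = sum(ok),
      statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
      p_value = NA_real_,
      skipped = length(usable) < 2
    )
    if (!out$skipped) {
      a <- oneway_anova(usable)
      out$statistic <- a$statistic
      out$df1 <- a$df1
      out$df2 <- a$df2
      out$p_value <- a$p_value
    }
    out$groups <- list(summaries)
    out
  })
}

#' Select the window of significant cluster separation
#'
#' Operationalizes "the continuous period where statistically significant
#' separation was achieved": with a per-comparison threshold from
#' `alpha_policy`, the window is the maximal run of consecutive grid
#' timepoints, beginning at the earliest significant one, whose tests are
#' all significant. An empty window means no timepoint separated the
#' clusters.
#'
#' @param tests Output of [compare_timepoints()].
#' @param alpha_policy `"bh"`, `"bonferroni"` or `"fixed:<alpha>"` applied
#'   across the per-timepoint p-values.
#' @param q Level for the bh/bonferroni policies.
#' @return A list of class `window_selection`: `hours` (possibly empty),
#'   `threshold`, `alpha_policy`, `rule`, and `tests` with a `significant`
#'   column added.
#' @export
select_window <- function(tests, alpha_policy = "bh", q = 0.05) {
  p <- tests$p_value
  ok <- !is.na(p)
  threshold <- if (any(ok)) alpha_threshold(p[ok], alpha_policy, q) else NA_real_
  tests$significant <- ok & p <= threshold
  hours <- numeric(0)
  if (any(tests$significant)) {
    first <- which(tests$significant)[1]
    run_end <- first
    while (run_end < nrow(tests) && tests$significant[run_end + 1]) {
      run_end <- run_end + 1
    }
    hours <- tests$hours[first:run_end]
  }
  structure(
    list(
      hours = hours,
      threshold = threshold,
      alpha_policy = alpha_policy,
      rule = "earliest_significant_run",
      tests = tests
    ),
    class = "window_selection"
  )
}

#' @export
print.window_selection <- function(x, ...) {
  if (length(x$hours)) {
    cat(sprintf(
      "<window_selection> %g-%g h (%d timepoints), threshold %.4g (%s)\n",
      min(x$hours), max(x$hours), length(x$hours), x$threshold,
      x$alpha_policy
    ))
  } else {
    cat("<window_selection> empty window: no significant separation\n")
  }
  invisible(x)
}

#' Two-pass trajectory clustering
#'
#' The end-to-end clustering procedure: (pass 1) cluster the full-grid
#' matrix, choosing k by the elbow of the fit curve unless a fixed `k` is
#' given; test per-timepoint cluster separation by one-way ANOVA; select
#' the contiguous window of significant separation; (pass 2) re-cluster,
#' at the same k, using only the window timepoints, so the final phenotypes
#' are driven by the period where the groups genuinely differ. Patients
#' contributing a single timepoint are clustered like any others; patients
#' with no observed value (overall, or inside the window for pass 2) are
#' dropped with a message.
#'
#' If pass 1 fails the convergence diagnostics (subsample instability, tiny
#' clusters, or insufficient sample size -- the typical outcome for a small
#' homogeneous group), the procedure aborts with a classed condition
#' (`cortclust_nonconvergence`) carrying the machine-readable diagnosis.
#'
#' @inheritParams kpod
#' @inheritParams select_window
#' @param k `"auto"` (elbow selection over `k_grid`) or a fixed integer.
#' @param k_grid Candidate cluster counts for the elbow (auto mode).
#' @param min_cluster_size,stability_threshold Passed to
#'   [diagnose_convergence()].
#' @return An object of class `two_pass_fit`: list with `pass1`, `pass2`
#'   (`kpod_fit` or `NULL` when the window is empty), `window`
#'   (`window_selection`), `elbow` (`elbow_report` or `NULL`), `diagnosis`,
#'   `k`, `seed`.
#' @examples
#' cohort <- generate_cohort(40, seed = 9)
#' res <- two_pass_cluster(cohort, k = 3, n_restarts = 5, seed = 9)
#' res$window$hours
#' @export
two_pass_cluster <- function(x, k = "auto", k_grid = 1:6,
                             n_restarts = 25, seed = NULL,
                             alpha_policy = "bh", q = 0.05,
                             min_cluster_size = 3, stability_threshold = 0.7,
                             max_iter = 200, tol = 1e-6) {
  xm <- as_matrix_input(x)
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), 2L)

  elbow <- NULL
  if (identical(k, "auto")) {
    elbow <- select_k(
      xm, k_grid = k_grid, n_restarts = n_restarts, seed = seeds[1],
      max_iter = max_iter, tol = tol
    )
    if (is.na(elbow$selected_k)) {
      abort("Elbow selection needs a k grid of length >= 3; pass a fixed `k`.")
    }
    k <- elbow$selected_k
    pass1 <- elbow$fits[[match(k, elbow$k_grid)]]
  } else {
    pass1 <- kpod(
      xm, k, n_restarts = n_restarts, seed = seeds[1],
      max_iter = max_iter, tol = tol
    )
  }

  diagnosis <- diagnose_convergence(
    pass1, min_cluster_size = min_cluster_size,
    stability_threshold = stability_threshold
  )
  if (!diagnosis$converged) {
    abort(
      c(
        "Pass-1 clustering failed to converge.",
        paste("Reasons:", paste(diagnosis$reason, collapse = ", "))
      ),
      class = "cortclust_nonconvergence",
      diagnosis = diagnosis,
      fit = pass1
    )
  }

  tests <- compare_timepoints(xm, pass1$assignments)
  window <- select_window(tests, alpha_policy = alpha_policy, q = q)

  pass2 <- NULL
  if (length(window$hours) > 0) {
    keep_cols <- xm$hours %in% window$hours
    sub <- xm$values[, keep_cols, drop = FALSE]
    has_obs <- rowSums(!is.na(sub)) > 0
    if (any(!has_obs)) {
      inform(sprintf(
        "Dropping %d patient(s) with no observed value inside the window.",
        sum(!has_obs)
      ))
    }
    sub_m <- new_cortisol_matrix(
      sub[has_obs, , drop = FALSE], xm$hours[keep_cols]
    )
    pass2 <- kpod(
      sub_m, k, n_restarts = n_restarts, seed = pass1$seed,
      max_iter = max_iter, tol = tol
    )
  }

  structure(
    list(
      pass1 = pass1,
      pass2 = pass2,
      window = window,
      elbow = elbow,
      diagnosis = diagnosis,
      k = as.integer(k),
      seed = seed
    ),
    class = "two_pass_fit"
  )
}

#' @export
print.two_pass_fit <- function(x, ...) {
  cat(sprintf("<two_pass_fit> k = %d\n", x$k))
  cat("pass 1: "); print(x$pass1)
  print(x$window)
  if (is.null(x$pass2)) {
    cat("pass 2: skipped (empty window)\n")
  } else {
    cat("pass 2: "); print(x$pass2)
  }
  invisible(x)
}
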