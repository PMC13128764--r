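#' Elbow-based selection of the cluster count
#'
#' Runs [kpod()] over a grid of candidate cluster counts and selects the
#' elbow of the fit-integrity curve, automating the usual visual
#' inspection. Two rules apply, in order:
#'
#' 1. *Saturation*: if the curve reaches its final value (within 1e-9)
#'    before the last candidate, the elbow is the first point of that
#'    plateau -- additional clusters add nothing.
#' 2. *Maximal curvature*: otherwise the selected k maximizes the drop in
#'    marginal gain, `(fit[k] - fit[k-1]) - (fit[k+1] - fit[k])`, over the
#'    interior candidates, excluding (a) the candidate adjacent to k = 1,
#'    because `fit(1) = 0` holds by definition (the fit statistic is
#'    measured against the one-cluster model) so the first gain measures
#'    total structure rather than elbow position, and (b) the last interior
#'    candidate, because an elbow is only identifiable when at least two
#'    later points show the plateau. Either exclusion is skipped when it
#'    would leave no candidate. Ties break toward smaller k.
#'
#' The full curve is always returned so a human can inspect it (and
#' override the choice by passing a fixed `k` downstream).
#'
#' Each candidate k is warm-started with the previous k's best centroids
#' plus the farthest point as one extra initialization, so the best-restart
#' fit curve is non-decreasing in k.
#'
#' @inheritParams kpod
#' @param k_grid Sorted candidate cluster counts (need at least 3 for a
#'   selection; shorter grids return the curve with `selected_k = NA`).
#' @param keep_fits Keep the underlying `kpod_fit` objects (default TRUE).
#'
#' @return An object of class `elbow_report`: list with `k_grid`,
#'   `fit_curve`, `selected_k`, `selection_rule` and (optionally) `fits`.
#' @examples
#' cohort <- generate_cohort(40, seed = 3)
#' select_k(cohort, k_grid = 1:4, n_restarts = 5, seed = 3)
#' @export
select_k <- function(x, k_grid = 1:6, n_restarts = 25, seed = NULL,
                     max_iter = 200, tol = 1e-6, keep_fits = TRUE,
                     fit_cells = c("observed", "completed")) {
  fit_cells <- match.arg(fit_cells)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (min(k_grid) < 1) abort("`k_grid` entries must be >= 1.")
  xm <- as_matrix_input(x)
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), length(k_grid))

  fits <- vector("list", length(k_grid))
  prev <- NULL
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    extra <- NULL
    if (!is.null(prev) && prev$k == k - 1L) {
      extra <- list(warm_start_centers(xm$values, prev))
    }
    fits[[i]] <- kpod(
      xm, k,
      n_restarts = n_restarts, max_iter = max_iter, tol = tol,
      seed = seeds[i], fit_cells = fit_cells, extra_init = extra
    )
    prev <- fits[[i]]
  }
  fit_curve <- vapply(fits, `[[`, numeric(1), "fit")

  selected <- NA_integer_
  rule <- "curve_only"
  if (length(k_grid) >= 3) {
    sat <- which(fit_curve >= fit_curve[length(fit_curve)] - 1e-9)[1]
    if (sat < length(k_grid)) {
      selected <- k_grid[sat]
      rule <- "saturation"
    } else {
      cand <- 2:(length(k_grid) - 1)
      if (k_grid[1] == 1 && length(cand) > 1) cand <- cand[-1]
      if (length(cand) > 1) cand <- cand[-length(cand)]
      strength <- 2 * fit_curve[cand] - fit_curve[cand - 1] -
        fit_curve[cand + 1]
      selected <- k_grid[cand[which.max(strength)]] # first max = smallest k
      rule <- "max_curvature_interior"
    }
  }

  structure(
    list(
      k_grid = k_grid,
      fit_curve = setNames(fit_curve, paste0("k", k_grid)),
      selected_k = selected,
      selection_rule = rule,
      fits = if (keep_fits) fits else NULL
    ),
    class = "elbow_report"
  )
}

# Previous best centroids (completed-data) plus the farthest point on the
# column-mean-imputed matrix, as a deterministic k-centroid warm start.
warm_start_centers <- function(values, prev_fit) {
  X0 <- impute_column_means(values)
  C <- prev_fit$completed_centroids
  d2 <- apply(dist2(X0, C), 1, min)
  rbind(C, X0[which.max(d2), ])
}

#' @export
print.elbow_report <- function(x, ...) {
  cat("<elbow_report>\n")
  curve <- tibble::tibble(k = x$k_grid, fit = as.numeric(x$fit_curve))
  print(curve, n = nrow(curve))
  if (is.na(x$selected_k)) {
    cat("  no selection (", x$selection_rule, ")\n", sep = "")
  } else {
    cat(sprintf("  selected k = %d (%s)\n", x$selected_k, x$selection_rule))
  }
  invisible(x)
}

#' Diagnose whether a clustering solution is trustworthy
#'
#' Small or homogeneous samples make k-means-type solutions untrustworthy:
#' the partition is determined by sample idiosyncrasies rather than
#' structure, and clusters shrink below a usable size. This mirrors how a
#' failed clustering of a small patient group is recognized in practice.
#' The fit is declared non-converged when any of the following hold:
#'
#' * *subsample instability*: re-clustering random subsamples (default 20
#'   draws of 80% of patients, at the same k) yields partitions whose mean
#'   adjusted Rand agreement with the reference partition falls below
#'   `stability_threshold` -- for genuine structure the same clusters
#'   reappear in every subsample, while for homogeneous data the split is
#'   arbitrary and agreement collapses toward 0;
#' * *small cluster*: any cluster smaller than `min_cluster_size`;
#' * *insufficient n*: fewer than `k * min_cluster_size` patients;
#' * *no fixed point*: the alternating minimization hit its iteration cap.
#'
#' @param fit A `kpod_fit`.
#' @param min_cluster_size Smallest acceptable cluster (default 3).
#' @param stability_threshold Minimum mean adjusted Rand agreement between
#'   the reference partition and subsample re-clusterings (default 0.7).
#' @param n_boot Number of subsample draws (default 20).
#' @param subsample Fraction of patients per draw (default 0.8).
#'
#' @return A list: `converged` (logical), `reason` (character vector of
#'   machine-readable failure codes, `"ok"` when converged), `stability`,
#'   `restart_agreement`, `cluster_sizes`.
#' @examples
#' fit <- kpod(generate_cohort(20, seed = 2), k = 2, n_restarts = 5, seed = 2)
#' diagnose_convergence(fit, n_boot = 5)
#' @export
diagnose_convergence <- function(fit, min_cluster_size = 3,
                                 stability_threshold = 0.7,
                                 n_boot = 20, subsample = 0.8) {
  stopifnot(inherits(fit, "kpod_fit"))
  sizes <- tabulate(fit$assignments, fit$k)
  n <- length(fit$assignments)
  reasons <- character(0)
  if (n < fit$k * min_cluster_size) reasons <- c(reasons, "insufficient_n")
  if (any(sizes < min_cluster_size)) reasons <- c(reasons, "small_cluster")

  stability <- NA_real_
  if (fit$k >= 2 && stability_threshold > 0 && n_boot > 0) {
    stability <- subsample_stability(fit, n_boot = n_boot,
                                     subsample = subsample)
    if (stability < stability_threshold) {
      reasons <- c(reasons, "subsample_instability")
    }
  }
  if (!fit$converged) reasons <- c(reasons, "no_fixed_point")
  list(
    converged = length(reasons) == 0,
    reason = if (length(reasons)) reasons else "ok",
    stability = stability,
    restart_agreement = fit$restart_agreement,
    cluster_sizes = sizes
  )
}

# Mean adjusted Rand agreement between the reference partition and
# re-clusterings of random subsamples; deterministic given the fit's seed.
subsample_stability <- function(fit, n_boot = 20, subsample = 0.8) {
  n <- length(fit$assignments)
  m <- max(2L, round(subsample * n))
  seeds <- spawn_seeds((fit$seed %||% 0) + 1L, n_boot)
  mean(vapply(seq_len(n_boot), function(b) {
    idx <- with_seed(seeds[b], sort(sample.int(n, m)))
    sub <- new_cortisol_matrix(fit$values[idx, , drop = FALSE], fit$hours)
    refit <- kpod(sub, fit$k, n_restarts = 10, seed = seeds[b])
    adjusted_rand_index(fit$assignments[idx], refit$assignments)
  }, numeric(1)))
}
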