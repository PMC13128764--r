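#' k-POD clustering of a partially observed matrix
#'
#' k-means for incomplete data by alternating minimization: missing cells
#' are completed with the coordinates of the currently assigned centroid,
#' then standard Lloyd updates run on the completed matrix, and the two
#' steps repeat until the assignment stabilizes or the completed-data
#' within-cluster sum of squares (WCSS) stops decreasing. Every move
#' (assignment, centroid update, completion, empty-cluster re-seeding) is
#' non-increasing in the completed-data objective, so each restart descends
#' monotonically to a fixed point; restarts with k-means++ initialization on
#' a column-mean-imputed matrix guard against local optima and the best
#' restart by fit is returned.
#'
#' The reported `wcss`, `tss` and `fit` (`1 - wcss/tss`) are recomputed on
#' *observed* cells only (see [fit_integrity()]): reporting them on imputed
#' cells would flatter the fit by construction, since imputed cells sit
#' exactly on their centroid. Set `fit_cells = "completed"` for the
#' completed-data variant.
#'
#' @param x A `cortisol_matrix`, a `cortisol_cohort`, a numeric matrix with
#'   `NA` for missing cells, or a long tibble (`patient_id`, `hours`,
#'   `cortisol`).
#' @param k Number of clusters, `1 <= k <= nrow`.
#' @param n_restarts Independent k-means++ restarts.
#' @param max_iter Iteration cap per restart.
#' @param tol Stop when the completed-data WCSS decreases by less than this.
#' @param seed Integer seed driving all restarts (ambient RNG untouched).
#' @param fit_cells `"observed"` (default) or `"completed"`: which cells the
#'   reported WCSS/TSS/fit are computed on.
#' @param extra_init Optional list of k-by-T centroid matrices to use as
#'   additional deterministic initializations (used by [select_k()] to
#'   warm-start from the previous k).
#'
#' @return An object of class `kpod_fit` with elements `k`, `assignments`
#'   (named integer vector in `1..k`), `centroids` (k-by-T observed-cell
#'   cluster mean curves), `completed_centroids`, `overall_mean`, `wcss`,
#'   `tss`, `fit`, `n_iter`, `converged`, `restart_agreement` (mean pairwise
#'   Rand index across restart solutions), `objective_trace` (completed-data
#'   WCSS per iteration of the best restart), `n_empty_repairs`, `hours`,
#'   `seed`.
#'
#' @examples
#' cohort <- generate_cohort(30, seed = 7)
#' fit <- kpod(cohort, k = 3, n_restarts = 5, seed = 7)
#' glance(fit)
#' @export
kpod <- function(x, k, n_restarts = 25, max_iter = 200, tol = 1e-6,
                 seed = NULL, fit_cells = c("observed", "completed"),
                 extra_init = NULL) {
  fit_cells <- match.arg(fit_cells)
  xm <- as_matrix_input(x)
  values <- xm$values
  n <- nrow(values)
  if (!is_scalar_number(k) || k < 1) abort("`k` must be a positive integer.")
  if (k > n) abort(sprintf("k = %d exceeds the number of rows (%d).", k, n))
  if (any(rowSums(!is.na(values)) == 0)) {
    abort("Every row must have at least one observed cell.")
  }

  X0 <- impute_column_means(values)
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), n_restarts)

  inits <- c(
    lapply(seeds, function(s) with_seed(s, kmeanspp(X0, k))),
    extra_init %||% list()
  )
  runs <- lapply(inits, function(centers0) {
    kpod_once(values, X0, centers0, max_iter = max_iter, tol = tol)
  })

  fits <- vapply(runs, function(r) {
    restart_fit(values, r, fit_cells)
  }, numeric(1))
  best_i <- which.max(fits)
  best <- runs[[best_i]]

  assignments <- setNames(best$assignments, rownames(values))
  obs_stats <- fit_integrity(xm, assignments)
  centroids <- observed_centroids(values, best$assignments, k)
  dimnames(centroids) <- list(
    paste0("cluster_", seq_len(k)), as.character(xm$hours)
  )
  completed <- best$centers
  dimnames(completed) <- dimnames(centroids)

  restart_mat <- vapply(runs, `[[`, integer(n), "assignments")
  agreement <- mean_pairwise_rand(restart_mat)

  stats <- if (fit_cells == "observed") {
    obs_stats
  } else {
    completed_stats(best)
  }

  structure(
    list(
      k = as.integer(k),
      assignments = assignments,
      centroids = centroids,
      completed_centroids = completed,
      overall_mean = setNames(
        colMeans(values, na.rm = TRUE), as.character(xm$hours)
      ),
      wcss = stats$wcss,
      tss = stats$tss,
      fit = stats$fit,
      degenerate = stats$degenerate,
      n_iter = best$n_iter,
      converged = best$converged,
      restart_agreement = agreement,
      restart_assignments = restart_mat,
      completed = best$completed,
      objective_trace = best$trace,
      objective_traces = lapply(runs, `[[`, "trace"),
      n_empty_repairs = best$n_repairs,
      values = values,
      hours = xm$hours,
      patient_id = rownames(values),
      fit_cells = fit_cells,
      seed = seed
    ),
    class = "kpod_fit"
  )
}

# One alternating-minimization descent from fixed initial centers.
kpod_once <- function(values, X0, centers0, max_iter, tol) {
  miss <- is.na(values)
  k <- nrow(centers0)
  Xc <- X0
  centers <- centers0
  assign_prev <- NULL
  wcss_prev <- Inf
  trace <- numeric(0)
  n_repairs <- 0L
  converged <- FALSE
  iter <- 0L
  empty_at_end <- FALSE

  while (iter < max_iter) {
    iter <- iter + 1L
    D <- dist2(Xc, centers)
    assign <- max.col(-D, ties.method = "first")

    # empty-cluster repair: re-seed at the point farthest from its centroid
    for (e in which(tabulate(assign, k) == 0)) {
      owndist <- D[cbind(seq_len(nrow(Xc)), assign)]
      far <- which.max(owndist)
      if (owndist[far] <= 0) break # duplicate-point degenerate data
      centers[e, ] <- Xc[far, ]
      n_repairs <- n_repairs + 1L
      D <- dist2(Xc, centers)
      assign <- max.col(-D, ties.method = "first")
    }
    empty_at_end <- any(tabulate(assign, k) == 0)

    sizes <- tabulate(assign, k)
    upd <- rowsum(Xc, assign, reorder = FALSE)
    present <- sort(unique(assign))
    centers[present, ] <- upd[as.character(present), , drop = FALSE] /
      sizes[present]

    Xc[miss] <- centers[assign, , drop = FALSE][miss]
    wcss <- sum((Xc - centers[assign, , drop = FALSE])^2)
    trace <- c(trace, wcss)

    if (identical(assign, assign_prev) || wcss_prev - wcss < tol) {
      converged <- TRUE
      assign_prev <- assign
      break
    }
    assign_prev <- assign
    wcss_prev <- wcss
  }
  list(
    assignments = as.integer(assign_prev),
    centers = centers,
    completed = Xc,
    trace = trace,
    n_iter = iter,
    n_repairs = n_repairs,
    converged = converged && !empty_at_end
  )
}

dist2 <- function(X, C) {
  D <- matrix(rowSums(X^2), nrow(X), nrow(C)) - 2 * X %*% t(C) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE)
  pmax(D, 0)
}

kmeanspp <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    idx <- if (sum(d2) <= 0) {
      sample.int(n, 1)
    } else {
      sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

impute_column_means <- function(values) {
  cm <- colMeans(values, na.rm = TRUE)
  cm[is.nan(cm)] <- mean(values, na.rm = TRUE)
  X0 <- values
  for (j in seq_len(ncol(X0))) {
    X0[is.na(X0[, j]), j] <- cm[j]
  }
  X0
}

observed_centroids <- function(values, assign, k) {
  t(vapply(seq_len(k), function(g) {
    rows <- values[assign == g, , drop = FALSE]
    if (nrow(rows) == 0) return(rep(NA_real_, ncol(values)))
    colMeans(rows, na.rm = TRUE)
  }, numeric(ncol(values))))
}

restart_fit <- function(values, run, fit_cells) {
  if (fit_cells == "completed") {
    completed_stats(run)$fit
  } else {
    observed_fit_stats(values, run$assignments)$fit
  }
}

completed_stats <- function(run) {
  Xc <- run$completed
  mu <- colMeans(Xc)
  tss <- sum(sweep(Xc, 2, mu)^2)
  wcss <- run$trace[length(run$trace)]
  degenerate <- tss <= 0
  list(
    tss = tss, wcss = wcss,
    fit = if (degenerate) 1 else 1 - wcss / tss,
    degenerate = degenerate
  )
}

observed_fit_stats <- function(values, assign) {
  mu <- colMeans(values, na.rm = TRUE)
  tss <- sum(sweep(values, 2, mu)^2, na.rm = TRUE)
  k <- max(assign)
  wcss <- 0
  for (g in seq_len(k)) {
    rows <- values[assign == g, , drop = FALSE]
    if (nrow(rows) == 0) next
    mug <- colMeans(rows, na.rm = TRUE)
    mug[is.nan(mug)] <- 0 # column unobserved in this cluster: no cells, no term
    wcss <- wcss + sum(sweep(rows, 2, mug)^2, na.rm = TRUE)
  }
  degenerate <- tss <= 0
  list(
    tss = tss, wcss = wcss,
    fit = if (degenerate) 1 else max(0, min(1, 1 - wcss / tss)),
    degenerate = degenerate
  )
}

#' Fit-integrity statistic (1 - WCSS/TSS) on observed cells
#'
#' The compactness measure used to compare cluster counts: the total sum of
#' squares around the overall per-timepoint mean, the within-cluster sum of
#' squares around each cluster's per-timepoint mean, and their ratio
#' `fit = 1 - WCSS/TSS`. Sums run over observed cells only; the overall and
#' per-cluster means are observed-cell column means, so `0 <= fit <= 1`
#' always holds. When TSS is 0 (all observed values identical) the fit is
#' defined as 1 and flagged degenerate.
#'
#' @inheritParams kpod
#' @param assignments Integer cluster index per row (values in `1..k`).
#' @return A list with `tss`, `wcss`, `fit`, `degenerate`.
#' @examples
#' m <- matrix(c(0, 0, 0, 2, 10, 0, 10, 2), 4, 2, byrow = TRUE)
#' fit_integrity(m, c(1, 1, 2, 2)) # tss 104, wcss 4, fit 25/26
#' @export
fit_integrity <- function(x, assignments) {
  xm <- as_matrix_input(x)
  if (length(assignments) != nrow(xm$values)) {
    abort("`assignments` must cover every row.")
  }
  observed_fit_stats(xm$values, as.integer(assignments))
}

mean_pairwise_rand <- function(assign_mat) {
  m <- ncol(assign_mat)
  if (m < 2) return(1)
  pairs <- utils::combn(m, 2)
  mean(apply(pairs, 2, function(p) {
    rand_index(assign_mat[, p[1]], assign_mat[, p[2]])
  }))
}

#' Partition agreement indices
#'
#' `rand_index()` is the fraction of point pairs on which two clusterings
#' agree (both together or both apart); 1 means identical partitions up to
#' relabeling. `adjusted_rand_index()` corrects for chance agreement, so
#' unrelated partitions score near 0.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return A number in \[0, 1\] (the adjusted index can be slightly
#'   negative for anti-correlated partitions).
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  n2 <- n * (n - 1) / 2
  (n2 + 2 * comb2(as.vector(tab)) - comb2(rowSums(tab)) -
    comb2(colSums(tab))) / n2
}

#' @rdname rand_index
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  expected <- si * sj / (n * (n - 1) / 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' @export
print.kpod_fit <- function(x, ...) {
  cat(sprintf(
    "<kpod_fit> k = %d, n = %d, fit = %.4f (%s cells), %d iter, %s\n",
    x$k, length(x$assignments), x$fit, x$fit_cells, x$n_iter,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = " "),
      "| restart agreement:", sprintf("%.3f", x$restart_agreement), "\n")
  invisible(x)
}
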