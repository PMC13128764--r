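#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for k-POD fits
#'
#' `tidy()` returns one row per cluster (size plus the observed-cell mean
#' curve, one `h<hours>` column per timepoint); `glance()` a one-row model
#' summary; `augment()` the per-patient assignments.
#'
#' @param x A `kpod_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kpod_fit
#' @export
tidy.kpod_fit <- function(x, ...) {
  cent <- tibble::as_tibble(x$centroids, .name_repair = ~ paste0("h", x$hours))
  dplyr::bind_cols(
    tibble::tibble(
      cluster = seq_len(x$k),
      size = tabulate(x$assignments, x$k)
    ),
    cent
  )
}

#' @rdname tidy.kpod_fit
#' @method glance kpod_fit
#' @export
glance.kpod_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$assignments),
    tss = x$tss,
    wcss = x$wcss,
    fit = x$fit,
    n_iter = x$n_iter,
    converged = x$converged,
    restart_agreement = x$restart_agreement
  )
}

#' @rdname tidy.kpod_fit
#' @param data Optional tibble with a `patient_id` column to join onto.
#' @method augment kpod_fit
#' @export
augment.kpod_fit <- function(x, data = NULL, ...) {
  out <- tibble::tibble(
    patient_id = x$patient_id,
    .cluster = factor(unname(x$assignments))
  )
  if (!is.null(data)) out <- dplyr::left_join(data, out, by = "patient_id")
  out
}

#' @rdname tidy.kpod_fit
#' @method tidy elbow_report
#' @export
tidy.elbow_report <- function(x, ...) {
  tibble::tibble(
    k = x$k_grid,
    fit = as.numeric(x$fit_curve),
    selected = x$k_grid == (x$selected_k %||% NA_integer_) &
      !is.na(x$selected_k)
  )
}

#' @rdname tidy.kpod_fit
#' @method tidy two_pass_fit
#' @export
tidy.two_pass_fit <- function(x, ...) {
  out <- tibble::tibble(
    patient_id = x$pass1$patient_id,
    .cluster_pass1 = factor(unname(x$pass1$assignments))
  )
  if (!is.null(x$pass2)) {
    out <- dplyr::left_join(
      out,
      tibble::tibble(
        patient_id = x$pass2$patient_id,
        .cluster = factor(unname(x$pass2$assignments))
      ),
      by = "patient_id"
    )
  } else {
    out$.cluster <- out$.cluster_pass1
  }
  out
}

#' @rdname tidy.kpod_fit
#' @method glance two_pass_fit
#' @export
glance.two_pass_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    window_start = if (length(x$window$hours)) min(x$window$hours) else NA_real_,
    window_end = if (length(x$window$hours)) max(x$window$hours) else NA_real_,
    window_size = length(x$window$hours),
    fit_pass1 = x$pass1$fit,
    fit_pass2 = if (is.null(x$pass2)) NA_real_ else x$pass2$fit,
    converged = x$diagnosis$converged
  )
}

#' @rdname tidy.kpod_fit
#' @method glance test_battery
#' @export
glance.test_battery <- function(x, ...) {
  tibble::tibble(
    m = attr(x, "m"),
    q = attr(x, "q"),
    alpha_policy = attr(x, "alpha_policy"),
    adjusted_alpha = attr(x, "adjusted_alpha"),
    n_significant = sum(x$significant, na.rm = TRUE)
  )
}

#' Plot the fit-integrity curve with the selected elbow
#'
#' @param object An `elbow_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot elbow_report
#' @export
autoplot.elbow_report <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$fit)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(
      x = "number of clusters K",
      y = "fit = 1 - WCSS/TSS",
      title = "Cluster-count selection (elbow of the fit curve)"
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$selected_k)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$selected_k, linetype = "dashed", colour = "red3"
    )
  }
  p
}

#' Plot cluster mean cortisol curves
#'
#' @param object A `kpod_fit`.
#' @param ... Unused.
#' @return A ggplot of the observed-cell cluster mean curves.
#' @method autoplot kpod_fit
#' @export
autoplot.kpod_fit <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(
      dplyr::starts_with("h"),
      names_to = "hours", values_to = "cortisol",
      names_transform = list(hours = ~ as.numeric(sub("^h", "", .x)))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$hours, y = .data$cortisol,
    colour = factor(.data$cluster), group = .data$cluster
  )) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "hours post-op", y = "serum cortisol (mcg/dL)",
      colour = "cluster", title = "Cluster mean cortisol trajectories"
    ) +
    ggplot2::theme_minimal()
}

#' Mean +/- SD cortisol curves per cluster
#'
#' @param measurements Long tibble (`patient_id`, `hours`, `cortisol`).
#' @param labels Tibble (`patient_id`, `.cluster`) as from
#'   [augment.kpod_fit()].
#' @return A ggplot with one ribbon per cluster.
#' @export
plot_cluster_means <- function(measurements, labels) {
  df <- measurements |>
    dplyr::inner_join(labels, by = "patient_id") |>
    dplyr::filter(!is.na(.data$cortisol)) |>
    dplyr::group_by(.data$.cluster, .data$hours) |>
    dplyr::summarise(
      mean = mean(.data$cortisol),
      sd = sd(.data$cortisol),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$hours, y = .data$mean,
    colour = .data$.cluster, fill = .data$.cluster, group = .data$.cluster
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "hours post-op", y = "serum cortisol (mcg/dL)",
      colour = "cluster", fill = "cluster",
      title = "Cluster mean cortisol (+/- SD)"
    ) +
    ggplot2::theme_minimal()
}

#' Individual cortisol trajectories, faceted by cluster
#'
#' @inheritParams plot_cluster_means
#' @return A ggplot (spaghetti plot).
#' @export
plot_spaghetti <- function(measurements, labels) {
  df <- measurements |>
    dplyr::inner_join(labels, by = "patient_id") |>
    dplyr::filter(!is.na(.data$cortisol))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$hours, y = .data$cortisol, group = .data$patient_id
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~.cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "hours post-op", y = "serum cortisol (mcg/dL)",
      title = "Individual cortisol trajectories by cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Data availability per timepoint
#'
#' Stacked per-timepoint counts of observed values, steroid-censored cells
#' and otherwise-missing cells -- the data-quality picture behind the
#' shrinking sample across the postoperative grid.
#'
#' @param cohort A `cortisol_cohort`, or a measurements tibble with a
#'   `steroid_hours` column.
#' @return A ggplot.
#' @export
plot_missingness <- function(cohort) {
  meas <- if (inherits(cohort, "cortisol_cohort")) {
    dplyr::left_join(cohort$measurements, cohort$steroids, by = "patient_id")
  } else {
    cohort
  }
  df <- meas |>
    dplyr::mutate(
      status = dplyr::case_when(
        !is.na(.data$cortisol) ~ "observed",
        !is.na(.data$steroid_hours) &
          .data$hours > .data$steroid_hours ~ "steroid-censored",
        TRUE ~ "missing"
      )
    ) |>
    dplyr::count(.data$hours, .data$status)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$hours), y = .data$n, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "hours post-op", y = "patients",
      title = "Cortisol data availability per timepoint"
    ) +
    ggplot2::theme_minimal()
}
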