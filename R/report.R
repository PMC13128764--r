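#' Run the full analysis end-to-end and write an artifact directory
#'
#' Orchestrates the whole pipeline: simulate a cohort (or take one as
#' given), censor post-steroid values, cluster in two passes, compare
#' timepoints, derive trajectory features, run the covariate/feature test
#' battery under the chosen multiple-testing policy, and write all outputs
#' -- labels, centroid curves, the significance window, per-timepoint
#' tests, the battery, figures and a machine-readable run manifest -- into
#' `out_dir`. Every file round-trips through the package's own readers.
#'
#' Pass-1 non-convergence (the expected outcome for a small homogeneous
#' group) is caught: the cohort is treated as a single group, the fallback
#' is recorded in the manifest together with the diagnosis, and the
#' remaining artifacts are still written.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort A `cortisol_cohort`, or `NULL` to simulate one.
#' @param seed Integer seed driving simulation and clustering.
#' @param n_patients,profiles,counts Passed to [generate_cohort()] when
#'   `cohort` is NULL.
#' @param k `"auto"` or a fixed integer cluster count.
#' @inheritParams two_pass_cluster
#' @param write_figures Write PNG figures (elbow, cluster means, spaghetti,
#'   missingness).
#' @param min_cluster_size,stability_threshold Convergence-diagnostic
#'   settings passed to [two_pass_cluster()].
#' @return Invisibly, a list with `paths`, `result` (`two_pass_fit` or
#'   `NULL` on the fallback path), `battery`, `features`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_full(tempfile(), seed = 1, n_patients = 30, n_restarts = 5)
#' names(res$paths)
#' }
#' @export
run_full <- function(out_dir,
                     cohort = NULL,
                     seed = 1L,
                     n_patients = 77,
                     profiles = default_profiles("remission"),
                     counts = NULL,
                     k = "auto",
                     k_grid = 1:6,
                     n_restarts = 25,
                     alpha_policy = "bh",
                     q = 0.05,
                     write_figures = TRUE,
                     min_cluster_size = 3,
                     stability_threshold = 0.7) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(seed, 2L)
  paths <- character(0)

  simulated <- is.null(cohort)
  if (simulated) {
    cohort <- generate_cohort(
      n_patients, profiles = profiles, counts = counts, seed = seeds[1]
    )
    paths <- c(paths, write_cohort(cohort, out_dir))
  }

  meas <- censor_after_steroids(
    cohort$measurements, cohort$steroids
  )
  xm <- as_cortisol_matrix(meas, grid = attr(cohort, "grid"))

  result <- NULL
  fallback <- NULL
  result <- tryCatch(
    two_pass_cluster(
      xm, k = k, k_grid = k_grid, n_restarts = n_restarts,
      seed = seeds[2], alpha_policy = alpha_policy, q = q,
      min_cluster_size = min_cluster_size,
      stability_threshold = stability_threshold
    ),
    cortclust_nonconvergence = function(cnd) {
      fallback <<- cnd$diagnosis
      NULL
    }
  )

  if (is.null(result)) {
    # one-group fallback, as used when a small homogeneous group cannot be
    # split reliably
    labels <- tibble::tibble(
      patient_id = xm$patient_id, .cluster = factor(1)
    )
    final_fit <- NULL
  } else {
    labels <- tidy(result) |>
      dplyr::transmute(
        patient_id = .data$patient_id,
        .cluster = .data$.cluster
      )
    final_fit <- result$pass2 %||% result$pass1
  }

  features <- derive_features(meas, window = range(attr(cohort, "grid")))

  battery <- NULL
  if (!is.null(result) && result$k >= 2) {
    covs <- cohort$covariates |>
      dplyr::inner_join(labels, by = "patient_id") |>
      dplyr::inner_join(features, by = "patient_id") |>
      dplyr::filter(!is.na(.data$.cluster))
    tp <- result$window$tests
    extra_p <- setNames(
      tp$p_value[!is.na(tp$p_value)],
      paste0("cortisol_", tp$hours[!is.na(tp$p_value)], "h")
    )
    battery <- test_battery(
      covs,
      group = ".cluster",
      continuous = c(
        "age", "length_of_stay", "ki67", "max_diameter_cm",
        "tumor_volume_cm3", "knosp_grade", "initial_cortisol",
        "nadir_cortisol", "descent_velocity"
      ),
      categorical = c(
        "male", "macroadenoma", "apoplexy", "crooke_hyaline",
        "piecemeal_resection", "intraop_csf_leak",
        "postop_complication", "postop_csf_leak"
      ),
      alpha_policy = alpha_policy, q = q, extra_p = extra_p
    )
  }

  # ---- write artifacts -------------------------------------------------
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(labels, p("labels.csv"))
  paths["labels"] <- p("labels.csv")

  if (!is.null(final_fit)) {
    cent <- tidy(final_fit)
    readr::write_csv(cent, p("centroids.csv"))
    paths["centroids"] <- p("centroids.csv")
    tests_flat <- result$window$tests |> dplyr::select(-"groups")
    readr::write_csv(tests_flat, p("timepoint_tests.csv"))
    paths["timepoint_tests"] <- p("timepoint_tests.csv")
    jsonlite::write_json(
      list(
        hours = result$window$hours,
        threshold = result$window$threshold,
        alpha_policy = result$window$alpha_policy,
        rule = result$window$rule
      ),
      p("window.json"),
      auto_unbox = TRUE, digits = NA
    )
    paths["window"] <- p("window.json")
  }

  if (!is.null(battery)) {
    readr::write_csv(
      dplyr::select(battery, -"groups", -dplyr::any_of("expected")),
      p("battery.csv")
    )
    paths["battery"] <- p("battery.csv")
    jsonlite::write_json(
      c(
        as.list(glance(battery)),
        list(tests = dplyr::select(
          tibble::as_tibble(battery), -"groups", -dplyr::any_of("expected")
        ))
      ),
      p("battery.json"),
      auto_unbox = TRUE, digits = NA
    )
    paths["battery_json"] <- p("battery.json")
  }

  config <- list(
    seed = seed, n_patients = n_patients, counts = counts,
    k = k, k_grid = k_grid, n_restarts = n_restarts,
    alpha_policy = alpha_policy, q = q, simulated = simulated
  )
  manifest <- list(
    package = "cortclust",
    version = as.character(utils::packageVersion("cortclust")),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    k_used = if (is.null(result)) NA else result$k,
    converged = is.null(fallback),
    fallback_diagnosis = fallback,
    n_patients_clustered = nrow(labels)
  )
  jsonlite::write_json(
    manifest, p("manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  paths["manifest"] <- p("manifest.json")

  if (write_figures) {
    save_plot <- function(name, plot) {
      f <- p(paste0(name, ".png"))
      ggplot2::ggsave(f, plot, width = 7, height = 5, dpi = 120)
      paths[name] <<- f
    }
    if (!is.null(result) && !is.null(result$elbow)) {
      save_plot("elbow", autoplot(result$elbow))
    }
    save_plot("cluster_means", plot_cluster_means(meas, labels))
    save_plot("spaghetti", plot_spaghetti(meas, labels))
    save_plot("missingness", plot_missingness(cohort))
  }

  invisible(list(
    paths = paths,
    result = result,
    battery = battery,
    features = features,
    labels = labels,
    manifest = manifest
  ))
}
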