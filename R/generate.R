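#' Simulate cortisol trajectories from one profile
#'
#' Draws `n` patient trajectories from a single profile. Each patient gets a
#' shared random intercept (SD = `patient_effect_sd_fraction` times the
#' per-timepoint SD) plus an independent residual scaled so the *marginal*
#' SD at every timepoint equals the profile's `sd` column; this induces a
#' within-curve correlation of `patient_effect_sd_fraction^2` between
#' timepoints, giving smooth patient curves while preserving the marginal
#' moments. Values are floored at `truncation_floor`. Afterwards two
#' missingness mechanisms apply: monotone steroid-replacement censoring
#' (per-interval hazard `censor_hazard`: every value strictly after the
#' steroid time is removed) and independent sporadic missingness.
#'
#' @param profile Tibble for a single profile label (`hours`, `mean`, `sd`),
#'   e.g. one label of [default_profiles()].
#' @param n Number of patients to draw.
#' @param patient_effect_sd_fraction Fraction (in \[0, 1\]) of each marginal
#'   SD attributed to the patient-level intercept.
#' @param censor_hazard Per-6-h-interval probability that replacement
#'   steroids start at that grid point (first grid point is never censored).
#' @param sporadic_missing_rate Per-cell independent missingness probability.
#' @param truncation_floor Minimum cortisol value (mcg/dL); use `-Inf` to
#'   disable flooring (e.g. when checking marginal moments).
#' @param patient_id Optional character vector of length `n` of ids.
#' @param seed Optional integer seed (the ambient RNG stream is untouched).
#'
#' @return A tibble with columns `patient_id`, `hours`, `cortisol` (NA where
#'   unobserved), `observed`, and `steroid_hours` (NA when no steroids were
#'   started on the grid).
#'
#' @examples
#' prof <- dplyr::filter(default_profiles("remission"), label == "B")
#' generate_trajectory(prof, n = 2, seed = 1)
#' @export
generate_trajectory <- function(profile,
                                n = 1,
                                patient_effect_sd_fraction = 0.5,
                                censor_hazard = 0,
                                sporadic_missing_rate = 0,
                                truncation_floor = 0.1,
                                patient_id = NULL,
                                seed = NULL) {
  if (length(unique(profile$label %||% "x")) > 1) {
    abort("`profile` must contain a single profile label.")
  }
  profile <- dplyr::arrange(profile, .data$hours)
  f <- patient_effect_sd_fraction
  if (!is_scalar_number(f) || f < 0) {
    abort("`patient_effect_sd_fraction` must be a non-negative number.")
  }
  if (f > 1) {
    abort(paste(
      "`patient_effect_sd_fraction` must be <= 1:",
      "the residual variance would be negative."
    ))
  }
  check_probability(censor_hazard, "censor_hazard")
  check_probability(sporadic_missing_rate, "sporadic_missing_rate")
  hours <- profile$hours
  T <- length(hours)
  ids <- patient_id %||% sprintf("P%03d", seq_len(n))
  stopifnot(length(ids) == n)

  with_seed(seed, {
    intercept <- rnorm(n)                       # shared per-patient deviate
    resid <- matrix(rnorm(n * T), n, T)
    values <- matrix(profile$mean, n, T, byrow = TRUE) +
      outer(intercept, f * profile$sd) +
      resid * matrix(sqrt(1 - f^2) * profile$sd, n, T, byrow = TRUE)
    values <- pmax(values, truncation_floor)

    # monotone censoring: geometric hazard over intervals after the first
    # grid point; steroid_hours is the grid time at which steroids begin
    steroid <- rep(NA_real_, n)
    if (censor_hazard > 0 && T > 1) {
      u <- matrix(runif(n * (T - 1)) < censor_hazard, n, T - 1)
      first <- apply(u, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
      steroid <- ifelse(is.na(first), NA_real_, hours[first + 1L])
    }
    observed <- matrix(TRUE, n, T)
    for (i in seq_len(n)) {
      if (!is.na(steroid[i])) observed[i, hours > steroid[i]] <- FALSE
    }
    if (sporadic_missing_rate > 0) {
      observed <- observed & matrix(runif(n * T) >= sporadic_missing_rate, n, T)
    }

    vals <- c(t(values))
    obs <- c(t(observed))
    tibble::tibble(
      patient_id = rep(ids, each = T),
      hours = rep(hours, n),
      cortisol = ifelse(obs, vals, NA_real_),
      observed = obs,
      steroid_hours = rep(steroid, each = T)
    )
  })
}

#' Simulate a synthetic postoperative cohort
#'
#' Generates a full cohort: cluster labels from the mixing weights (or fixed
#' per-profile counts), trajectories via [generate_trajectory()], and a
#' per-patient covariate table (demographics, tumor and treatment variables)
#' drawn from independent marginal distributions typical of surgical
#' Cushing's-disease series. Fully deterministic given `seed`.
#'
#' @param n_patients Cohort size.
#' @param profiles Profile tibble as returned by [default_profiles()].
#' @param counts Optional integer vector (one per profile label, in label
#'   order) of exact per-cluster sizes; must sum to `n_patients`. When `NULL`
#'   labels are drawn from the mixing weights.
#' @param remission Logical flag stored on every patient's covariate record
#'   (defaults to `TRUE` when the profile set has more than one component).
#' @param seed Integer seed; required for a reproducible cohort.
#' @inheritParams generate_trajectory
#'
#' @return An object of class `cortisol_cohort`: a list of tibbles
#'   `measurements` (`patient_id`, `hours`, `cortisol`, `observed`),
#'   `steroids` (`patient_id`, `steroid_hours`), `covariates` (one row per
#'   patient) and `true_labels` (`patient_id`, `true_label`), plus the grid
#'   as attribute `"grid"`.
#'
#' @examples
#' cohort <- generate_cohort(20, default_profiles("remission"), seed = 1)
#' cohort
#' @export
generate_cohort <- function(n_patients,
                            profiles = default_profiles("remission"),
                            counts = NULL,
                            patient_effect_sd_fraction = 0.5,
                            censor_hazard = 0.13,
                            sporadic_missing_rate = 0.05,
                            truncation_floor = 0.1,
                            remission = NULL,
                            seed = NULL) {
  profiles <- validate_profiles(profiles)
  labels <- unique(profiles$label)
  if (n_patients < length(labels)) {
    abort("`n_patients` must be at least the number of profiles.")
  }
  weights <- profiles |>
    dplyr::distinct(.data$label, .data$weight) |>
    dplyr::arrange(match(.data$label, labels))
  if (!is.null(counts)) {
    if (length(counts) != length(labels) || sum(counts) != n_patients) {
      abort("`counts` must have one entry per profile and sum to `n_patients`.")
    }
  }
  remission <- remission %||% (length(labels) > 1)

  seeds <- spawn_seeds(seed, 2L + length(labels))
  assignment <- with_seed(seeds[1], {
    if (is.null(counts)) {
      sample(labels, n_patients, replace = TRUE, prob = weights$weight)
    } else {
      sample(rep(labels, counts))
    }
  })
  ids <- sprintf("P%03d", seq_len(n_patients))

  meas <- purrr::imap(labels, function(lab, j) {
    idx <- which(assignment == lab)
    if (length(idx) == 0) return(NULL)
    generate_trajectory(
      dplyr::filter(profiles, .data$label == lab),
      n = length(idx),
      patient_effect_sd_fraction = patient_effect_sd_fraction,
      censor_hazard = censor_hazard,
      sporadic_missing_rate = sporadic_missing_rate,
      truncation_floor = truncation_floor,
      patient_id = ids[idx],
      seed = seeds[2L + j]
    )
  })
  meas <- dplyr::bind_rows(meas) |>
    dplyr::arrange(match(.data$patient_id, ids), .data$hours)

  steroids <- meas |>
    dplyr::distinct(.data$patient_id, .data$steroid_hours)
  covariates <- with_seed(
    seeds[2],
    draw_covariates(ids, remission = remission)
  )

  new_cortisol_cohort(
    measurements = dplyr::select(meas, -"steroid_hours"),
    steroids = steroids,
    covariates = covariates,
    true_labels = tibble::tibble(patient_id = ids, true_label = assignment),
    grid = profile_grid(profiles)
  )
}

# Independent marginal draws for the covariate table; `remission` selects
# between the remission-group and non-remission-group marginals.
draw_covariates <- function(ids, remission = TRUE) {
  n <- length(ids)
  p <- if (isTRUE(remission)) {
    list(
      male = 0.416, age = c(45.1, 15.2), los = c(3.2, 1.5),
      ki67 = c(0.1, 0.1), diam = c(1.0, 0.7), vol = c(1.1, 2.4),
      knosp = c(1.2, 1.3), macro = 0.286, apoplexy = 0.065,
      crooke = 0.117, piecemeal = 0.468, iop_leak = 0.130,
      complication = 0.143, postop_leak = 0.026
    )
  } else {
    list(
      male = 0.471, age = c(43.1, 13.3), los = c(3.4, 2.0),
      ki67 = c(0.0, 0.05), diam = c(1.1, 0.8), vol = c(1.7, 2.9),
      knosp = c(1.7, 1.5), macro = 0.471, apoplexy = 0.176,
      crooke = 0.059, piecemeal = 0.412, iop_leak = 0.118,
      complication = 0.176, postop_leak = 0.118
    )
  }
  tibble::tibble(
    patient_id = ids,
    male = rbinom(n, 1, p$male) == 1,
    age = rnorm(n, p$age[1], p$age[2]),
    length_of_stay = pmax(round(rnorm(n, p$los[1], p$los[2]), 1), 1),
    ki67 = pmax(rnorm(n, p$ki67[1], p$ki67[2]), 0),
    max_diameter_cm = pmax(rnorm(n, p$diam[1], p$diam[2]), 0.1),
    tumor_volume_cm3 = pmax(rnorm(n, p$vol[1], p$vol[2]), 0.01),
    knosp_grade = pmin(pmax(round(rnorm(n, p$knosp[1], p$knosp[2])), 0), 4),
    macroadenoma = rbinom(n, 1, p$macro) == 1,
    apoplexy = rbinom(n, 1, p$apoplexy) == 1,
    crooke_hyaline = rbinom(n, 1, p$crooke) == 1,
    piecemeal_resection = rbinom(n, 1, p$piecemeal) == 1,
    intraop_csf_leak = rbinom(n, 1, p$iop_leak) == 1,
    postop_complication = rbinom(n, 1, p$complication) == 1,
    postop_csf_leak = rbinom(n, 1, p$postop_leak) == 1,
    remission = isTRUE(remission)
  )
}

new_cortisol_cohort <- function(measurements, steroids, covariates,
                                true_labels, grid) {
  structure(
    list(
      measurements = measurements,
      steroids = steroids,
      covariates = covariates,
      true_labels = true_labels
    ),
    grid = grid,
    class = "cortisol_cohort"
  )
}

#' @export
print.cortisol_cohort <- function(x, ...) {
  n <- nrow(x$covariates)
  grid <- attr(x, "grid")
  n_obs <- sum(x$measurements$observed)
  n_cells <- nrow(x$measurements)
  cat(sprintf(
    "<cortisol_cohort> %d patients, grid %g-%g h (%d timepoints)\n",
    n, min(grid), max(grid), length(grid)
  ))
  cat(sprintf(
    "  observed cells: %d / %d (%.1f%%); steroid-censored patients: %d\n",
    n_obs, n_cells, 100 * n_obs / n_cells,
    sum(!is.na(x$steroids$steroid_hours))
  ))
  if (!is.null(x$true_labels)) {
    tab <- table(x$true_labels$true_label)
    cat("  true labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes three CSV files into `dir`: `measurements.csv`
#' (long format, one row per patient-timepoint, empty cells for missing
#' values), `covariates.csv` and, when ground truth is present,
#' `labels.csv`. `read_measurements()` and `read_covariates()` read them
#' back; unobserved rows come back with `cortisol = NA`.
#'
#' @param cohort A `cortisol_cohort`.
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` returns the written paths invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meas <- cohort$measurements |>
    dplyr::left_join(cohort$steroids, by = "patient_id") |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      hours_postop = .data$hours,
      cortisol_mcg_dl = .data$cortisol,
      steroid_hours = .data$steroid_hours
    )
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    covariates = file.path(dir, "covariates.csv")
  )
  readr::write_csv(meas, paths[["measurements"]], na = "")
  readr::write_csv(cohort$covariates, paths[["covariates"]], na = "")
  if (!is.null(cohort$true_labels)) {
    paths[["labels"]] <- file.path(dir, "labels.csv")
    readr::write_csv(cohort$true_labels, paths[["labels"]], na = "")
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @param path A CSV path written by `write_cohort()`.
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::transmute(
      patient_id = as.character(.data$patient_id),
      hours = .data$hours_postop,
      cortisol = .data$cortisol_mcg_dl,
      observed = !is.na(.data$cortisol_mcg_dl),
      steroid_hours = .data$steroid_hours
    )
}

#' @rdname write_cohort
#' @export
read_covariates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(patient_id = as.character(.data$patient_id))
}
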