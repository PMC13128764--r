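#' Pivot long measurements to a patients-by-timepoints matrix
#'
#' Builds the rectangular input of the clustering stage: an n-by-T matrix of
#' cortisol values with `NA` marking unobserved cells. Patients with no
#' observed value on the grid cannot be clustered and are dropped with a
#' message reporting the count.
#'
#' @param measurements Long tibble with columns `patient_id`, `hours`,
#'   `cortisol` (NA = unobserved). Rows for unobserved cells may be present
#'   (with NA) or simply absent.
#' @param grid Timepoint grid in hours; defaults to the sorted unique
#'   `hours` present.
#'
#' @return An object of class `cortisol_matrix`: a list with `values`
#'   (numeric matrix, rownames = patient ids, NA = missing), `hours`, and
#'   `patient_id`.
#' @examples
#' cohort <- generate_cohort(10, seed = 1)
#' as_cortisol_matrix(cohort$measurements)
#' @export
as_cortisol_matrix <- function(measurements, grid = NULL) {
  grid <- grid %||% sort(unique(measurements$hours))
  wide <- measurements |>
    dplyr::filter(.data$hours %in% grid, !is.na(.data$cortisol)) |>
    dplyr::group_by(.data$patient_id, .data$hours) |>
    dplyr::summarise(cortisol = mean(.data$cortisol), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "hours", values_from = "cortisol")
  ids_all <- unique(as.character(measurements$patient_id))
  values <- matrix(
    NA_real_, length(ids_all), length(grid),
    dimnames = list(ids_all, as.character(grid))
  )
  have <- intersect(as.character(grid), names(wide))
  values[as.character(wide$patient_id), have] <-
    as.matrix(wide[, have, drop = FALSE])
  empty <- rowSums(!is.na(values)) == 0
  if (any(empty)) {
    inform(sprintf(
      "Dropping %d patient(s) with no observed value on the grid.",
      sum(empty)
    ))
    values <- values[!empty, , drop = FALSE]
  }
  new_cortisol_matrix(values, grid)
}

new_cortisol_matrix <- function(values, hours) {
  structure(
    list(
      values = values,
      hours = as.numeric(hours),
      patient_id = rownames(values)
    ),
    class = "cortisol_matrix"
  )
}

# Accept a cortisol_matrix, a cortisol_cohort, or a bare matrix with NAs.
as_matrix_input <- function(x) {
  if (inherits(x, "cortisol_matrix")) return(x)
  if (inherits(x, "cortisol_cohort")) {
    return(as_cortisol_matrix(x$measurements, grid = attr(x, "grid")))
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("R%03d", seq_len(nrow(x)))
    hours <- suppressWarnings(as.numeric(colnames(x)))
    if (is.null(colnames(x)) || anyNA(hours)) hours <- seq_len(ncol(x))
    return(new_cortisol_matrix(x, hours))
  }
  if (is.data.frame(x)) return(as_cortisol_matrix(x))
  abort("Cannot interpret `x` as a patients-by-timepoints matrix.")
}

#' @export
print.cortisol_matrix <- function(x, ...) {
  cat(sprintf(
    "<cortisol_matrix> %d patients x %d timepoints (%g-%g h), %.1f%% observed\n",
    nrow(x$values), ncol(x$values), min(x$hours), max(x$hours),
    100 * mean(!is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.cortisol_matrix <- function(x) dim(x$values)

#' Snap irregular measurement times onto the 6-hourly grid
#'
#' Assigns each raw measurement to the nearest grid point within a
#' half-open window of +/- 3 h (`[t - 3, t + 3)`); multiple measurements
#' landing in the same bin are averaged. Measurements beyond the last grid
#' point + 3 h are dropped with a message.
#'
#' @param measurements Tibble with `patient_id`, `hours` (raw, non-negative)
#'   and `cortisol`.
#' @param grid Target grid, default 6, 12, ..., 96 h.
#' @return A tibble `patient_id`, `hours` (grid values), `cortisol` with one
#'   row per observed patient-gridpoint.
#' @examples
#' bin_to_grid(tibble::tibble(patient_id = "P1", hours = 7, cortisol = 20))
#' @export
bin_to_grid <- function(measurements, grid = seq(6, 96, by = 6)) {
  if (any(measurements$hours < 0)) {
    abort("Measurement times must be non-negative hours post-op.")
  }
  half <- min(diff(grid)) / 2
  snapped <- measurements |>
    dplyr::mutate(
      .bin = purrr::map_dbl(.data$hours, function(t) {
        hit <- which(t >= grid - half & t < grid + half)
        if (length(hit)) grid[hit[1]] else NA_real_
      })
    )
  dropped <- sum(is.na(snapped$.bin) & !is.na(snapped$cortisol))
  if (dropped > 0) {
    inform(sprintf(
      "Dropping %d measurement(s) outside the %g-%g h grid (+/- %g h).",
      dropped, min(grid), max(grid), half
    ))
  }
  snapped |>
    dplyr::filter(!is.na(.data$.bin), !is.na(.data$cortisol)) |>
    dplyr::group_by(.data$patient_id, hours = .data$.bin) |>
    dplyr::summarise(cortisol = mean(.data$cortisol), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$hours)
}

#' Discard cortisol values after replacement steroids begin
#'
#' Values measured after exogenous glucocorticoids no longer reflect
#' endogenous secretion. Every grid point strictly after a patient's
#' steroid-start time is set to missing; values at or before it are kept.
#' Patients without a steroid time are unchanged.
#'
#' @param measurements Tibble with `patient_id`, `hours`, `cortisol`
#'   (and optionally a `steroid_hours` column used when `steroid_times` is
#'   not supplied).
#' @param steroid_times Either a tibble `patient_id`, `steroid_hours`
#'   (NA = never) or `NULL` to use a `steroid_hours` column in
#'   `measurements`.
#' @return `measurements` with censored cells set to `cortisol = NA` and an
#'   `observed` column updated accordingly.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", hours = c(6, 12, 18), cortisol = 1:3)
#' censor_after_steroids(m, tibble::tibble(patient_id = "P1", steroid_hours = 12))
#' @export
censor_after_steroids <- function(measurements, steroid_times = NULL) {
  if (is.null(steroid_times)) {
    if (!"steroid_hours" %in% names(measurements)) {
      abort("Provide `steroid_times` or a `steroid_hours` column.")
    }
    out <- measurements
  } else {
    out <- measurements |>
      dplyr::select(-dplyr::any_of("steroid_hours")) |>
      dplyr::left_join(steroid_times, by = "patient_id")
  }
  out |>
    dplyr::mutate(
      .censored = !is.na(.data$steroid_hours) &
        .data$hours > .data$steroid_hours,
      cortisol = ifelse(.data$.censored, NA_real_, .data$cortisol),
      observed = !is.na(.data$cortisol)
    ) |>
    dplyr::select(-".censored")
}
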