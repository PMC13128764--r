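#' Derive per-patient trajectory features
#'
#' Summarizes each (already censored) trajectory by the three quantities
#' used to characterize postoperative cortisol dynamics:
#'
#' * `initial_cortisol` -- the value at the 6 h timepoint (mcg/dL);
#' * `nadir_cortisol` -- the minimum observed value within the analysis
#'   window (mcg/dL);
#' * `descent_velocity` -- `(cortisol(6 h) - cortisol(18 h)) / 12` in
#'   mcg/dL per hour. Positive values mean decline; a negative velocity
#'   means the cortisol rose between 6 h and 18 h. Defined only when both
#'   the 6 h and 18 h values are observed.
#'
#' Patients with no observed value inside the window get all-NA features.
#'
#' @param measurements Long tibble (`patient_id`, `hours`, `cortisol`) with
#'   steroid censoring already applied (see [censor_after_steroids()]).
#' @param window Length-2 numeric, inclusive bounds of the analysis window
#'   in hours (default `c(6, 36)`).
#' @param initial_hour,velocity_hours Timepoints defining the initial value
#'   and the descent interval.
#' @return A tibble with one row per patient: `patient_id`,
#'   `initial_cortisol`, `nadir_cortisol`, `descent_velocity`.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", hours = c(6, 18), cortisol = c(30, 18))
#' derive_features(m) # descent_velocity = 1
#' @export
derive_features <- function(measurements, window = c(6, 36),
                            initial_hour = 6, velocity_hours = c(6, 18)) {
  stopifnot(length(window) == 2, length(velocity_hours) == 2)
  span <- diff(velocity_hours)
  measurements |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      initial_cortisol = value_at(.data$hours, .data$cortisol, initial_hour),
      nadir_cortisol = {
        w <- .data$hours >= window[1] & .data$hours <= window[2] &
          !is.na(.data$cortisol)
        if (any(w)) min(.data$cortisol[w]) else NA_real_
      },
      descent_velocity = (value_at(.data$hours, .data$cortisol,
                                   velocity_hours[1]) -
        value_at(.data$hours, .data$cortisol, velocity_hours[2])) / span,
      .groups = "drop"
    )
}

value_at <- function(hours, cortisol, h) {
  i <- which(hours == h & !is.na(cortisol))
  if (length(i)) mean(cortisol[i]) else NA_real_
}
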