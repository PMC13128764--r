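#' Default cortisol trajectory profiles
#'
#' Per-timepoint means and SDs (mcg/dL) of serum cortisol on the 6-hourly
#' grid over the first 36 h after transsphenoidal surgery, for the two
#' patient groups the package models. The remission group is a mixture of
#' three trajectory phenotypes -- A (low initial value, slow fall),
#' B (high initial value, moderate fall) and C (low initial value, rapid
#' fall) -- mixing in proportions 23/77, 15/77 and 39/77. The non-remission
#' group is a single profile with persistently elevated cortisol.
#'
#' These moments are the defaults used by [generate_cohort()]; replace them
#' with your own tibble of the same shape to simulate other scenarios.
#'
#' @param group `"remission"` (three profiles) or `"non_remission"`
#'   (one profile).
#'
#' @return A tibble with one row per profile-timepoint: `label`, `hours`,
#'   `mean`, `sd` (both mcg/dL) and `weight` (mixing proportion, constant
#'   within a label and summing to 1 across labels).
#'
#' @examples
#' default_profiles("remission")
#' default_profiles("non_remission")
#' @export
default_profiles <- function(group = c("remission", "non_remission")) {
  group <- match.arg(group)
  hours <- seq(6, 36, by = 6)
  if (group == "remission") {
    out <- dplyr::bind_rows(
      tibble::tibble(
        label = "A", hours = hours,
        mean = c(25.5, 31.5, 32.1, 12.7, 4.7, 2.7),
        sd   = c(8.6, 10.7, 11.4, 5.4, 1.9, 1.4),
        weight = 23 / 77
      ),
      tibble::tibble(
        label = "B", hours = hours,
        mean = c(61.2, 56.6, 34.7, 21.5, 17.1, 11.9),
        sd   = c(15.4, 23.7, 19.2, 11.9, 10.2, 8.4),
        weight = 15 / 77
      ),
      tibble::tibble(
        label = "C", hours = hours,
        mean = c(25.5, 10.6, 4.6, 3.5, 3.4, 3.6),
        sd   = c(14.7, 7.3, 3.5, 3.3, 2.3, 2.7),
        weight = 39 / 77
      )
    )
  } else {
    out <- tibble::tibble(
      label = "NR", hours = hours,
      mean = c(54.0, 26.9, 24.7, 22.8, 18.4, 16.6),
      sd   = c(25.2, 15.2, 20.4, 11.0, 15.8, 11.8),
      weight = 1
    )
  }
  validate_profiles(out)
}

#' Validate a profile tibble
#'
#' Checks the invariants [generate_cohort()] relies on: every profile is
#' defined on the same strictly increasing grid, SDs are non-negative, and
#' mixing weights are constant within a profile and sum to 1.
#'
#' @param profiles A tibble with columns `label`, `hours`, `mean`, `sd`,
#'   `weight`.
#' @return `profiles`, invisibly unchanged, or an error.
#' @export
validate_profiles <- function(profiles) {
  needed <- c("label", "hours", "mean", "sd", "weight")
  if (!all(needed %in% names(profiles))) {
    abort(paste0(
      "`profiles` must have columns ",
      paste(needed, collapse = ", "), "."
    ))
  }
  grids <- profiles |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(grid = list(sort(.data$hours)), .groups = "drop")
  ref <- grids$grid[[1]]
  if (any(diff(ref) <= 0)) abort("Profile grid must be strictly increasing.")
  same <- vapply(grids$grid, identical, logical(1), y = ref)
  if (!all(same)) abort("All profiles must share the same timepoint grid.")
  if (any(profiles$sd < 0)) abort("Profile SDs must be non-negative.")
  w <- profiles |>
    dplyr::distinct(.data$label, .data$weight)
  if (nrow(w) != length(unique(profiles$label))) {
    abort("`weight` must be constant within each profile label.")
  }
  if (abs(sum(w$weight) - 1) > 1e-9) {
    abort("Mixing weights must sum to 1 (tolerance 1e-9).")
  }
  profiles
}

profile_grid <- function(profiles) sort(unique(profiles$hours))
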