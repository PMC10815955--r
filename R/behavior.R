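# Behavioral endpoint aggregation: horizontal-activity counts summed over a
# scoring window, and social-interaction time with the pair as the
# statistical unit.

#' Sum activity counts over a scoring window
#'
#' Per-subject total of activity counts over `[t0, t1)` minutes since
#' dosing. The window must align exactly with bin edges (no pro-rating, so
#' endpoints stay exact integers); typical windows are `(0, 90)`,
#' `(80, 150)` and `(0, 120)` minutes.
#'
#' @param activity Tibble with columns `subject`, `arm`, `t0_min`, `t1_min`,
#'   `counts` (one row per subject x bin), as produced by
#'   [simulate_behavior()] or read from CSV.
#' @param window `(t0, t1)` minutes.
#' @return Tibble (subject, arm, value) of window totals.
#' @export
activity_sum <- function(activity, window = c(0, 90)) {
  needed <- c("subject", "arm", "t0_min", "t1_min", "counts")
  if (!all(needed %in% names(activity))) {
    stop_input(sprintf("activity table needs columns: %s",
                       paste(needed, collapse = ", ")))
  }
  if (any(activity$counts < 0)) stop_input("activity counts must be >= 0")
  if (window[2] <= window[1]) stop_config("window must have t1 > t0")
  span <- range(activity$t0_min, activity$t1_min)
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9) {
    stop_config(sprintf("window [%g, %g] min outside recorded span [%g, %g] min",
                        window[1], window[2], span[1], span[2]))
  }
  edges <- sort(unique(c(activity$t0_min, activity$t1_min)))
  if (!any(abs(edges - window[1]) < 1e-9) || !any(abs(edges - window[2]) < 1e-9)) {
    stop_config(sprintf("window [%g, %g] min is not aligned to bin edges",
                        window[1], window[2]))
  }
  sel <- dplyr::filter(activity,
    .data$t0_min >= window[1] - 1e-9, .data$t1_min <= window[2] + 1e-9
  )
  dplyr::summarise(
    dplyr::group_by(sel, .data$subject, .data$arm),
    value = sum(.data$counts), .groups = "drop"
  )
}

#' Social-interaction endpoint per pair
#'
#' The endpoint is the total time a pair spent in active, non-aggressive
#' social behavior during the test; the pair (not the individual animal) is
#' the statistical unit.
#'
#' @param social Tibble with columns `pair`, `arm`, `social_s`,
#'   `test_duration_s`.
#' @return Tibble (pair, arm, value, fraction) where `fraction` is the
#'   endpoint as a proportion of the test duration.
#' @export
social_endpoint <- function(social) {
  needed <- c("pair", "arm", "social_s", "test_duration_s")
  if (!all(needed %in% names(social))) {
    stop_input(sprintf("social table needs columns: %s",
                       paste(needed, collapse = ", ")))
  }
  if (any(social$social_s < 0 | social$social_s > social$test_duration_s)) {
    stop_input("social time must lie in [0, test_duration]")
  }
  tibble(
    pair = social$pair, arm = social$arm,
    value = social$social_s,
    fraction = social$social_s / social$test_duration_s
  )
}
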