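#' Activity and movement-phase thresholds
#'
#' Two velocity cut-offs drive all activity classification: intervals with
#' velocity above `theta_active` (default 0.1 mm/s) are *active*, at or
#' below it *inactive*; active intervals are further split into *normal*
#' (0.1-1.2 mm/s] and *abrupt* (> 1.2 mm/s) movement phases.
#'
#' @param theta_active Active/inactive cut-off in mm/s (default 0.1).
#' @param theta_abrupt Normal/abrupt cut-off in mm/s (default 1.2).
#' @return A list of class `activity_thresholds`.
#' @export
activity_thresholds <- function(theta_active = 0.1, theta_abrupt = 1.2) {
  check_number(theta_active, "theta_active", min = 0, strict_min = TRUE)
  check_number(theta_abrupt, "theta_abrupt", min = theta_active, strict_min = TRUE)
  structure(list(theta_active = theta_active, theta_abrupt = theta_abrupt),
            class = "activity_thresholds")
}

#' Instantaneous swim velocity from a trajectory
#'
#' Velocity over interval i is the Euclidean step length between samples
#' i and i+1 divided by the sampling interval; no smoothing is applied by
#' default (an optional centred moving average of odd width can be applied
#' before thresholding).
#'
#' @param traj A single-well trajectory tibble with columns `t_s`, `x_mm`,
#'   `y_mm` (as produced by [cohort_trajectories()]).
#' @param smooth_window Optional odd integer; width of a centred moving
#'   average applied to the velocity series.  `1` (default) disables it.
#'
#' @return A tibble with one row per inter-sample interval: `t_start`,
#'   `t_mid`, `t_end` (s), `v` (mm/s) and `dt` (s).
#' @examples
#' traj <- tibble::tibble(t_s = c(0, 0.1), x_mm = c(0, 0.03), y_mm = c(0, 0.04))
#' compute_velocity(traj)$v # 0.5 mm/s (3-4-5 triangle over 0.1 s)
#' @export
compute_velocity <- function(traj, smooth_window = 1L) {
  n <- nrow(traj)
  if (is.null(n) || n < 2L) {
    abort_validation("a trajectory needs at least 2 samples to compute velocity")
  }
  dx <- diff(traj$x_mm)
  dy <- diff(traj$y_mm)
  dts <- diff(traj$t_s)
  v <- sqrt(dx^2 + dy^2) / dts
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) abort_validation("`smooth_window` must be odd")
    k <- rep(1 / smooth_window, smooth_window)
    # centred moving average; shrink the window at the edges
    v <- stats::filter(v, k, sides = 2)
    half <- (smooth_window - 1L) %/% 2L
    m <- length(dx)
    for (i in seq_len(m)) {
      if (is.na(v[i])) {
        lo <- max(1L, i - half); hi <- min(m, i + half)
        v[i] <- mean(sqrt(dx[lo:hi]^2 + dy[lo:hi]^2) / dts[lo:hi])
      }
    }
    v <- as.numeric(v)
  }
  tibble::tibble(
    t_start = traj$t_s[-n],
    t_mid = (traj$t_s[-n] + traj$t_s[-1]) / 2,
    t_end = traj$t_s[-1],
    v = v,
    dt = dts
  )
}

#' Classify velocity intervals into activity states and movement phases
#'
#' @param vel A velocity tibble from [compute_velocity()].
#' @param thresholds An [activity_thresholds()] object.
#'
#' @return `vel` with two added columns: `state` (`"active"` if
#'   v > theta_active else `"inactive"`) and `phase` (`"stationary"`,
#'   `"normal"` (theta_active, theta_abrupt], or `"abrupt"`
#'   (> theta_abrupt)).
#' @export
classify_activity <- function(vel, thresholds = activity_thresholds()) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  vel |>
    dplyr::mutate(
      state = dplyr::if_else(.data$v > thresholds$theta_active, "active", "inactive"),
      phase = dplyr::case_when(
        .data$v <= thresholds$theta_active ~ "stationary",
        .data$v <= thresholds$theta_abrupt ~ "normal",
        TRUE ~ "abrupt"
      )
    )
}
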