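#' Assemble a cohort of tracked larvae
#'
#' A cohort bundles per-well swim trajectories with the light schedule they
#' were recorded under.  Trajectories live in one long tibble with columns
#' `well`, `group`, `t_s`, `x_mm`, `y_mm`: positions in mm relative to the
#' well centre, sampled at a fixed rate.
#'
#' @param tracks A data frame with columns `well`, `group`, `t_s`, `x_mm`,
#'   `y_mm`; `group` must be `"control"` or `"treated"`.
#' @param schedule A [light_schedule()] covering the assay.
#' @param rate_hz Sampling rate in samples per second.  Always explicit,
#'   never inferred.
#' @param metadata Optional named list of free-form metadata.
#'
#' @return An object of class `swim_cohort`: a list with elements `tracks`
#'   (tibble), `schedule`, `rate_hz`, `metadata`.
#' @export
swim_cohort <- function(tracks, schedule, rate_hz = 25, metadata = list()) {
  tracks <- validate_tracks(tracks, rate_hz)
  validate_schedule(schedule)
  span <- schedule_span(schedule)
  dt <- 1 / rate_hz
  bad <- if (nrow(tracks) == 0L) tracks[0, 0] else tracks |>
    dplyr::summarise(
      t0 = min(.data$t_s), t1 = max(.data$t_s), .by = "well"
    ) |>
    dplyr::filter(abs(.data$t0) > 1e-6 | .data$t1 > span + 1e-6 |
                    .data$t1 < span - dt - 1e-6)
  if (nrow(bad) > 0L) {
    abort_validation(sprintf(
      "trajectory for well '%s' spans [%.3f, %.3f] s but the schedule spans [0, %.3f] s",
      bad$well[1], bad$t0[1], bad$t1[1], span
    ))
  }
  structure(
    list(
      tracks = tracks,
      schedule = schedule,
      rate_hz = rate_hz,
      metadata = metadata
    ),
    class = "swim_cohort"
  )
}

#' @export
print.swim_cohort <- function(x, ...) {
  wells <- dplyr::distinct(x$tracks, .data$well, .data$group)
  cat(sprintf(
    "<swim_cohort> %d larvae (%d control, %d treated), %.0f Hz, %d epochs over %g s\n",
    nrow(wells), sum(wells$group == "control"), sum(wells$group == "treated"),
    x$rate_hz, nrow(x$schedule), schedule_span(x$schedule)
  ))
  invisible(x)
}

# Trajectory invariants: sorted strictly-increasing times per well, uniform
# sampling within 1e-6 s (a dropped frame is an error, not an interpolation
# target), finite coordinates, >= 2 samples, one group label per well.
validate_tracks <- function(tracks, rate_hz) {
  check_number(rate_hz, "rate_hz", min = 0, strict_min = TRUE)
  need <- c("well", "group", "t_s", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf("track table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  tracks <- tibble::as_tibble(tracks)[need]
  if (!all(tracks$group %in% c("control", "treated"))) {
    abort_validation("`group` must be 'control' or 'treated' for every row")
  }
  if (!all(is.finite(tracks$t_s)) || !all(is.finite(tracks$x_mm)) ||
      !all(is.finite(tracks$y_mm))) {
    abort_validation("t_s, x_mm and y_mm must all be finite")
  }
  multi <- tracks |>
    dplyr::distinct(.data$well, .data$group) |>
    dplyr::count(.data$well) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort_validation(sprintf("well '%s' carries more than one group label", multi$well[1]))
  }
  tracks <- dplyr::arrange(tracks, factor(.data$well, levels = unique(tracks$well)), .data$t_s)
  dt <- 1 / rate_hz
  for (w in unique(tracks$well)) {
    tw <- tracks$t_s[tracks$well == w]
    if (length(tw) < 2L) {
      abort_validation(sprintf("well '%s' has fewer than 2 samples", w))
    }
    gaps <- diff(tw)
    if (any(gaps <= 0)) {
      i <- which(gaps <= 0)[1]
      abort_validation(sprintf(
        "well '%s': duplicated or non-increasing time at sample %d (t = %g s)",
        w, i + 1L, tw[i + 1L]
      ))
    }
    off <- abs(gaps - dt)
    if (any(off > 1e-6)) {
      i <- which(off > 1e-6)[1]
      abort_validation(sprintf(
        "well '%s': non-uniform sampling at sample %d (gap %.6f s, expected %.6f s)",
        w, i + 1L, gaps[i], dt
      ))
    }
  }
  tracks
}

#' Read tracked trajectories from CSV
#'
#' Expects the schema `well,group,t_s,x_mm,y_mm` (UTF-8, "." decimal
#' separator).  Rows are grouped by well and sorted by time; trajectory
#' invariants (uniform sampling at `rate_hz`, finite coordinates) are
#' enforced on read.
#'
#' @param path Path to a CSV file.
#' @param schedule A [light_schedule()] the recording follows.
#' @param rate_hz Sampling rate in Hz (default 25).
#' @param metadata Optional metadata list stored on the cohort.
#'
#' @return A [swim_cohort()].
#' @export
read_tracks <- function(path, schedule, rate_hz = 25, metadata = list()) {
  if (!file.exists(path)) abort_io(sprintf("track file '%s' does not exist", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  swim_cohort(raw, schedule, rate_hz = rate_hz,
              metadata = c(metadata, list(source = path)))
}

#' Write a cohort's trajectories to CSV
#'
#' Emits the `well,group,t_s,x_mm,y_mm` schema with wells in their input
#' order and times rounded to 6 decimals.  `read_tracks()` of the result
#' reproduces coordinates to well below 1e-9 mm.
#'
#' @param cohort A [swim_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(cohort, path) {
  stopifnot(inherits(cohort, "swim_cohort"))
  out <- cohort$tracks |>
    dplyr::mutate(
      t_s = sprintf("%.6f", .data$t_s),
      x_mm = sprintf("%.12g", .data$x_mm),
      y_mm = sprintf("%.12g", .data$y_mm)
    )
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write track file '%s'", path))
  invisible(path)
}

#' Split a cohort into per-well trajectory tibbles
#'
#' @param cohort A [swim_cohort()].
#' @return A named list of tibbles, one per well, each with columns
#'   `well`, `group`, `t_s`, `x_mm`, `y_mm`.
#' @export
cohort_trajectories <- function(cohort) {
  stopifnot(inherits(cohort, "swim_cohort"))
  split(cohort$tracks, factor(cohort$tracks$well, levels = unique(cohort$tracks$well)))
}
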