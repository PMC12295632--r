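#' Per-larva locomotor summary
#'
#' Computes the standard locomotor metric vector for one tracked larva:
#' total distance, mean velocity, activity fractions, and bolt statistics
#' (count, mean duration, mean distance, mean inter-bolt interval), both
#' overall and split by light/dark condition.
#'
#' Velocity intervals are assigned to the epoch containing their midpoint,
#' so the light + dark distances sum exactly to the total.  Bolts are
#' assigned to the epoch containing the bolt's temporal midpoint.  The
#' bolt interval is gap-wise (end of one bolt to start of the next) and is
#' `NA` with fewer than two bolts; all bolt means are `NA` with zero bolts.
#'
#' @param traj A single-well trajectory tibble (`well`, `group`, `t_s`,
#'   `x_mm`, `y_mm`).
#' @param schedule A [light_schedule()].
#' @param thresholds An [activity_thresholds()].
#' @param min_duration_s,merge_gap_s Bolt segmentation parameters, see
#'   [segment_bolts()].
#' @param smooth_window Optional velocity smoothing, see
#'   [compute_velocity()].
#'
#' @return A one-row tibble with the overall metrics and a `per_condition`
#'   list-column holding a tibble with the same metrics per condition.
#' @export
summarize_larva <- function(traj, schedule, thresholds = activity_thresholds(),
                            min_duration_s = 0.2, merge_gap_s = 0.1,
                            smooth_window = 1L) {
  validate_schedule(schedule)
  vel <- compute_velocity(traj, smooth_window = smooth_window)
  if (max(vel$t_end) > schedule_span(schedule) + 1e-6) {
    abort_validation("trajectory extends beyond the schedule span")
  }
  vel <- classify_activity(vel, thresholds)
  bolts <- segment_bolts(vel, thresholds, min_duration_s = min_duration_s,
                         merge_gap_s = merge_gap_s)
  cond <- epoch_condition_at(schedule, vel$t_mid)
  bolt_cond <- if (nrow(bolts) > 0L) {
    epoch_condition_at(schedule, (bolts$start_s + bolts$end_s) / 2)
  } else {
    character(0)
  }

  conditions <- unique(schedule$condition)
  per_cond <- purrr::map_dfr(conditions, function(cc) {
    metric_row(vel[cond == cc, ], bolts[bolt_cond == cc, ], condition = cc)
  })

  overall <- metric_row(vel, bolts, condition = NA_character_)
  overall$condition <- NULL
  dplyr::bind_cols(
    tibble::tibble(well_id = traj$well[1], group = traj$group[1]),
    overall,
    tibble::tibble(per_condition = list(per_cond))
  )
}

# Shared metric computation over a subset of velocity intervals and an
# associated subset of bolts.
metric_row <- function(vel, bolts, condition) {
  time_obs <- sum(vel$dt)
  dist <- sum(vel$v * vel$dt)
  active_time <- sum(vel$dt[vel$state == "active"])
  nb <- nrow(bolts)
  tibble::tibble(
    condition = condition,
    total_distance_mm = dist,
    mean_velocity_mms = if (time_obs > 0) dist / time_obs else NA_real_,
    n_bolts = nb,
    bolt_interval_s = if (nb >= 2L) {
      mean(bolts$start_s[-1] - bolts$end_s[-nb])
    } else {
      NA_real_
    },
    bolt_duration_s = if (nb > 0L) mean(bolts$duration_s) else NA_real_,
    bolt_distance_mm = if (nb > 0L) mean(bolts$distance_mm) else NA_real_,
    distance_per_bolt_mm = if (nb > 0L) sum(bolts$distance_mm) / nb else NA_real_,
    active_fraction = if (time_obs > 0) active_time / time_obs else NA_real_,
    inactive_fraction = if (time_obs > 0) 1 - active_time / time_obs else NA_real_
  )
}

schedule_id <- function(schedule) {
  paste(sprintf("%g-%g-%s", schedule$start_s, schedule$end_s, schedule$condition),
        collapse = ";")
}

#' Summaries for every larva in a cohort
#'
#' @param cohort A [swim_cohort()].
#' @inheritParams summarize_larva
#' @return A tibble with one row per larva (see [summarize_larva()]) plus a
#'   `schedule_id` column identifying the shared schedule.
#' @export
summarize_cohort <- function(cohort, thresholds = activity_thresholds(),
                             min_duration_s = 0.2, merge_gap_s = 0.1,
                             smooth_window = 1L) {
  stopifnot(inherits(cohort, "swim_cohort"))
  out <- purrr::map_dfr(
    cohort_trajectories(cohort),
    summarize_larva,
    schedule = cohort$schedule, thresholds = thresholds,
    min_duration_s = min_duration_s, merge_gap_s = merge_gap_s,
    smooth_window = smooth_window
  )
  out$schedule_id <- schedule_id(cohort$schedule)
  out
}

#' Long-format per-condition metric table
#'
#' Unnests per-larva summaries into a tidy larva x condition x metric
#' table, the shape used for light-vs-dark comparisons (two-way ANOVA,
#' per-metric group tests).
#'
#' @param summaries A summary tibble from [summarize_cohort()] (all rows
#'   must share one schedule).
#' @return A tibble with columns `well_id`, `group`, `condition`, `metric`,
#'   `value`.
#' @export
epoch_metrics <- function(summaries) {
  if (!"per_condition" %in% names(summaries)) {
    abort_validation("`summaries` must come from summarize_cohort()/summarize_larva()")
  }
  if ("schedule_id" %in% names(summaries) &&
      length(unique(summaries$schedule_id)) > 1L) {
    abort_validation("summaries mix more than one light schedule")
  }
  summaries |>
    dplyr::select("well_id", "group", "per_condition") |>
    tidyr::unnest("per_condition") |>
    tidyr::pivot_longer(
      cols = -c("well_id", "group", "condition"),
      names_to = "metric", values_to = "value"
    )
}

#' Group-mean locomotor profile (distance per time bin)
#'
#' Accumulates each larva's distance into fixed-width time bins (interval
#' midpoints decide bin membership) and averages across the larvae of one
#' group, giving the familiar distance-per-second activity trace with its
#' light-evoked peaks.
#'
#' @param cohort A [swim_cohort()].
#' @param group `"control"` or `"treated"`.
#' @param bin_s Bin width in seconds (default 1); must divide the assay
#'   span.
#' @return A tibble of class `swim_profile` with columns `group`,
#'   `bin_start_s`, `bin_mid_s`, `mean_distance_mm`, `sem`.
#' @export
locomotor_profile <- function(cohort, group, bin_s = 1) {
  stopifnot(inherits(cohort, "swim_cohort"))
  if (!group %in% c("control", "treated")) {
    abort_validation("`group` must be 'control' or 'treated'")
  }
  span <- schedule_span(cohort$schedule)
  n_bins <- span / bin_s
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort_validation("`bin_s` must divide the assay span")
  }
  n_bins <- as.integer(round(n_bins))
  trajs <- purrr::keep(cohort_trajectories(cohort), ~ .x$group[1] == group)
  if (length(trajs) == 0L) {
    abort_validation(sprintf("no larvae in group '%s'", group))
  }
  per_larva <- purrr::map(trajs, function(tr) {
    vel <- compute_velocity(tr)
    bin <- pmin(floor(vel$t_mid / bin_s) + 1L, n_bins)
    as.numeric(tapply(vel$v * vel$dt, factor(bin, levels = seq_len(n_bins)), sum,
                      default = 0))
  })
  mat <- do.call(cbind, per_larva)
  out <- tibble::tibble(
    group = group,
    bin_start_s = (seq_len(n_bins) - 1L) * bin_s,
    bin_mid_s = (seq_len(n_bins) - 0.5) * bin_s,
    mean_distance_mm = rowMeans(mat),
    sem = apply(mat, 1L, stats::sd) / sqrt(ncol(mat))
  )
  class(out) <- c("swim_profile", class(out))
  out
}
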