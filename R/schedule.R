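#' Build a light/dark schedule from explicit epochs
#'
#' A light schedule is a tibble of contiguous, non-overlapping epochs with
#' alternating illumination conditions, starting at t = 0.  It defines which
#' parts of a recording are analysed as "light" and which as "dark".
#'
#' @param start_s,end_s Numeric vectors of epoch boundaries in seconds.
#' @param condition Character vector, each element `"light"` or `"dark"`.
#'
#' @return A tibble of class `light_schedule` with columns `start_s`,
#'   `end_s`, `condition`.
#' @examples
#' light_schedule(c(0, 30), c(30, 60), c("light", "dark"))
#' @export
light_schedule <- function(start_s, end_s, condition) {
  if (length(start_s) == 0L) abort_validation("a schedule needs at least one epoch")
  if (length(start_s) != length(end_s) || length(start_s) != length(condition)) {
    abort_validation("`start_s`, `end_s` and `condition` must have equal length")
  }
  sched <- tibble::tibble(
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    condition = as.character(condition)
  )
  validate_schedule(sched)
  class(sched) <- c("light_schedule", class(sched))
  sched
}

validate_schedule <- function(sched) {
  if (!all(sched$condition %in% c("light", "dark"))) {
    abort_validation("schedule conditions must be 'light' or 'dark'")
  }
  if (abs(sched$start_s[1]) > 1e-9) {
    abort_validation("the first epoch must start at t = 0")
  }
  if (any(sched$end_s <= sched$start_s)) {
    abort_validation("every epoch must have end_s > start_s")
  }
  n <- nrow(sched)
  if (n > 1L) {
    if (any(abs(sched$start_s[-1] - sched$end_s[-n]) > 1e-9)) {
      abort_validation("epochs must be contiguous (start of each epoch = end of the previous)")
    }
    if (any(sched$condition[-1] == sched$condition[-n])) {
      abort_validation("epoch conditions must alternate")
    }
  }
  invisible(sched)
}

#' Standard alternating light/dark assay schedule
#'
#' Builds the conventional larval photo-motor schedule: `n_cycles`
#' repetitions of a light epoch followed by a dark epoch, light first,
#' starting at t = 0.  The default `standard_schedule(3, 30, 30)` is the
#' common 180 s assay (three 30 s light / 30 s dark cycles) that follows a
#' dark acclimation period; t = 0 is the start of the recording, the
#' acclimation itself is not part of the schedule.
#'
#' @param n_cycles Positive integer, number of light+dark cycles.
#' @param light_s,dark_s Positive epoch durations in seconds.
#'
#' @return A `light_schedule` tibble with `2 * n_cycles` rows.
#' @examples
#' standard_schedule(3, 30, 30) # 6 epochs spanning 180 s
#' @export
standard_schedule <- function(n_cycles = 3L, light_s = 30, dark_s = 30) {
  check_number(n_cycles, "n_cycles", min = 1)
  if (n_cycles != round(n_cycles)) abort_validation("`n_cycles` must be an integer")
  check_number(light_s, "light_s", min = 0, strict_min = TRUE)
  check_number(dark_s, "dark_s", min = 0, strict_min = TRUE)
  cycle <- light_s + dark_s
  starts <- as.vector(vapply(seq_len(n_cycles) - 1L, function(i) {
    c(i * cycle, i * cycle + light_s)
  }, numeric(2)))
  ends <- starts + rep(c(light_s, dark_s), n_cycles)
  light_schedule(starts, ends, rep(c("light", "dark"), n_cycles))
}

#' Total duration covered by a schedule
#'
#' @param sched A `light_schedule`.
#' @return The schedule span in seconds.
#' @export
schedule_span <- function(sched) {
  validate_schedule(sched)
  sched$end_s[nrow(sched)]
}

# Vectorized lookup: condition of the epoch containing each time point.
# Times exactly on a boundary belong to the epoch starting there; the
# final end point belongs to the last epoch.
epoch_condition_at <- function(sched, t) {
  idx <- findInterval(t, sched$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(sched)] <- nrow(sched)
  sched$condition[idx]
}

#' Read a schedule specification from a list or YAML config
#'
#' Accepts either `list(n_cycles=, light_s=, dark_s=)` or an explicit epoch
#' list `list(epochs = list(list(start_s=, end_s=, condition=), ...))`.
#'
#' @param spec A named list (e.g. parsed from YAML).
#' @return A `light_schedule`.
#' @export
schedule_from_spec <- function(spec) {
  if (!is.list(spec)) abort_config("schedule spec must be a list")
  if (!is.null(spec$epochs)) {
    ep <- spec$epochs
    return(light_schedule(
      vapply(ep, function(e) as.numeric(e$start_s), numeric(1)),
      vapply(ep, function(e) as.numeric(e$end_s), numeric(1)),
      vapply(ep, function(e) as.character(e$condition), character(1))
    ))
  }
  need <- c("n_cycles", "light_s", "dark_s")
  if (!all(need %in% names(spec))) {
    abort_config("schedule spec needs n_cycles, light_s, dark_s (or an explicit `epochs` list)")
  }
  standard_schedule(spec$n_cycles, spec$light_s, spec$dark_s)
}
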