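#' Swim-behavior generator parameters
#'
#' Parameters of the two-state (quiescence/bolt) alternating-renewal swim
#' model.  Bolt initiations follow a Poisson process whose rate switches
#' with the light condition (`bolt_rate_light` vs `bolt_rate_dark`);
#' bolt durations are Gamma; within a bolt the per-step speed is a
#' truncated normal (at zero) and the heading performs a bounded random
#' walk; during quiescence the larva drifts isotropically at a small
#' sub-threshold jitter speed.
#'
#' @param bolt_rate_dark,bolt_rate_light Bolt initiation rates (events/s)
#'   under dark and light conditions.
#' @param bolt_duration_mean_s Mean bolt duration (s).
#' @param bolt_duration_shape Gamma shape for bolt durations.
#' @param speed_mean_mms,speed_sd_mms Within-bolt speed distribution
#'   (mm/s), truncated at 0.
#' @param quiescent_jitter_mms Sub-threshold drift speed while quiescent
#'   (mm/s); must stay below the active threshold.
#' @param turn_sd_rad Heading noise per step within a bolt (radians).
#' @return A list of class `swim_params`.
#' @export
swim_params <- function(bolt_rate_dark = 0.2, bolt_rate_light = 0.6,
                        bolt_duration_mean_s = 0.5, bolt_duration_shape = 2,
                        speed_mean_mms = 6, speed_sd_mms = 2,
                        quiescent_jitter_mms = 0.02, turn_sd_rad = 0.5) {
  p <- list(
    bolt_rate_dark = bolt_rate_dark, bolt_rate_light = bolt_rate_light,
    bolt_duration_mean_s = bolt_duration_mean_s,
    bolt_duration_shape = bolt_duration_shape,
    speed_mean_mms = speed_mean_mms, speed_sd_mms = speed_sd_mms,
    quiescent_jitter_mms = quiescent_jitter_mms, turn_sd_rad = turn_sd_rad
  )
  for (nm in names(p)) check_number(p[[nm]], nm, min = 0)
  structure(p, class = "swim_params")
}

#' Preset parameter sets for the two study arms
#'
#' `control_swim_params()` gives a responsive larva whose bolt rate
#' triples under illumination (light-evoked activity peaks);
#' `treated_swim_params()` gives the hypokinetic phenotype: a much lower
#' bolt rate with no light modulation (light rate = dark rate), while
#' within-bolt speed is left unchanged -- movement, when it happens, looks
#' normal; it is initiation that is suppressed.
#'
#' @return A `swim_params` object.
#' @export
control_swim_params <- function() {
  swim_params(bolt_rate_dark = 0.2, bolt_rate_light = 0.6)
}

#' @rdname control_swim_params
#' @export
treated_swim_params <- function() {
  swim_params(bolt_rate_dark = 0.05, bolt_rate_light = 0.05)
}

rate_for <- function(p, condition) {
  if (condition == "light") p$bolt_rate_light else p$bolt_rate_dark
}

# Draw one waiting time of a Poisson process with piecewise-constant rate
# given by the schedule condition, starting at time tau.  Returns Inf if
# no event occurs before the schedule ends.
draw_quiescence_end <- function(p, schedule, tau) {
  span <- schedule_span(schedule)
  repeat {
    if (tau >= span) return(Inf)
    idx <- findInterval(tau, schedule$start_s)
    idx <- min(max(idx, 1L), nrow(schedule))
    boundary <- schedule$end_s[idx]
    r <- rate_for(p, schedule$condition[idx])
    if (r <= 0) {
      tau <- boundary
      next
    }
    e <- stats::rexp(1L, rate = r)
    if (tau + e <= boundary) return(tau + e)
    tau <- boundary
  }
}

rtrunc_norm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- stats::rnorm(n, mean, sd)
  while (any(out < 0)) {
    bad <- out < 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Simulate one larval swim trajectory
#'
#' Runs the alternating-renewal swim model over a light schedule: the
#' larva alternates between quiescence (exponential waiting times at the
#' condition-dependent bolt rate) and bolts (Gamma durations), moving at
#' the within-bolt speed with a random-walk heading, reflected at the
#' wall of a circular well (default 10 mm diameter, the 24-well-plate
#' scale).  Fully deterministic given `seed`.
#'
#' @param params A [swim_params()] object.
#' @param schedule A [light_schedule()].
#' @param rate_hz Sampling rate of the emitted trajectory (default 25).
#' @param group `"control"` or `"treated"` label carried on the rows.
#' @param well_id Well identifier string.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param well_diameter_mm Well diameter (default 10).
#'
#' @return A trajectory tibble (`well`, `group`, `t_s`, `x_mm`, `y_mm`)
#'   spanning the schedule at `rate_hz`.
#' @export
simulate_larva <- function(params, schedule = standard_schedule(),
                           rate_hz = 25, group = "control", well_id = "W01",
                           seed = NULL, well_diameter_mm = 10) {
  stopifnot(inherits(params, "swim_params"))
  check_number(rate_hz, "rate_hz", min = 0, strict_min = TRUE)
  validate_schedule(schedule)
  run <- function() {
    span <- schedule_span(schedule)
    dt <- 1 / rate_hz
    n_steps <- as.integer(round(span * rate_hz))
    t_mid <- (seq_len(n_steps) - 0.5) * dt

    # event timeline: alternating quiescence / bolt
    bolt_start <- numeric(0); bolt_end <- numeric(0)
    tau <- 0
    while (tau < span) {
      s <- draw_quiescence_end(params, schedule, tau)
      if (!is.finite(s) || s >= span) break
      d <- stats::rgamma(1L, shape = params$bolt_duration_shape,
                         scale = params$bolt_duration_mean_s /
                           max(params$bolt_duration_shape, 1e-12))
      e <- min(s + d, span)
      bolt_start <- c(bolt_start, s); bolt_end <- c(bolt_end, e)
      tau <- e
    }

    in_bolt <- rep(FALSE, n_steps)
    for (j in seq_along(bolt_start)) {
      in_bolt[t_mid >= bolt_start[j] & t_mid < bolt_end[j]] <- TRUE
    }

    speed <- rep(params$quiescent_jitter_mms, n_steps)
    speed[in_bolt] <- rtrunc_norm_pos(sum(in_bolt), params$speed_mean_mms,
                                      params$speed_sd_mms)
    heading <- numeric(n_steps)
    theta <- stats::runif(1L, 0, 2 * pi)
    turn <- stats::rnorm(n_steps, 0, params$turn_sd_rad)
    iso <- stats::runif(n_steps, 0, 2 * pi)
    for (i in seq_len(n_steps)) {
      theta <- if (in_bolt[i]) theta + turn[i] else iso[i]
      heading[i] <- theta
    }

    radius <- well_diameter_mm / 2
    x <- numeric(n_steps + 1L); y <- numeric(n_steps + 1L)
    for (i in seq_len(n_steps)) {
      nx <- x[i] + speed[i] * dt * cos(heading[i])
      ny <- y[i] + speed[i] * dt * sin(heading[i])
      r <- sqrt(nx^2 + ny^2)
      if (r > radius) {
        # radial reflection at the well wall
        scale <- (2 * radius - r) / r
        if (scale < 0) scale <- 0 # step longer than the well: clamp to centre side
        nx <- nx * scale; ny <- ny * scale
        theta <- theta + pi
      }
      x[i + 1L] <- nx; y[i + 1L] <- ny
    }

    tibble::tibble(
      well = well_id, group = group,
      t_s = (0:n_steps) * dt, x_mm = x, y_mm = y
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Simulate a two-group cohort of larvae
#'
#' Generates `n_per_group` control and treated larvae under one schedule.
#' Per-larva seeds are derived from the master seed by a counter scheme,
#' so any larva can be regenerated independently of the others and the
#' cohort is reproducible regardless of generation order.
#'
#' @param control,treated [swim_params()] for each arm (defaults:
#'   [control_swim_params()], [treated_swim_params()]).
#' @param n_per_group Larvae per group (default 12, the standard 24-well
#'   design).
#' @param schedule A [light_schedule()] (default [standard_schedule()]).
#' @param rate_hz Sampling rate (default 25).
#' @param seed Master integer seed.
#' @return A [swim_cohort()] whose metadata records all parameters.
#' @export
simulate_cohort <- function(control = control_swim_params(),
                            treated = treated_swim_params(),
                            n_per_group = 12, schedule = standard_schedule(),
                            rate_hz = 25, seed = 1) {
  check_number(n_per_group, "n_per_group", min = 1)
  trajs <- vector("list", 2L * n_per_group)
  for (i in seq_len(n_per_group)) {
    trajs[[i]] <- simulate_larva(
      control, schedule, rate_hz = rate_hz, group = "control",
      well_id = sprintf("C%02d", i), seed = derive_seed(seed, i)
    )
    trajs[[n_per_group + i]] <- simulate_larva(
      treated, schedule, rate_hz = rate_hz, group = "treated",
      well_id = sprintf("T%02d", i), seed = derive_seed(seed, n_per_group + i)
    )
  }
  swim_cohort(
    dplyr::bind_rows(trajs), schedule, rate_hz = rate_hz,
    metadata = list(seed = seed, n_per_group = n_per_group,
                    control = unclass(control), treated = unclass(treated))
  )
}

#' LFQ simulation parameters
#'
#' Parameters of the synthetic label-free intensity model: protein base
#' abundances are log-normal (normal on the log2 scale), a chosen number
#' of proteins carry a fixed-magnitude log2 effect of random sign in the
#' treated group, replicate noise is additive on the log2 scale, and
#' detection missingness strikes cells at random with an optional boost
#' for low-abundance proteins (missing-not-at-random).
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param n_de Number of truly differential proteins (default 100).
#' @param effect_log2fc Effect magnitude on the log2 scale; a length-2
#'   vector gives a uniform magnitude range.  Sign is random per protein.
#' @param base_log2_mean,base_log2_sd Base-abundance distribution (log2).
#' @param replicate_noise_sd Replicate noise SD on the log2 scale.
#' @param n_replicates Replicates per group (default 2, the
#'   duplicate-pool design).
#' @param missing_rate Per-cell missingness probability.
#' @param low_abundance_boost Extra missingness probability for proteins
#'   in the lowest abundance decile.
#' @return A list of class `lfq_sim_params`.
#' @export
lfq_sim_params <- function(n_proteins = 2000, n_de = 100, effect_log2fc = 2,
                           base_log2_mean = 20, base_log2_sd = 2,
                           replicate_noise_sd = 0.25, n_replicates = 2,
                           missing_rate = 0, low_abundance_boost = 0) {
  check_number(n_proteins, "n_proteins", min = 1)
  check_number(n_de, "n_de", min = 0, max = n_proteins)
  check_number(missing_rate, "missing_rate", min = 0, max = 1)
  check_number(low_abundance_boost, "low_abundance_boost", min = 0, max = 1)
  check_number(n_replicates, "n_replicates", min = 2)
  if (!length(effect_log2fc) %in% c(1L, 2L) || any(effect_log2fc < 0)) {
    abort_validation("`effect_log2fc` must be one non-negative magnitude or a range of two")
  }
  structure(as.list(environment()), class = "lfq_sim_params")
}

#' Simulate an LFQ matrix with known ground truth
#'
#' @param params An [lfq_sim_params()] object.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A list with elements `matrix` (an [lfq_matrix()] on the
#'   intensity scale) and `truth` (tibble `protein_id`, `gene_symbol`,
#'   `true_log2fc`, `is_de`).
#' @export
simulate_lfq <- function(params = lfq_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "lfq_sim_params"))
  run <- function() {
    np <- params$n_proteins
    nr <- params$n_replicates
    ids <- sprintf("P%05d", seq_len(np))
    genes <- sprintf("GENE%05d", seq_len(np))
    base <- stats::rnorm(np, params$base_log2_mean, params$base_log2_sd)
    effect <- rep(0, np)
    if (params$n_de > 0) {
      de_idx <- sample.int(np, params$n_de)
      mag <- if (length(params$effect_log2fc) == 2L) {
        stats::runif(params$n_de, params$effect_log2fc[1], params$effect_log2fc[2])
      } else {
        rep(params$effect_log2fc, params$n_de)
      }
      effect[de_idx] <- mag * sample(c(-1, 1), params$n_de, replace = TRUE)
    }
    samples <- tibble::tibble(
      sample = c(sprintf("ctl_r%d", seq_len(nr)), sprintf("trt_r%d", seq_len(nr))),
      group = rep(c("control", "treated"), each = nr),
      replicate = rep(seq_len(nr), 2L)
    )
    lmat <- matrix(NA_real_, np, 2L * nr, dimnames = list(ids, samples$sample))
    for (j in seq_len(2L * nr)) {
      grp_eff <- if (samples$group[j] == "treated") effect else 0
      lmat[, j] <- base + grp_eff + stats::rnorm(np, 0, params$replicate_noise_sd)
    }
    intensity <- 2^lmat
    if (params$missing_rate > 0 || params$low_abundance_boost > 0) {
      p_miss <- rep(params$missing_rate, np)
      if (params$low_abundance_boost > 0) {
        low <- base <= stats::quantile(base, 0.1)
        p_miss[low] <- pmin(1, p_miss[low] + params$low_abundance_boost)
      }
      mask <- matrix(stats::runif(np * 2L * nr), np) < p_miss
      intensity[mask] <- NA_real_
    }
    values <- dplyr::bind_cols(
      tibble::tibble(protein_id = ids, gene_symbol = genes),
      tibble::as_tibble(intensity)
    )
    list(
      matrix = lfq_matrix(values, samples),
      truth = tibble::tibble(protein_id = ids, gene_symbol = genes,
                             true_log2fc = effect, is_de = effect != 0)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
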