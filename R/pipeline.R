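#' Load and normalise a pipeline run configuration
#'
#' The configuration is the single source of parameters for the pipeline
#' drivers; every effective value is echoed into the run report.  It can
#' be a YAML file or a named list with (subsets of) the keys:
#' `tracks`, `lfq`, `annotation`, `out_dir`, `schedule` (either
#' `n_cycles`/`light_s`/`dark_s` or an `epochs` list), `rate_hz`,
#' `samples` (sample name to group map for the LFQ columns),
#' `theta_active`, `theta_abrupt`, `min_duration_s`, `merge_gap_s`,
#' `smooth_window`, `alpha`, `fc_min`, `q_max`, `detection_rule`,
#' `normalization`, `regulation_subset`, `run_enrichment`, `seed`.
#'
#' @param config A YAML path or named list.
#' @return A normalised config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_config(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "run_config")) return(config)
  if (!is.list(config)) abort_config("config must be a list or a YAML file path")
  defaults <- list(
    tracks = NULL, lfq = NULL, annotation = NULL, out_dir = NULL,
    schedule = list(n_cycles = 3, light_s = 30, dark_s = 30),
    rate_hz = 25, samples = NULL,
    theta_active = 0.1, theta_abrupt = 1.2,
    min_duration_s = 0.2, merge_gap_s = 0.1, smooth_window = 1,
    alpha = 0.05, fc_min = 1, q_max = 0.01,
    detection_rule = "both_replicates", normalization = "median_center",
    regulation_subset = NULL, run_enrichment = FALSE, seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  structure(cfg, class = "run_config")
}

cfg_thresholds <- function(cfg) {
  activity_thresholds(cfg$theta_active, cfg$theta_abrupt)
}

report_row <- function(stage, n_in, n_out, note = "") {
  tibble::tibble(stage = stage, n_in = as.integer(n_in),
                 n_out = as.integer(n_out), note = note)
}

write_table <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  drop <- names(x)[vapply(x, is.list, logical(1))]
  readr::write_tsv(x[setdiff(names(x), drop)], path, progress = FALSE)
  invisible(path)
}

#' Run the behavioral half of the pipeline
#'
#' Reads (or accepts) a cohort of tracked larvae, computes per-larva
#' summaries, the long light/dark condition table, per-group locomotor
#' profiles, the group x condition two-way ANOVA with Tukey post-hoc on
#' per-condition distance, and per-metric Welch comparisons between
#' groups.  When `out_dir` is configured, all tables are written as TSV.
#'
#' @param config A [run_config()] (list or YAML path); `tracks` must be
#'   set unless `cohort` is supplied directly.
#' @param cohort Optional [swim_cohort()] overriding `config$tracks`.
#' @return A list of class `behavior_run`: `summaries`,
#'   `condition_metrics`, `profiles`, `anova`, `tukey`, `group_tests`,
#'   `report`, `config`.
#' @export
run_behavior <- function(config = list(), cohort = NULL) {
  cfg <- run_config(config)
  schedule <- schedule_from_spec(cfg$schedule)
  if (is.null(cohort)) {
    if (is.null(cfg$tracks)) abort_config("config must set `tracks` (or pass a cohort)")
    cohort <- read_tracks(cfg$tracks, schedule, rate_hz = cfg$rate_hz)
  }
  report <- report_row("load_tracks", NA, length(unique(cohort$tracks$well)))

  thr <- cfg_thresholds(cfg)
  summaries <- summarize_cohort(cohort, thr, cfg$min_duration_s,
                                cfg$merge_gap_s, cfg$smooth_window)
  report <- dplyr::bind_rows(report,
    report_row("summarize", length(unique(cohort$tracks$well)), nrow(summaries)))

  cond <- epoch_metrics(summaries)
  report <- dplyr::bind_rows(report, report_row("epoch_metrics", nrow(summaries), nrow(cond)))

  profiles <- dplyr::bind_rows(lapply(
    intersect(c("control", "treated"), unique(cohort$tracks$group)),
    function(g) locomotor_profile(cohort, g)
  ))

  dist_cond <- dplyr::filter(cond, .data$metric == "total_distance_mm")
  anova <- two_way_anova(dist_cond, "value", "group", "condition")
  tukey <- tukey_hsd(dist_cond, "value", "group", "condition")

  metrics <- c("total_distance_mm", "mean_velocity_mms", "n_bolts",
               "bolt_interval_s", "bolt_duration_s", "bolt_distance_mm",
               "distance_per_bolt_mm", "active_fraction")
  group_tests <- purrr::map_dfr(metrics, function(mm) {
    a <- summaries[[mm]][summaries$group == "control"]
    b <- summaries[[mm]][summaries$group == "treated"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    res <- tryCatch(welch_t(a, b), error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(metric = mm, estimate = mean(a) - mean(b),
                     statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                     note = "degenerate or insufficient data")
    } else {
      td <- tidy(res)
      tibble::tibble(metric = mm, estimate = td$estimate,
                     statistic = td$statistic, df = td$df,
                     p.value = td$p.value, note = "")
    }
  })
  report <- dplyr::bind_rows(report, report_row("group_tests", length(metrics),
                                               nrow(group_tests)))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(summaries, cfg$out_dir, "larva_summaries.tsv")
    write_table(cond, cfg$out_dir, "condition_metrics.tsv")
    write_table(profiles, cfg$out_dir, "locomotor_profile.tsv")
    write_table(tidy(anova), cfg$out_dir, "anova.tsv")
    write_table(tukey, cfg$out_dir, "tukey.tsv")
    write_table(group_tests, cfg$out_dir, "group_tests.tsv")
    write_table(report, cfg$out_dir, "behavior_report.tsv")
  }
  structure(
    list(summaries = summaries, condition_metrics = cond, profiles = profiles,
         anova = anova, tukey = tukey, group_tests = group_tests,
         report = report, config = cfg),
    class = "behavior_run"
  )
}

#' Run the proteomics half of the pipeline
#'
#' Reads (or accepts) an LFQ matrix and runs the full differential
#' expression chain: shared/exclusive detection accounting, the
#' replicate-consistency filter, log2 transform + normalization, Welch +
#' Benjamini-Hochberg calling, an optional curated-subset regulation
#' table, and optional hypergeometric enrichment of the significant set
#' against all tested proteins.  Requesting enrichment without a readable
#' annotation file is a configuration error raised before any
#' computation.
#'
#' @param config A [run_config()]; `lfq` + `samples` must be set unless
#'   `lfq` is supplied directly.
#' @param lfq Optional [lfq_matrix()] overriding `config$lfq`.
#' @return A list of class `proteomics_run`: `detection`, `de`,
#'   `regulation`, `enrichment`, `report`, `config`.
#' @export
run_proteomics <- function(config = list(), lfq = NULL) {
  cfg <- run_config(config)
  want_enrich <- isTRUE(cfg$run_enrichment) || !is.null(cfg$annotation)
  if (want_enrich) {
    if (is.null(cfg$annotation)) {
      abort_config("enrichment requested but no `annotation` file configured")
    }
    if (!file.exists(cfg$annotation)) {
      abort_config(sprintf("annotation file '%s' does not exist", cfg$annotation))
    }
  }
  if (is.null(lfq)) {
    if (is.null(cfg$lfq)) abort_config("config must set `lfq` (or pass a matrix)")
    if (is.null(cfg$samples)) abort_config("config must set `samples` (sample -> group map)")
    lfq <- read_lfq(cfg$lfq, unlist(cfg$samples))
  }
  report <- report_row("load_lfq", NA, nrow(lfq$values))

  det <- detection_sets(lfq, cfg$detection_rule)
  filtered <- filter_consistent(lfq)
  report <- dplyr::bind_rows(report,
    report_row("filter_consistent", nrow(lfq$values), nrow(filtered$values)))

  normed <- log2_normalize(filtered, cfg$normalization)
  de <- differential_expression(normed, alpha = cfg$alpha, fc_min = cfg$fc_min)
  report <- dplyr::bind_rows(report,
    report_row("differential_expression", nrow(normed$values), nrow(de),
               note = sprintf("up=%d down=%d ns=%d untested=%d",
                              sum(de$status == "up", na.rm = TRUE),
                              sum(de$status == "down", na.rm = TRUE),
                              sum(de$status == "ns", na.rm = TRUE),
                              sum(!de$tested))))

  regulation <- NULL
  if (!is.null(cfg$regulation_subset)) {
    subset <- if (identical(cfg$regulation_subset, "neuro40")) {
      curated_neuro_set()$gene_symbol
    } else {
      readr::read_tsv(cfg$regulation_subset, show_col_types = FALSE,
                      progress = FALSE)$gene_symbol
    }
    regulation <- regulation_table(de, subset)
    report <- dplyr::bind_rows(report,
      report_row("regulation_table", length(subset), nrow(regulation),
                 note = if (length(attr(regulation, "unresolved")) > 0L) {
                   sprintf("unresolved: %s",
                           paste(attr(regulation, "unresolved"), collapse = ","))
                 } else ""))
  }

  enrichment <- NULL
  if (want_enrich) {
    ann <- read_annotation(cfg$annotation)
    background <- de$gene_symbol[de$tested]
    query <- de$gene_symbol[de$status %in% c("up", "down")]
    enrichment <- enrich(query, ann, background, q_max = cfg$q_max)
    report <- dplyr::bind_rows(report,
      report_row("enrichment", length(unique(ann$term_id)), nrow(enrichment)))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(de, cfg$out_dir, "de_table.tsv")
    write_table(tidy(det), cfg$out_dir, "detection_counts.tsv")
    if (!is.null(regulation)) write_table(regulation, cfg$out_dir, "regulation_table.tsv")
    if (!is.null(enrichment)) write_table(enrichment, cfg$out_dir, "enrichment.tsv")
    write_table(report, cfg$out_dir, "proteomics_report.tsv")
  }
  structure(
    list(detection = det, de = de, regulation = regulation,
         enrichment = enrichment, report = report, config = cfg),
    class = "proteomics_run"
  )
}

#' Run both pipeline halves
#'
#' Equivalent to calling [run_behavior()] and [run_proteomics()] on the
#' same configuration; the combined report stacks both stage records.
#'
#' @param config A [run_config()] (list or YAML path).
#' @return A list of class `full_run`: `behavior`, `proteomics`,
#'   `report`.
#' @export
run_all <- function(config = list()) {
  cfg <- run_config(config)
  behavior <- run_behavior(cfg)
  proteomics <- run_proteomics(cfg)
  report <- dplyr::bind_rows(
    dplyr::mutate(behavior$report, half = "behavior", .before = 1),
    dplyr::mutate(proteomics$report, half = "proteomics", .before = 1)
  )
  if (!is.null(cfg$out_dir)) {
    write_table(report, cfg$out_dir, "combined_report.tsv")
  }
  structure(list(behavior = behavior, proteomics = proteomics, report = report),
            class = "full_run")
}

#' Write a complete synthetic demonstration bundle
#'
#' Generates a seeded synthetic cohort and LFQ matrix, writes every input
#' the pipeline consumes (trajectory CSV, schedule + full config YAML,
#' LFQ TSV, ground-truth TSV, annotation TSV, curated gene-set copies)
#' into `dir`, and returns the config path.  `run_all()` on that config
#' reproduces the whole analysis end to end.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed for both generators.
#' @param n_per_group Larvae per group (default 12).
#' @param rate_hz Trajectory sampling rate (default 25).
#' @param lfq_params An [lfq_sim_params()]; the default adds mild
#'   missingness so the consistency filter has work to do.
#' @return The path of the written `config.yaml`, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1, n_per_group = 12, rate_hz = 25,
                                 lfq_params = lfq_sim_params(
                                   n_proteins = 1500, n_de = 60,
                                   missing_rate = 0.05, low_abundance_boost = 0.2
                                 )) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- standard_schedule()
  cohort <- simulate_cohort(n_per_group = n_per_group, schedule = schedule,
                            rate_hz = rate_hz, seed = seed)
  write_tracks(cohort, file.path(dir, "tracks.csv"))

  sim <- simulate_lfq(lfq_params, seed = derive_seed(seed, 999))
  write_lfq(sim$matrix, file.path(dir, "lfq.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "lfq_truth.tsv"), progress = FALSE)

  ann <- synthetic_annotation()
  readr::write_tsv(ann, file.path(dir, "annotation.tsv"), progress = FALSE)
  readr::write_tsv(curated_neuro_set(), file.path(dir, "curated_neuro40.tsv"),
                   progress = FALSE)
  readr::write_tsv(curated_parkinson_set(), file.path(dir, "curated_parkinson8.tsv"),
                   progress = FALSE)

  samples <- as.list(stats::setNames(sim$matrix$samples$group,
                                     sim$matrix$samples$sample))
  cfg <- list(
    tracks = file.path(dir, "tracks.csv"),
    lfq = file.path(dir, "lfq.tsv"),
    out_dir = file.path(dir, "results"),
    schedule = list(n_cycles = 3, light_s = 30, dark_s = 30),
    rate_hz = rate_hz, samples = samples, seed = seed
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
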