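test_that("zero bolt rates give a sub-threshold drifting larva", {
  p <- swim_params(bolt_rate_dark = 0, bolt_rate_light = 0)
  sch <- standard_schedule()
  tr <- simulate_larva(p, sch, rate_hz = 10, seed = 2)
  vel <- compute_velocity(tr)
  expect_equal(nrow(segment_bolts(vel)), 0L)
  expect_lte(sum(vel$v * vel$dt), p$quiescent_jitter_mms * 180 + 1e-9)
})

test_that("simulation is deterministic and reproducible per larva", {
  p <- control_swim_params()
  a <- simulate_larva(p, rate_hz = 10, seed = 33)
  b <- simulate_larva(p, rate_hz = 10, seed = 33)
  expect_identical(a, b)
  expect_false(identical(a, simulate_larva(p, rate_hz = 10, seed = 34)))

  # counter-based seeds: any cohort member can be regenerated on its own
  co <- simulate_cohort(n_per_group = 3, rate_hz = 10, seed = 101)
  solo <- simulate_larva(control_swim_params(), standard_schedule(),
                         rate_hz = 10, group = "control", well_id = "C02",
                         seed = swimprot:::derive_seed(101, 2))
  expect_identical(dplyr::filter(co$tracks, well == "C02"),
                   solo)
})

test_that("generated trajectories satisfy the data-model invariants", {
  co <- simulate_cohort(n_per_group = 4, rate_hz = 25, seed = 6)
  expect_equal(dplyr::n_distinct(co$tracks$well), 8L)
  expect_equal(as.integer(table(dplyr::distinct(co$tracks, well, group)$group)),
               c(4L, 4L))
  # positions stay inside the 10 mm well
  r <- sqrt(co$tracks$x_mm^2 + co$tracks$y_mm^2)
  expect_lte(max(r), 5 + 1e-9)
  # re-validation passes (uniform sampling, finite coordinates)
  expect_silent(swimprot:::validate_tracks(co$tracks, 25))
  expect_error(simulate_cohort(n_per_group = 0), class = "swimprot_validation_error")
  expect_error(simulate_larva(control_swim_params(), rate_hz = 0),
               class = "swimprot_validation_error")
})

test_that("detected bolt counts track the renewal expectation", {
  # constant rate, no light modulation: compare a 40-larva sample against
  # a 400-larva Monte-Carlo expectation of the same detector
  p <- swim_params(bolt_rate_dark = 0.5, bolt_rate_light = 0.5)
  sch <- standard_schedule()
  count_bolts <- function(seed) {
    tr <- simulate_larva(p, sch, rate_hz = 10, seed = seed)
    nrow(segment_bolts(compute_velocity(tr)))
  }
  sample_counts <- vapply(1:40, count_bolts, numeric(1))
  oracle_counts <- vapply(5001:5400, count_bolts, numeric(1))
  se <- sqrt(stats::var(sample_counts) / 40 + stats::var(oracle_counts) / 400)
  expect_lt(abs(mean(sample_counts) - mean(oracle_counts)), 3 * se)
  # sanity: the renewal mean cycle length bounds the expected count
  upper <- 180 / (1 / 0.5 + 0) # quiescence alone limits the event rate
  expect_lt(mean(sample_counts), upper)
  expect_gt(mean(sample_counts), 0.3 * upper)
})

test_that("LFQ simulation honours its ground truth contract", {
  par0 <- lfq_sim_params(n_proteins = 120, n_de = 0, missing_rate = 0)
  sim0 <- simulate_lfq(par0, seed = 9)
  expect_equal(nrow(filter_consistent(sim0$matrix)$values), 120L)
  expect_true(all(sim0$truth$true_log2fc == 0))

  par <- lfq_sim_params(n_proteins = 120, n_de = 25, missing_rate = 0.1,
                        low_abundance_boost = 0.3)
  sim <- simulate_lfq(par, seed = 9)
  expect_equal(sum(sim$truth$true_log2fc != 0), 25L)
  expect_equal(sum(sim$truth$is_de), 25L)
  expect_identical(simulate_lfq(par, seed = 9)$matrix$values, sim$matrix$values)

  # missingness boost concentrates NAs in low-abundance proteins
  mat <- as.matrix(sim$matrix$values[sim$matrix$samples$sample])
  expect_gt(sum(is.na(mat)), 0)

  # the spiked effect is recoverable on average
  full <- simulate_lfq(lfq_sim_params(n_proteins = 400, n_de = 50,
                                      effect_log2fc = 2, missing_rate = 0),
                       seed = 21)
  de <- differential_expression(log2_normalize(full$matrix, "none"))
  est <- de$log2fc[match(full$truth$protein_id[full$truth$is_de], de$protein_id)]
  truth <- full$truth$true_log2fc[full$truth$is_de]
  expect_equal(mean(est * sign(truth)), 2, tolerance = 0.15)
})

test_that("default cohorts give the ANOVA power the design was calibrated for", {
  # group x condition interaction (the light-evoked response present only
  # in controls) should be detected in >= 80% of seeded cohorts
  hits <- vapply(1:15, function(seed) {
    co <- simulate_cohort(n_per_group = 12, rate_hz = 10, seed = 300 + seed)
    cond <- epoch_metrics(summarize_cohort(co)) |>
      dplyr::filter(metric == "total_distance_mm")
    td <- tidy(two_way_anova(cond, "value", "group", "condition"))
    td$p.value[td$term == "group:condition"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
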