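log2_lfq <- function(mat, groups = c("control", "control", "treated", "treated")) {
  m <- lfq_from_matrix(2^mat, groups)
  log2_normalize(m, "none")
}

test_that("log2 fold changes and calls match the primitive oracles", {
  mat <- rbind(
    c(10.0, 10.2, 10.0, 10.2),  # identical across groups -> fc 0, ns
    c(10.0, 10.2, 12.0, 12.4)   # the worked +2.1 example
  )
  de <- differential_expression(log2_lfq(mat))
  expect_equal(de$log2fc, c(0, 2.1), tolerance = 1e-9)
  expect_equal(de$status[1], "ns")
  # p for row 2 equals the direct Welch oracle, BH over the 2 tested rows
  w <- welch_t(c(12.0, 12.4), c(10.0, 10.2))
  expect_equal(de$t[2], w$statistic, tolerance = 1e-12)
  expect_equal(de$p[2], w$p, tolerance = 1e-12)
  expect_equal(de$p_adj, bh_brute(de$p), tolerance = 1e-12)
  expect_equal(de$status[2], ifelse(de$p_adj[2] < 0.05 & de$log2fc[2] > 1, "up", "ns"))
})

test_that("zero-variance rows are excluded from testing, not given p = 0", {
  mat <- rbind(c(10, 10, 12, 12), c(10, 10.5, 12, 12.4))
  de <- differential_expression(log2_lfq(mat))
  expect_false(de$tested[1])
  expect_true(is.na(de$p[1]) && is.na(de$status[1]))
  expect_true(de$tested[2])
  # BH family = tested rows only
  expect_equal(de$p_adj[2], de$p[2])
})

test_that("status partitions tested proteins and flips under label swap", {
  sim <- simulate_lfq(lfq_sim_params(n_proteins = 300, n_de = 40,
                                     replicate_noise_sd = 0.25,
                                     n_replicates = 4), seed = 19)
  normed <- log2_normalize(filter_consistent(sim$matrix))
  de <- differential_expression(normed)
  expect_true(all(de$status[de$tested] %in% c("up", "down", "ns")))
  expect_equal(sum(is.na(de$status)), sum(!de$tested))

  swapped <- normed
  swapped$samples$group <- ifelse(swapped$samples$group == "control",
                                  "treated", "control")
  de2 <- differential_expression(swapped)
  expect_equal(de2$log2fc, -de$log2fc, tolerance = 1e-9)
  expect_equal(de2$p, de$p, tolerance = 1e-9)
  expect_equal(de2$status[de$status == "up"], rep("down", sum(de$status == "up")))
  expect_equal(de2$status[de$status == "down"], rep("up", sum(de$status == "down")))

  # with strong spiked effects every directional call matches the truth sign
  truth <- sim$truth$true_log2fc[match(de$protein_id, sim$truth$protein_id)]
  expect_true(all(truth[de$status == "up"] >= 0))
  expect_true(all(truth[de$status == "down"] <= 0))
})

test_that("the regulation table reports subset order, arrows, and unresolved symbols", {
  n40 <- curated_neuro_set()
  de <- classify_de_status(n40)
  reg <- regulation_table(de, c("PARK7", "VAMP2", "NOT_A_GENE"))
  expect_equal(reg$gene_symbol, c("PARK7", "VAMP2"))
  expect_equal(reg$log2fc, c(1.946, -4.728))
  expect_equal(reg$direction, c("↑", "↓"))
  expect_equal(attr(reg, "unresolved"), "NOT_A_GENE")
  expect_equal(nrow(regulation_table(de, character(0))), 0L)
  # non-significant rows carry no arrow
  de$status[de$gene_symbol == "PARK7"] <- "ns"
  expect_true(is.na(regulation_table(de, "PARK7")$direction))
})

test_that("enrichment reproduces the exact tail probabilities before BH", {
  background <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(term_id = "t1", gene_symbol = background[1:5])
  query <- c(background[1:3], background[10]) # overlap 3 of 4
  out <- enrich(query, ann, background, q_max = 1)
  expect_equal(out$p, 55 / 210, tolerance = 1e-12)
  expect_equal(out$k, 3L)
  expect_equal(out$K, 5L)

  # a term equal to the query with background = query is never enriched
  out2 <- enrich(query, tibble::tibble(term_id = "t", gene_symbol = query),
                 query, q_max = 1)
  expect_equal(out2$p, 1)

  # zero-overlap terms have p = 1 and never pass any q_max < 1
  ann3 <- tibble::tibble(term_id = c("hit", "miss"),
                         gene_symbol = c("g01", "g07"))
  out3 <- enrich(c("g01", "g02"), ann3, background, q_max = 0.99)
  expect_false("miss" %in% out3$term_id)

  expect_error(enrich("zz", ann, background), class = "swimprot_validation_error")
  expect_error(enrich("g01", ann, character(0)), class = "swimprot_validation_error")
})

test_that("the packaged curated sets are intact", {
  n40 <- curated_neuro_set()
  expect_equal(nrow(n40), 40L)
  expect_true(all(abs(n40$log2fc) > 1))
  expect_true(all(n40$significant))
  expect_equal(n40$direction, ifelse(n40$log2fc > 0, "↑", "↓"))

  p8 <- curated_parkinson_set()
  expect_equal(nrow(p8), 8L)
  # every matched symbol resolves in the 40-protein table
  matched <- unlist(strsplit(p8$matched_symbols, ";"))
  expect_true(all(matched %in% n40$gene_symbol))
})
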