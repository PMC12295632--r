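test_that("detection sets follow the rule and partition the union", {
  mat <- rbind(
    c(10, 12, 11, 13),   # everywhere -> shared
    c(10, 12, NA, NA),   # control only (both rules)
    c(10, NA, 11, 13),   # control r2 missing
    c(NA, NA, 14, NA)    # treated r1 only
  )
  m <- lfq_from_matrix(mat)
  both <- detection_sets(m, "both_replicates")
  expect_equal(both$shared, "P001")
  expect_equal(both$detected_control, c("P001", "P002"))
  expect_equal(both$control_only, "P002")
  expect_equal(both$treated_only, "P003") # control r2 missing, treated complete
  any_r <- detection_sets(m, "any_replicate")
  expect_equal(any_r$shared, c("P001", "P003"))
  expect_equal(any_r$treated_only, "P004")
  expect_error(detection_sets(m, "sometimes"), class = "swimprot_validation_error")
})

test_that("detection counts agree with a set-comprehension oracle on random data", {
  withr::with_seed(41, {
    present <- matrix(stats::runif(400) < 0.7, 100, 4)
    mat <- matrix(stats::runif(400, 10, 100), 100, 4)
    mat[!present] <- NA
    m <- lfq_from_matrix(mat)
    ids <- m$values$protein_id
    for (rule in c("both_replicates", "any_replicate")) {
      ds <- detection_sets(m, rule)
      f <- if (rule == "both_replicates") all else any
      ctl <- ids[apply(present[, 1:2, drop = FALSE], 1, f)]
      trt <- ids[apply(present[, 3:4, drop = FALSE], 1, f)]
      expect_equal(sort(ds$detected_control), sort(ctl))
      expect_equal(sort(ds$detected_treated), sort(trt))
      expect_equal(sort(ds$shared), sort(intersect(ctl, trt)))
      # the three output sets partition the union
      parts <- c(ds$shared, ds$control_only, ds$treated_only)
      expect_equal(sort(parts), sort(union(ctl, trt)))
      expect_equal(anyDuplicated(parts), 0L)
    }
  })
})

test_that("the consistency filter keeps exactly the fully observed rows", {
  mat <- rbind(c(10, 12, 11, 13), c(10, 12, NA, 13), c(10, 12, 11, NA))
  m <- lfq_from_matrix(mat)
  f <- filter_consistent(m)
  expect_equal(f$values$protein_id, "P001")

  full <- lfq_from_matrix(matrix(stats::runif(40, 1, 10), 10, 4))
  expect_equal(filter_consistent(full)$values, full$values)

  withr::with_seed(43, {
    mat2 <- matrix(stats::runif(200, 10, 100), 50, 4)
    mat2[stats::runif(200) < 0.25] <- NA
    m2 <- lfq_from_matrix(mat2)
    keep_oracle <- logical(50)
    for (i in 1:50) keep_oracle[i] <- !anyNA(mat2[i, ]) # row scan
    f2 <- filter_consistent(m2)
    expect_equal(f2$values$protein_id, m2$values$protein_id[keep_oracle])
    # idempotence
    expect_equal(filter_consistent(f2)$values, f2$values)
  })
})

test_that("log2 transform and median centering behave as documented", {
  m <- lfq_from_matrix(matrix(c(1024, 2048, 512, 4096), 1, 4))
  plain <- log2_normalize(m, "none")
  expect_equal(unlist(plain$values[1, 3:6], use.names = FALSE), c(10, 11, 9, 12))
  expect_equal(plain$scale, "log2")

  withr::with_seed(47, {
    big <- lfq_from_matrix(matrix(2^stats::rnorm(200, 20, 2), 50, 4))
    cent <- log2_normalize(big)
    vals <- as.matrix(cent$values[cent$samples$sample])
    expect_equal(unname(apply(vals, 2, stats::median)), rep(0, 4),
                 tolerance = 1e-9)
  })

  withNA <- lfq_from_matrix(rbind(c(10, NA, 11, 12)))
  expect_error(log2_normalize(withNA), class = "swimprot_validation_error")
  zero <- lfq_from_matrix(rbind(c(0, 1, 1, 1)))
  expect_error(log2_normalize(zero), class = "swimprot_validation_error")
  expect_error(log2_normalize(log2_normalize(m, "none")),
               class = "swimprot_validation_error")
})

test_that("lfq_matrix validates its schema", {
  expect_error(lfq_from_matrix(matrix(1:4, 1, 4),
                               groups = rep("control", 4)),
               class = "swimprot_validation_error")
  vals <- tibble::tibble(protein_id = c("P1", "P1"), gene_symbol = c("a", "b"),
                         s1 = c(1, 2), s2 = c(1, 2))
  smp <- tibble::tibble(sample = c("s1", "s2"), group = c("control", "treated"))
  expect_error(lfq_matrix(vals, smp), class = "swimprot_validation_error")
  expect_error(lfq_matrix(vals[1, c(1, 3, 4)], smp), class = "swimprot_format_error")
})
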