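test_that("welch_t reproduces the hand-computed statistic and df", {
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  # means 2 and 3, both variances 1: t = -1 / sqrt(2/3), df = 4
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(res$statistic, -1.224744871, tolerance = 1e-8)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(res$statistic, 4), tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("welch_t is antisymmetric and rejects degenerate input", {
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- stats::rnorm(4)
      b <- stats::rnorm(5)
      expect_equal(welch_t(a, b)$statistic, -welch_t(b, a)$statistic)
      expect_equal(welch_t(a, b)$p, welch_t(b, a)$p)
    }
  })
  expect_error(welch_t(c(1, 1), c(2, 2)), class = "swimprot_degenerate_variance")
  expect_error(welch_t(1, c(1, 2)), class = "swimprot_validation_error")
  # one degenerate sample is fine (Welch df -> n-1 of the other sample)
  expect_s3_class(welch_t(c(1, 1), c(2, 3)), "swim_test")
})

test_that("student variant matches the pooled-variance test", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(2.0, 4.1, 3.3)
  res <- welch_t(a, b, var_equal = TRUE)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, length(a) + length(b) - 2)
})

test_that("bh_adjust matches the printed examples and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04, 0.045)),
               c(0.025, 0.0275, 1 / 30, 0.045, 0.045), tolerance = 1e-12)
  withr::with_seed(77, {
    for (i in 1:20) {
      p <- stats::runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_brute(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))           # never below the input
      expect_true(all(diff(adj[order(p)]) >= -1e-15)) # order preserving
      expect_true(all(adj <= 1))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), class = "swimprot_validation_error")
  expect_error(bh_adjust(c(0.5, NA)), class = "swimprot_validation_error")
})

test_that("two-way ANOVA partitions sums of squares on balanced data", {
  withr::with_seed(13, {
    for (i in 1:10) {
      d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                       rep = 1:sample(2:5, 1))
      d$y <- stats::rnorm(nrow(d))
      td <- tidy(two_way_anova(d, "y", "A", "B"))
      total_ss <- sum((d$y - mean(d$y))^2)
      expect_equal(sum(td$sumsq), total_ss, tolerance = 1e-9)
      expect_equal(sum(td$df), nrow(d) - 1)
      expect_true(all(td$sumsq >= -1e-12))
    }
  })
})

test_that("degenerate and additive designs give the expected ANOVA shape", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- 5
  td <- tidy(two_way_anova(d, "y", "A", "B"))
  expect_equal(td$statistic[td$term != "residual"], rep(0, 3))
  expect_equal(td$p.value[td$term != "residual"], rep(1, 3))

  # additive cell means, zero noise -> zero interaction SS
  d$y <- ifelse(d$A == "a2", 2, 0) + ifelse(d$B == "b2", 5, 0)
  td2 <- tidy(two_way_anova(d, "y", "A", "B"))
  expect_equal(td2$sumsq[td2$term == "A:B"], 0, tolerance = 1e-12)

  # unbalanced designs are refused
  d_unb <- rbind(d, d[d$A == "a1" & d$B == "b1", ][1, ])
  expect_error(two_way_anova(d_unb, "y", "A", "B"),
               class = "swimprot_not_supported")
})

test_that("tukey_hsd matches the pooled t-test for two cells and respects symmetry", {
  withr::with_seed(55, {
    d <- data.frame(g = rep(c("x", "y"), each = 6), y = stats::rnorm(12))
    tk <- tukey_hsd(d, "y", "g")
    tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
    # q = t * sqrt(2): the studentized range p equals the pooled t p
    expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-6)

    # identical cell means -> all adjusted p near 1
    d2 <- expand.grid(A = c("a", "b"), B = c("c", "d"), rep = 1:4)
    d2$y <- rep(c(0.01, -0.01), each = 8) # every cell mean is exactly 0
    tk2 <- tukey_hsd(d2, "y", "A", "B")
    expect_equal(nrow(tk2), 6L)
    expect_true(all(tk2$adj.p.value > 1 - 1e-3))

    # relabeling cells permutes rows but not the p-values
    d3 <- expand.grid(A = c("a", "b"), B = c("c", "d"), rep = 1:4)
    d3$y <- stats::rnorm(16)
    d4 <- dplyr::mutate(d3, A = dplyr::recode(A, a = "zz", b = "aa"))
    expect_equal(unname(sort(tukey_hsd(d3, "y", "A", "B")$adj.p.value)),
                 unname(sort(tukey_hsd(d4, "y", "A", "B")$adj.p.value)),
                 tolerance = 1e-9)
  })
  expect_error(tukey_hsd(data.frame(g = rep("x", 4), y = 1:4), "y", "g"),
               class = "swimprot_validation_error")
})

test_that("hypergeometric tail matches full enumeration", {
  expect_equal(hypergeom_enrich_p(0, 5, 4, 10), 1)
  expect_equal(hypergeom_enrich_p(3, 5, 4, 10), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enrich_p(3, 5, 4, 10), hyper_enum(3, 5, 4, 10),
               tolerance = 1e-12)
  withr::with_seed(17, {
    for (i in 1:10) {
      N <- sample(6:12, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      k <- sample(0:min(n, K), 1)
      expect_equal(hypergeom_enrich_p(k, K, n, N), hyper_enum(k, K, n, N),
                   tolerance = 1e-12)
    }
  })
  expect_error(hypergeom_enrich_p(6, 5, 4, 10), class = "swimprot_validation_error")
  expect_error(hypergeom_enrich_p(1, 5, 4, 3), class = "swimprot_validation_error")
})
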