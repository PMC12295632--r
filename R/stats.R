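#' Two-sided two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance t statistic
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Welch is the default for group comparisons with small, possibly
#' heteroscedastic replicates (as in duplicate-pool LFQ designs); a
#' pooled-variance Student test is available via `var_equal = TRUE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return An object of class `swim_test`: list with `statistic`, `df`,
#'   `p`, `method`, `estimate` (mean(a) - mean(b)).  [generics::tidy()]
#'   gives a one-row tibble.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4)) # t = -1.2247, df = 4
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_validation("both samples need at least 2 observations")
  }
  if (anyNA(a) || anyNA(b) || !all(is.finite(a)) || !all(is.finite(b))) {
    abort_validation("samples must be finite and free of missing values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    abort_validation("both samples have zero variance; the t statistic is undefined",
                     class = "swimprot_degenerate_variance")
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  structure(
    list(
      statistic = unname(fit$statistic),
      df = unname(fit$parameter),
      p = fit$p.value,
      method = if (var_equal) "student" else "welch",
      estimate = mean(a) - mean(b)
    ),
    class = "swim_test"
  )
}

#' @export
print.swim_test <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4f, df = %.3f, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy swim_test
#' @export
tidy.swim_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p.value = x$p, method = x$method
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' p(i) by m/i, enforce monotonicity by a cumulative minimum from the
#' largest rank, cap at 1, and return in the input order.  Output is
#' elementwise >= input; the procedure is not idempotent.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort_validation("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-way ANOVA for a balanced factorial design
#'
#' Fits `value ~ A * B` by [stats::aov()] and returns the full
#' sum-of-squares decomposition (A, B, interaction, residual).  Only
#' balanced designs with at least two replicates per cell are accepted;
#' under balance the type-I and type-II decompositions coincide and
#' total SS = SS(A) + SS(B) + SS(A:B) + SS(residual).
#'
#' @param data A data frame.
#' @param value,factor_a,factor_b Column names (strings) of the response
#'   and the two factors.
#' @return An object of class `swim_anova` wrapping the `aov` fit;
#'   `tidy()` returns the effect table (term, df, sumsq, meansq,
#'   statistic, p.value).
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  d <- tibble::tibble(
    y = as.numeric(data[[value]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (anyNA(d$y)) abort_validation("response contains missing values")
  cell_n <- table(d$A, d$B)
  if (any(cell_n < 2L)) {
    abort_validation("every factor cell needs at least 2 replicates")
  }
  if (length(unique(as.vector(cell_n))) != 1L) {
    abort_validation("unbalanced designs are not supported; all cells must have equal n",
                     class = "swimprot_not_supported")
  }
  fit <- stats::aov(y ~ A * B, data = d)
  structure(
    list(fit = fit, terms = c(A = factor_a, B = factor_b), data = d),
    class = "swim_anova"
  )
}

#' @method tidy swim_anova
#' @export
tidy.swim_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  term_raw <- trimws(rownames(s))
  relabel <- c(A = unname(x$terms["A"]), B = unname(x$terms["B"]),
               `A:B` = paste0(unname(x$terms["A"]), ":", unname(x$terms["B"])),
               Residuals = "residual")
  out <- tibble::tibble(
    term = unname(relabel[term_raw]),
    df = s[["Df"]],
    sumsq = s[["Sum Sq"]],
    meansq = s[["Mean Sq"]],
    statistic = s[["F value"]],
    p.value = s[["Pr(>F)"]]
  )
  # fully degenerate data (zero variance everywhere): define F = 0, p = 1
  zero_res <- out$meansq[out$term == "residual"] < .Machine$double.eps
  if (length(zero_res) == 1L && zero_res) {
    fix <- out$term != "residual" & out$sumsq < .Machine$double.eps
    out$statistic[fix] <- 0
    out$p.value[fix] <- 1
  }
  out
}

#' @method glance swim_anova
#' @export
glance.swim_anova <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n = nrow(x$data),
    df.residual = td$df[td$term == "residual"],
    ss.total = sum(td$sumsq)
  )
}

#' @export
print.swim_anova <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Tukey HSD comparisons over the cells of a two-factor design
#'
#' Forms the A x B cell factor and applies Tukey's honest significant
#' difference (studentized-range) adjustment to all pairwise cell-mean
#' comparisons.  For the 2-group x 2-condition assay design this is the
#' standard post-hoc test after [two_way_anova()].
#'
#' @param data A data frame.
#' @param value,factor_a,factor_b Column names as in [two_way_anova()].
#' @return A tibble with columns `contrast`, `estimate`, `conf.low`,
#'   `conf.high`, `adj.p.value`.
#' @export
tukey_hsd <- function(data, value, factor_a, factor_b = NULL) {
  y <- as.numeric(data[[value]])
  cell <- if (is.null(factor_b)) {
    factor(data[[factor_a]])
  } else {
    interaction(factor(data[[factor_a]]), factor(data[[factor_b]]), sep = ":")
  }
  cell <- droplevels(cell)
  if (nlevels(cell) < 2L) abort_validation("Tukey HSD needs at least 2 cells")
  if (any(table(cell) < 2L)) abort_validation("every cell needs at least 2 replicates")
  fit <- stats::aov(y ~ cell, data = data.frame(y = y, cell = cell))
  tk <- stats::TukeyHSD(fit)$cell
  tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"]
  )
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a background of `N` genes of which `K`
#' carry the annotation: `P[X >= k]` under Hypergeometric(N, K, n).
#'
#' @param k Observed overlap (hits in the query).
#' @param K Annotation (term) size within the background.
#' @param n Query size.
#' @param N Background size.
#' @return The exact upper-tail p-value.
#' @examples
#' hypergeom_enrich_p(3, K = 5, n = 4, N = 10) # 55/210
#' @export
hypergeom_enrich_p <- function(k, K, n, N) {
  for (nm in c("k", "K", "n", "N")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v) || v < 0) {
      abort_validation(sprintf("`%s` must be a single non-negative integer", nm))
    }
  }
  if (k > min(n, K) || K > N || n > N) {
    abort_validation("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}
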