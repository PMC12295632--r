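#' Differential expression over an LFQ matrix
#'
#' Per protein: group means on the log2 scale, log2 fold change
#' (treated - control), a Welch t-test (Student optional), and
#' Benjamini-Hochberg adjustment across all tested proteins.  A protein is
#' called `up` when `p_adj < alpha` and `log2fc > fc_min`, `down` when
#' `p_adj < alpha` and `log2fc < -fc_min`, otherwise `ns`.  The defaults
#' (`alpha = 0.05`, `fc_min = 1`) are the conventional volcano-plot
#' thresholds.
#'
#' Proteins whose variance is zero in both groups have no defined t
#' statistic; they are excluded from testing (statistic columns `NA`,
#' `tested = FALSE`) rather than handed a spurious p-value -- important
#' with duplicate replicates, where a zero-variance row would otherwise
#' dominate the top of the list.
#'
#' @param m A filtered, log2-scale `lfq_matrix` (see
#'   [filter_consistent()], [log2_normalize()]).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param fc_min Minimum absolute log2 fold change (default 1).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#'
#' @return A tibble of class `swim_de` with one row per protein:
#'   `protein_id`, `gene_symbol`, `mean_log2_control`,
#'   `mean_log2_treated`, `log2fc`, `t`, `df`, `p`, `p_adj`, `status`,
#'   `tested`.  Thresholds are stored as attributes `alpha` and `fc_min`.
#' @export
differential_expression <- function(m, alpha = 0.05, fc_min = 1,
                                    var_equal = FALSE) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (m$scale != "log2") {
    abort_validation("differential expression expects a log2-scale matrix; run log2_normalize()")
  }
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(fc_min, "fc_min", min = 0)
  mat <- lfq_intensity_matrix(m)
  if (anyNA(mat)) {
    abort_validation("missing values present; run filter_consistent() before testing")
  }
  ctl <- mat[, group_samples(m, "control"), drop = FALSE]
  trt <- mat[, group_samples(m, "treated"), drop = FALSE]
  if (ncol(ctl) < 2L || ncol(trt) < 2L) {
    abort_validation("differential expression needs >= 2 replicates per group")
  }

  mean_c <- unname(rowMeans(ctl))
  mean_t <- unname(rowMeans(trt))
  var_c <- unname(apply(ctl, 1L, stats::var))
  var_t <- unname(apply(trt, 1L, stats::var))
  tested <- (var_c > 0) | (var_t > 0)

  t_stat <- df <- p <- rep(NA_real_, nrow(mat))
  for (i in which(tested)) {
    res <- welch_t(trt[i, ], ctl[i, ], var_equal = var_equal)
    t_stat[i] <- res$statistic
    df[i] <- res$df
    p[i] <- res$p
  }
  p_adj <- rep(NA_real_, nrow(mat))
  p_adj[tested] <- bh_adjust(p[tested])

  log2fc <- mean_t - mean_c
  status <- dplyr::case_when(
    !tested ~ NA_character_,
    p_adj < alpha & log2fc > fc_min ~ "up",
    p_adj < alpha & log2fc < -fc_min ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::tibble(
    protein_id = m$values$protein_id,
    gene_symbol = m$values$gene_symbol,
    mean_log2_control = mean_c,
    mean_log2_treated = mean_t,
    log2fc = log2fc,
    t = t_stat,
    df = df,
    p = p,
    p_adj = p_adj,
    status = status,
    tested = tested
  )
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  class(out) <- c("swim_de", class(out))
  out
}

#' Classify differential-expression status from effect and significance
#'
#' The volcano-plot rule applied to any table that carries a log2 fold
#' change and either an adjusted p-value (`p_adj`) or a logical
#' `significant` column: `up` when significant and `log2fc > fc_min`,
#' `down` when significant and `log2fc < -fc_min`, else `ns`.
#'
#' @param data A data frame with `log2fc` plus `p_adj` or `significant`.
#' @param alpha,fc_min Thresholds (defaults 0.05 and 1).
#' @return `data` with an added `status` column.
#' @export
classify_de_status <- function(data, alpha = 0.05, fc_min = 1) {
  if (!"log2fc" %in% names(data)) abort_validation("`data` needs a log2fc column")
  sig <- if ("p_adj" %in% names(data)) {
    data$p_adj < alpha
  } else if ("significant" %in% names(data)) {
    as.logical(data$significant)
  } else {
    abort_validation("`data` needs a p_adj or significant column")
  }
  data$status <- dplyr::case_when(
    sig & data$log2fc > fc_min ~ "up",
    sig & data$log2fc < -fc_min ~ "down",
    TRUE ~ "ns"
  )
  data
}

#' Regulation table for a curated gene subset
#'
#' Extracts a curated, ordered subset of genes from a differential
#' expression table and reports each one's log2 fold change with a
#' direction arrow: "↑" for upregulated (log2fc > 0 among
#' significant rows), "↓" for downregulated.  Gene symbols that do
#' not resolve in the DE table are listed in the `unresolved` attribute,
#' not silently dropped.
#'
#' @param de A data frame with columns `gene_symbol`, `log2fc` and
#'   `status` (e.g. from [differential_expression()] or
#'   [classify_de_status()]); an optional `protein_name` column is carried
#'   through.
#' @param subset Character vector of gene symbols, in the desired output
#'   order.
#' @return A tibble with columns `gene_symbol` (subset order),
#'   `protein_name` (if available), `log2fc`, `status`, `direction`
#'   (arrow, `NA` for non-significant rows); attribute `unresolved` holds
#'   the unmatched symbols.
#' @export
regulation_table <- function(de, subset) {
  if (!all(c("gene_symbol", "log2fc", "status") %in% names(de))) {
    abort_validation("`de` needs gene_symbol, log2fc and status columns")
  }
  found <- subset[subset %in% de$gene_symbol]
  unresolved <- setdiff(subset, found)
  keep_cols <- intersect(c("gene_symbol", "protein_name", "log2fc", "status"),
                         names(de))
  out <- tibble::tibble(gene_symbol = found) |>
    dplyr::left_join(de[keep_cols], by = "gene_symbol") |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$status %in% c("up", "down") & .data$log2fc > 0 ~ "↑",
      .data$status %in% c("up", "down") & .data$log2fc < 0 ~ "↓",
      TRUE ~ NA_character_
    ))
  attr(out, "unresolved") <- unresolved
  out
}

#' Read a term-to-gene annotation table
#'
#' Flat two-column TSV mapping `term_id` to `gene_symbol` (one pair per
#' row), optionally joined with a `term_id`/`term_name` table.
#'
#' @param path Annotation TSV path.
#' @param names_path Optional term-name TSV path.
#' @return A tibble with columns `term_id`, `gene_symbol` and (if
#'   provided) `term_name`.
#' @export
read_annotation <- function(path, names_path = NULL) {
  if (!file.exists(path)) abort_io(sprintf("annotation file '%s' does not exist", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("term_id", "gene_symbol") %in% names(ann))) {
    abort_format("annotation must have columns term_id and gene_symbol")
  }
  if (!is.null(names_path)) {
    nm <- readr::read_tsv(names_path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("term_id", "term_name") %in% names(nm))) {
      abort_format("term-name table must have columns term_id and term_name")
    }
    ann <- dplyr::left_join(ann, nm, by = "term_id")
  }
  ann
}

#' Hypergeometric gene-set over-representation analysis
#'
#' For every annotation term, tests whether the query gene set contains
#' more of the term's genes than expected from drawing `|query|` genes at
#' random from the background (exact upper-tail hypergeometric test),
#' then applies Benjamini-Hochberg correction across all terms.  Term
#' gene sets are intersected with the background first; the query must be
#' a subset of the background.
#'
#' @param query Character vector of gene symbols (e.g. the significant
#'   proteins).
#' @param annotation A term-to-gene tibble from [read_annotation()] (or
#'   equivalent, columns `term_id`, `gene_symbol`, optional `term_name`).
#' @param background Character vector of gene symbols defining the tested
#'   universe (e.g. all quantified proteins).
#' @param q_max Report terms with adjusted p below this cutoff
#'   (default 0.01).  `q_max = 1` reports everything.
#'
#' @return A tibble ranked by ascending `p_adj` with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `neg_log10_p_adj`; only rows with `p_adj < q_max` are kept.
#' @export
enrich <- function(query, annotation, background, q_max = 0.01) {
  query <- unique(query)
  background <- unique(background)
  if (length(background) == 0L) abort_validation("background gene set is empty")
  extra <- setdiff(query, background)
  if (length(extra) > 0L) {
    abort_validation(sprintf("query genes absent from background: %s",
                             paste(utils::head(extra, 5), collapse = ", ")))
  }
  check_number(q_max, "q_max", min = 0, max = 1)
  has_names <- "term_name" %in% names(annotation)
  terms <- annotation |>
    dplyr::filter(.data$gene_symbol %in% background) |>
    dplyr::distinct(.data$term_id, .data$gene_symbol) |>
    dplyr::summarise(genes = list(.data$gene_symbol), .by = "term_id")
  n_bg <- length(background)
  n_query <- length(query)
  out <- terms |>
    dplyr::mutate(
      K = purrr::map_int(.data$genes, length),
      k = purrr::map_int(.data$genes, ~ length(intersect(.x, query))),
      n = n_query, N = n_bg
    ) |>
    dplyr::select(-"genes")
  out$p <- purrr::map2_dbl(out$k, out$K,
                           ~ hypergeom_enrich_p(.x, .y, n_query, n_bg))
  out$p_adj <- bh_adjust(out$p)
  if (has_names) {
    nm <- dplyr::distinct(annotation, .data$term_id, .data$term_name)
    out <- dplyr::left_join(out, nm, by = "term_id")
  } else {
    out$term_name <- NA_character_
  }
  out |>
    dplyr::mutate(neg_log10_p_adj = -log10(.data$p_adj)) |>
    dplyr::filter(q_max >= 1 | .data$p_adj < q_max) |>
    dplyr::arrange(.data$p_adj) |>
    dplyr::select("term_id", "term_name", "k", "K", "n", "N", "p",
                  "p_adj", "neg_log10_p_adj")
}
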