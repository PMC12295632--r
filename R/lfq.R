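#' Construct a label-free quantification (LFQ) matrix
#'
#' Bundles a protein x sample intensity table with its sample annotation.
#' Intensities are non-negative (or `NA` for not-detected); the design is
#' the usual two-group layout (control vs treated) with replicate indices.
#'
#' @param values A data frame with columns `protein_id`, `gene_symbol`,
#'   then one numeric column per sample.
#' @param samples A data frame with columns `sample` (matching the value
#'   columns), `group` (`"control"`/`"treated"`) and `replicate`.
#' @param scale `"intensity"` (raw, default) or `"log2"`.
#'
#' @return An object of class `lfq_matrix`: list with `values`, `samples`,
#'   `scale`.
#' @export
lfq_matrix <- function(values, samples, scale = c("intensity", "log2")) {
  scale <- match.arg(scale)
  values <- tibble::as_tibble(values)
  samples <- tibble::as_tibble(samples)
  need <- c("protein_id", "gene_symbol")
  if (!all(need %in% names(values))) {
    abort_format("`values` must have columns protein_id and gene_symbol")
  }
  if (!all(c("sample", "group") %in% names(samples))) {
    abort_format("`samples` must have columns sample and group")
  }
  if (!all(samples$group %in% c("control", "treated"))) {
    abort_validation("sample groups must be 'control' or 'treated'")
  }
  if (length(unique(samples$group)) < 2L) {
    abort_validation("sample annotation must cover both groups")
  }
  if (!"replicate" %in% names(samples)) {
    samples <- samples |>
      dplyr::mutate(replicate = dplyr::row_number(), .by = "group")
  }
  missing_cols <- setdiff(samples$sample, names(values))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf("sample column(s) absent from `values`: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(values$protein_id)) {
    abort_validation("protein_id must be unique")
  }
  m <- as.matrix(values[samples$sample])
  if (any(is.infinite(m))) abort_validation("intensities must be finite or NA")
  if (scale == "intensity" && any(m < 0, na.rm = TRUE)) {
    abort_validation("raw intensities must be non-negative")
  }
  structure(
    list(
      values = values[c("protein_id", "gene_symbol", samples$sample)],
      samples = samples,
      scale = scale
    ),
    class = "lfq_matrix"
  )
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples (%s scale)\n",
              nrow(x$values), nrow(x$samples), x$scale))
  print(dplyr::count(x$samples, .data$group))
  invisible(x)
}

lfq_intensity_matrix <- function(m) {
  out <- as.matrix(m$values[m$samples$sample])
  rownames(out) <- m$values$protein_id
  out
}

group_samples <- function(m, group) {
  m$samples$sample[m$samples$group == group]
}

#' Read an LFQ matrix from CSV/TSV
#'
#' Expects `protein_id,gene_symbol,<sample columns>`; empty cells or "NA"
#' mark proteins not detected in that sample.  The sample-to-group map is
#' given separately (a data frame, or a named character vector
#' `c(sample = "control", ...)`).
#'
#' @param path CSV or TSV file (delimiter chosen by extension).
#' @param samples Sample annotation; see [lfq_matrix()].
#' @return An `lfq_matrix` on the intensity scale.
#' @export
read_lfq <- function(path, samples) {
  if (!file.exists(path)) abort_io(sprintf("LFQ file '%s' does not exist", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  values <- reader(path, na = c("", "NA"), show_col_types = FALSE, progress = FALSE)
  if (is.character(samples) && !is.null(names(samples))) {
    samples <- tibble::tibble(sample = names(samples), group = unname(samples))
  }
  lfq_matrix(values, samples)
}

#' Write an LFQ matrix to TSV
#'
#' @param m An `lfq_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfq <- function(m, path) {
  stopifnot(inherits(m, "lfq_matrix"))
  readr::write_tsv(m$values, path, progress = FALSE)
  invisible(path)
}

#' Per-group detection sets (shared / exclusive protein accounting)
#'
#' A protein is "detected" in a group when it is quantified in both
#' replicates of that group (`rule = "both_replicates"`, the conservative
#' default) or in at least one (`rule = "any_replicate"`).  The shared set
#' is the intersection of the two groups' detections; the shared,
#' control-only and treated-only sets partition the union.
#'
#' @param m An `lfq_matrix` (raw, unfiltered).
#' @param rule Detection rule.
#' @return A list of class `detection_sets` with character-vector elements
#'   `detected_control`, `detected_treated`, `shared`, `control_only`,
#'   `treated_only`; `tidy()` returns the counts.
#' @export
detection_sets <- function(m, rule = c("both_replicates", "any_replicate")) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (is.character(rule) && length(rule) == 1L &&
      !rule %in% c("both_replicates", "any_replicate")) {
    abort_validation(sprintf("unknown detection rule '%s'", rule))
  }
  rule <- match.arg(rule)
  mat <- lfq_intensity_matrix(m)
  detected_in <- function(group) {
    sub <- !is.na(mat[, group_samples(m, group), drop = FALSE])
    hit <- if (rule == "both_replicates") rowSums(sub) == ncol(sub) else rowSums(sub) > 0
    rownames(mat)[hit]
  }
  ctl <- detected_in("control")
  trt <- detected_in("treated")
  structure(
    list(
      detected_control = ctl,
      detected_treated = trt,
      shared = intersect(ctl, trt),
      control_only = setdiff(ctl, trt),
      treated_only = setdiff(trt, ctl),
      rule = rule
    ),
    class = "detection_sets"
  )
}

#' @method tidy detection_sets
#' @export
tidy.detection_sets <- function(x, ...) {
  tibble::tibble(
    set = c("detected_control", "detected_treated", "shared",
            "control_only", "treated_only"),
    n = c(length(x$detected_control), length(x$detected_treated),
          length(x$shared), length(x$control_only), length(x$treated_only))
  )
}

#' @export
print.detection_sets <- function(x, ...) {
  cat(sprintf("<detection_sets> rule = %s\n", x$rule))
  print(tidy(x))
  invisible(x)
}

#' Replicate-consistency filter
#'
#' Retains exactly the proteins quantified in every sample of every group;
#' proteins with any missing value are excluded outright.  No imputation
#' is performed anywhere in the pipeline -- dropping inconsistent proteins
#' trades coverage for high-confidence quantification, the appropriate
#' stance for duplicate-pool discovery designs.  Idempotent.
#'
#' @param m An `lfq_matrix`.
#' @return The filtered `lfq_matrix`.
#' @export
filter_consistent <- function(m) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (any(table(m$samples$group) < 2L)) {
    abort_validation("filtering requires at least 2 replicates per group")
  }
  mat <- lfq_intensity_matrix(m)
  keep <- rowSums(is.na(mat)) == 0L
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}

#' Log2 transform and normalize an LFQ matrix
#'
#' Transforms intensities to log2 and, with the default
#' `normalization = "median_center"`, subtracts each sample's median log2
#' intensity so every sample's median is zero; `"none"` leaves plain log2
#' values.  Run after [filter_consistent()] -- zero or missing intensities
#' are an error here.
#'
#' @param m An `lfq_matrix` on the intensity scale.
#' @param normalization `"median_center"` (default) or `"none"`.
#' @return An `lfq_matrix` with `scale = "log2"`.
#' @export
log2_normalize <- function(m, normalization = c("median_center", "none")) {
  stopifnot(inherits(m, "lfq_matrix"))
  normalization <- match.arg(normalization)
  if (m$scale != "intensity") abort_validation("matrix is already on the log2 scale")
  mat <- lfq_intensity_matrix(m)
  if (anyNA(mat)) {
    abort_validation("missing intensities present; apply filter_consistent() first")
  }
  if (any(mat <= 0)) {
    abort_validation("zero or negative intensities cannot be log2-transformed")
  }
  lmat <- log2(mat)
  if (normalization == "median_center") {
    med <- apply(lmat, 2L, stats::median)
    lmat <- sweep(lmat, 2L, med)
  }
  out <- m
  out$values[m$samples$sample] <- as.data.frame(lmat)
  out$scale <- "log2"
  out$normalization <- normalization
  out
}
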