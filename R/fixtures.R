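#' Curated neurodegeneration-associated protein set (MPP+ larval model)
#'
#' Forty proteins with known or putative roles in neurodegeneration that
#' were differentially expressed in MPP+-exposed zebrafish larvae
#' (mitochondrial metabolism, redox regulation, proteasome subunits,
#' synaptic and cytoskeletal proteins).  Each row records the reported
#' log2 fold change (treated vs control), a significance flag (all rows
#' passed adjusted p < 0.05) and the reported regulation arrow.  This is
#' a curated reference input, not an algorithmic selection: functional
#' relevance to neurobiology is literature knowledge, not something the
#' pipeline computes.
#'
#' @return A tibble with columns `gene_symbol`, `protein_name`, `log2fc`,
#'   `significant`, `direction`.
#' @export
curated_neuro_set <- function() {
  path <- system.file("extdata", "mpp_neuro40.tsv", package = "swimprot",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    gene_symbol = "c", protein_name = "c",
                    log2fc = "d", significant = "l", direction = "c"
                  ))
}

#' Curated Parkinsonism-associated protein subset
#'
#' Eight proteins central to Parkinsonian mechanisms (TCA-cycle enzymes
#' SDHA and CS, the redox chaperone PARK7/DJ-1, and 26S proteasome
#' subunits).  Two symbol spellings circulate for several proteasome
#' members (e.g. PSMA5 vs PSMA8, PSMD11 vs PSMD11B); the fixture records
#' both -- `symbol` is the prose spelling, `matched_symbols` the
#' spelling(s) used in the curated 40-protein table -- and leaves the
#' discrepancy documented rather than resolved.
#'
#' @return A tibble with columns `symbol`, `matched_symbols` (semicolon
#'   separated), `category`, `note`.
#' @export
curated_parkinson_set <- function() {
  path <- system.file("extdata", "mpp_parkinson8.tsv", package = "swimprot",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Synthetic demonstration annotation built from protein names
#'
#' Builds a small term-to-gene annotation by keyword-matching protein
#' names (mitochondrial, proteasome, vesicle/synaptic, calcium handling).
#' Synthetic: a stand-in for a real GO/KEGG annotation, sufficient to
#' exercise the enrichment machinery in examples and tests.
#'
#' @param proteins A data frame with `gene_symbol` and `protein_name`
#'   columns (defaults to [curated_neuro_set()]).
#' @return A tibble with columns `term_id`, `term_name`, `gene_symbol`.
#' @export
synthetic_annotation <- function(proteins = curated_neuro_set()) {
  rules <- list(
    list(id = "T:MITO", name = "mitochondrial protein", pattern = "itochondri"),
    list(id = "T:PROT", name = "proteasome complex", pattern = "roteasome"),
    list(id = "T:VESI", name = "vesicle and synaptic organization",
         pattern = "esicle|ynap|eurofilament"),
    list(id = "T:CALC", name = "calcium ion handling", pattern = "alcium|Ca\\+\\+")
  )
  purrr::map_dfr(rules, function(r) {
    hit <- grepl(r$pattern, proteins$protein_name)
    tibble::tibble(term_id = r$id, term_name = r$name,
                   gene_symbol = proteins$gene_symbol[hit])
  })
}
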