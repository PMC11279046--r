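#' Bundled bladder-cancer example tables
#'
#' Two small tables from a published TCGA-BLCA methylation analysis,
#' bundled so the gene-frequency ranking and final-gene selection steps
#' have a real worked example:
#'
#' * `blca_enriched_terms()` — 14 GO biological-process terms enriched
#'   (p < 0.05) among the survival-associated genes of that cohort, with
#'   their overlapping gene symbols; returned in the shape produced by
#'   [enrich()] (`genes` as a list-column, `enriched = TRUE`).
#' * `blca_final_probe_annotation()` — annotation of the cohort's four
#'   final prognostic CpG probes (PRKCZ, PTK2 and two IL18 probes);
#'   genomic positions are approximate.
#'
#' @return a tibble (see above).
#' @export
blca_enriched_terms <- function() {
  path <- system.file("extdata", "blca_enriched_bp_terms.tsv",
                      package = "methmark")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "ccidc")
  tibble::tibble(
    term_id = df$term_id,
    term_name = df$term_name,
    overlap_count = df$count,
    p_value = df$p_value,
    genes = strsplit(df$genes, ";", fixed = TRUE),
    enriched = TRUE
  )
}

#' @rdname blca_enriched_terms
#' @export
blca_final_probe_annotation <- function() {
  read_probe_annotation(system.file("extdata",
                                    "blca_final_probe_annotation.tsv",
                                    package = "methmark"))
}
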