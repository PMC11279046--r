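#' Default pipeline configuration
#'
#' Every analysis threshold is a named key, defaulting to the canonical
#' settings of the three-step strategy: FDR 0.01 for discovery, raw Cox
#' p < 0.01 for the survival screen, enrichment p < 0.05, top 3 genes.
#'
#' @param simulate generate the cohorts with the synthetic module
#'   (default TRUE). When FALSE, `inputs` must name the on-disk files.
#' @param sim a [simulation_config()] (used when `simulate = TRUE`).
#' @param inputs named list of file paths when `simulate = FALSE`:
#'   `pair_matrix` (TSV beta matrix covering both tissues), `sample_meta`
#'   (TSV `sample_id`, `patient_id`, `sample_type`), `validation_matrix`,
#'   `clinical`, `annotation`, `gene_sets` (GMT).
#' @param q_fdr,correction,separation discovery settings (see
#'   [discover()]).
#' @param cox_alpha,enrich_p,enrich_method,min_enrich_overlap,blacklist,top_k
#'   survival-validation settings.
#' @param min_group_abs,min_group_frac,permutations threshold-search
#'   settings; `permutations = 0` reports the raw minimal log-rank p.
#' @param seed root seed for synthetic mode and permutations.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = simulation_config(seed = seed),
                            inputs = list(),
                            q_fdr = 0.01,
                            correction = "bh",
                            separation = TRUE,
                            cox_alpha = 0.01,
                            enrich_p = 0.05,
                            enrich_method = "hypergeometric",
                            min_enrich_overlap = 2,
                            blacklist = character(0),
                            top_k = 3,
                            min_group_abs = 2,
                            min_group_frac = 0.01,
                            permutations = 0,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the three-step biomarker pipeline end to end
#'
#' Executes discovery (paired testing + FDR + separation filter), survival
#' validation (Cox screen, gene mapping, over-representation, gene
#' frequency ranking) and threshold determination (constrained minimal-p
#' cutpoint scans) with one configuration, writing every intermediate
#' table as TSV plus a machine-readable run report.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return a `methmark_run` report: configuration echo, per-stage counts
#'   (the selection funnel), threshold table, seed, package version,
#'   timestamp and a file manifest with MD5 checksums. Inspect with
#'   [summary()] or [tidy()].
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("methmark_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out_path <- function(f) file.path(outdir, f)

  if (isTRUE(config$simulate)) {
    sim <- simulate_matched_cohort(config$sim)
    pairs <- sim$pairs
    truth <- sim$truth
    val <- simulate_validation_cohort(config$sim, truth)
    uni <- simulate_gene_universe(config$sim, truth)
    vbeta <- val$beta; clinical <- val$clinical
    annotation <- uni$annotation; sets <- uni$sets
    write_truth(truth, out_path("truth.tsv"))
  } else {
    inp <- config$inputs
    need <- c("pair_matrix", "sample_meta", "validation_matrix", "clinical",
              "annotation", "gene_sets")
    miss <- setdiff(need, names(inp))
    if (length(miss)) {
      stop("missing input path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    pm <- read_beta_matrix(inp$pair_matrix)
    meta <- readr::read_tsv(inp$sample_meta, show_col_types = FALSE,
                            progress = FALSE)
    pairs <- build_matched_pairs(pm, meta)
    vbeta <- read_beta_matrix(inp$validation_matrix)
    clinical <- read_clinical(inp$clinical)
    annotation <- read_probe_annotation(inp$annotation)
    sets <- read_gene_sets(inp$gene_sets)
  }

  # -- step 1: discovery -------------------------------------------------
  disc <- discover(pairs, q = config$q_fdr, correction = config$correction,
                   separation = config$separation)
  candidates <- select_candidates(disc, q_threshold = config$q_fdr)
  readr::write_tsv(disc, out_path("discovery.tsv"), na = "NA",
                   progress = FALSE)
  readr::write_tsv(candidates, out_path("candidates.tsv"), na = "NA",
                   progress = FALSE)
  manh <- manhattan_table(disc, annotation)
  readr::write_tsv(manh, out_path("manhattan.tsv"), na = "NA",
                   progress = FALSE)
  message(sprintf("discovery: %d probes tested, %d FDR-significant, %d candidates",
                  sum(!is.na(disc$p_value)), sum(disc$q_value <= config$q_fdr,
                                                 na.rm = TRUE),
                  nrow(candidates)))

  # -- step 2: survival validation --------------------------------------
  cox <- cox_screen(vbeta, clinical, probes = candidates$probe_id)
  cox_sig <- filter_by_p(cox, alpha = config$cox_alpha)
  readr::write_tsv(cox, out_path("cox.tsv"), na = "NA", progress = FALSE)
  links <- map_to_genes(cox_sig$probe_id, annotation)
  universe <- unique(expand_annotation_genes(annotation)$gene)
  enr <- enrich(unique(links$gene), sets, universe,
                method = config$enrich_method, p_cutoff = config$enrich_p,
                min_overlap = config$min_enrich_overlap)
  enr_sig <- enr[enr$enriched, ]
  enr_kept <- apply_term_blacklist(enr_sig, config$blacklist)
  freq <- gene_frequency_rank(enr_kept)
  final <- select_final_genes(freq, links, top_k = config$top_k)
  enr_flat <- dplyr::mutate(enr, genes = vapply(.data$genes, paste,
                                                character(1),
                                                collapse = ";"))
  readr::write_tsv(enr_flat, out_path("enrichment.tsv"), na = "NA",
                   progress = FALSE)
  freq_flat <- dplyr::mutate(freq, term_ids = vapply(.data$term_ids, paste,
                                                     character(1),
                                                     collapse = ";"))
  readr::write_tsv(freq_flat, out_path("gene_frequency.tsv"), na = "NA",
                   progress = FALSE)
  readr::write_tsv(final$probes, out_path("final_candidates.tsv"),
                   na = "NA", progress = FALSE)
  message(sprintf(
    "validation: %d Cox-significant probes (%d genes), %d/%d enriched terms kept, %d final genes / %d probes",
    nrow(cox_sig), length(unique(links$gene)), nrow(enr_kept),
    nrow(enr_sig), length(final$genes), nrow(final$probes)))

  # -- step 3: threshold determination ----------------------------------
  final_probes <- unique(final$probes$probe_id)
  final_probes <- intersect(final_probes, rownames(vbeta))
  thr <- if (length(final_probes)) {
    threshold_screen(vbeta, clinical, final_probes,
                     min_group_frac = config$min_group_frac,
                     min_group_abs = config$min_group_abs)
  } else list(summary = tibble::tibble(), results = list())
  if (config$permutations > 0 && length(final_probes)) {
    thr$summary$adjusted_p <- vapply(final_probes, function(p) {
      permutation_adjusted_p(vbeta, clinical, thr$results[[p]],
                             n_permutations = config$permutations,
                             seed = config$seed, probe = p)
    }, numeric(1))
  }
  readr::write_tsv(thr$summary, out_path("thresholds.tsv"), na = "NA",
                   progress = FALSE)
  km_tables <- dplyr::bind_rows(lapply(final_probes, function(p) {
    dplyr::mutate(km_plot_table(thr$results[[p]], clinical, vbeta,
                                probe = p),
                  probe_id = p, .before = 1)
  }))
  readr::write_tsv(km_tables, out_path("km_curves.tsv"), na = "NA",
                   progress = FALSE)

  files <- list.files(outdir, full.names = TRUE)
  report <- structure(list(
    config = config,
    funnel = tibble::tibble(
      stage = c("probes_tested", "fdr_significant", "candidates",
                "cox_significant", "genes_mapped", "enriched_terms",
                "enriched_after_blacklist", "final_genes", "final_probes",
                "thresholds"),
      count = c(sum(!is.na(disc$p_value)),
                sum(disc$q_value <= config$q_fdr, na.rm = TRUE),
                nrow(candidates), nrow(cox_sig),
                length(unique(links$gene)), nrow(enr_sig), nrow(enr_kept),
                length(final$genes), nrow(final$probes),
                nrow(thr$summary))
    ),
    final_genes = final$genes,
    thresholds = thr$summary,
    seed = config$seed,
    version = as.character(utils::packageVersion("methmark")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    manifest = tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  ), class = "methmark_run")
  writeLines(report_json(report), out_path("run_report.json"))
  report$manifest <- dplyr::bind_rows(
    report$manifest,
    tibble::tibble(file = "run_report.json",
                   md5 = unname(tools::md5sum(out_path("run_report.json")))))
  report$outdir <- outdir
  report
}

# serialized report; the timestamp is the only field expected to differ
# between identically-seeded runs
report_json <- function(report) {
  jsonlite::toJSON(list(
    seed = report$seed,
    version = report$version,
    timestamp = report$timestamp,
    funnel = report$funnel,
    final_genes = report$final_genes,
    thresholds = report$thresholds,
    manifest = report$manifest
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @export
print.methmark_run <- function(x, ...) {
  summary(x)
  invisible(x)
}

#' @export
summary.methmark_run <- function(object, ...) {
  cat("== methmark run (seed ", object$seed, ") ==\n", sep = "")
  cat("selection funnel:\n")
  for (i in seq_len(nrow(object$funnel))) {
    cat(sprintf("  %-26s %d\n", object$funnel$stage[i],
                object$funnel$count[i]))
  }
  if (nrow(object$thresholds)) {
    cat("thresholds:\n")
    print(object$thresholds)
  } else {
    cat("thresholds: none (empty final set)\n")
  }
  invisible(object$funnel)
}

#' @export
#' @method tidy methmark_run
tidy.methmark_run <- function(x, ...) x$funnel

#' @export
#' @method glance methmark_run
glance.methmark_run <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    probes_tested = x$funnel$count[x$funnel$stage == "probes_tested"],
    candidates = x$funnel$count[x$funnel$stage == "candidates"],
    final_genes = length(x$final_genes),
    thresholds = nrow(x$thresholds)
  )
}
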