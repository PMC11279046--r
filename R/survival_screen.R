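#' Univariate Cox screening of candidate probes
#'
#' Fits, for each probe, a univariate Cox proportional-hazards model with
#' the continuous beta value as the only covariate (Breslow tie handling)
#' on the validation cohort, and reports the Wald two-sided p-value.
#' Patients missing a probe's value are dropped for that probe
#' (complete-case per probe). Probes with a constant covariate are flagged
#' `"degenerate"` with p = 1 by convention; non-converging fits are flagged
#' `"no_convergence"` and excluded from downstream selection by
#' [filter_by_p()].
#'
#' @param beta a [beta_matrix] of tumor beta values; column names must map
#'   to `clinical$patient_id`.
#' @param clinical tibble with `patient_id`, `event`, `time` (see
#'   [read_clinical()]).
#' @param probes probe ids to screen (default: all rows of `beta`).
#' @param p_type `"wald"` (default) or `"lrt"` (likelihood-ratio).
#' @return tibble with one row per probe: `probe_id`, `n_used`, `n_events`,
#'   `log_hazard_ratio` (per unit beta), `standard_error`, `wald_p`,
#'   `flag`.
#' @export
cox_screen <- function(beta, clinical, probes = rownames(beta),
                       p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  stopifnot(inherits(beta, "beta_matrix"))
  clinical <- validate_clinical(clinical)
  common <- intersect(colnames(beta), clinical$patient_id)
  if (length(common) < 2) {
    stop("no overlap between beta matrix samples and clinical patients",
         call. = FALSE)
  }
  probes <- intersect(probes, rownames(beta))
  cl <- clinical[match(common, clinical$patient_id), ]
  vals <- unclass(beta)[probes, common, drop = FALSE]

  fit_one <- function(x) {
    keep <- !is.na(x)
    x <- x[keep]
    n <- length(x)
    ev <- cl$event[keep]
    if (n < 2 || sum(ev) == 0 || var(x) == 0) {
      return(list(n = n, n_events = sum(ev), coef = NA_real_,
                  se = NA_real_, p = 1,
                  flag = if (n >= 2 && var(x) == 0 || n < 2) "degenerate"
                         else "no_events"))
    }
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(survival::Surv(cl$time[keep], ev) ~ x,
                        ties = "breslow"),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coef[1]) ||
        !is.finite(sqrt(fit$var[1, 1])) || abs(fit$coef[1]) > 50) {
      return(list(n = n, n_events = sum(ev), coef = NA_real_,
                  se = NA_real_, p = NA_real_, flag = "no_convergence"))
    }
    co <- unname(fit$coef[1])
    se <- sqrt(fit$var[1, 1])
    p <- if (p_type == "wald") {
      2 * stats::pnorm(-abs(co / se))
    } else {
      stats::pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
    }
    list(n = n, n_events = sum(ev), coef = co, se = se, p = p,
         flag = NA_character_)
  }

  res <- lapply(seq_len(nrow(vals)), function(i) fit_one(vals[i, ]))
  tibble::tibble(
    probe_id = probes,
    n_used = vapply(res, function(r) as.integer(r$n), integer(1)),
    n_events = vapply(res, function(r) as.integer(r$n_events), integer(1)),
    log_hazard_ratio = vapply(res, `[[`, numeric(1), "coef"),
    standard_error = vapply(res, `[[`, numeric(1), "se"),
    wald_p = vapply(res, `[[`, numeric(1), "p"),
    flag = vapply(res, `[[`, character(1), "flag")
  )
}

#' Filter Cox records by significance
#'
#' @param records tibble from [cox_screen()].
#' @param alpha raw significance level (default 0.01); flagged records are
#'   always dropped.
#' @return surviving records sorted by p-value.
#' @export
filter_by_p <- function(records, alpha = 0.01) {
  records |>
    dplyr::filter(is.na(.data$flag), !is.na(.data$wald_p),
                  .data$wald_p < alpha) |>
    dplyr::arrange(.data$wald_p, .data$probe_id)
}

#' Map probes to gene symbols
#'
#' @param probes character vector of probe ids.
#' @param annotation probe annotation tibble (see
#'   [read_probe_annotation()]); probes annotated with several genes emit
#'   one row per gene.
#' @return tibble `probe_id`, `gene` (one row per link), with attribute
#'   `unmapped` listing probes without any gene.
#' @export
map_to_genes <- function(probes, annotation) {
  links <- expand_annotation_genes(annotation) |>
    dplyr::filter(.data$probe_id %in% probes)
  out <- links[order(links$probe_id, links$gene), ]
  attr(out, "unmapped") <- setdiff(probes, out$probe_id)
  out
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, tests whether the query genes overlap it more than
#' expected by chance: upper-tail hypergeometric probability
#' `P(X >= overlap)` with population `|universe|`, successes
#' `|set intersect universe|` and draws `|query|`. Method `"ease"` uses the
#' EASE score variant (overlap reduced by one), which penalizes small
#' overlaps. A term is flagged *enriched* when `p < p_cutoff` and the
#' overlap reaches `min_overlap` (default 2, so single-gene overlaps never
#' drive a term). No multiplicity correction is applied across terms by
#' default; set `adjust = TRUE` for BH-adjusted flags.
#'
#' @param query character vector of query gene symbols.
#' @param sets gene-set tibble (see [read_gene_sets()]).
#' @param universe character vector of background gene symbols; query genes
#'   outside it are dropped with a warning, sets are intersected with it.
#' @param method `"hypergeometric"` (default) or `"ease"`.
#' @param p_cutoff enrichment level (default 0.05).
#' @param min_overlap minimum overlapping genes (default 2).
#' @param adjust apply BH across terms before flagging (default FALSE).
#' @return tibble `term_id`, `term_name`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `genes` (list-column of
#'   overlapping symbols), `enriched`; sorted by p-value.
#' @export
enrich <- function(query, sets, universe,
                   method = c("hypergeometric", "ease"),
                   p_cutoff = 0.05, min_overlap = 2, adjust = FALSE) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    members <- intersect(sets$genes[[i]], universe)
    ov <- intersect(query, members)
    k <- length(ov)
    shift <- if (method == "ease") 1L else 0L
    p <- if (k - shift <= 0) 1 else {
      phyper(k - shift - 1L, length(members), n_u - length(members), n_q,
             lower.tail = FALSE)
    }
    tibble::tibble(term_id = sets$term_id[i], term_name = sets$term_name[i],
                   overlap_count = k, set_size = length(members),
                   query_size = n_q, universe_size = n_u,
                   p_value = p, genes = list(sort(ov)))
  })
  out <- dplyr::bind_rows(rows)
  flag_p <- if (adjust) p.adjust(out$p_value, "BH") else out$p_value
  out$enriched <- flag_p < p_cutoff & out$overlap_count >= min_overlap
  dplyr::arrange(out, .data$p_value, .data$term_id)
}

#' Remove blacklisted (ubiquitous) terms from enrichment records
#'
#' Terms describing processes active in essentially every cell type add no
#' cancer-specific signal; their ids can be supplied as a configuration
#' blacklist and are removed here.
#'
#' @param records enrichment tibble from [enrich()].
#' @param blacklist character vector of term ids to drop; ids absent from
#'   `records` trigger a warning (no-op for them).
#' @return the records without blacklisted terms.
#' @export
apply_term_blacklist <- function(records, blacklist) {
  if (length(blacklist) == 0) return(records)
  absent <- setdiff(blacklist, records$term_id)
  if (length(absent)) {
    warning("blacklisted term(s) not present: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- records[!records$term_id %in% blacklist, ]
  removed <- nrow(records) - nrow(out)
  if (removed > 0) message(removed, " blacklisted term(s) removed")
  out
}

#' Rank genes by their frequency across enriched terms
#'
#' Counts, for every gene, how many enriched terms list it among their
#' overlapping genes. Genes recurring across many survival-linked
#' biological processes are taken as the strongest prognostic leads.
#'
#' @param records enrichment tibble (typically already filtered to
#'   `enriched` terms and blacklist-cleaned).
#' @return tibble `gene`, `count`, `term_ids` (list-column), sorted by
#'   count descending then gene symbol.
#' @export
gene_frequency_rank <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(gene = character(0), count = integer(0),
                          term_ids = list()))
  }
  long <- tibble::tibble(
    term_id = rep(records$term_id,
                  vapply(records$genes, length, integer(1))),
    gene = unlist(records$genes)
  )
  long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(count = dplyr::n(),
                     term_ids = list(sort(unique(.data$term_id))),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene)
}

#' Select the final biomarker genes and their probes
#'
#' @param frequency tibble from [gene_frequency_rank()].
#' @param probe_gene_table probe-to-gene links of the surviving candidate
#'   probes (from [map_to_genes()]).
#' @param top_k number of genes to keep (default 3); ties at the boundary
#'   are broken lexicographically and reported.
#' @return list with `genes` (character) and `probes` (tibble `probe_id`,
#'   `gene` restricted to the selected genes).
#' @export
select_final_genes <- function(frequency, probe_gene_table, top_k = 3) {
  k <- min(top_k, nrow(frequency))
  if (k < nrow(frequency) &&
      frequency$count[k] == frequency$count[k + 1]) {
    message("tie at rank ", k,
            " broken lexicographically by gene symbol")
  }
  genes <- frequency$gene[seq_len(k)]
  probes <- probe_gene_table |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::arrange(.data$probe_id)
  list(genes = genes, probes = probes)
}
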