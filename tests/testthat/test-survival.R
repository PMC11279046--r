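make_surv_cohort <- function(n = 300, seed = 1, hr_high = 3) {
  set.seed(seed)
  beta <- rep(c(0.1, 0.9), each = n / 2)
  h <- 0.002 * ifelse(beta > 0.5, hr_high, 1)
  t_ev <- rexp(n, h)
  t_c <- runif(n, 200, 1500)
  list(
    beta = beta_matrix(matrix(beta, 1,
                              dimnames = list("cgX", paste0("P", 1:n)))),
    clinical = tibble::tibble(patient_id = paste0("P", 1:n),
                              event = as.integer(t_ev <= t_c),
                              time = pmin(t_ev, t_c)))
}

test_that("cox screen recovers a strong binary-like effect", {
  hits <- 0
  for (s in 1:25) {
    co <- make_surv_cohort(n = 300, seed = s)
    rec <- cox_screen(co$beta, co$clinical)
    expect_true(is.na(rec$flag))
    if (rec$log_hazard_ratio > 0 && rec$wald_p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
})

test_that("cox screen agrees with survival::coxph and flags degeneracy", {
  co <- make_surv_cohort(n = 80, seed = 4)
  rec <- cox_screen(co$beta, co$clinical)
  ref <- survival::coxph(
    survival::Surv(co$clinical$time, co$clinical$event) ~
      unclass(co$beta)["cgX", ], ties = "breslow")
  expect_equal(rec$log_hazard_ratio, unname(ref$coef), tolerance = 1e-8)
  expect_equal(rec$standard_error, sqrt(ref$var[1, 1]), tolerance = 1e-8)

  flat <- beta_matrix(matrix(0.5, 1, 80,
                             dimnames = list("cgX", paste0("P", 1:80))))
  rec2 <- cox_screen(flat, co$clinical)
  expect_equal(rec2$flag, "degenerate")
  expect_equal(rec2$wald_p, 1)
})

test_that("per-probe complete-case handling drops only affected patients", {
  co <- make_surv_cohort(n = 60, seed = 8)
  vals <- rbind(unclass(co$beta), cgY = runif(60, 0.2, 0.8))
  vals["cgY", 1:5] <- NA
  bm <- beta_matrix(vals)
  rec <- cox_screen(bm, co$clinical)
  expect_equal(rec$n_used, c(60L, 55L))
})

test_that("filter_by_p keeps unflagged records below alpha, sorted", {
  records <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    n_used = 10L, n_events = 5L,
    log_hazard_ratio = 1, standard_error = 1,
    wald_p = c(0.009, 0.011, 0.001, 0.002),
    flag = c(NA, NA, "no_convergence", NA))
  kept <- filter_by_p(records, alpha = 0.01)
  expect_equal(kept$probe_id, c("d", "a"))   # c is flagged, b above alpha
})

test_that("probe-to-gene mapping expands multi-gene probes and reports unmapped", {
  ann <- tibble::tibble(
    probe_id = c("cg11304234", "cg26534425", "cg2genes", "cgnone"),
    gene = c("IL18", "IL18", "PTK2;PRKCZ", NA),
    chromosome = "chr1", position = 1:4)
  links <- map_to_genes(c("cg11304234", "cg26534425", "cg2genes", "cgnone"),
                        ann)
  expect_equal(sort(unique(links$gene)), c("IL18", "PRKCZ", "PTK2"))
  expect_equal(nrow(links[links$gene == "IL18", ]), 2)
  expect_equal(nrow(links[links$probe_id == "cg2genes", ]), 2)
  expect_equal(attr(links, "unmapped"), "cgnone")
})

test_that("hypergeometric enrichment matches the combinatorial closed form", {
  sets <- tibble::tibble(term_id = "T", term_name = "t",
                         genes = list(paste0("G", 1:5)))
  universe <- paste0("G", 1:20)
  rec <- enrich(paste0("G", c(1:4, 10)), sets, universe, min_overlap = 2)
  expect_equal(rec$overlap_count, 4)
  expect_equal(rec$p_value,
               (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5),
               tolerance = 1e-12)
  expect_true(rec$enriched)

  rec0 <- enrich(paste0("G", 10:14), sets, universe)
  expect_equal(rec0$overlap_count, 0)
  expect_equal(rec0$p_value, 1)
})

test_that("enrichment equals exhaustive enumeration for all small universes", {
  set.seed(5)
  for (i in 1:60) {
    u_size <- sample(5:25, 1)
    universe <- paste0("G", seq_len(u_size))
    set_genes <- sample(universe, sample(2:u_size, 1))
    query <- sample(universe, sample(1:u_size, 1))
    sets <- tibble::tibble(term_id = "T", term_name = "t",
                           genes = list(set_genes))
    got <- enrich(query, sets, universe)
    ov <- length(intersect(query, set_genes))
    expect_equal(got$p_value,
                 hyper_tail_bruteforce(ov, length(set_genes), u_size,
                                       length(query)),
                 tolerance = 1e-12)
    # EASE variant shifts the overlap down by one
    ease <- enrich(query, sets, universe, method = "ease")
    expect_equal(ease$p_value,
                 hyper_tail_bruteforce(ov - 1, length(set_genes), u_size,
                                       length(query)),
                 tolerance = 1e-12)
    expect_gte(ease$p_value, got$p_value)
  }
})

test_that("planted enriched set is recovered from the simulated universe", {
  cfg <- simulation_config(n_pairs = 10, n_probes = 500,
                           n_separated_hyper = 10, n_separated_hypo = 10,
                           n_prognostic = 4, seed = 19)
  sim <- simulate_matched_cohort(cfg)
  uni <- simulate_gene_universe(cfg, sim$truth)
  prog <- sim$truth$probe_id[sim$truth$is_prognostic]
  query <- unique(map_to_genes(prog, uni$annotation)$gene)
  universe <- unique(unlist(strsplit(stats::na.omit(uni$annotation$gene),
                                     ";")))
  rec <- enrich(query, uni$sets, universe)
  expect_true(rec$enriched[rec$term_id == "SIM:ENRICHED"])
  expect_lt(rec$p_value[rec$term_id == "SIM:ENRICHED"], 0.05)
})

test_that("term blacklist removes listed terms and warns about absent ids", {
  records <- blca_enriched_terms()
  expect_equal(nrow(records), 14)
  expect_warning(out <- apply_term_blacklist(records, c("GO:0010744", "nope")),
                 "nope")
  expect_equal(nrow(out), 13)
  expect_identical(apply_term_blacklist(records, character(0)), records)
})

test_that("gene frequency ranking reproduces the published worked example", {
  # the 14 enriched biological-process terms of the bundled bladder-cancer
  # table: PRKCZ recurs in 7 of them, PTK2 in 6, IL18 in 4
  freq <- gene_frequency_rank(blca_enriched_terms())
  expect_equal(freq$count[freq$gene == "PRKCZ"], 7L)
  expect_equal(freq$count[freq$gene == "PTK2"], 6L)
  expect_equal(freq$count[freq$gene == "IL18"], 4L)
  expect_equal(freq$gene[1:3], c("PRKCZ", "PTK2", "IL18"))
  # conservation: counts sum to total gene-list length over terms
  expect_equal(sum(freq$count),
               sum(vapply(blca_enriched_terms()$genes, length, integer(1))))
  # count equals the number of contributing terms
  expect_equal(freq$count, vapply(freq$term_ids, length, integer(1)))

  ann <- blca_final_probe_annotation()
  final <- select_final_genes(freq, map_to_genes(ann$probe_id, ann))
  expect_setequal(final$genes, c("PRKCZ", "PTK2", "IL18"))
  expect_equal(nrow(final$probes), 4)
})

test_that("final-gene selection breaks ties lexicographically and caps top_k", {
  freq <- tibble::tibble(gene = c("B", "A", "C"), count = c(3L, 2L, 2L),
                         term_ids = list("t", "t", "t")) |>
    dplyr::arrange(dplyr::desc(count), gene)
  links <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                          gene = c("B", "A", "C"))
  expect_message(sel <- select_final_genes(freq, links, top_k = 2), "tie")
  expect_equal(sel$genes, c("B", "A"))
  sel_all <- select_final_genes(freq, links, top_k = 10)
  expect_equal(length(sel_all$genes), 3)
})

test_that("enrichment output is invariant to set and query order", {
  sets <- tibble::tibble(term_id = c("T1", "T2"), term_name = c("a", "b"),
                         genes = list(paste0("G", 1:6), paste0("G", 4:9)))
  universe <- paste0("G", 1:30)
  query <- paste0("G", c(2, 4, 5, 9))
  a <- enrich(query, sets, universe)
  b <- enrich(rev(query), sets[2:1, ], universe)
  expect_equal(a, b)
})
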