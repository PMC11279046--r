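#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: a discovery set
#' of 10 matched tumor/adjacent-normal pairs and an independent validation
#' cohort of 275 tumors, with four planted prognostic CpGs whose survival
#' effect switches on at fixed beta-value cutpoints (0.74, 0.14, 0.29,
#' 0.321). The baseline hazard corresponds to a median survival of roughly
#' six years for an unexposed patient, so that within the censoring
#' horizon roughly 30% of an all-null cohort experiences the event — about
#' the vital-status mix of the emulated cohort; censoring mixes an
#' administrative cap with uniform staggered-entry censoring.
#'
#' Null probes draw both tissues from the same per-probe baseline (probe
#' mean Beta-distributed, mildly bimodal as on methylation arrays) shifted
#' by a shared per-patient effect on the logit scale, so pairs are
#' correlated and tumor-normal differences are centered at zero. Planted
#' probes draw normal and tumor values uniformly from disjoint intervals
#' separated by at least `separation_gap`, above the normal range for
#' hypermethylated probes and below it for hypomethylated ones. All values
#' land in (0,1) by construction (truncated sampling), never by clamping.
#'
#' @param n_pairs discovery patients (matched pairs).
#' @param n_validation independent validation patients (tumor only).
#' @param n_probes total probes simulated.
#' @param n_separated_hyper,n_separated_hypo planted probes with complete
#'   tumor/normal separation in each direction.
#' @param n_prognostic planted survival markers, a subset of the separated
#'   probes; one per entry of `planted_cutpoints`.
#' @param separation_gap minimum distance (beta units) between the normal
#'   and tumor value intervals of a planted probe.
#' @param patient_effect_sd SD of the shared per-patient shift (logit scale).
#' @param noise_sd SD of per-measurement noise (logit scale).
#' @param baseline_hazard events/day for a patient with no risk indicator on.
#' @param planted_log_hr log hazard ratio of each planted threshold
#'   indicator.
#' @param planted_cutpoints beta-value cutpoints, in (0,1), at which the
#'   planted survival effects switch on; length `n_prognostic`.
#' @param censor_time_max administrative censoring horizon (days, > 0).
#' @param n_genes,n_gene_sets,genes_per_set gene-universe size parameters
#'   for [simulate_gene_universe()].
#' @param seed integer root seed; all draws across the three generators are
#'   derived from it (matched cohort uses `seed`, validation cohort
#'   `seed + 1`, gene universe `seed + 2`).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_pairs = 10,
                              n_validation = 275,
                              n_probes = 10000,
                              n_separated_hyper = 20,
                              n_separated_hypo = 20,
                              n_prognostic = 4,
                              separation_gap = 0.1,
                              patient_effect_sd = 0.5,
                              noise_sd = 0.3,
                              baseline_hazard = 3e-4,
                              planted_log_hr = 1.5,
                              planted_cutpoints = c(0.74, 0.14, 0.29, 0.321),
                              censor_time_max = 1500,
                              n_genes = 500,
                              n_gene_sets = 50,
                              genes_per_set = c(5L, 25L),
                              seed = 1L) {
  cfg <- as.list(environment())
  if (length(planted_cutpoints) < n_prognostic) {
    stop("need one planted cutpoint per prognostic probe", call. = FALSE)
  }
  cfg$planted_cutpoints <- planted_cutpoints[seq_len(n_prognostic)]
  cfg$planted_log_hr <- rep_len(planted_log_hr, n_prognostic)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_pairs >= 2, n_validation >= 2, n_probes >= 1,
      n_separated_hyper >= 0, n_separated_hypo >= 0,
      n_separated_hyper + n_separated_hypo <= n_probes,
      n_prognostic >= 0,
      n_prognostic <= n_separated_hyper + n_separated_hypo,
      separation_gap > 0, separation_gap < 1,
      patient_effect_sd >= 0, noise_sd >= 0,
      baseline_hazard > 0, censor_time_max > 0,
      length(planted_cutpoints) == n_prognostic,
      all(planted_cutpoints > 0 & planted_cutpoints < 1)
    )
  })
  # each cutpoint needs room for a tumor interval around it plus the gap
  # plus a normal interval on one side
  for (cut in cfg$planted_cutpoints) {
    w <- 0.1
    room_below <- cut - w - cfg$separation_gap
    room_above <- 1 - (cut + w) - cfg$separation_gap
    if (cut - w <= 0 || cut + w >= 1 || max(room_below, room_above) < 0.02) {
      stop(sprintf(
        "infeasible planted cutpoint %.3g: no room for disjoint intervals with gap %.3g",
        cut, cfg$separation_gap), call. = FALSE)
    }
  }
  invisible(cfg)
}

# truncated Beta draw for per-probe baseline means: keeps means away from
# the boundaries so logit shifts stay well-behaved
draw_probe_means <- function(n, lo = 0.02, hi = 0.98, shape = 0.85) {
  u <- runif(n, pbeta(lo, shape, shape), pbeta(hi, shape, shape))
  qbeta(u, shape, shape)
}

# interval layout for one planted probe; prognostic probes centre the tumor
# interval on their cutpoint, others get a random location
plan_planted_probe <- function(cfg, cutpoint = NA_real_,
                               direction = NA_character_) {
  gap <- cfg$separation_gap
  if (!is.na(cutpoint)) {
    w <- 0.1
    tumor <- c(cutpoint - w, cutpoint + w)
    room_below <- tumor[1] - gap
    room_above <- 1 - tumor[2] - gap
    if (room_below >= room_above) {       # normal below tumor => hyper
      wn <- min(0.15, 0.8 * room_below)
      normal <- c(tumor[1] - gap - wn, tumor[1] - gap)
      direction <- "hyper"
    } else {
      wn <- min(0.15, 0.8 * room_above)
      normal <- c(tumor[2] + gap, tumor[2] + gap + wn)
      direction <- "hypo"
    }
  } else {
    wn <- 0.12; wt <- 0.12
    lo <- runif(1, 0.02, 1 - wn - gap - wt - 0.02)
    if (direction == "hyper") {
      normal <- c(lo, lo + wn)
      tumor <- c(lo + wn + gap, lo + wn + gap + wt)
    } else {
      tumor <- c(lo, lo + wt)
      normal <- c(lo + wt + gap, lo + wt + gap + wn)
    }
  }
  list(direction = direction, normal = normal, tumor = tumor)
}

#' Simulate a matched tumor/normal discovery cohort
#'
#' @param config a [simulation_config()].
#' @return list with `pairs` (a `matched_pair_set`) and `truth` (a
#'   `synthetic_truth` tibble: per planted probe its direction, value
#'   intervals, prognostic status, cutpoint and log hazard ratio; per-probe
#'   baseline parameters are carried as attributes for the companion
#'   generators).
#' @export
simulate_matched_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_pairs
  P <- config$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(P))
  patient_ids <- sprintf("SIM-P%04d", seq_len(n))

  mu <- draw_probe_means(P)
  u <- rnorm(n, 0, config$patient_effect_sd)
  lp <- qlogis(mu)
  draw_tissue <- function() {
    plogis(outer(lp, u, `+`) + rnorm(P * n, 0, config$noise_sd))
  }
  normal <- draw_tissue()
  tumor <- draw_tissue()

  n_planted <- config$n_separated_hyper + config$n_separated_hypo
  planted_idx <- if (n_planted > 0) sort(sample.int(P, n_planted)) else integer(0)

  plans <- vector("list", n_planted)
  k <- config$n_prognostic
  if (k > 0) {
    for (i in seq_len(k)) {
      plans[[i]] <- plan_planted_probe(config, cutpoint =
                                         config$planted_cutpoints[i])
    }
  }
  remaining <- n_planted - k
  n_hyper_left <- config$n_separated_hyper -
    sum(vapply(plans[seq_len(k)], function(p) {
      identical(p$direction, "hyper")
    }, logical(1)))
  n_hyper_left <- min(max(0L, n_hyper_left), remaining)
  dirs_left <- c(rep("hyper", n_hyper_left),
                 rep("hypo", remaining - n_hyper_left))
  for (i in seq_along(dirs_left)) {
    plans[[k + i]] <- plan_planted_probe(config, direction = dirs_left[i])
  }

  for (j in seq_along(planted_idx)) {
    pl <- plans[[j]]
    idx <- planted_idx[j]
    normal[idx, ] <- runif(n, pl$normal[1], pl$normal[2])
    tumor[idx, ] <- runif(n, pl$tumor[1], pl$tumor[2])
  }
  dimnames(normal) <- dimnames(tumor) <- list(probe_ids, patient_ids)

  pairs <- structure(list(
    patient_ids = patient_ids,
    probe_ids = probe_ids,
    normal = normal,
    tumor = tumor,
    pairing = tibble::tibble(
      patient_id = patient_ids,
      normal_sample = paste0(patient_ids, "-N"),
      tumor_sample = paste0(patient_ids, "-T"))
  ), class = "matched_pair_set")

  truth <- tibble::tibble(
    probe_id = probe_ids[planted_idx],
    direction = vapply(plans, `[[`, character(1), "direction"),
    normal_lo = vapply(plans, function(p) p$normal[1], numeric(1)),
    normal_hi = vapply(plans, function(p) p$normal[2], numeric(1)),
    tumor_lo = vapply(plans, function(p) p$tumor[1], numeric(1)),
    tumor_hi = vapply(plans, function(p) p$tumor[2], numeric(1)),
    is_prognostic = seq_len(n_planted) <= k,
    cutpoint = c(config$planted_cutpoints, rep(NA_real_, n_planted - k)),
    log_hr = c(config$planted_log_hr, rep(NA_real_, n_planted - k))
  )
  attr(truth, "seed") <- config$seed
  attr(truth, "config") <- config
  attr(truth, "probe_mu") <- setNames(mu, probe_ids)
  class(truth) <- c("synthetic_truth", class(truth))

  assert_planted_separation(pairs, truth)
  list(pairs = pairs, truth = truth)
}

# post-generation assertion pass: planted separation must hold exactly
assert_planted_separation <- function(pairs, truth) {
  for (i in seq_len(nrow(truth))) {
    p <- truth$probe_id[i]
    tm <- pairs$tumor[p, ]; nm <- pairs$normal[p, ]
    ok <- if (truth$direction[i] == "hyper") min(tm) > max(nm)
          else max(tm) < min(nm)
    if (!ok) stop("planted separation violated for probe ", p, call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate an independent tumor-only validation cohort with survival
#'
#' Per-patient hazard is `baseline_hazard * exp(sum(log_hr * risk))` where
#' `risk` is `beta > cutpoint` for hypermethylated planted markers and
#' `beta < cutpoint` for hypomethylated ones. Event times are exponential
#' given the hazard; censoring is the minimum of the administrative horizon
#' and a uniform draw on (0, 1.5 * `censor_time_max`).
#'
#' @param config the [simulation_config()] used for the matched cohort.
#' @param truth the `truth` component of [simulate_matched_cohort()].
#' @return list with `beta` (a [beta_matrix], probes x patients) and
#'   `clinical` (tibble `patient_id`, `event`, `time`).
#' @export
simulate_validation_cohort <- function(config, truth) {
  validate_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_validation
  mu <- attr(truth, "probe_mu")
  stopifnot(!is.null(mu))
  probe_ids <- names(mu)
  patient_ids <- sprintf("SIM-V%04d", seq_len(n))

  # independent noise per measurement: the shared per-patient shift exists
  # to correlate tissues within a matched pair, which has no counterpart in
  # a tumor-only cohort; leaving it out keeps null probes independent so
  # per-probe screens are calibrated probe-wise
  values <- matrix(plogis(qlogis(mu) + rnorm(length(mu) * n, 0,
                                             config$noise_sd)),
                   nrow = length(mu),
                   dimnames = list(probe_ids, patient_ids))
  for (i in seq_len(nrow(truth))) {
    values[truth$probe_id[i], ] <- runif(n, truth$tumor_lo[i],
                                         truth$tumor_hi[i])
  }

  log_hr_sum <- rep(0, n)
  prog <- truth[truth$is_prognostic, ]
  for (i in seq_len(nrow(prog))) {
    beta <- values[prog$probe_id[i], ]
    risk <- if (prog$direction[i] == "hyper") beta > prog$cutpoint[i]
            else beta < prog$cutpoint[i]
    log_hr_sum <- log_hr_sum + prog$log_hr[i] * risk
  }
  hazard <- config$baseline_hazard * exp(log_hr_sum)
  t_event <- rexp(n, hazard)
  t_censor <- pmin(config$censor_time_max,
                   runif(n, 0, 1.5 * config$censor_time_max))
  list(
    beta = beta_matrix(values),
    clinical = tibble::tibble(
      patient_id = patient_ids,
      event = as.integer(t_event <= t_censor),
      time = pmin(t_event, t_censor)
    )
  )
}

#' Simulate a probe annotation and gene-set universe
#'
#' Each probe receives 0-2 gene symbols; prognostic planted probes get
#' dedicated genes, with the last two probes sharing one gene (with the
#' default four prognostic probes the funnel therefore ends at three genes
#' and four probes, the many-probes-per-gene situation real annotations
#' produce). One "enriched"
#' set is seeded with the prognostic genes (padded with random genes), the
#' remaining sets are random draws from the universe, so hypergeometric
#' over-representation of the prognostic genes is detectable by
#' construction.
#'
#' @inheritParams simulate_validation_cohort
#' @return list with `annotation` (tibble as [read_probe_annotation()]) and
#'   `sets` (tibble as [read_gene_sets()]); the planted enriched term is
#'   `"SIM:ENRICHED"`.
#' @export
simulate_gene_universe <- function(config, truth) {
  validate_config(config)
  set.seed(config$seed + 2L)
  mu <- attr(truth, "probe_mu")
  probe_ids <- names(mu)
  P <- length(probe_ids)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))

  n_genes_per_probe <- sample(0:2, P, replace = TRUE,
                              prob = c(0.2, 0.6, 0.2))
  gene_col <- vapply(n_genes_per_probe, function(k) {
    if (k == 0) NA_character_
    else paste(sample(genes, k), collapse = ";")
  }, character(1))

  prog <- truth$probe_id[truth$is_prognostic]
  prog_genes <- genes[pmin(seq_along(prog), max(length(prog) - 1L, 1L))]
  gene_col[match(prog, probe_ids)] <- prog_genes
  prog_genes <- unique(prog_genes)

  annotation <- tibble::tibble(
    probe_id = probe_ids,
    gene = gene_col,
    chromosome = paste0("chr", sample(1:22, P, replace = TRUE)),
    position = sample.int(100000000L, P, replace = TRUE)
  )

  set_sizes <- sample(config$genes_per_set[1]:config$genes_per_set[2],
                      config$n_gene_sets, replace = TRUE)
  sets <- tibble::tibble(
    term_id = sprintf("SIM:%04d", seq_len(config$n_gene_sets)),
    term_name = sprintf("simulated process %d", seq_len(config$n_gene_sets)),
    genes = lapply(set_sizes, function(k) sample(genes, k))
  )
  pad <- sample(setdiff(genes, prog_genes),
                max(0, 10 - length(prog_genes)))
  enriched <- tibble::tibble(term_id = "SIM:ENRICHED",
                             term_name = "planted prognostic process",
                             genes = list(c(prog_genes, pad)))
  list(annotation = annotation, sets = dplyr::bind_rows(enriched, sets))
}

#' Read / write the planted-marker truth ledger
#'
#' The ledger is written as TSV next to the simulated cohort so recovery
#' tests never re-derive ground truth.
#'
#' @param truth a `synthetic_truth` tibble.
#' @param path TSV file path.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(tibble::as_tibble(truth), path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccddddldd")
}
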