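#' Kaplan-Meier product-limit curve
#'
#' Thin tidy wrapper around [survival::survfit()]: the survival probability
#' steps only at event times and censored subjects leave the risk set after
#' their time.
#'
#' @param time positive follow-up times (days).
#' @param event binary event indicator (1 = death).
#' @param group optional label attached to every row.
#' @return tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `group`.
#' @export
km_curve <- function(time, event, group = NA_character_) {
  stopifnot(length(time) >= 1, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv,
    group = group
  )
}

# Vectorized two-group log-rank engine.
#
# z is an n x K 0/1 matrix assigning each patient to the "high" group under
# K different splits. Returns chi-square statistics (1 df) for all splits
# at once: observed-minus-expected deaths in the high group summed over
# distinct event times, with the hypergeometric variance.
logrank_engine <- function(time, event, z) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0) {
    return(list(chi2 = rep(0, ncol(z)), no_events = TRUE))
  }
  at_risk <- outer(ev_times, time, `<=`)             # J x n
  deaths <- outer(ev_times, time, `==`) *
    matrix(event, nrow = length(ev_times), ncol = length(time),
           byrow = TRUE)
  nj <- rowSums(at_risk)
  dj <- rowSums(deaths)
  n1 <- at_risk %*% z                                # J x K at risk, high
  d1 <- deaths %*% z
  expd <- dj * n1 / nj
  denom <- ifelse(nj > 1, nj - 1, 1)
  vr <- dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / denom
  oe <- colSums(d1 - expd)
  v <- colSums(vr)
  chi2 <- ifelse(v > 0, oe^2 / v, 0)
  list(chi2 = as.vector(chi2), no_events = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: for group A, observed minus expected deaths
#' summed over distinct event times, variance by the hypergeometric
#' formula, chi-square with 1 degree of freedom, two-sided p. With zero
#' total events the statistic is 0 and p = 1 with a flag.
#'
#' @param time_a,event_a,time_b,event_b follow-up times and event
#'   indicators for the two groups (both non-empty).
#' @return list with `chi2`, `p`, `flag`.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) >= 1, length(time_b) >= 1)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  z <- matrix(rep(c(1, 0), c(length(time_a), length(time_b))), ncol = 1)
  eng <- logrank_engine(time, event, z)
  chi2 <- eng$chi2[1]
  list(chi2 = chi2,
       p = pchisq(chi2, df = 1, lower.tail = FALSE),
       flag = if (eng$no_events) "no_events" else NA_character_)
}

#' Constrained minimal-p-value survival cutpoint scan
#'
#' Finds the beta-value threshold that best separates a probe's patients
#' into two survival groups. Candidate thresholds are the midpoints of
#' consecutive distinct sorted beta values (so the scan is exhaustive over
#' distinct patient partitions). Candidates producing a group smaller than
#' `max(min_group_abs, ceiling(min_group_frac * n))` are inadmissible —
#' this is the concrete form of "avoiding extreme sample sizes". Among
#' admissible candidates the threshold with the smallest log-rank p is
#' selected; exact ties go to the smallest threshold. The reported p is the
#' raw minimal log-rank p; see [permutation_adjusted_p()] for a
#' selection-corrected version.
#'
#' @param beta named numeric vector of one probe's beta values (names =
#'   patient ids) or a [beta_matrix] together with `probe`.
#' @param clinical tibble `patient_id`, `event`, `time`.
#' @param probe probe id when `beta` is a matrix.
#' @param min_group_frac minimum group size as a fraction of analyzed
#'   patients (default 0.01).
#' @param min_group_abs minimum absolute group size (default 2).
#' @return a `threshold_result`: list with `probe_id`, `threshold`,
#'   `direction` (`"high_is_hyper"`: patients above the threshold form the
#'   hypermethylated group), `n_low`, `n_high`, `deaths_low`,
#'   `deaths_high`, `logrank_chi2`, `logrank_p`, `n_excluded` (patients
#'   dropped for missing beta), `trace` (tibble of every candidate
#'   threshold with group sizes, chi-square, p and admissibility), and
#'   `constraints`.
#' @export
threshold_scan <- function(beta, clinical, probe = NULL,
                           min_group_frac = 0.01, min_group_abs = 2) {
  if (inherits(beta, "beta_matrix")) {
    stopifnot(!is.null(probe), probe %in% rownames(beta))
    beta <- unclass(beta)[probe, ]
  } else if (is.null(probe)) {
    probe <- NA_character_
  }
  clinical <- validate_clinical(clinical)
  stopifnot(!is.null(names(beta)))
  common <- intersect(names(beta), clinical$patient_id)
  beta <- beta[common]
  n_missing <- sum(is.na(beta))
  if (n_missing > 0) {
    message(n_missing, " patient(s) excluded for missing beta value")
  }
  beta <- beta[!is.na(beta)]
  cl <- clinical[match(names(beta), clinical$patient_id), ]
  n <- length(beta)
  min_size <- max(min_group_abs, ceiling(min_group_frac * n))
  if (n < 2 * max(min_group_abs, 1)) {
    stop("too few patients with observed beta values (", n, ")",
         call. = FALSE)
  }
  vals <- sort(unique(beta))
  if (length(vals) < 2) {
    stop("no candidate thresholds: all beta values identical",
         call. = FALSE)
  }
  cand <- (vals[-length(vals)] + vals[-1]) / 2
  z <- outer(beta, cand, `>`)                       # n x K high-group flags
  n_high <- colSums(z)
  n_low <- n - n_high
  admissible <- pmin(n_high, n_low) >= min_size
  eng <- logrank_engine(cl$time, cl$event, z)
  p <- pchisq(eng$chi2, df = 1, lower.tail = FALSE)
  trace <- tibble::tibble(
    threshold = cand,
    n_low = as.integer(n_low),
    n_high = as.integer(n_high),
    chi2 = eng$chi2,
    p = p,
    admissible = admissible
  )
  if (!any(admissible)) {
    stop(sprintf(
      "no admissible threshold: every split leaves a group below %d (= max(min_group_abs %d, ceil(min_group_frac %.3g * n %d)))",
      min_size, min_group_abs, min_group_frac, n), call. = FALSE)
  }
  adm <- trace[trace$admissible, ]
  best <- adm[order(adm$p, adm$threshold), ][1, ]
  high <- beta > best$threshold
  structure(list(
    probe_id = probe,
    threshold = best$threshold,
    direction = "high_is_hyper",
    n_low = best$n_low,
    n_high = best$n_high,
    deaths_low = sum(cl$event[!high]),
    deaths_high = sum(cl$event[high]),
    logrank_chi2 = best$chi2,
    logrank_p = best$p,
    n_excluded = n_missing,
    trace = trace,
    constraints = list(min_group_frac = min_group_frac,
                       min_group_abs = min_group_abs,
                       min_size = min_size)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> probe %s: threshold %.4g (log-rank chi2 %.3g, p %.3g)\n  hypo n=%d (%d deaths) | hyper n=%d (%d deaths)\n",
    x$probe_id, x$threshold, x$logrank_chi2, x$logrank_p,
    x$n_low, x$deaths_low, x$n_high, x$deaths_high))
  invisible(x)
}

#' Permutation-adjusted p-value for a cutpoint scan
#'
#' The minimal-p cutpoint search is optimistic: its reported p-value does
#' not account for having scanned many thresholds. This permutation test
#' re-runs the full constrained scan on data with survival decoupled from
#' methylation (by permuting the beta assignment) and reports
#' `(1 + #{permutation min-p <= observed min-p}) / (n_permutations + 1)`.
#' Off by default in the pipeline, where the raw minimal p is the contract.
#'
#' @inheritParams threshold_scan
#' @param scan_result the observed [threshold_scan()] result.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return adjusted p-value (numeric scalar).
#' @export
permutation_adjusted_p <- function(beta, clinical, scan_result,
                                   n_permutations = 999, seed = 1L,
                                   probe = NULL) {
  stopifnot(n_permutations >= 1)
  if (inherits(beta, "beta_matrix")) {
    stopifnot(!is.null(probe), probe %in% rownames(beta))
    beta <- unclass(beta)[probe, ]
  }
  clinical <- validate_clinical(clinical)
  common <- intersect(names(beta), clinical$patient_id)
  beta <- beta[common]
  beta <- beta[!is.na(beta)]
  cl <- clinical[match(names(beta), clinical$patient_id), ]
  cons <- scan_result$constraints
  obs <- scan_result$logrank_p
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- setNames(sample(beta), names(beta))
    res <- threshold_scan(perm, cl,
                          min_group_frac = cons$min_group_frac,
                          min_group_abs = cons$min_group_abs)
    if (res$logrank_p <= obs) count <- count + 1L
  }
  (1 + count) / (n_permutations + 1)
}

#' Kaplan-Meier curves for the two threshold groups
#'
#' @inheritParams threshold_scan
#' @param result a [threshold_scan()] result for the same probe.
#' @return tibble of two stacked [km_curve()] tables labeled `"hypo"`
#'   (beta at or below the threshold) and `"hyper"` (above), with
#'   attribute `group_sizes`.
#' @export
km_plot_table <- function(result, clinical, beta, probe = NULL) {
  stopifnot(inherits(result, "threshold_result"))
  if (inherits(beta, "beta_matrix")) {
    if (is.null(probe)) probe <- result$probe_id
    beta <- unclass(beta)[probe, ]
  }
  clinical <- validate_clinical(clinical)
  common <- intersect(names(beta), clinical$patient_id)
  beta <- beta[common]
  beta <- beta[!is.na(beta)]
  cl <- clinical[match(names(beta), clinical$patient_id), ]
  high <- beta > result$threshold
  out <- dplyr::bind_rows(
    km_curve(cl$time[!high], cl$event[!high], group = "hypo"),
    km_curve(cl$time[high], cl$event[high], group = "hyper")
  )
  attr(out, "group_sizes") <- c(hypo = sum(!high), hyper = sum(high))
  out
}

#' Scan several probes and collect tidy results
#'
#' @param beta a [beta_matrix].
#' @param clinical clinical tibble.
#' @param probes probe ids to scan.
#' @inheritParams threshold_scan
#' @return list with `summary` (one [glance()] row per probe) and
#'   `results` (named list of `threshold_result` objects).
#' @export
threshold_screen <- function(beta, clinical, probes,
                             min_group_frac = 0.01, min_group_abs = 2) {
  results <- lapply(probes, function(p) {
    threshold_scan(beta, clinical, probe = p,
                   min_group_frac = min_group_frac,
                   min_group_abs = min_group_abs)
  })
  names(results) <- probes
  list(summary = dplyr::bind_rows(lapply(results, glance)),
       results = results)
}

#' @export
#' @method tidy threshold_result
tidy.threshold_result <- function(x, ...) x$trace

#' @export
#' @method glance threshold_result
glance.threshold_result <- function(x, ...) {
  tibble::tibble(
    probe_id = x$probe_id,
    threshold = x$threshold,
    n_low = x$n_low, n_high = x$n_high,
    deaths_low = x$deaths_low, deaths_high = x$deaths_high,
    logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p,
    n_excluded = x$n_excluded
  )
}
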