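#' Per-probe paired t-test on matched tumor/normal pairs
#'
#' For each probe, pairs with a missing value on either side are dropped
#' (per-probe complete-case), the tumor-minus-normal differences `d` are
#' tested with `t = mean(d) / (sd(d)/sqrt(n))` on `n - 1` degrees of
#' freedom, and a two-sided p-value is reported. Degenerate probes are
#' flagged: `sd(d) = 0` with a nonzero mean gives an infinite t (p reported
#' as 0, flag `"degenerate_infinite_t"`); identical tumor and normal values
#' give p = 1 (flag `"degenerate_zero_diff"`); fewer than 2 complete pairs
#' gives `NA` (flag `"insufficient_pairs"`).
#'
#' @param pairs a `matched_pair_set` (see [build_matched_pairs()]).
#' @return tibble with one row per probe: `probe_id`, `n_pairs`,
#'   `mean_difference` (tumor - normal, beta units), `t_statistic`,
#'   `p_value`, `flag`.
#' @export
paired_t_table <- function(pairs) {
  stopifnot(inherits(pairs, "matched_pair_set"))
  d <- pairs$tumor - pairs$normal
  ok <- !is.na(d)
  n <- rowSums(ok)
  d0 <- ifelse(ok, d, 0)
  m <- rowSums(d0) / n
  ss <- rowSums(d0^2) - n * m^2
  s <- sqrt(pmax(ss, 0) / (n - 1))
  t_stat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)

  flag <- rep(NA_character_, nrow(d))
  zero_sd <- !is.na(s) & s == 0 & n >= 2
  flag[zero_sd & m != 0] <- "degenerate_infinite_t"
  flag[zero_sd & m == 0] <- "degenerate_zero_diff"
  p[zero_sd & m != 0] <- 0
  t_stat[zero_sd & m != 0] <- Inf * sign(m[zero_sd & m != 0])
  p[zero_sd & m == 0] <- 1
  t_stat[zero_sd & m == 0] <- 0
  low_n <- n < 2
  flag[low_n] <- "insufficient_pairs"
  p[low_n] <- NA_real_
  t_stat[low_n] <- NA_real_

  tibble::tibble(
    probe_id = pairs$probe_ids,
    n_pairs = as.integer(unname(n)),
    mean_difference = unname(m),
    t_statistic = unname(t_stat),
    p_value = unname(p),
    flag = unname(flag)
  )
}

#' @param probe a single probe id.
#' @rdname paired_t_table
#' @return [paired_t_test()] returns a one-row list for one probe:
#'   `t_statistic`, `p_value`, `mean_difference`, `n`.
#' @export
paired_t_test <- function(pairs, probe) {
  stopifnot(probe %in% pairs$probe_ids)
  sub <- pairs
  keep <- match(probe, pairs$probe_ids)
  sub$probe_ids <- probe
  sub$normal <- pairs$normal[keep, , drop = FALSE]
  sub$tumor <- pairs$tumor[keep, , drop = FALSE]
  row <- paired_t_table(sub)
  list(t_statistic = row$t_statistic, p_value = row$p_value,
       mean_difference = row$mean_difference, n = row$n_pairs,
       flag = row$flag)
}

#' Benjamini-Hochberg (or Bonferroni) multiplicity adjustment
#'
#' Step-up FDR control: with ordered p-values `p(1) <= ... <= p(m)`, reject
#' the `k` smallest where `k = max{i : p(i) <= i*q/m}`. Adjusted q-values
#' are the standard monotone-enforced values; the rejection flags are
#' exactly `q_value <= q`.
#'
#' @param p_values numeric vector of p-values in \[0,1\] (`NA` allowed;
#'   propagated, never rejected).
#' @param q target false-discovery-rate level in (0,1).
#' @param method `"bh"` (default) or `"bonferroni"` for a family-wise
#'   sensitivity analysis.
#' @return tibble with `q_value` and `reject`, aligned with `p_values`.
#' @export
bh_adjust <- function(p_values, q = 0.01, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0) {
    return(tibble::tibble(q_value = numeric(0), reject = logical(0)))
  }
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)),
            q > 0, q < 1)
  qv <- p.adjust(p_values, method = if (method == "bh") "BH" else
    "bonferroni")
  tibble::tibble(q_value = qv, reject = !is.na(qv) & qv <= q)
}

#' Complete-separation effect-size filter
#'
#' A probe is called *hyper*methylated when the smallest tumor value
#' strictly exceeds the largest normal value across all patients, and
#' *hypo*methylated in the mirrored case; any overlap (including exact
#' ties) yields `"none"`. This is the strictest reading of "no overlapping
#' methylation levels across all patients": the two groups' value ranges
#' must be disjoint, not merely consistently signed per pair.
#'
#' @inheritParams paired_t_table
#' @return tibble with `probe_id`, `direction`
#'   (`"hyper"`/`"hypo"`/`"none"`), `flag` (`"insufficient_pairs"` when
#'   fewer than 2 complete pairs).
#' @export
separation_filter <- function(pairs) {
  stopifnot(inherits(pairs, "matched_pair_set"))
  both <- !is.na(pairs$tumor) & !is.na(pairs$normal)
  n <- rowSums(both)
  tmin <- suppressWarnings(apply(ifelse(both, pairs$tumor, NA), 1, min,
                                 na.rm = TRUE))
  tmax <- suppressWarnings(apply(ifelse(both, pairs$tumor, NA), 1, max,
                                 na.rm = TRUE))
  nmin <- suppressWarnings(apply(ifelse(both, pairs$normal, NA), 1, min,
                                 na.rm = TRUE))
  nmax <- suppressWarnings(apply(ifelse(both, pairs$normal, NA), 1, max,
                                 na.rm = TRUE))
  direction <- rep("none", length(n))
  direction[tmin > nmax] <- "hyper"
  direction[tmax < nmin] <- "hypo"
  direction[n < 2] <- "none"
  tibble::tibble(
    probe_id = pairs$probe_ids,
    direction = direction,
    flag = ifelse(n < 2, "insufficient_pairs", NA_character_)
  )
}

#' Discovery step: paired testing, FDR control and separation filtering
#'
#' Runs [paired_t_table()], [bh_adjust()] and (optionally)
#' [separation_filter()] over all probes and combines them into one
#' discovery record per probe. A probe is a *candidate* when it is
#' BH-rejected at `q` and its tumor/normal value ranges are completely
#' separated (direction not `"none"`).
#'
#' @inheritParams paired_t_table
#' @param q FDR level for candidate selection (default 0.01).
#' @param correction `"bh"` or `"bonferroni"`.
#' @param separation apply the complete-separation filter (default TRUE;
#'   when FALSE every tested probe gets direction from the sign of its mean
#'   difference and only the FDR gate applies).
#' @return a `methmark_discovery` tibble: `probe_id`, `n_pairs`,
#'   `mean_difference`, `t_statistic`, `p_value`, `q_value`, `direction`,
#'   `is_candidate`, `flag`.
#' @export
discover <- function(pairs, q = 0.01, correction = c("bh", "bonferroni"),
                     separation = TRUE) {
  correction <- match.arg(correction)
  tt <- paired_t_table(pairs)
  adj <- bh_adjust(tt$p_value, q = q, method = correction)
  if (separation) {
    sep <- separation_filter(pairs)
    direction <- sep$direction
  } else {
    direction <- ifelse(tt$mean_difference > 0, "hyper",
                        ifelse(tt$mean_difference < 0, "hypo", "none"))
    direction[is.na(tt$p_value)] <- "none"
  }
  out <- dplyr::mutate(
    tt,
    q_value = adj$q_value,
    direction = direction,
    is_candidate = adj$reject & direction != "none",
    .before = "flag"
  )
  class(out) <- c("methmark_discovery", class(out))
  out
}

#' Select candidate biomarkers from discovery records
#'
#' @param records a discovery tibble from [discover()].
#' @param q_threshold FDR level; rows must carry `q_value <= q_threshold`
#'   and a non-`"none"` direction.
#' @return the candidate rows, sorted by p-value ascending with ties broken
#'   by probe id.
#' @export
select_candidates <- function(records, q_threshold = 0.01) {
  records |>
    dplyr::filter(!is.na(.data$q_value),
                  .data$q_value <= q_threshold,
                  .data$direction != "none") |>
    dplyr::arrange(.data$p_value, .data$probe_id)
}

#' Manhattan-plot table
#'
#' Joins discovery records with genomic coordinates and emits a plot-ready
#' table of -log10 p-values. Probes absent from the annotation are dropped
#' and counted (attribute `n_dropped`); p-values of 0 (degenerate
#' infinite-t records) are shown at `cap`.
#'
#' @param records discovery tibble from [discover()].
#' @param annotation probe annotation tibble (see
#'   [read_probe_annotation()]).
#' @param cap maximum displayed -log10 p (default 50).
#' @return tibble `probe_id`, `chromosome`, `position`, `neg_log10_p`,
#'   `candidate`, with attribute `n_dropped`.
#' @export
manhattan_table <- function(records, annotation, cap = 50) {
  joined <- dplyr::inner_join(
    records[, c("probe_id", "p_value", "is_candidate")],
    annotation[, c("probe_id", "chromosome", "position")],
    by = "probe_id")
  out <- joined |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(
      neg_log10_p = pmin(-log10(pmax(.data$p_value,
                                     .Machine$double.xmin)), cap)) |>
    dplyr::transmute(.data$probe_id, .data$chromosome, .data$position,
                     .data$neg_log10_p, candidate = .data$is_candidate)
  n_dropped <- nrow(records) - nrow(out)
  if (n_dropped > 0) {
    message(n_dropped,
            " probe(s) dropped from Manhattan table (unannotated or untested)")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
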