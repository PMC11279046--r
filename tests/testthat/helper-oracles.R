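# Independent brute-force oracles. Each re-derives a quantity from its
# textbook definition, deliberately sharing no code with the package.

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# reject the k smallest p where k = max{i : p(i) <= i*q/m}
bh_stepup_bruteforce <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i * q / m) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# hypergeometric upper tail P(X >= ov) by summing the pmf with choose()
hyper_tail_bruteforce <- function(ov, set_size, universe, query) {
  if (ov <= 0) return(1)
  xs <- ov:min(set_size, query)
  if (length(xs) == 0 || ov > min(set_size, query)) return(0)
  sum(choose(set_size, xs) * choose(universe - set_size, query - xs)) /
    choose(universe, query)
}

# textbook two-group log-rank: loop over distinct event times
logrank_textbook <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o - e)^2 / v else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# hand product-limit estimator: loop over distinct observed times
km_hand <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# tiny valid beta matrix with seeded random values
random_beta_matrix <- function(n_probes = 6, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.01, 0.99), n_probes,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  beta_matrix(m)
}

# minimal matched pair set built directly from two matrices
make_pairs <- function(normal, tumor) {
  patients <- colnames(normal)
  structure(list(
    patient_ids = patients,
    probe_ids = rownames(normal),
    normal = normal,
    tumor = tumor,
    pairing = tibble::tibble(patient_id = patients,
                             normal_sample = paste0(patients, "-N"),
                             tumor_sample = paste0(patients, "-T"))
  ), class = "matched_pair_set")
}
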