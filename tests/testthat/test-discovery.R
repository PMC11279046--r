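test_that("paired t-test matches the closed form for df = 2", {
  # d = (0.1, 0.2, 0.3): t = 3.4641, and for df 2 the t CDF has the closed
  # form F(t) = 1/2 + t / (2 * sqrt(2 + t^2))
  normal <- matrix(c(0.2, 0.2, 0.2), 1,
                   dimnames = list("cgX", paste0("P", 1:3)))
  tumor <- normal + c(0.1, 0.2, 0.3)
  res <- paired_t_test(make_pairs(normal, tumor), "cgX")
  t_expect <- 0.2 / (0.1 / sqrt(3))
  p_expect <- 2 * (1 - (0.5 + t_expect / (2 * sqrt(2 + t_expect^2))))
  expect_equal(res$t_statistic, t_expect, tolerance = 1e-10)
  expect_equal(res$p_value, p_expect, tolerance = 1e-10)
  expect_equal(res$mean_difference, 0.2)
  expect_equal(res$n, 3L)
})

test_that("degenerate difference vectors are flagged, not propagated as NaN", {
  normal <- matrix(c(0.2, 0.3, 0.4, 0.5), 2,
                   dimnames = list(c("same", "shift"), c("P1", "P2")))
  tumor <- normal
  tumor["shift", ] <- tumor["shift", ] + 0.1      # constant nonzero diff
  tt <- paired_t_table(make_pairs(normal, tumor))
  expect_equal(tt$p_value[tt$probe_id == "same"], 1)
  expect_equal(tt$flag[tt$probe_id == "same"], "degenerate_zero_diff")
  expect_equal(tt$p_value[tt$probe_id == "shift"], 0)
  expect_equal(tt$flag[tt$probe_id == "shift"], "degenerate_infinite_t")
})

test_that("pairs with missing values are dropped per probe", {
  set.seed(1)
  normal <- matrix(runif(8, 0.2, 0.4), 2,
                   dimnames = list(c("cgA", "cgB"), paste0("P", 1:4)))
  tumor <- matrix(runif(8, 0.5, 0.7), 2, dimnames = dimnames(normal))
  tumor["cgA", "P2"] <- NA
  tt <- paired_t_table(make_pairs(normal, tumor))
  expect_equal(tt$n_pairs, c(3L, 4L))
  # cgA must equal a 3-pair test with P2 removed
  ref <- t.test(tumor["cgA", -2], normal["cgA", -2], paired = TRUE)
  expect_equal(tt$p_value[1], ref$p.value, tolerance = 1e-12)
})

test_that("paired t p-values match stats::t.test across random probes", {
  set.seed(42)
  n <- 8
  normal <- matrix(runif(20 * n, 0.1, 0.9), 20,
                   dimnames = list(sprintf("cg%02d", 1:20),
                                   paste0("P", 1:n)))
  tumor <- matrix(runif(20 * n, 0.1, 0.9), 20, dimnames = dimnames(normal))
  tt <- paired_t_table(make_pairs(normal, tumor))
  for (i in 1:20) {
    ref <- t.test(tumor[i, ], normal[i, ], paired = TRUE)
    expect_equal(tt$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(tt$t_statistic[i], unname(ref$statistic),
                 tolerance = 1e-12)
  }
})

test_that("bh_adjust equals the brute-force step-up rule", {
  # the worked example: only the smallest p survives at q = 0.01
  adj <- bh_adjust(c(0.001, 0.008, 0.039, 0.041), q = 0.01)
  expect_equal(adj$reject, c(TRUE, FALSE, FALSE, FALSE))

  expect_equal(nrow(bh_adjust(numeric(0))), 0)
  expect_false(any(bh_adjust(rep(1, 5), q = 0.01)$reject))

  set.seed(7)
  for (i in 1:300) {
    m <- sample(1:50, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    got <- bh_adjust(p, q = q)
    expect_identical(got$reject, bh_stepup_bruteforce(p, q))
  }
})

test_that("separation filter classifies disjoint ranges and rejects overlap/ties", {
  normal <- rbind(hyper = c(0.10, 0.15, 0.12),
                  over = c(0.10, 0.50, 0.30),
                  tie  = c(0.10, 0.20, 0.30))
  colnames(normal) <- paste0("P", 1:3)
  tumor <- rbind(hyper = c(0.30, 0.40, 0.35),
                 over = c(0.40, 0.90, 0.60),
                 tie  = c(0.30, 0.40, 0.50))   # max(normal) == min(tumor)
  colnames(tumor) <- paste0("P", 1:3)
  sep <- separation_filter(make_pairs(normal, tumor))
  expect_equal(sep$direction, c("hyper", "none", "none"))

  # hypo is the mirror image
  sep2 <- separation_filter(make_pairs(tumor, normal))
  expect_equal(sep2$direction[1], "hypo")
})

test_that("separation filter is invariant to patient order and pair relabeling", {
  set.seed(9)
  normal <- matrix(runif(40, 0.1, 0.6), 4,
                   dimnames = list(sprintf("cg%d", 1:4), paste0("P", 1:10)))
  tumor <- matrix(runif(40, 0.3, 0.9), 4, dimnames = dimnames(normal))
  base <- separation_filter(make_pairs(normal, tumor))
  perm <- sample(10)
  shuffled <- separation_filter(make_pairs(normal[, perm], tumor[, perm]))
  expect_equal(base$direction, shuffled$direction)
})

test_that("null separation rate matches a Monte-Carlo exchangeability estimate", {
  # Null probes have exchangeable tumor/normal values, so complete
  # separation is a pure order statistic event. Estimate its probability
  # by brute-force shuffling, then compare with the generator's rate.
  set.seed(31)
  n <- 5                                  # small n so the event is visible
  mc <- mean(replicate(40000, {
    x <- rnorm(2 * n)
    g <- sample(rep(c(TRUE, FALSE), n))
    min(x[g]) > max(x[!g]) || max(x[g]) < min(x[!g])
  }))
  exact <- 2 / choose(2 * n, n)           # closed form under exchangeability
  expect_equal(mc, exact, tolerance = 0.15)

  cfg <- simulation_config(n_pairs = n, n_probes = 20000,
                           n_separated_hyper = 0, n_separated_hypo = 0,
                           n_prognostic = 0,
                           planted_cutpoints = numeric(0), seed = 13)
  sim <- simulate_matched_cohort(cfg)
  rate <- mean(separation_filter(sim$pairs)$direction != "none")
  # patient effects shift both tissues jointly, so the rate cannot exceed
  # the exchangeable bound by more than noise; 3 binomial SD band
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(rate, exact + 3 * se + 1e-6)
})

test_that("discover combines FDR and separation; candidates need both", {
  cfg <- simulation_config(n_pairs = 10, n_probes = 800,
                           n_separated_hyper = 15, n_separated_hypo = 15,
                           n_prognostic = 0, planted_cutpoints = numeric(0),
                           seed = 17)
  sim <- simulate_matched_cohort(cfg)
  disc <- discover(sim$pairs, q = 0.01)
  cand <- select_candidates(disc, 0.01)

  # candidate set algebra: subset of BH rejections and of separated probes
  expect_true(all(cand$q_value <= 0.01))
  expect_true(all(cand$direction != "none"))
  # every planted probe is recovered (separation holds by construction and
  # the effect is far beyond the FDR gate)
  expect_setequal(intersect(cand$probe_id, sim$truth$probe_id),
                  sim$truth$probe_id)
  # direction agrees with the ledger
  got <- cand[match(sim$truth$probe_id, cand$probe_id), ]
  expect_equal(got$direction, sim$truth$direction)
  # candidates sorted by p ascending
  expect_false(is.unsorted(cand$p_value, strictly = FALSE))
})

test_that("manhattan table transforms, caps, and conserves row counts", {
  records <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    p_value = c(0.01, 1e-80, 0, NA),
    is_candidate = c(FALSE, TRUE, TRUE, FALSE))
  ann <- tibble::tibble(probe_id = c("cg1", "cg2", "cg3"),
                        gene = NA_character_,
                        chromosome = "chr1", position = 1:3)
  tab <- suppressMessages(manhattan_table(records, ann, cap = 50))
  expect_equal(tab$neg_log10_p[tab$probe_id == "cg1"], 2)
  expect_equal(tab$neg_log10_p[tab$probe_id == "cg2"], 50)   # capped
  expect_equal(tab$neg_log10_p[tab$probe_id == "cg3"], 50)   # p = 0 flagged
  expect_equal(nrow(tab) + attr(tab, "n_dropped"), nrow(records))
})
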