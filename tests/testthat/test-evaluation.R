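test_that("AUC equals the pairwise-concordance brute force", {
  res <- roc_auc(c(3, 1), c(2, 0))
  expect_equal(res$auc, 0.75)
  expect_equal(res$auc, brute_auc(c(3, 1), c(2, 0)))
  expect_equal(roc_auc(1:5 + 10, 1:5)$auc, 1)

  set.seed(9)
  for (i in 1:10) {
    pos <- round(rnorm(sample(5:200, 1)), 1)  # rounding forces ties
    neg <- round(rnorm(sample(5:200, 1)), 1)
    res <- roc_auc(pos, neg)
    expect_equal(res$auc, brute_auc(pos, neg), tolerance = 1e-12)
    # ROC is a monotone staircase from (0,0) to (1,1)
    expect_true(all(diff(res$roc$fpr) >= 0))
    expect_true(all(diff(res$roc$tpr) >= 0))
    expect_equal(res$roc$fpr[1], 0)
    expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("rank-sum approximation tracks exact enumeration at small n", {
  expect_equal(ranksum(c(1, 1, 1), c(1, 1)), 1)
  expect_lt(ranksum(rnorm(50) + 10, rnorm(50)), 1e-6)
  set.seed(5)
  for (i in 1:5) {
    pos <- rnorm(8); neg <- rnorm(8)
    expect_equal(ranksum(pos, neg), exact_ranksum_p(pos, neg),
                 tolerance = 0.06)
  }
})

test_that("cross-validation: null behaviour, planted signal, reproducibility", {
  imp <- published_model()$importance
  # no signal: mean AUC over a few generator seeds stays near 0.5
  null_auc <- vapply(1:3, function(s) {
    sets <- generate_sets(generator_config(n_imm = 500, n_non = 500,
                                           seed = 100 + s))
    cross_validate(sets$imm, sets$non, sets$masks, imp, reps = 8,
                   seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)

  # strong planted signal: CV AUC matches the simulation oracle of the
  # population-optimal discriminator (~0.805 for |e*| = 1 on 5 residues)
  cfg <- generator_config(n_imm = 1500, n_non = 1500, seed = 201,
                          planted_log_enrichment = c(W = 1, F = 1, I = 1,
                                                     S = -1, K = -1))
  e <- cfg$planted_log_enrichment
  set.seed(77)
  n_sim <- 100000
  opt_i <- colSums(matrix(sample(e, 6 * n_sim, TRUE,
                                 prob = cfg$background * exp(e)), 6))
  opt_n <- colSums(matrix(sample(e, 6 * n_sim, TRUE,
                                 prob = cfg$background), 6))
  r <- rank(c(opt_i, opt_n))
  oracle_auc <- (sum(r[seq_len(n_sim)]) - n_sim * (n_sim + 1) / 2) / n_sim^2
  sets <- generate_sets(cfg)
  cv <- cross_validate(sets$imm, sets$non, sets$masks,
                       importance = c(0, 0, rep(1, 6), 0), reps = 3,
                       seed = 11)
  expect_equal(cv$auc, oracle_auc, tolerance = 0.025)
  expect_gt(cv$auc, 0.75)
  expect_lt(cv$ranksum_p, 1e-10)

  # bit-exact reproducibility given (seed, reps, k)
  cv2 <- cross_validate(sets$imm, sets$non, sets$masks,
                        importance = c(0, 0, rep(1, 6), 0), reps = 3,
                        seed = 11)
  expect_identical(cv$auc, cv2$auc)
  expect_identical(cv$roc, cv2$roc)
  expect_error(cross_validate(make_set(c("AAAAAAAAA", "CCCCCCCCC")),
                              sets$non, sets$masks, imp, k = 3),
               "at least k")
})

test_that("affinity matching equalizes bin histograms and affinities", {
  scheme <- affinity_bin_scheme()
  expect_equal(scheme$edges, c(1, 4.7, 22.4, 106, 500))
  set.seed(61)
  # paper-like affinities: log-uniform between 0.1 and 500 nM
  aff_a <- exp(runif(200, log(0.1), log(500)))
  aff_b <- exp(runif(80, log(0.1), log(500)))
  a <- make_set(generate_sets(generator_config(200, 1, seed = 8))$imm$sequence,
                label = "immunogenic", predicted_affinity_nM = aff_a)
  b <- make_set(generate_sets(generator_config(80, 1, seed = 9))$imm$sequence,
                label = "non_immunogenic", predicted_affinity_nM = aff_b)
  m <- matched_sets(a, b, scheme, seed = 4)
  bins_of <- function(s) table(cut(s$predicted_affinity_nM,
                                   c(-Inf, scheme$edges, Inf)))
  expect_equal(bins_of(m$a), bins_of(m$b))
  expect_gt(m$ranksum_p, 0.05)

  # identical sets are fully retained; min rule per bin
  m_same <- matched_sets(a, a, scheme, seed = 1)
  expect_equal(nrow(m_same$a), nrow(a))
  aa <- make_set(a$sequence[1:13], predicted_affinity_nM = c(rep(0.5, 10),
                                                             rep(2, 3)))
  bb <- make_set(b$sequence[1:6], predicted_affinity_nM = c(rep(0.5, 3),
                                                            rep(2, 3)))
  m2 <- matched_sets(aa, bb, scheme, seed = 2)
  expect_equal(m2$bin_counts[1:2], c(3L, 3L))
  expect_error(matched_sets(make_set("AAAAAAAAA"), bb, scheme), "affinity")

  # NetCTL-style scheme shifts scores before log-scale binning
  ns <- netctl_bin_scheme()
  expect_equal(ns$offset, 1.1625)
  expect_equal(ns$edges, exp(seq(log(1), log(5), length.out = 5)))
})

test_that("triage reports discarded fraction and epitope retention", {
  expect_equal(triage_summary(c(1, 2, 3), rep("immunogenic", 3)),
               list(frac_discarded = 0, frac_epitopes_retained = 1))
  expect_equal(triage_summary(c(-1, -2), c("immunogenic", "non_immunogenic")),
               list(frac_discarded = 1, frac_epitopes_retained = 0))
  res <- triage_summary(c(0.5, -0.1, 0.2, -0.3),
                        c("immunogenic", "immunogenic",
                          "non_immunogenic", "non_immunogenic"))
  expect_equal(res$frac_discarded, 0.5)
  expect_equal(res$frac_epitopes_retained, 0.5)
  expect_true(is.na(triage_summary(c(1, -1),
                                   rep("non_immunogenic", 2))$frac_epitopes_retained))
})

test_that("sign test on paired fractions matches the binomial tail", {
  # 27 of 28 molecules favour one side: p = 2 * 29 / 2^28 < 0.001
  p <- sign_test_fraction_positive(c(rep(0.8, 27), 0.1), rep(0.5, 28))
  expect_equal(p, 2 * 29 / 2^28, tolerance = 1e-12)
  expect_lt(p, 0.001)
  # 14 of 28: symmetric, p = 1
  expect_equal(sign_test_fraction_positive(c(rep(1, 14), rep(0, 14)),
                                           rep(0.5, 28)), 1)
  # a single pair: p = 1
  expect_equal(sign_test_fraction_positive(1, 0), 1)
  expect_error(sign_test_fraction_positive(c(1, 1), c(1, 1)), "ties")
  # ties are dropped before testing
  expect_equal(sign_test_fraction_positive(c(1, 0.5), c(0, 0.5)), 1)
})
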