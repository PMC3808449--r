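test_that("non-anchor counting contributes exactly six residues per 9mer", {
  set <- make_set("AAAAAAAAA")
  cnt <- count_nonanchor_aa(set)
  expect_equal(unclass(cnt)[["A"]], 6)
  expect_equal(attr(cnt, "total"), 6)

  empty <- make_set(character(0))
  expect_equal(attr(count_nonanchor_aa(empty), "total"), 0)

  # allele-specific mask changes which residues are counted
  masks <- anchor_mask(list("HLA-B*08:01" = c(2, 5, 9)))
  set2 <- peptide_set("CADEFGHIW", "HLA-B*08:01")
  cnt2 <- count_nonanchor_aa(set2, masks)
  # positions 2, 5, 9 (A, F, W) are excluded
  expect_equal(unclass(cnt2)[c("A", "F", "W")], c(A = 0, F = 0, W = 0),
               ignore_attr = TRUE)
  expect_equal(attr(cnt2, "total"), 6)

  sets <- generate_sets(generator_config(n_imm = 40, n_non = 15, seed = 3))
  expect_equal(attr(count_nonanchor_aa(sets$imm, sets$masks), "total"),
               6 * nrow(sets$imm))
  expect_error(count_nonanchor_aa(sets$imm, anchor_mask(), fallback = FALSE),
               "fallback")
})

test_that("background frequencies exclude X and are concatenation-invariant", {
  expect_equal(background_frequencies(source_proteins("p", "AC"))[c("A", "C")],
               c(A = 0.5, C = 0.5))
  expect_equal(background_frequencies(source_proteins("p", "AXA"))[["A"]], 1)
  split2 <- source_proteins(c("p1", "p2"), c("ACDEF", "GHIKL"))
  joined <- source_proteins("p", "ACDEFGHIKL")
  expect_equal(background_frequencies(split2), background_frequencies(joined))
  expect_error(background_frequencies(source_proteins("p", "XXX")),
               "countable")
})

test_that("log enrichment follows the pseudocount formula, natural log", {
  # A at 4 vs 2 out of equal totals with zero pseudocount -> ln 2
  base <- stats::setNames(rep(5, 20), amino_acids())
  imm <- base; imm["A"] <- 4
  non <- base; non["A"] <- 2; non["C"] <- 7   # equal totals of 99
  tab <- compute_enrichment(aa_counts(imm), aa_counts(non), pseudocount = 0)
  expect_equal(tab$log_enrichment[tab$aa == "A"], log(2), tolerance = 1e-12)

  # a 2.5% vs 1.5% frequency gives a ~1.7-fold enrichment, log ~0.51-0.54
  rest <- stats::setNames(rep(1, 17), setdiff(amino_acids(),
                                              c("Y", "A", "C")))
  imm2 <- aa_counts(c(c(Y = 25, A = 500, C = 458), rest))
  non2 <- aa_counts(c(c(Y = 15, A = 510, C = 458), rest))
  e <- compute_enrichment(imm2, non2, pseudocount = 0)
  ratio <- with(e[e$aa == "Y", ], freq_imm / freq_non)
  expect_equal(ratio, 5 / 3, tolerance = 1e-12)
  expect_equal(e$log_enrichment[e$aa == "Y"], log(5 / 3), tolerance = 1e-12)

  # identical counts -> all-zero scores; frequencies sum to 1
  same <- compute_enrichment(aa_counts(imm), aa_counts(imm),
                             pseudocount = 0.5)
  expect_true(all(same$log_enrichment == 0))
  expect_equal(sum(same$freq_imm), 1, tolerance = 1e-9)

  # explicit zero pseudocount with a zero count names the amino acid
  expect_error(compute_enrichment(aa_counts(c(A = 5)), aa_counts(c(C = 5)),
                                  pseudocount = 0), "C|A")
  expect_error(compute_enrichment(aa_counts(), aa_counts(c(A = 1))),
               "positive")
})

test_that("enrichment is antisymmetric in the two classes", {
  set.seed(42)
  for (i in 1:10) {
    ci <- aa_counts(stats::setNames(rpois(20, 30), amino_acids()))
    cn <- aa_counts(stats::setNames(rpois(20, 12), amino_acids()))
    fwd <- compute_enrichment(ci, cn, pseudocount = 0.5)$log_enrichment
    rev <- compute_enrichment(cn, ci, pseudocount = 0.5)$log_enrichment
    expect_equal(fwd, -rev, tolerance = 1e-12)
  }
})

test_that("permutation test matches exhaustive enumeration on a tiny case", {
  # two residues per class, background concentrated on A and C
  bg <- stats::setNames(numeric(20), amino_acids())
  bg["A"] <- 0.3; bg["C"] <- 0.7
  imm <- aa_counts(c(A = 1, C = 1))
  non <- aa_counts(c(A = 2))
  obs <- abs(1 / 2 - 2 / 2)
  # exact: counts of A in each arm are Binomial(2, 0.3)
  exact <- 0
  for (k1 in 0:2) for (k2 in 0:2)
    if (abs(k1 / 2 - k2 / 2) >= obs - 1e-12)
      exact <- exact + dbinom(k1, 2, 0.3) * dbinom(k2, 2, 0.3)
  p <- permutation_test("A", imm, non, bg, n_perm = 40000, seed = 9)
  expect_equal(p, exact, tolerance = 4 * sqrt(exact * (1 - exact) / 40000) +
                 1 / 40000)

  # zero observed difference: every permutation ties or exceeds
  expect_equal(permutation_test("A", imm, imm, bg, n_perm = 500, seed = 1), 1)
  # reproducibility and argument validation
  expect_identical(permutation_test("C", imm, non, bg, 1000, seed = 5),
                   permutation_test("C", imm, non, bg, 1000, seed = 5))
  expect_error(permutation_test("A", imm, non, bg, n_perm = 0), "n_perm")
  expect_error(permutation_test("AC", imm, non, bg), "single")
})

test_that("permutation p-values are ~uniform under the null", {
  bg <- stats::setNames(rep(1 / 20, 20), amino_acids())
  set.seed(2024)
  ps <- replicate(200, {
    ci <- aa_counts(stats::setNames(as.numeric(rmultinom(1, 1848, bg)),
                                    amino_acids()))
    cn <- aa_counts(stats::setNames(as.numeric(rmultinom(1, 810, bg)),
                                    amino_acids()))
    permutation_test("A", ci, cn, bg, n_perm = 999,
                     seed = sample.int(1e6, 1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("q-values: BH fixes pi0 at 1, Storey shrinks by the pi0 estimate", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(qvalues(rep(1, 5), "storey"), rep(1, 5))
  p <- c(0.001, 0.2, 0.6, 0.8, 0.9, 0.95)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  expect_equal(qvalues(p, "storey"), pmin(1, pi0 * p.adjust(p, "BH")))
  expect_lte(qvalues(0.3, "storey"), 0.3)
  expect_equal(qvalues(0.3, "bh"), 0.3)
  expect_error(qvalues(numeric(0)), "empty")
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("class analysis counts members, forms opposite-pair Fisher tests", {
  cnt <- table1_counts()
  res <- class_analysis(cnt$imm, cnt$non)
  # every class count equals the sum of its member amino-acid counts
  defs <- aa_class_definitions()
  for (nm in names(defs)) {
    expect_equal(res$count_imm[res$class == nm],
                 sum(unclass(cnt$imm)[defs[[nm]]$members]))
  }
  # identical sets: enrichment 1, p 1
  same <- class_analysis(cnt$imm, cnt$imm)
  expect_equal(same$enrichment, rep(1, nrow(same)))
  expect_equal(same$p_value, rep(1, nrow(same)), tolerance = 1e-9)
  # zero class count in the non-immunogenic set -> enrichment undefined
  res0 <- class_analysis(aa_counts(c(D = 5, A = 5)), aa_counts(c(A = 10)))
  expect_true(is.na(res0$enrichment[res0$class == "acidic"]))
})

test_that("property correlation is a two-sided Spearman test", {
  sets <- generate_sets(generator_config(
    n_imm = 150, n_non = 80, seed = 5,
    planted_log_enrichment = c(W = 1, F = 0.6, S = -0.8)))
  tab <- compute_enrichment(count_nonanchor_aa(sets$imm, sets$masks),
                            count_nonanchor_aa(sets$non, sets$masks))
  E <- stats::setNames(tab$log_enrichment, tab$aa)
  expect_equal(property_correlation(tab, E)$rho, 1)
  expect_equal(property_correlation(tab, -E)$rho, -1)
  # hand rank formula on tie-free vectors
  set.seed(8)
  E_distinct <- stats::setNames(sample(seq(-1, 0.9, by = 0.1)), amino_acids())
  prop <- stats::setNames(sample(seq(0.05, 1, by = 0.05)), amino_acids())
  got <- property_correlation(E_distinct, prop)
  d <- rank(E_distinct[amino_acids()]) - rank(prop[amino_acids()])
  expect_equal(got$rho, 1 - 6 * sum(d^2) / (20 * (20^2 - 1)),
               tolerance = 1e-9)
  expect_error(property_correlation(tab, stats::setNames(rep(1, 20),
                                                         amino_acids())),
               "constant")
})
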