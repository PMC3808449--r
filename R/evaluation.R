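#' ROC curve and AUC from two score samples
#'
#' The AUC is the normalized Mann-Whitney U statistic (ties counted half):
#' the probability that a random immunogenic peptide outscores a random
#' non-immunogenic one. The ROC is a score-threshold sweep from (0,0) to
#' (1,1).
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors for the
#'   positive (immunogenic) and negative class.
#' @return An `evaluation_result` list: `roc` (data frame `fpr`, `tpr`),
#'   `auc`, `ranksum_p`, `frac_pos_imm`, `frac_pos_non` (fractions scoring
#'   strictly above 0).
#' @export
#' @examples
#' roc_auc(c(3, 1), c(2, 0))$auc  # 0.75
roc_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0)
    stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(pos_scores, neg_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thresholds <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg_scores >= t), numeric(1))
  structure(list(
    roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)),
    auc = auc,
    ranksum_p = ranksum(pos_scores, neg_scores),
    frac_pos_imm = mean(pos_scores > 0),
    frac_pos_non = mean(neg_scores > 0)
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "evaluation_result: AUC %.3f, rank-sum p %.3g, positive fractions %.1f%% / %.1f%%\n",
    x$auc, x$ranksum_p, 100 * x$frac_pos_imm, 100 * x$frac_pos_non))
  invisible(x)
}

#' Wilcoxon rank-sum p-value for a score separation
#'
#' Two-sided normal-approximation Mann-Whitney test with tie correction.
#' Returns 1 when every value is identical (no evidence of separation).
#'
#' @param pos_scores,neg_scores Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
ranksum <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score vectors must be non-empty", call. = FALSE)
  if (length(unique(c(pos_scores, neg_scores))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(pos_scores, neg_scores, exact = FALSE,
                       correct = FALSE)$p.value)
}

#' Stratified k-fold cross-validation of the immunogenicity model
#'
#' Per repetition: each class is independently split into k folds (seeded,
#' preserving the class imbalance per fold); for every fold a model is
#' trained on the remaining k-1 folds — re-estimating the log-enrichment
#' scores only, with the importance weights held fixed — and the held-out
#' peptides are scored. The pooled held-out scores give one AUC, ROC and
#' positive-fraction pair per repetition; results are averaged over
#' repetitions, with ROC curves averaged vertically on a 101-point FPR grid.
#'
#' @param imm,non Labelled [peptide_set()]s of 9mers, each of size >= k.
#' @param masks An [anchor_mask()].
#' @param importance Importance weights held fixed across folds.
#' @param k Number of folds (default 3: two-thirds train, one-third test).
#' @param reps Number of repetitions (default 25).
#' @param seed Integer seed; the whole procedure is reproducible given
#'   (seed, reps, k).
#' @param pseudocount Passed to [compute_enrichment()] during fold training.
#' @return An `evaluation_result` with the averaged ROC and mean AUC,
#'   rank-sum p of the pooled scores over all reps, mean positive fractions,
#'   and a `rep_auc` element with the per-repetition AUCs.
#' @export
cross_validate <- function(imm, non, masks = anchor_mask(), importance,
                           k = 3, reps = 25, seed = 1L, pseudocount = NULL) {
  if (nrow(imm) < k || nrow(non) < k)
    stop("each class must have at least k peptides", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- seq(0, 1, length.out = 101)
  rep_auc <- numeric(reps)
  rep_tpr <- matrix(0, reps, length(grid))
  rep_fpos <- rep_fneg <- numeric(reps)
  all_pos <- all_neg <- list()
  folds_of <- function(n) sample(rep_len(seq_len(k), n))
  for (r in seq_len(reps)) {
    fi <- folds_of(nrow(imm))
    fn <- folds_of(nrow(non))
    pos <- neg <- numeric(0)
    for (fold in seq_len(k)) {
      model <- train_model(subset_peptides(imm, fi != fold),
                           subset_peptides(non, fn != fold),
                           masks, importance, pseudocount)
      hi <- subset_peptides(imm, fi == fold)
      hn <- subset_peptides(non, fn == fold)
      if (nrow(hi)) pos <- c(pos, score_peptides(model, hi$sequence,
                                                 hi$mhc_allele))
      if (nrow(hn)) neg <- c(neg, score_peptides(model, hn$sequence,
                                                 hn$mhc_allele))
    }
    res <- roc_auc(pos, neg)
    rep_auc[r] <- res$auc
    # vertical averaging: best TPR at FPR <= grid point
    rep_tpr[r, ] <- vapply(grid, function(g)
      max(res$roc$tpr[res$roc$fpr <= g]), numeric(1))
    rep_fpos[r] <- res$frac_pos_imm
    rep_fneg[r] <- res$frac_pos_non
    all_pos[[r]] <- pos; all_neg[[r]] <- neg
  }
  structure(list(
    roc = data.frame(fpr = grid, tpr = colMeans(rep_tpr)),
    auc = mean(rep_auc),
    ranksum_p = ranksum(unlist(all_pos), unlist(all_neg)),
    frac_pos_imm = mean(rep_fpos),
    frac_pos_non = mean(rep_fneg),
    rep_auc = rep_auc
  ), class = "evaluation_result")
}

#' Affinity bin scheme
#'
#' @param edges Strictly increasing bin edges on the affinity (or combined
#'   score) axis. Values below the first edge form the first bin; values
#'   above the last edge form a final open bin.
#' @param offset Added to every value before binning (used for combined
#'   predictor scores that must be positive before log-scale binning).
#' @return A `bin_scheme` object.
#' @export
bin_scheme <- function(edges, offset = 0) {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  structure(list(edges = edges, offset = offset), class = "bin_scheme")
}

#' Default binding-affinity bin scheme (nM)
#'
#' One bin below 1 nM, then bins separated by five values on a logarithmic
#' scale from 1 nM to 500 nM: 1, 4.7, 22.4, 106 and 500 nM.
#'
#' @return A [bin_scheme()].
#' @export
affinity_bin_scheme <- function() bin_scheme(c(1, 4.7, 22.4, 106, 500))

#' Combined-score bin scheme for processing-aware predictors
#'
#' Scores are shifted by +1.1625 so the minimum exceeds 1, then binned by
#' five values on a logarithmic scale from 1 to 5.
#'
#' @return A [bin_scheme()].
#' @export
netctl_bin_scheme <- function()
  bin_scheme(exp(seq(log(1), log(5), length.out = 5)), offset = 1.1625)

assign_bins <- function(values, scheme) {
  cut(values + scheme$offset, breaks = c(-Inf, scheme$edges, Inf),
      labels = FALSE, right = TRUE)
}

#' Build affinity-matched subsets of two peptide sets
#'
#' Bins both sets on the affinity axis and keeps, per bin, the same number
#' of records from each set (the smaller side's count; the larger side is
#' subsampled with the given seed), so the two subsets have identical bin
#' histograms. The rank-sum p-value of the matched affinity values is
#' reported; successful matching should leave the distributions not
#' significantly different (p > 0.05).
#'
#' @param a,b [peptide_set()]s with `predicted_affinity_nM` present on every
#'   record.
#' @param scheme A [bin_scheme()] (default [affinity_bin_scheme()]).
#' @param seed Integer seed for subsampling.
#' @return List with `a`, `b` (the matched subsets), `bin_counts` (the shared
#'   per-bin histogram) and `ranksum_p`.
#' @export
matched_sets <- function(a, b, scheme = affinity_bin_scheme(), seed = 1L) {
  for (nm in c("a", "b")) {
    set <- get(nm)
    if (any(is.na(set$predicted_affinity_nM))) {
      i <- which(is.na(set$predicted_affinity_nM))[1]
      stop(sprintf("record %d of set %s (%s) has no affinity value",
                   i, nm, set$sequence[i]), call. = FALSE)
    }
  }
  bins_a <- assign_bins(a$predicted_affinity_nM, scheme)
  bins_b <- assign_bins(b$predicted_affinity_nM, scheme)
  n_bins <- length(scheme$edges) + 1
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep_a <- keep_b <- integer(0)
  counts <- integer(n_bins)
  for (bin in seq_len(n_bins)) {
    ia <- which(bins_a == bin); ib <- which(bins_b == bin)
    m <- min(length(ia), length(ib))
    counts[bin] <- m
    if (m > 0) {
      keep_a <- c(keep_a, if (length(ia) > m) sample(ia, m) else ia)
      keep_b <- c(keep_b, if (length(ib) > m) sample(ib, m) else ib)
    }
  }
  sub_a <- subset_peptides(a, sort(keep_a))
  sub_b <- subset_peptides(b, sort(keep_b))
  p <- if (length(keep_a)) ranksum(sub_a$predicted_affinity_nM,
                                   sub_b$predicted_affinity_nM) else NA_real_
  list(a = sub_a, b = sub_b, bin_counts = counts, ranksum_p = p)
}

#' Epitope-discovery triage summary
#'
#' If candidates with a non-positive immunogenicity score are not tested,
#' what fraction of the work is saved, and what fraction of the true
#' epitopes is still found?
#'
#' @param scores Numeric immunogenicity scores.
#' @param labels Labels parallel to `scores`; `"immunogenic"` marks epitopes.
#' @return List with `frac_discarded` (fraction of all candidates with score
#'   <= 0) and `frac_epitopes_retained` (fraction of epitopes with score >
#'   0; NA when there are no epitopes).
#' @export
triage_summary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  is_epi <- labels == "immunogenic"
  list(frac_discarded = mean(scores <= 0),
       frac_epitopes_retained = if (!any(is_epi)) NA_real_
         else mean(scores[is_epi] > 0))
}

#' Sign test on paired positive-score fractions
#'
#' For paired per-allele fractions (e.g. fraction of viral vs of human
#' ligands scoring positive), tests whether `frac_a > frac_b` more often
#' than chance: two-sided exact binomial test on the count of pairs with
#' `frac_a > frac_b`, ties dropped.
#'
#' @param frac_a,frac_b Paired numeric vectors of fractions.
#' @return Two-sided p-value.
#' @export
#' @examples
#' sign_test_fraction_positive(rep(1, 27), c(rep(0, 27)))  # one-sided extreme
sign_test_fraction_positive <- function(frac_a, frac_b) {
  stopifnot(length(frac_a) == length(frac_b))
  if (!length(frac_a)) stop("at least one pair required", call. = FALSE)
  keep <- frac_a != frac_b
  if (!any(keep)) stop("all pairs are ties; sign test undefined",
                       call. = FALSE)
  stats::binom.test(sum(frac_a[keep] > frac_b[keep]), sum(keep),
                    p = 0.5)$p.value
}
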