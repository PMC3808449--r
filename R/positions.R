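#' Per-position amino-acid profiles of the two classes
#'
#' Counts amino acids per peptide position, separately for immunogenic and
#' non-immunogenic peptides. A peptide contributes to a position only if that
#' position is a non-anchor position under its allele's mask, so positions
#' masked for every peptide (1, 2 and 9 under the default rule) come out
#' empty and are flagged NA.
#'
#' @param imm,non [peptide_set()]s of 9mers.
#' @param masks An [anchor_mask()].
#' @return List with elements `imm` and `non`, each a list of 9
#'   [aa_counts()], and `estimable`, a logical vector marking positions with
#'   observations in both classes.
#' @export
position_profiles <- function(imm, non, masks = anchor_mask()) {
  profile_one <- function(set) {
    if (nrow(set) && any(nchar(set$sequence) != 9))
      stop("position_profiles expects 9mer peptides", call. = FALSE)
    masks_by_pep <- lapply(set$mhc_allele, resolve_mask, mask = masks,
                           length = 9L)
    lapply(1:9, function(p) {
      use <- vapply(masks_by_pep, function(m) !(p %in% m), logical(1))
      count_residues(substr(set$sequence[use], p, p))
    })
  }
  pi <- profile_one(imm)
  pn <- profile_one(non)
  estimable <- vapply(1:9, function(p)
    aa_total(pi[[p]]) > 0 && aa_total(pn[[p]]) > 0, logical(1))
  list(imm = pi, non = pn, estimable = estimable)
}

#' Kullback-Leibler divergence between two amino-acid profiles
#'
#' `D(P || Q) = sum_a p(a) ln(p(a)/q(a))` on pseudocount-smoothed
#' frequencies, with `p` from the immunogenic counts and `q` from the
#' non-immunogenic counts: how poorly the immunogenic profile is described by
#' the non-immunogenic one. Natural-log base, consistent with the
#' log-enrichment scores.
#'
#' @param P,Q [aa_counts()] (P conventionally the immunogenic profile).
#' @param pseudocount Added to every cell before normalizing (default 0.5;
#'   20-category profiles from a few hundred peptides contain zeros).
#' @param symmetric If TRUE, returns the symmetrized divergence
#'   `(D(P||Q) + D(Q||P)) / 2`.
#' @return Non-negative divergence in nats; 0 iff the smoothed profiles are
#'   identical.
#' @export
kl_divergence <- function(P, Q, pseudocount = 0.5, symmetric = FALSE) {
  tp <- aa_total(P); tq <- aa_total(Q)
  if (tp <= 0 || tq <= 0) stop("both totals must be positive", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  k <- length(unclass(P))
  p <- (unclass(P) + pseudocount) / (tp + k * pseudocount)
  q <- (unclass(Q) + pseudocount) / (tq + k * pseudocount)
  if (any(q == 0 & p > 0) || any(p == 0 & q > 0 & symmetric))
    stop("zero smoothed frequency; use a positive pseudocount", call. = FALSE)
  d <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  if (symmetric) (d(p, q) + d(q, p)) / 2 else d(p, q)
}

#' Test whether two positional profiles differ
#'
#' Forms the 2 x 20 contingency table of class by amino acid and tests
#' independence. When the Cochran conditions hold on the expected counts (no
#' expected cell is zero and at least 80% of cells have expected count >= 5)
#' the asymptotic chi-squared probability is used; otherwise a seeded
#' Monte-Carlo p-value from tables simulated under fixed margins.
#'
#' @param P,Q [aa_counts()] for the two classes at one position.
#' @param n_mc Number of Monte-Carlo tables (used only when the asymptotic
#'   route is unsafe).
#' @param seed Integer seed for the Monte-Carlo route.
#' @return p-value.
#' @export
position_divergence_test <- function(P, Q, n_mc = 10000, seed = 1L) {
  tp <- aa_total(P); tq <- aa_total(Q)
  if (tp <= 0 || tq <= 0)
    stop("degenerate table: a class margin is zero", call. = FALSE)
  tab <- rbind(unclass(P), unclass(Q))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]  # drop unobserved amino acids
  if (ncol(tab) < 2) stop("degenerate table: fewer than 2 observed categories",
                          call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cochran <- all(expected > 0) && mean(expected >= 5) >= 0.8
  if (cochran)
    return(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats::chisq.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
}

#' Assemble per-position importance weights
#'
#' Positions estimable from the data carry their Kullback-Leibler divergence
#' as importance weight I(p); positions masked for (nearly) all peptides are
#' not estimable and carry weight 0, so they contribute nothing to scores
#' even for alleles whose mask leaves them open.
#'
#' @param divergences Numeric vector of divergences named by position, e.g.
#'   `c("3" = 0.10, "4" = 0.31, ...)`, or an unnamed length-9 vector.
#' @param na_positions Positions to force to 0 (default `c(1, 2, 9)`).
#' @return An `importance_weights` numeric vector of length 9 named "1".."9".
#' @export
#' @examples
#' build_importance_weights(c("3" = 0.10, "4" = 0.31, "5" = 0.30,
#'                            "6" = 0.29, "7" = 0.26, "8" = 0.18))
build_importance_weights <- function(divergences, na_positions = c(1, 2, 9)) {
  w <- stats::setNames(numeric(9), as.character(1:9))
  if (is.null(names(divergences))) {
    if (length(divergences) != 9)
      stop("unnamed divergences must have length 9", call. = FALSE)
    names(divergences) <- as.character(1:9)
  }
  pos <- as.integer(names(divergences))
  if (any(is.na(pos) | pos < 1 | pos > 9))
    stop("divergence names must be positions 1..9", call. = FALSE)
  if (any(divergences < 0, na.rm = TRUE))
    stop("divergences must be non-negative", call. = FALSE)
  keep <- !is.na(divergences) & !(pos %in% na_positions)
  w[as.character(pos[keep])] <- divergences[keep]
  w[as.character(na_positions)] <- 0
  structure(w, class = "importance_weights")
}

#' Estimate importance weights from data
#'
#' Convenience wrapper: per-position profiles, KL divergence at estimable
#' positions, zero elsewhere.
#'
#' @inheritParams position_profiles
#' @param pseudocount Smoothing passed to [kl_divergence()].
#' @return List with `weights` (an `importance_weights` vector), `divergence`
#'   (per-position KL, NA where not estimable) and `p_value` (per-position
#'   profile-difference test, NA where not estimable).
#' @export
estimate_importance <- function(imm, non, masks = anchor_mask(),
                                pseudocount = 0.5) {
  prof <- position_profiles(imm, non, masks)
  div <- p <- rep(NA_real_, 9)
  for (pos in which(prof$estimable)) {
    div[pos] <- kl_divergence(prof$imm[[pos]], prof$non[[pos]], pseudocount)
    p[pos] <- position_divergence_test(prof$imm[[pos]], prof$non[[pos]])
  }
  names(div) <- names(p) <- as.character(1:9)
  w <- build_importance_weights(div, na_positions = which(!prof$estimable))
  list(weights = w, divergence = div, p_value = p)
}
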