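#' Count amino acids at non-anchor positions
#'
#' Each 9mer peptide contributes exactly its six non-anchor residues, where
#' the anchor positions are resolved per allele from the mask table (default
#' {1, 2, 9}). Counting the non-anchor residues only avoids confounding
#' T-cell preferences with MHC binding motifs.
#'
#' @param set A [peptide_set()] of 9mers.
#' @param masks An [anchor_mask()].
#' @param fallback Passed to [resolve_mask()]; if FALSE, alleles missing from
#'   the mask table are an error.
#' @return An [aa_counts()] with total `6 * nrow(set)`.
#' @export
count_nonanchor_aa <- function(set, masks = anchor_mask(), fallback = TRUE) {
  stopifnot(inherits(set, "peptide_set"))
  if (nrow(set) == 0) return(aa_counts())
  len <- nchar(set$sequence)
  if (any(len != 9))
    stop("count_nonanchor_aa expects 9mer peptides", call. = FALSE)
  residues <- unlist(lapply(seq_len(nrow(set)), function(i) {
    m <- resolve_mask(masks, set$mhc_allele[i], 9L, fallback = fallback)
    ch <- strsplit(set$sequence[i], "")[[1]]
    ch[-m]
  }))
  count_residues(residues)
}

#' Background amino-acid frequencies from source proteins
#'
#' @param proteins A [source_proteins()] table.
#' @return Named numeric vector of 20 frequencies summing to 1. `X` and any
#'   other non-canonical residues are excluded from numerator and
#'   denominator.
#' @export
background_frequencies <- function(proteins) {
  stopifnot(inherits(proteins, "source_proteins"))
  if (nrow(proteins) == 0) stop("at least one protein required", call. = FALSE)
  ch <- unlist(split_residues(proteins$sequence))
  ch <- ch[ch %in% amino_acids()]
  if (length(ch) == 0)
    stop("no countable (canonical) residues in source proteins", call. = FALSE)
  tab <- table(factor(ch, levels = amino_acids()))
  stats::setNames(as.numeric(tab) / length(ch), amino_acids())
}

# Pseudocount policy: explicit value wins; NULL means 0 when all counts are
# positive (the published-model regime) and 0.5 per amino acid otherwise.
resolve_pseudocount <- function(pseudocount, imm, non) {
  if (!is.null(pseudocount)) return(pseudocount)
  if (all(imm > 0) && all(non > 0)) 0 else 0.5
}

#' Log-enrichment table of amino acids in immunogenic peptides
#'
#' For each amino acid `a`, the enrichment is the ratio of its frequency
#' among non-anchor residues of immunogenic peptides to its frequency in
#' non-immunogenic peptides; the natural logarithm of this ratio is the log
#' enrichment score E(a) used by the immunogenicity model. With pseudocount
#' `c`, `E(a) = ln((imm_a + c)/(imm_total + 20c)) -
#' ln((non_a + c)/(non_total + 20c))`.
#'
#' @param imm,non [aa_counts()] for the immunogenic and non-immunogenic
#'   classes.
#' @param pseudocount Per-amino-acid pseudocount. `NULL` (default) uses 0
#'   when every count is positive and 0.5 otherwise; an explicit 0 with a
#'   zero count is an error.
#' @return An `enrichment_table` data frame with columns `aa`, `freq_imm`,
#'   `freq_non` (raw frequencies) and `log_enrichment`.
#' @export
compute_enrichment <- function(imm, non, pseudocount = NULL) {
  ti <- aa_total(imm); tn <- aa_total(non)
  if (ti <= 0 || tn <= 0) stop("both totals must be positive", call. = FALSE)
  pc <- resolve_pseudocount(pseudocount, imm, non)
  if (pc < 0) stop("pseudocount must be non-negative", call. = FALSE)
  if (pc == 0 && (any(imm == 0) || any(non == 0))) {
    zero <- amino_acids()[unclass(imm) == 0 | unclass(non) == 0]
    stop("zero count for ", paste(zero, collapse = ","),
         " with pseudocount 0; enrichment undefined", call. = FALSE)
  }
  E <- log((unclass(imm) + pc) / (ti + 20 * pc)) -
       log((unclass(non) + pc) / (tn + 20 * pc))
  structure(
    data.frame(aa = amino_acids(),
               freq_imm = unclass(imm) / ti,
               freq_non = unclass(non) / tn,
               log_enrichment = as.numeric(E),
               row.names = NULL, stringsAsFactors = FALSE),
    pseudocount = pc, total_imm = ti, total_non = tn,
    class = c("enrichment_table", "data.frame"))
}

#' Permutation test for the association of one amino acid with immunogenicity
#'
#' Under the null, both classes are random draws from the background
#' amino-acid distribution of the source proteins. Random immunogenic and
#' non-immunogenic residue samples of the observed total sizes are drawn from
#' the background, and the absolute difference in the amino acid's frequency
#' between the two drawn samples is compared with the observed absolute
#' difference. The amino acid's count in a multinomial background draw is
#' Binomial(total, bg), which is how the draws are generated. The p-value is
#' `(k + 1) / (n_perm + 1)` where `k` permutations reach the observed
#' difference.
#'
#' @param aa Single amino-acid letter.
#' @param imm,non Observed [aa_counts()] per class.
#' @param background Named background frequency vector summing to 1.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Two-sided p-value.
#' @export
permutation_test <- function(aa, imm, non, background, n_perm = 10000,
                             seed = 1L) {
  if (!is.character(aa) || length(aa) != 1 || !aa %in% amino_acids())
    stop("aa must be a single amino-acid letter", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1", call. = FALSE)
  ti <- aa_total(imm); tn <- aa_total(non)
  if (ti <= 0 || tn <= 0) stop("both totals must be positive", call. = FALSE)
  q <- background[[aa]]
  obs <- abs(unclass(imm)[[aa]] / ti - unclass(non)[[aa]] / tn)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fi <- stats::rbinom(n_perm, ti, q) / ti
  fn <- stats::rbinom(n_perm, tn, q) / tn
  k <- sum(abs(fi - fn) >= obs - 1e-12)
  (k + 1) / (n_perm + 1)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's
# random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up values (`method = "bh"`, equivalent to fixing
#' the null proportion pi0 at 1), or Storey q-values using the lambda = 0.5
#' point estimate `pi0 = min(1, mean(p > 0.5) / 0.5)`.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @param method `"storey"` or `"bh"`.
#' @return Vector of q-values in \code{[0, 1]}.
#' @export
qvalues <- function(p_values, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pi0 <- if (method == "bh") 1 else min(1, mean(p_values > 0.5) / 0.5)
  pmin(1, pi0 * stats::p.adjust(p_values, method = "BH"))
}

#' Class-level enrichment of amino-acid characteristics
#'
#' Counts the residues belonging to each amino-acid class (size, aromaticity,
#' acidity, charge; see [aa_class_definitions()]) in the immunogenic and
#' non-immunogenic count vectors. The class enrichment is the ratio of the
#' class's share of all immunogenic residues to its share of all
#' non-immunogenic residues. Each characteristic is tested once with a
#' two-sided Fisher's exact test opposing the class to its stated opposite
#' (large vs small, aromatic vs non-aromatic, acidic vs basic, charged vs
#' non-charged).
#'
#' @param imm,non [aa_counts()] per class of peptides.
#' @param classes Class definition list as from [aa_class_definitions()].
#' @return A data frame with columns `class`, `count_imm`, `count_non`,
#'   `enrichment` (NA when the non-immunogenic class count is zero) and
#'   `p_value`.
#' @export
class_analysis <- function(imm, non, classes = aa_class_definitions()) {
  ti <- aa_total(imm); tn <- aa_total(non)
  if (ti <= 0 || tn <= 0) stop("both totals must be positive", call. = FALSE)
  count_class <- function(counts, members) sum(unclass(counts)[members])
  rows <- lapply(names(classes), function(nm) {
    cls <- classes[[nm]]
    if (any(!cls$members %in% amino_acids()))
      stop("class ", nm, " has members outside the amino-acid alphabet",
           call. = FALSE)
    ci <- count_class(imm, cls$members)
    cn <- count_class(non, cls$members)
    opp <- classes[[cls$opposite]]
    if (is.null(opp)) stop("opposite class ", cls$opposite, " undefined",
                           call. = FALSE)
    oi <- count_class(imm, opp$members)
    on_ <- count_class(non, opp$members)
    p <- stats::fisher.test(matrix(c(ci, cn, oi, on_), 2, byrow = TRUE))$p.value
    data.frame(class = nm, count_imm = ci, count_non = cn,
               enrichment = if (cn == 0) NA_real_ else (ci / ti) / (cn / tn),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of log-enrichment scores with an amino-acid property
#'
#' Used to ask whether the T-cell preference profile follows a known
#' physicochemical property (an AAindex-style 20-value vector supplied by the
#' user).
#'
#' @param enrichments An `enrichment_table` from [compute_enrichment()], or a
#'   named 20-vector of log-enrichment scores.
#' @param property Named numeric vector with one value per amino acid.
#' @return List with elements `rho` and `p_value` (two-sided).
#' @export
property_correlation <- function(enrichments, property) {
  E <- if (inherits(enrichments, "enrichment_table"))
    stats::setNames(enrichments$log_enrichment, enrichments$aa)
  else enrichments
  if (is.null(names(property)) || any(!amino_acids() %in% names(property)))
    stop("property must be named with a value for each amino acid",
         call. = FALSE)
  property <- property[amino_acids()]
  E <- E[amino_acids()]
  if (stats::sd(property) == 0)
    stop("property vector is constant; rank correlation undefined",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(E, property, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
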