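#' Construct an immunogenicity model
#'
#' The model is the triple behind the immunogenicity score: 20 amino-acid
#' log-enrichment scores E(a), 9 per-position importance weights I(p), and a
#' per-allele anchor-mask table M(H, p). The score of a 9mer ligand L on
#' molecule H is `S = sum_p M(H,p) I(p) E(A(L,p))`, where M(H,p) is 0 at H's
#' anchor positions and 1 elsewhere.
#'
#' @param enrichment Named numeric vector of 20 finite log-enrichment scores.
#' @param importance Numeric vector of 9 finite importance weights.
#' @param masks An [anchor_mask()].
#' @param metadata List of free-form metadata (training sizes, seed, ...).
#' @return An `immunogenicity_model`.
#' @export
immunogenicity_model <- function(enrichment, importance,
                                 masks = anchor_mask(), metadata = list()) {
  if (inherits(enrichment, "enrichment_table"))
    enrichment <- stats::setNames(enrichment$log_enrichment, enrichment$aa)
  if (is.null(names(enrichment)) ||
      !setequal(names(enrichment), amino_acids()))
    stop("enrichment must be named by the 20 amino acids", call. = FALSE)
  enrichment <- enrichment[amino_acids()]
  if (any(!is.finite(enrichment)))
    stop("log-enrichment scores must be finite", call. = FALSE)
  importance <- as.numeric(importance)
  if (length(importance) != 9 || any(!is.finite(importance)))
    stop("importance must be 9 finite weights", call. = FALSE)
  stopifnot(inherits(masks, "anchor_mask"))
  structure(list(enrichment = enrichment,
                 importance = stats::setNames(importance, as.character(1:9)),
                 masks = masks, metadata = metadata),
            class = "immunogenicity_model")
}

#' @export
print.immunogenicity_model <- function(x, ...) {
  cat("immunogenicity_model\n")
  cat("  E(a): ", paste(sprintf("%s=%.3f", names(x$enrichment)[1:5],
                                x$enrichment[1:5]), collapse = " "),
      " ...\n", sep = "")
  cat("  I(p): ", paste(sprintf("%.2f", x$importance), collapse = " "), "\n",
      sep = "")
  cat("  allele-specific masks: ", length(x$masks$masks), "\n", sep = "")
  invisible(x)
}

#' Score peptides with an immunogenicity model
#'
#' Sums, over the non-anchor positions of each 9mer, the log-enrichment score
#' of the residue weighted by the position's importance. Positive scores
#' predict immunogenic peptides. The model is trained on 9mers only; other
#' lengths are rejected rather than scored by an invented extension scheme.
#'
#' @param model An [immunogenicity_model()].
#' @param sequence Character vector of 9mer peptide sequences.
#' @param allele Allele name(s), recycled; alleles absent from the model's
#'   mask table use the default {1, 2, 9} mask.
#' @return Numeric vector of immunogenicity scores.
#' @export
#' @examples
#' m <- published_model()
#' score_peptides(m, "SLFNTVATL", "HLA-A*02:01")
score_peptides <- function(model, sequence, allele = NA_character_) {
  stopifnot(inherits(model, "immunogenicity_model"))
  sequence <- as.character(sequence)
  if (any(nchar(sequence) != 9))
    stop("the immunogenicity model is trained on 9mers; got length(s) ",
         paste(unique(nchar(sequence)[nchar(sequence) != 9]), collapse = ","),
         call. = FALSE)
  assert_peptide_alphabet(sequence)
  allele <- rep_len(as.character(allele), length(sequence))
  vapply(seq_along(sequence), function(i) {
    m <- if (is.na(allele[i])) default_mask(9L) else
      resolve_mask(model$masks, allele[i], 9L)
    ch <- strsplit(sequence[i], "")[[1]]
    use <- setdiff(1:9, m)
    sum(model$importance[use] * model$enrichment[ch[use]])
  }, numeric(1))
}

#' @rdname score_peptides
#' @export
score_peptide <- function(model, sequence, allele = NA_character_) {
  stopifnot(length(sequence) == 1)
  score_peptides(model, sequence, allele)
}

#' Train an immunogenicity model from labelled peptide sets
#'
#' Log-enrichment scores are estimated from the non-anchor amino-acid counts
#' of the two sets; the importance weights are taken as given (they are held
#' fixed during cross-validation and retraining rather than re-estimated per
#' fold).
#'
#' @param imm,non Non-empty [peptide_set()]s of 9mers.
#' @param masks An [anchor_mask()].
#' @param importance Importance weights (length 9), e.g. from
#'   [estimate_importance()] or [published_model()].
#' @param pseudocount Passed to [compute_enrichment()].
#' @return An [immunogenicity_model()].
#' @export
train_model <- function(imm, non, masks = anchor_mask(),
                        importance, pseudocount = NULL) {
  if (nrow(imm) == 0 || nrow(non) == 0)
    stop("both training sets must be non-empty", call. = FALSE)
  ci <- count_nonanchor_aa(imm, masks)
  cn <- count_nonanchor_aa(non, masks)
  enr <- compute_enrichment(ci, cn, pseudocount)
  immunogenicity_model(enr, importance, masks,
                       metadata = list(n_imm = nrow(imm), n_non = nrow(non),
                                       pseudocount = attr(enr, "pseudocount")))
}

#' Train a final model by averaging over redundancy resamplings
#'
#' The redundancy-reduced training set is not unique: equal-priority
#' redundant peptides are broken by chance. The final model repeats the
#' non-redundancy selection and model building `n_resamplings` times (100 by
#' default) and averages the log-enrichment scores over the resampled models.
#'
#' @param imm_pool,non_pool Redundant [peptide_set()] pools (with
#'   `entry_count` priorities).
#' @param proteins [source_proteins()] used for redundancy mapping.
#' @param masks An [anchor_mask()].
#' @param importance Importance weights (held fixed).
#' @param n_resamplings Number of selection/build repetitions.
#' @param seed Integer seed; resampling `i` uses `seed + i`.
#' @param pseudocount Passed to [compute_enrichment()].
#' @return An [immunogenicity_model()] with averaged E(a).
#' @export
train_final_model <- function(imm_pool, non_pool, proteins,
                              masks = anchor_mask(), importance,
                              n_resamplings = 100, seed = 1L,
                              pseudocount = NULL) {
  if (n_resamplings < 1) stop("n_resamplings must be >= 1", call. = FALSE)
  Es <- vapply(seq_len(n_resamplings), function(i) {
    imm <- reduce_redundancy(imm_pool, proteins, seed = seed + i)
    non <- reduce_redundancy(non_pool, proteins, seed = seed + i)
    train_model(imm, non, masks, importance, pseudocount)$enrichment
  }, numeric(20))
  immunogenicity_model(rowMeans(Es), importance, masks,
                       metadata = list(n_resamplings = n_resamplings,
                                       seed = seed))
}

#' The bundled published immunogenicity model
#'
#' Loads the model shipped with the package: the published final
#' log-enrichment scores (transcribed by the package authors from the
#' published model's score table), the per-position importance weights
#' (0, 0, 0.10, 0.31, 0.30, 0.29, 0.26, 0.18, 0) and an anchor-mask table
#' containing the default {1, 2, 9} rule plus the HLA-B*08:01 mask {2, 5, 9}.
#'
#' @return An [immunogenicity_model()].
#' @export
#' @examples
#' published_model()
published_model <- function() {
  read_model(system.file("extdata", "published_model_v1.json",
                         package = "immunopep", mustWork = TRUE))
}
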