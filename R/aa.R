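#' @keywords internal
"_PACKAGE"

#' The 20 canonical amino acids
#'
#' One-letter codes in alphabetical order. All count vectors, frequency
#' vectors and enrichment tables in this package are indexed by this
#' alphabet, in this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Split a peptide/protein string into single residues.
split_residues <- function(x) strsplit(x, "", fixed = TRUE)

assert_peptide_alphabet <- function(sequences, context = "peptide") {
  chars <- split_residues(sequences)
  bad <- vapply(chars, function(ch) any(!ch %in% amino_acids()), logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    res <- setdiff(unique(chars[[i]]), amino_acids())
    stop(sprintf("invalid residue(s) %s in %s %d (sequence '%s')",
                 paste(res, collapse = ","), context, i, sequences[i]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Amino-acid count vector
#'
#' A named integer vector over the 20-letter alphabet with an attached total.
#'
#' @param counts Named numeric vector; names must be amino-acid letters.
#'   Missing letters count 0.
#' @return An `aa_counts` object: a named vector of length 20 whose
#'   `total` attribute equals its sum.
#' @export
#' @examples
#' aa_counts(c(A = 4, W = 2))
aa_counts <- function(counts = numeric(0)) {
  if (length(counts) && is.null(names(counts)))
    stop("counts must be named by amino-acid letter", call. = FALSE)
  extra <- setdiff(names(counts), amino_acids())
  if (length(extra))
    stop("unknown amino acid(s): ", paste(extra, collapse = ","), call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- stats::setNames(numeric(20), amino_acids())
  out[names(counts)] <- counts
  structure(out, total = sum(out), class = "aa_counts")
}

#' @export
print.aa_counts <- function(x, ...) {
  cat("aa_counts (total ", attr(x, "total"), ")\n", sep = "")
  print(unclass(x)[unclass(x) > 0])
  invisible(x)
}

aa_total <- function(x) {
  t <- attr(x, "total")
  if (is.null(t)) sum(x) else t
}

count_residues <- function(residues) {
  tab <- table(factor(residues, levels = amino_acids()))
  aa_counts(stats::setNames(as.numeric(tab), names(tab)))
}

#' Amino-acid class definitions
#'
#' The side-chain classes used for class-level enrichment analysis: small
#' (< 120 Da: A,G,P,S,T,V), large (> 150 Da: F,H,R,W,Y), aromatic (F,H,W,Y),
#' charged (D,E,H,K,R), acidic (D,E) and basic (H,K,R), plus the complements
#' non-aromatic and non-charged. Each class names the opposite class against
#' which its Fisher's exact test is formed (large vs small, aromatic vs
#' non-aromatic, acidic vs basic, charged vs non-charged).
#'
#' @return A named list; each element has fields `members` (character vector
#'   of amino-acid letters) and `opposite` (name of the contrasting class).
#' @export
#' @examples
#' aa_class_definitions()$large
aa_class_definitions <- function() {
  aromatic <- c("F", "H", "W", "Y")
  charged <- c("D", "E", "H", "K", "R")
  list(
    large        = list(members = c("F", "H", "R", "W", "Y"), opposite = "small"),
    small        = list(members = c("A", "G", "P", "S", "T", "V"), opposite = "large"),
    aromatic     = list(members = aromatic, opposite = "non_aromatic"),
    non_aromatic = list(members = setdiff(amino_acids(), aromatic), opposite = "aromatic"),
    acidic       = list(members = c("D", "E"), opposite = "basic"),
    basic        = list(members = c("H", "K", "R"), opposite = "acidic"),
    charged      = list(members = charged, opposite = "non_charged"),
    non_charged  = list(members = setdiff(amino_acids(), charged), opposite = "charged")
  )
}
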