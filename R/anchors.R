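#' Default anchor mask
#'
#' Most HLA class I molecules use the second and C-terminal residues as main
#' binding anchors; position 1 additionally influences binding in most
#' molecules, so the default rule masks positions 1, 2 and the last position
#' from immunogenicity analysis.
#'
#' @param length Peptide length (>= 8).
#' @return Sorted integer vector of masked 1-based positions.
#' @export
#' @examples
#' default_mask(9)  # 1, 2, 9
default_mask <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 8)
    stop("peptide length must be at least 8", call. = FALSE)
  c(1L, 2L, length)
}

#' Anchor mask table
#'
#' Maps MHC alleles to the set of peptide positions masked as binding
#' anchors. Alleles absent from the table fall back to [default_mask()]
#' ({1, 2, last}) unless `fallback = FALSE` when resolving.
#'
#' @param masks Named list: allele name -> integer vector of 1-based masked
#'   positions. Names are normalized with [normalize_allele()].
#' @return An `anchor_mask` object.
#' @export
#' @examples
#' anchor_mask(list("HLA-B*08:01" = c(2, 5, 9)))
anchor_mask <- function(masks = list()) {
  if (length(masks)) {
    if (is.null(names(masks)) || any(names(masks) == ""))
      stop("masks must be a named list (allele -> positions)", call. = FALSE)
    masks <- lapply(masks, function(p) {
      p <- sort(unique(as.integer(p)))
      if (any(is.na(p) | p < 1))
        stop("masked positions must be positive integers", call. = FALSE)
      p
    })
    names(masks) <- normalize_allele(names(masks))
  }
  structure(list(masks = masks), class = "anchor_mask")
}

#' @export
print.anchor_mask <- function(x, ...) {
  cat("anchor_mask: default rule {1, 2, last}")
  if (length(x$masks)) {
    cat("; allele-specific entries:\n")
    for (a in names(x$masks))
      cat(sprintf("  %s: {%s}\n", a, paste(x$masks[[a]], collapse = ",")))
  } else cat(" (no allele-specific entries)\n")
  invisible(x)
}

#' Resolve the masked positions for one allele
#'
#' @param mask An [anchor_mask()].
#' @param allele Allele name (normalized internally).
#' @param length Peptide length.
#' @param fallback If TRUE (default) an allele absent from the table gets the
#'   default {1, 2, last} mask; if FALSE this is an error.
#' @return Integer vector of masked positions, all within `length`.
#' @export
resolve_mask <- function(mask, allele, length, fallback = TRUE) {
  stopifnot(inherits(mask, "anchor_mask"))
  allele <- normalize_allele(allele)
  m <- mask$masks[[allele]]
  if (is.null(m)) {
    if (!fallback)
      stop("no anchor mask for allele ", allele,
           " and fallback is disabled", call. = FALSE)
    m <- default_mask(length)
  }
  if (any(m > length))
    stop(sprintf("mask for %s has positions beyond peptide length %d",
                 allele, length), call. = FALSE)
  m
}

#' Derive an allele's anchor mask from a binding-impact profile
#'
#' Given the externally computed impact of each of the 9 peptide positions on
#' predicted binding affinity, the six positions with least impact are defined
#' as non-anchor positions; the three highest-impact positions are masked.
#' A tie across the 3rd/4th rank boundary makes the anchor set ambiguous and
#' is an error: supply an explicit mask for such alleles instead.
#'
#' @param impact Numeric vector of 9 non-negative, finite per-position impact
#'   values.
#' @return Sorted integer vector of the 3 masked positions.
#' @export
#' @examples
#' derive_anchor_mask(c(9, 8, 1, 1, 1, 1, 1, 1, 7))  # 1, 2, 9
derive_anchor_mask <- function(impact) {
  impact <- as.numeric(impact)
  if (length(impact) != 9)
    stop("impact profile must have exactly 9 values", call. = FALSE)
  if (any(!is.finite(impact)) || any(impact < 0))
    stop("impact values must be finite and non-negative", call. = FALSE)
  ord <- order(impact, decreasing = TRUE)
  if (impact[ord[3]] == impact[ord[4]])
    stop("tie at the anchor/non-anchor boundary (ranks 3 and 4 share impact ",
         impact[ord[3]], "); supply an explicit mask for this allele",
         call. = FALSE)
  sort(ord[1:3])
}
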