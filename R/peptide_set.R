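#' Normalize an MHC allele name
#'
#' HLA allele names are stored in the colon-delimited nomenclature
#' (`HLA-A*02:01`); the older four-digit spelling (`HLA-A*0201`) is accepted
#' and converted. Murine H-2 names (`H-2-Kb`, `H-2-Db`, ...) pass through
#' unchanged apart from whitespace trimming.
#'
#' @param allele Character vector of allele names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_allele(c("HLA-A*0201", "HLA-A*02:01", "H-2-Kb"))
normalize_allele <- function(allele) {
  a <- trimws(as.character(allele))
  # HLA-X*dddd -> HLA-X*dd:dd (only when no colon present)
  sub("^(HLA-[A-Z]+\\*)(\\d{2})(\\d{2,})$", "\\1\\2:\\3", a)
}

valid_hosts <- function() c("human", "hla_transgenic_mouse", "wild_type_mouse")
valid_labels <- function() c("immunogenic", "non_immunogenic", "unknown")

# File-vocabulary -> internal label. Evaluation sets use epitope/non-epitope.
map_label <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(x)))
  key[key %in% c("", "_", "na")] <- "unknown"
  lut <- c(immunogenic = "immunogenic",
           non_immunogenic = "non_immunogenic",
           nonimmunogenic = "non_immunogenic",
           epitope = "immunogenic",
           non_epitope = "non_immunogenic",
           nonepitope = "non_immunogenic",
           positive = "immunogenic",
           negative = "non_immunogenic",
           unknown = "unknown")
  out <- unname(lut[key])
  if (any(is.na(out)))
    stop("unrecognized immunogenicity label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Construct a peptide set
#'
#' A `peptide_set` is a data frame of peptide/MHC observations with columns
#' `sequence`, `mhc_allele`, `host`, `label`, `predicted_affinity_nM`
#' (NA when absent), `entry_count` (database entry multiplicity, default 1)
#' and `source_protein_ids` (comma-separated identifiers, possibly empty).
#'
#' Sequences must be uppercase over the 20-letter amino-acid alphabet and at
#' least 8 residues long; duplicate (sequence, allele) pairs are rejected.
#'
#' @param sequence Character vector of peptide sequences.
#' @param mhc_allele Allele names (normalized on construction).
#' @param host One of `"human"`, `"hla_transgenic_mouse"`,
#'   `"wild_type_mouse"`; recycled.
#' @param label `"immunogenic"`, `"non_immunogenic"` or `"unknown"`; recycled.
#' @param predicted_affinity_nM Positive predicted binding affinities in nM,
#'   or NA; recycled.
#' @param entry_count Non-negative integer multiplicities; recycled.
#' @param source_protein_ids Character vector of comma-separated protein ids.
#' @param required_length If non-NULL, all sequences must have this length.
#' @return A `peptide_set` (data frame subclass).
#' @export
#' @examples
#' peptide_set("SLFNTVATL", "HLA-A*0201", label = "immunogenic")
peptide_set <- function(sequence, mhc_allele, host = "hla_transgenic_mouse",
                        label = "unknown", predicted_affinity_nM = NA_real_,
                        entry_count = 1L, source_protein_ids = "",
                        required_length = NULL) {
  n <- length(sequence)
  sequence <- as.character(sequence)
  if (n == 0)
    return(structure(
      data.frame(sequence = character(0), mhc_allele = character(0),
                 host = character(0), label = character(0),
                 predicted_affinity_nM = numeric(0), entry_count = integer(0),
                 source_protein_ids = character(0),
                 stringsAsFactors = FALSE),
      required_length = required_length,
      class = c("peptide_set", "data.frame")))
  if (any(sequence != toupper(sequence)))
    stop("peptide sequences must be uppercase", call. = FALSE)
  assert_peptide_alphabet(sequence)
  if (any(nchar(sequence) < 8))
    stop("peptide sequences must be at least 8 residues", call. = FALSE)
  if (!is.null(required_length) && any(nchar(sequence) != required_length))
    stop("all sequences must have length ", required_length, call. = FALSE)
  host <- rep_len(as.character(host), n)
  if (any(!host %in% valid_hosts()))
    stop("host must be one of: ", paste(valid_hosts(), collapse = ", "),
         call. = FALSE)
  label <- rep_len(as.character(label), n)
  if (any(!label %in% valid_labels()))
    stop("labels must be one of: ", paste(valid_labels(), collapse = ", "),
         call. = FALSE)
  aff <- rep_len(as.numeric(predicted_affinity_nM), n)
  if (any(!is.na(aff) & aff <= 0))
    stop("predicted_affinity_nM must be positive when present", call. = FALSE)
  ec <- rep_len(as.integer(entry_count), n)
  if (any(is.na(ec) | ec < 0))
    stop("entry_count must be a non-negative integer", call. = FALSE)
  allele <- normalize_allele(rep_len(mhc_allele, n))
  key <- paste(sequence, allele)
  if (anyDuplicated(key))
    stop("duplicate (sequence, allele) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  structure(
    data.frame(sequence = sequence, mhc_allele = allele, host = host,
               label = label, predicted_affinity_nM = aff, entry_count = ec,
               source_protein_ids = rep_len(as.character(source_protein_ids), n),
               stringsAsFactors = FALSE),
    required_length = required_length,
    class = c("peptide_set", "data.frame"))
}

#' Coerce a data frame to a peptide set
#'
#' @param x Data frame with at least `sequence` and `mhc_allele` columns.
#' @param required_length Optional common sequence length to enforce.
#' @return A [peptide_set()].
#' @export
as_peptide_set <- function(x, required_length = NULL) {
  stopifnot(is.data.frame(x))
  get_col <- function(nm, default) if (nm %in% names(x)) x[[nm]] else default
  peptide_set(x$sequence, x$mhc_allele,
              host = get_col("host", "hla_transgenic_mouse"),
              label = get_col("label", "unknown"),
              predicted_affinity_nM = get_col("predicted_affinity_nM", NA_real_),
              entry_count = get_col("entry_count", 1L),
              source_protein_ids = get_col("source_protein_ids", ""),
              required_length = required_length)
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d peptides (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  NextMethod()
}

# Subset rows, keeping the class and required_length attribute.
subset_peptides <- function(set, i) {
  out <- as.data.frame(set)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, required_length = attr(set, "required_length"),
            class = c("peptide_set", "data.frame"))
}
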