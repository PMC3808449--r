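#' Read a peptide table
#'
#' Reads a delimited text table of peptide/MHC observations into a
#' [peptide_set()]. The default dialect is tab-separated with a header row
#' and columns `sequence`, `allele`, `host`, `label`, `affinity_nM`,
#' `entry_count`, `source_protein_ids`; only `sequence` and `allele` are
#' required and extra columns are ignored. Labels are mapped from the file's
#' vocabulary (`epitope`/`non-epitope` become
#' `immunogenic`/`non_immunogenic`).
#'
#' @param path Path to the table.
#' @param dialect List with elements `sep` (default `"\t"`) and optional
#'   `columns`, a named character vector mapping the canonical column names
#'   above to the names used in the file.
#' @param required_length Optional common peptide length to enforce.
#' @return A [peptide_set()].
#' @export
read_peptide_table <- function(path, dialect = list(sep = "\t"),
                               required_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (is.null(dialect$sep)) "\t" else dialect$sep
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  cols <- c(sequence = "sequence", allele = "allele", host = "host",
            label = "label", affinity_nM = "affinity_nM",
            entry_count = "entry_count",
            source_protein_ids = "source_protein_ids")
  if (!is.null(dialect$columns)) cols[names(dialect$columns)] <- dialect$columns
  for (required in c("sequence", "allele"))
    if (!cols[[required]] %in% names(df))
      stop(sprintf("peptide table %s is missing required column '%s'",
                   path, cols[[required]]), call. = FALSE)
  pick <- function(nm, default) {
    if (cols[[nm]] %in% names(df)) df[[cols[[nm]]]] else rep(default, nrow(df))
  }
  seqs <- toupper(trimws(df[[cols[["sequence"]]]]))
  ok <- vapply(split_residues(seqs),
               function(ch) all(ch %in% amino_acids()), logical(1))
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop(sprintf("row %d of %s: sequence '%s' contains non-canonical residues",
                 i, path, seqs[i]), call. = FALSE)
  }
  aff <- suppressWarnings(as.numeric(pick("affinity_nM", NA_character_)))
  ec <- pick("entry_count", "1")
  ec[is.na(ec) | ec == ""] <- "1"
  host <- tolower(trimws(pick("host", "hla_transgenic_mouse")))
  host[host %in% c("mouse", "hla transgenic mouse", "hla-transgenic mouse",
                   "transgenic_mouse")] <- "hla_transgenic_mouse"
  host[host %in% c("wild type mouse", "wild-type mouse", "wt_mouse")] <-
    "wild_type_mouse"
  peptide_set(seqs, df[[cols[["allele"]]]], host = host,
              label = map_label(pick("label", "unknown")),
              predicted_affinity_nM = aff,
              entry_count = as.integer(round(as.numeric(ec))),
              source_protein_ids = pick("source_protein_ids", ""),
              required_length = required_length)
}

#' Write a peptide table
#'
#' Inverse of [read_peptide_table()] under the default dialect: tab-separated,
#' header row, canonical column names.
#'
#' @param set A [peptide_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(set, path) {
  stopifnot(inherits(set, "peptide_set"))
  out <- data.frame(sequence = set$sequence, allele = set$mhc_allele,
                    host = set$host, label = set$label,
                    affinity_nM = set$predicted_affinity_nM,
                    entry_count = set$entry_count,
                    source_protein_ids = set$source_protein_ids,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read source proteins from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data frame with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence` (uppercased). `X` residues are tolerated in
#'   proteins; they are skipped by background counting and never match during
#'   peptide mapping.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in FASTA file: ", path,
                              call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  source_proteins(ids, toupper(as.character(seqs)))
}

#' Construct a source-protein table
#'
#' @param id Character vector of unique protein identifiers.
#' @param sequence Non-empty amino-acid sequences (`X` allowed).
#' @return A `source_proteins` data frame with columns `id`, `sequence`.
#' @export
source_proteins <- function(id, sequence) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence lengths differ", call. = FALSE)
  if (any(nchar(sequence) == 0)) stop("empty protein sequence", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  structure(data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE),
            class = c("source_proteins", "data.frame"))
}

#' Write source proteins to FASTA
#'
#' @param proteins A [source_proteins()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Serialize an immunogenicity model to JSON
#'
#' The model document is versioned JSON holding the 20 log-enrichment scores,
#' the 9 importance weights, the per-allele anchor-mask table, the default
#' mask rule and metadata. [read_model()] restores it bit-exactly.
#'
#' @param model An [immunogenicity_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "immunogenicity_model"))
  doc <- list(
    format = "immunopep-model",
    format_version = MODEL_FORMAT_VERSION,
    log_enrichment = as.list(model$enrichment),
    importance = as.numeric(model$importance),
    masks = model$masks$masks,
    default_rule = c("1", "2", "last"),
    metadata = model$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized immunogenicity model
#'
#' @param path Path to a JSON document produced by [write_model()].
#' @return An [immunogenicity_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$format_version) ||
      doc$format_version != MODEL_FORMAT_VERSION)
    stop(sprintf("model format version mismatch in %s: found %s, expected %d",
                 path, format(doc$format_version), MODEL_FORMAT_VERSION),
         call. = FALSE)
  enr <- unlist(doc$log_enrichment)
  masks <- lapply(doc$masks, function(p) as.integer(unlist(p)))
  immunogenicity_model(
    enrichment = enr[amino_acids()],
    importance = as.numeric(unlist(doc$importance)),
    masks = anchor_mask(masks),
    metadata = doc$metadata
  )
}
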