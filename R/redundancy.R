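#' Map a peptide onto source proteins
#'
#' Ungapped sliding-window alignment of the peptide against every window of
#' every protein. A mapping is successful when strictly more than 75% of the
#' residues match (for 9mers: at least 7 of 9). `X` residues in a protein
#' never match. For short peptides at this identity threshold gapped
#' alignments are effectively excluded, so the sliding window stands in for a
#' full local aligner.
#'
#' @param peptide Single peptide sequence.
#' @param proteins A [source_proteins()] table.
#' @return Data frame with one row per successful mapping: `protein_id`,
#'   `start` (1-based window start), `identity` (matches / peptide length)
#'   and `matched_positions` (list column of matched protein positions).
#'   Zero rows when the peptide maps nowhere.
#' @export
map_peptide <- function(peptide, proteins) {
  stopifnot(is.character(peptide), length(peptide) == 1)
  stopifnot(inherits(proteins, "source_proteins"))
  pep <- strsplit(peptide, "")[[1]]
  L <- length(pep)
  min_matches <- floor(0.75 * L) + 1  # strictly more than 75%
  hits <- list()
  for (j in seq_len(nrow(proteins))) {
    prot <- strsplit(proteins$sequence[j], "")[[1]]
    prot[!prot %in% amino_acids()] <- NA_character_  # X etc. never match
    n <- length(prot)
    if (n < L) next
    n_win <- n - L + 1L
    # flags[s, k]: does window starting at s match the peptide at offset k?
    flags <- vapply(seq_len(L), function(k)
      !is.na(prot[k:(k + n_win - 1L)]) & prot[k:(k + n_win - 1L)] == pep[k],
      logical(n_win))
    if (n_win == 1L) flags <- matrix(flags, nrow = 1L)
    m <- rowSums(flags)
    for (s in which(m >= min_matches)) {
      hits[[length(hits) + 1]] <- list(
        protein_id = proteins$id[j], start = s, identity = m[s] / L,
        matched_positions = list(s - 1L + which(flags[s, ])))
    }
  }
  if (!length(hits))
    return(data.frame(protein_id = character(0), start = integer(0),
                      identity = numeric(0),
                      matched_positions = I(list()),
                      stringsAsFactors = FALSE))
  data.frame(
    protein_id = vapply(hits, `[[`, character(1), "protein_id"),
    start = vapply(hits, `[[`, integer(1), "start"),
    identity = vapply(hits, `[[`, numeric(1), "identity"),
    matched_positions = I(lapply(hits, function(h) h$matched_positions[[1]])),
    stringsAsFactors = FALSE)
}

# Redundancy on precomputed mappings: two peptides are redundant iff, in some
# shared protein, strictly more than half of the shorter peptide's residues
# match the same protein positions. Only matched residues count as "mapping
# to" a position.
redundant_from_mappings <- function(map1, map2, len1, len2) {
  if (nrow(map1) == 0 || nrow(map2) == 0) return(FALSE)
  shared <- intersect(map1$protein_id, map2$protein_id)
  threshold <- min(len1, len2) / 2
  for (prot in shared) {
    pos1 <- unique(unlist(map1$matched_positions[map1$protein_id == prot]))
    pos2 <- unique(unlist(map2$matched_positions[map2$protein_id == prot]))
    if (length(intersect(pos1, pos2)) > threshold) return(TRUE)
  }
  FALSE
}

#' Are two peptides redundant?
#'
#' Two peptides are redundant if strictly more than half of their residues
#' map to the same positions in any shared source protein.
#'
#' @param p1,p2 Peptide sequences.
#' @param proteins A [source_proteins()] table, or NULL when `mappings` are
#'   supplied.
#' @param mappings Optional list of two precomputed [map_peptide()] results.
#' @return Logical.
#' @export
are_redundant <- function(p1, p2, proteins = NULL, mappings = NULL) {
  if (is.null(mappings))
    mappings <- list(map_peptide(p1, proteins), map_peptide(p2, proteins))
  redundant_from_mappings(mappings[[1]], mappings[[2]],
                          nchar(p1), nchar(p2))
}

#' Redundancy-reduce a peptide set by source-protein mapping
#'
#' Maps every peptide to the source proteins, discards peptides that map
#' nowhere, and removes redundant peptides, prioritizing those with more
#' database entries (`entry_count`); equal-priority redundant peptides are
#' resolved by seeded chance. The redundancy graph is resolved greedily in
#' descending priority order, removing the neighbours of each kept peptide,
#' so the output contains no redundant pair and reducing twice equals
#' reducing once.
#'
#' @param set A [peptide_set()].
#' @param proteins A [source_proteins()] table.
#' @param seed Integer seed for tie-breaking; the result is deterministic
#'   given the seed.
#' @return The reduced [peptide_set()]. Attribute `tie_break_fraction` gives
#'   the fraction of kept peptides that were selected by chance among
#'   equal-priority redundant alternatives.
#' @export
reduce_redundancy <- function(set, proteins, seed = 1L) {
  stopifnot(inherits(set, "peptide_set"))
  n <- nrow(set)
  if (n == 0) return(set)
  maps <- lapply(set$sequence, map_peptide, proteins = proteins)
  mapped <- vapply(maps, nrow, integer(1)) > 0
  idx <- which(mapped)
  if (!length(idx)) {
    out <- subset_peptides(set, integer(0))
    attr(out, "tie_break_fraction") <- 0
    return(out)
  }
  # adjacency restricted to peptides sharing a protein
  prot_of <- lapply(maps, function(m) unique(m$protein_id))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (a in seq_along(idx)) {
    i <- idx[a]
    for (b in seq_len(a - 1L)) {
      j <- idx[b]
      if (!length(intersect(prot_of[[i]], prot_of[[j]]))) next
      if (redundant_from_mappings(maps[[i]], maps[[j]],
                                  nchar(set$sequence[i]),
                                  nchar(set$sequence[j]))) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffle <- sample.int(n)  # seeded tie-break among equal entry counts
  ord <- idx[order(-set$entry_count[idx], shuffle[idx])]
  removed <- rep(FALSE, n)
  keep <- logical(n)
  tie_broken <- 0L
  for (i in ord) {
    if (removed[i]) next
    keep[i] <- TRUE
    live <- adj[[i]][!removed[adj[[i]]] & !keep[adj[[i]]]]
    if (length(live) && any(set$entry_count[live] == set$entry_count[i]))
      tie_broken <- tie_broken + 1L
    removed[live] <- TRUE
  }
  out <- subset_peptides(set, which(keep))
  attr(out, "tie_break_fraction") <- tie_broken / max(1L, sum(keep))
  out
}
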