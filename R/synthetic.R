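#' Configuration for the synthetic peptide generator
#'
#' The generator emulates the statistical structure assumed by the
#' enrichment analysis: non-anchor residues of non-immunogenic peptides are
#' drawn from a background distribution, those of immunogenic peptides from
#' the background exponentially tilted by the planted log-enrichments, so
#' that the planted vector is the exact population log-enrichment (the
#' closed-form recovery target). Anchor residues are drawn from a fixed
#' per-allele motif.
#'
#' Default sizes (600 immunogenic vs 181 non-immunogenic) mirror the
#' training-set imbalance of the published model.
#'
#' @param n_imm,n_non Class sizes.
#' @param planted_log_enrichment Named 20-vector e*; default all zero (no
#'   signal). Unnamed entries default to 0. The vector is centered on
#'   construction (shifted so the tilted class distribution is already
#'   normalized); the stored vector is then exactly the population
#'   log-enrichment at unit position signal.
#' @param background Named 20-frequency vector summing to 1 (default
#'   uniform).
#' @param position_signal Per-position multiplier on e* (length 9, default 1
#'   everywhere); 0 at a position removes the class signal there.
#' @param alleles Named list: allele -> list(mask = masked positions,
#'   motif = named list position -> character vector of allowed anchor
#'   residues). Default: HLA-A*02:01 with mask {1,2,9}, P2 in {L,M}, P9 in
#'   {V,L,I}.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_imm = 600, n_non = 181,
                             planted_log_enrichment = NULL,
                             background = NULL,
                             position_signal = rep(1, 9),
                             alleles = NULL, seed = 1L) {
  e <- stats::setNames(numeric(20), amino_acids())
  if (!is.null(planted_log_enrichment)) {
    if (is.null(names(planted_log_enrichment)))
      stop("planted_log_enrichment must be named", call. = FALSE)
    e[names(planted_log_enrichment)] <- planted_log_enrichment
  }
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), amino_acids())
  background <- background[amino_acids()]
  if (any(is.na(background)) || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 20 non-negative frequencies summing to 1",
         call. = FALSE)
  # Center the tilt so the tilted distribution needs no renormalization:
  # the stored vector then IS the population log-enrichment (at unit
  # position signal), giving a closed-form recovery target.
  if (any(e != 0)) e <- e - log(sum(background * exp(e)))
  if (length(position_signal) != 9)
    stop("position_signal must have length 9", call. = FALSE)
  if (is.null(alleles))
    alleles <- list("HLA-A*02:01" = list(
      mask = c(1L, 2L, 9L),
      motif = list("2" = c("L", "M"), "9" = c("V", "L", "I"))))
  structure(list(n_imm = n_imm, n_non = n_non,
                 planted_log_enrichment = e, background = background,
                 position_signal = as.numeric(position_signal),
                 alleles = alleles, seed = as.integer(seed)),
            class = "generator_config")
}

# Tilted per-position distribution for the immunogenic class.
tilted_background <- function(background, e, signal) {
  w <- background * exp(e * signal)
  if (any(!is.finite(w)) || sum(w) <= 0)
    stop("invalid tilted distribution", call. = FALSE)
  w / sum(w)
}

#' Generate labelled synthetic peptide sets
#'
#' @param config A [generator_config()].
#' @return List with `imm` and `non` [peptide_set()]s of 9mers and `masks`,
#'   the matching [anchor_mask()]. Deterministic given `config$seed`.
#' @export
#' @examples
#' sets <- generate_sets(generator_config(n_imm = 20, n_non = 10, seed = 7))
#' nrow(sets$imm)
generate_sets <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  allele_names <- names(config$alleles)
  draw_class <- function(n, class_dist, label) {
    if (n == 0) return(peptide_set(character(0), character(0)))
    alleles <- sample(allele_names, n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      al <- config$alleles[[alleles[i]]]
      ch <- character(9)
      for (p in 1:9) {
        if (p %in% al$mask) {
          allowed <- al$motif[[as.character(p)]]
          if (is.null(allowed)) {
            ch[p] <- sample(amino_acids(), 1, prob = config$background)
          } else ch[p] <- allowed[sample.int(length(allowed), 1)]
        } else {
          ch[p] <- sample(amino_acids(), 1, prob = class_dist[[p]])
        }
      }
      seqs[i] <- paste(ch, collapse = "")
    }
    # enforce unique (sequence, allele) pairs by redrawing clashes
    tries <- 0
    repeat {
      dup <- duplicated(paste(seqs, alleles))
      if (!any(dup) || tries > 50) break
      tries <- tries + 1
      for (i in which(dup)) {
        al <- config$alleles[[alleles[i]]]
        ch <- strsplit(seqs[i], "")[[1]]
        open <- setdiff(1:9, al$mask)
        p <- open[sample.int(length(open), 1)]
        ch[p] <- sample(amino_acids(), 1, prob = class_dist[[p]])
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    peptide_set(seqs, alleles, label = label, required_length = 9L)
  }
  imm_dist <- lapply(1:9, function(p)
    tilted_background(config$background, config$planted_log_enrichment,
                      config$position_signal[p]))
  non_dist <- lapply(1:9, function(p) config$background)
  imm <- draw_class(config$n_imm, imm_dist, "immunogenic")
  non <- draw_class(config$n_non, non_dist, "non_immunogenic")
  masks <- anchor_mask(lapply(config$alleles, `[[`, "mask"))
  list(imm = imm, non = non, masks = masks)
}

#' Generate a redundant peptide pool with its source proteins
#'
#' Emulates database oversampling: each cluster is a seed 9mer embedded in a
#' generated source protein, plus variants differing from the seed by at most
#' two substitutions. Within a cluster all peptides map to the same protein
#' window, so they are mutually redundant under the mapping definition;
#' peptides from different clusters map to different proteins and are not.
#'
#' @param n_clusters Number of redundancy clusters.
#' @param variants_per_cluster Peptides per cluster (the seed plus
#'   `variants_per_cluster - 1` mutants).
#' @param planted_entry_count If not NULL, this entry count is planted on the
#'   seed peptide of every cluster (others get 1), making the seed the
#'   deterministic survivor of redundancy reduction.
#' @param protein_length Length of each generated source protein.
#' @param id_prefix Prefix for generated protein identifiers (change it when
#'   combining several generated pools, so ids stay unique).
#' @param seed Integer seed.
#' @return List with `peptides` (a [peptide_set()]) and `proteins` (a
#'   [source_proteins()] table). Peptide `source_protein_ids` name the
#'   embedding protein; cluster membership is recoverable from it.
#' @export
generate_redundant_pool <- function(n_clusters, variants_per_cluster,
                                    planted_entry_count = NULL,
                                    protein_length = 60, id_prefix = "prot",
                                    seed = 1L) {
  stopifnot(n_clusters >= 1, variants_per_cluster >= 1,
            protein_length >= 20)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  aa <- amino_acids()
  seqs <- alleles <- prot_ids <- character(0)
  entry <- integer(0)
  prot_seq <- character(n_clusters)
  for (cl in seq_len(n_clusters)) {
    prot <- sample(aa, protein_length, replace = TRUE)
    start <- sample.int(protein_length - 8L, 1)
    core <- prot[start:(start + 8L)]
    prot_seq[cl] <- paste(prot, collapse = "")
    variants <- character(variants_per_cluster)
    variants[1] <- paste(core, collapse = "")
    i <- 2
    while (i <= variants_per_cluster) {
      v <- core
      k <- sample(1:2, 1)
      at <- sample(9, k)
      v[at] <- sample(aa, k, replace = TRUE)
      v <- paste(v, collapse = "")
      if (!v %in% variants[seq_len(i - 1)]) {
        variants[i] <- v
        i <- i + 1
      }
    }
    seqs <- c(seqs, variants)
    alleles <- c(alleles, rep("HLA-A*02:01", variants_per_cluster))
    prot_ids <- c(prot_ids, rep(sprintf("%s%03d", id_prefix, cl),
                                variants_per_cluster))
    ec <- rep(1L, variants_per_cluster)
    if (!is.null(planted_entry_count)) ec[1] <- as.integer(planted_entry_count)
    entry <- c(entry, ec)
  }
  # distinct sequences across clusters (collisions are astronomically rare,
  # but the peptide_set invariant forbids them)
  stopifnot(!anyDuplicated(paste(seqs, alleles)))
  list(
    peptides = peptide_set(seqs, alleles, label = "immunogenic",
                           entry_count = entry,
                           source_protein_ids = prot_ids,
                           required_length = 9L),
    proteins = source_proteins(sprintf("%s%03d", id_prefix, seq_len(n_clusters)),
                               prot_seq))
}
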