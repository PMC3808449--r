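# Independent oracles and small fixture builders shared across tests.

# Pairwise-concordance AUC: brute force over all (pos, neg) pairs.
brute_auc <- function(pos, neg) {
  grid <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
exact_ranksum_p <- function(pos, neg) {
  all <- c(pos, neg)
  n1 <- length(pos)
  r <- rank(all)
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(all), n1)
  W <- apply(sets, 2, function(i) sum(r[i]))
  mu <- mean(W)
  min(1, 2 * min(mean(W <= obs), mean(W >= obs)))
}

# Naive peptide->protein mapping, written independently of map_peptide:
# returns matched protein positions per (protein, window) passing > 75%.
naive_mappings <- function(peptide, proteins) {
  pep <- strsplit(peptide, "")[[1]]
  res <- list()
  for (j in seq_len(nrow(proteins))) {
    prot <- strsplit(proteins$sequence[j], "")[[1]]
    if (length(prot) < length(pep)) next
    for (s in 1:(length(prot) - length(pep) + 1)) {
      win <- prot[s:(s + length(pep) - 1)]
      ok <- win == pep & win != "X"
      if (sum(ok) / length(pep) > 0.75)
        res[[length(res) + 1]] <- list(protein = proteins$id[j],
                                       positions = s - 1 + which(ok))
    }
  }
  res
}

naive_redundant <- function(p1, p2, proteins) {
  m1 <- naive_mappings(p1, proteins)
  m2 <- naive_mappings(p2, proteins)
  thr <- min(nchar(p1), nchar(p2)) / 2
  for (a in m1) for (b in m2) {
    if (a$protein == b$protein &&
        length(intersect(a$positions, b$positions)) > thr) return(TRUE)
  }
  FALSE
}

# Quick 9mer peptide set on one default-mask allele.
make_set <- function(seqs, allele = "HLA-A*02:01", label = "unknown", ...) {
  peptide_set(seqs, allele, label = label, required_length = 9L, ...)
}

# Per-amino-acid counts consistent with the printed class-level totals of the
# published characteristics table: totals 1848 (immunogenic) / 810
# (non-immunogenic); large 384/132, small 653/304, aromatic 326/111,
# acidic 185/67, basic 147/78, charged 332/145. The within-class split is
# arbitrary; only class sums matter for the class analysis.
table1_counts <- function() {
  imm <- c(A = 150, G = 100, P = 80, S = 133, T = 100, V = 90,   # small 653
           F = 120, W = 60, Y = 106, H = 40, R = 58,             # large 384
           D = 90, E = 95,                                       # acidic 185
           K = 49,                                               # basic 147
           C = 50, I = 120, L = 150, M = 80, N = 90, Q = 87)     # rest
  non <- c(A = 70, G = 50, P = 40, S = 60, T = 45, V = 39,       # small 304
           F = 40, W = 16, Y = 30, H = 25, R = 21,               # large 132
           D = 30, E = 37,                                       # acidic 67
           K = 32,                                               # basic 78
           C = 30, I = 60, L = 70, M = 40, N = 40, Q = 35)       # rest
  list(imm = aa_counts(imm), non = aa_counts(non))
}
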