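---
title: "Scoring MHC class I peptide immunogenicity from amino-acid enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring MHC class I peptide immunogenicity from amino-acid enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopep)
```

## The problem and the model

A peptide presented by an MHC class I molecule (a pMHC) is *immunogenic* when
CD8+ T-cells can recognize it. Among peptides that bind MHC-I equally well,
some elicit responses and some never do, and the difference is partly encoded
in the peptide sequence itself: residues with large, aromatic side chains at
the TCR-facing positions favour recognition, while small residues such as
serine disfavour it, and the central positions P4–P6 of a 9mer matter most.

`immunopep` implements a linear model of this effect. For a 9mer ligand $L$
presented on molecule $H$,

$$ S(L, H) \;=\; \sum_{p=1}^{9} M(H, p)\, I(p)\, E\!\big(A(L,p)\big), $$

where

* $E(a)$ is the **log enrichment score** of amino acid $a$: the natural log
  of the ratio of $a$'s frequency among non-anchor residues of immunogenic
  versus non-immunogenic training peptides,
* $I(p)$ is the **importance weight** of position $p$: the Kullback–Leibler
  divergence (in nats) between the positional amino-acid profiles of the two
  classes, and
* $M(H, p)$ is the **anchor mask**: 0 at $H$'s binding-anchor positions,
  1 elsewhere. Anchors are masked because their residues reflect MHC binding
  preferences, not T-cell preferences.

A positive score predicts an immunogenic pMHC. The package bundles a
published final model (`published_model()`): 20 enrichment scores transcribed
by the package authors from the published model's score table, the
importance weights $(0, 0, 0.10, 0.31, 0.30, 0.29, 0.26, 0.18, 0)$, and a
mask table holding the default rule $\{1, 2, 9\}$ plus the HLA-B\*08:01
anchor set $\{2, 5, 9\}$. Only 9mers are scored: the model is 9mer-trained,
and any scheme for extending it to other lengths would be an invention, so
other lengths raise an error instead.

```{r}
m <- published_model()
score_peptide(m, "SLFNTVATL", "HLA-A*02:01")
```

## Anchor masks

Most HLA class I molecules anchor the peptide at P2 and the C-terminus, with
P1 also influencing binding, hence the default mask $\{1, 2, \mathrm{last}\}$
(`default_mask()`). For molecules with non-standard anchor use, a mask can be
derived from an externally computed per-position binding-impact profile with
`derive_anchor_mask()`: the three highest-impact positions are masked, the
six lowest-impact positions are the non-anchor positions used throughout.
Ties across the anchor/non-anchor boundary are an error rather than being
silently broken — masking changes every downstream count and score, so an
ambiguous profile must be resolved explicitly by the user.

Alleles absent from a mask table fall back to the default rule. Positions
that are masked for essentially all training peptides (1, 2 and 9 under the
default rule) are not estimable and carry $I(p) = 0$; for alleles whose mask
leaves such a position open (e.g. P1 under a B\*08:01-style mask) that
position therefore contributes nothing to the score. This is a documented
limitation of any model trained with the default-mask majority.

## Estimation choices

**Enrichment.** $E(a)$ uses the natural logarithm throughout. With
pseudocount $c$,
$E(a) = \ln\frac{n^{imm}_a + c}{N^{imm} + 20c} - \ln\frac{n^{non}_a + c}{N^{non} + 20c}$.
The default policy (`pseudocount = NULL`) uses raw counts when every count is
positive — the regime of the published model, whose scores are finite — and
$c = 0.5$ otherwise, so small user sets cannot produce infinite scores. An
explicit `pseudocount = 0` with a zero count is an error naming the amino
acid.

**Position importance.** Profiles are compared with
$D(P^{imm} \Vert P^{non})$, i.e. how poorly the immunogenic profile is
described by the non-immunogenic one; the symmetrized variant is available
via `kl_divergence(..., symmetric = TRUE)`. Cells are smoothed with a 0.5
pseudocount before normalizing: 20-category profiles estimated from a few
hundred peptides regularly contain zeros, and unsmoothed KL would be
infinite. Natural-log base keeps $I(p)$ on the same scale as $E(a)$.

**Permutation test.** The null model for a single amino acid's association
draws random "immunogenic" and "non-immunogenic" residue samples of the
observed total sizes from the source-protein background distribution and
compares the absolute frequency difference with the observed one;
$p = (k+1)/(n_{perm}+1)$ over 10000 permutations by default. Because only
one amino acid's frequency is inspected per test, each multinomial draw
reduces to its binomial marginal, which is how the draws are generated (the
two are exactly equivalent, and the binomial form vectorizes). This is a
parametric resampling from the background, which is the literal reading of
the procedure's description; a conditional permutation of the pooled
observed residues is a possible variant but is not what the wording
describes, so it was not made the default.

**Multiple testing.** `qvalues()` offers Benjamini–Hochberg (`"bh"`,
$\pi_0 = 1$) and Storey q-values with the $\lambda = 0.5$ point estimate
$\hat\pi_0 = \min(1, \overline{\#\{p > 0.5\}}/0.5)$ — the simplest published
variant, chosen over the smoother for transparency.

**Class analysis.** Residue classes (small < 120 Da: A,G,P,S,T,V; large
> 150 Da: F,H,R,W,Y; aromatic F,H,W,Y; charged D,E,H,K,R; acidic D,E; basic
H,K,R; plus complements) are tested once per characteristic with a
two-sided Fisher's exact test opposing each class to its stated opposite
(large vs small, aromatic vs non-aromatic, acidic vs basic, charged vs
non-charged). Two-sidedness reproduces the printed p-values (0.014, 0.012)
of the reference analysis, which was checked against `fisher.test` before
the implementation was written.

**Positional test.** The 2×20 class-by-amino-acid table is tested with the
asymptotic chi-squared probability when the Cochran conditions hold on the
expected counts (no zero cell, ≥ 80% of cells ≥ 5), and otherwise with a
seeded Monte-Carlo test under fixed margins.

## Training, cross-validation and evaluation

`train_model()` re-estimates only $E(a)$; the importance weights are taken
as given and held fixed, mirroring how the reference procedure re-computes
enrichment per fold while keeping the published position weights.
`cross_validate()` runs, per repetition, a stratified k-fold pass (each
class split independently, so the class imbalance is preserved per fold;
the reference description does not say whether its folds were stratified —
stratification was chosen because the 600:181-scale imbalance otherwise
produces folds with very few negatives). Defaults are $k = 3$ and 25
repetitions. Every peptide is scored exactly once per repetition; per-rep
AUCs are averaged, and the mean ROC is formed by vertical averaging of the
per-rep curves on a 101-point false-positive-rate grid (the averaging scheme
of the reference figure is unspecified; vertical averaging is the common
convention). The positive/negative decision threshold is 0 throughout, since
the score's sign is its calibrated meaning.

`matched_sets()` builds binding-affinity-matched control sets: records are
binned (default bins: < 1 nM, then edges at 1, 4.7, 22.4, 106, 500 nM — five
values log-spaced from 1 to 500), and per bin both sets keep the smaller
side's count, subsampling the larger side with a seed. The per-bin minimum
is forced by the requirement that the selection be maximal with identical
bin distributions. A scheme for combined processing+binding scores
(`netctl_bin_scheme()`) shifts scores by +1.1625 before log-scale binning
from 1 to 5. The matched subsets are checked with a rank-sum test
(successful matching leaves $p > 0.05$).

`reduce_redundancy()` removes database oversampling: peptides are mapped to
source proteins by ungapped sliding-window alignment (a mapping succeeds
when strictly more than 75% of residues match — for 9mers, ≥ 7 of 9; for
queries this short at that identity, gapped alignments are effectively
excluded, so a sliding window replaces an external local aligner). Two
peptides are redundant when strictly more than half of the shorter one's
residues match the *same* protein positions (mismatched residues do not
count as mapping to a position). The redundancy graph is resolved greedily
in descending `entry_count` priority with seeded tie-breaking, which matches
a priority-then-chance selection without inventing a global optimization;
the output is maximal (every removed mapped peptide is redundant with a
kept one), redundancy-free, and idempotent. Unmappable peptides are
discarded. The fraction of survivors chosen by chance among equal-priority
alternatives is reported as the `tie_break_fraction` attribute.

Because equal-priority ties make the reduced set non-unique,
`train_final_model()` repeats the selection and model build (100 times by
default) and averages the enrichment scores across repetitions.

## The synthetic-data generator

`generate_sets()` emulates exactly the statistical structure the enrichment
analysis assumes: non-anchor residues of non-immunogenic peptides are i.i.d.
draws from a background distribution (uniform by default — the simplest
null; supply protein-derived frequencies for realism), and immunogenic
residues are drawn from the background exponentially tilted by a planted
log-enrichment vector $e^*$, position-modulated by an optional signal
profile. The planted vector is centered at construction so the tilted
distribution is already normalized; the stored $e^*$ is then *exactly* the
population log-enrichment, giving a closed-form recovery target. Anchor
positions are filled from a fixed allele motif (default HLA-A\*02:01-like:
P2 ∈ {L, M}, P9 ∈ {V, L, I}).

Default class sizes are 600 immunogenic versus 181 non-immunogenic,
mirroring the imbalance of the reference training data.
`generate_redundant_pool()` embeds seed 9mers in generated proteins and adds
variants within two substitutions — the structure of heavily-studied
epitopes and their point mutants in sequence databases — so that redundancy
reduction has known ground truth (within-cluster pairs redundant,
cross-cluster pairs not).

What the generator does *not* emulate: real MHC binding motifs beyond a
fixed anchor set, allele mixtures with different masks in one set,
correlations between positions, affinity–immunogenicity dependence
(affinities, when needed, are drawn log-uniform on [0.1, 500] nM), and
host effects. Passing tests on generated data therefore demonstrate the
estimators' correctness under the model's own assumptions, not performance
on real immunological data; the latter requires the curated evaluation
tables (see below).

## Problem sizes and numerical checks in the test suite

The suite validates parameter recovery at 2000 peptides per class (mean
absolute error of $\hat E$ below 0.1; at these sizes the binomial standard
error of a single score is ≈ 0.03), null cross-validation at 500 per class
(AUC within 0.05 of chance, averaged over generator seeds), planted-signal
cross-validation at 1500 per class against a 100,000-draw simulation of the
population-optimal discriminator (for $|e^*| = 1$ on five residues the
optimum is ≈ 0.805, so the cross-validated estimate is checked against that
oracle rather than against a round threshold), permutation-test p-value
uniformity at the reference scale of 1848/810 residues (at coarser totals
the discreteness of the statistic makes the add-one-smoothed p-values
visibly conservative — a property of the test's construction, not a bug),
rank-sum normal approximation against exact enumeration at $n = 8 + 8$,
AUC against pairwise concordance up to $n = 200$, and redundancy reduction
against a naive re-implementation on pools of ≤ 50 peptides.

## Reproducing published accuracies

The curated training and evaluation peptide tables (the supplementary
datasets of the reference study) are spreadsheets that cannot be
redistributed with this package. Users who transcribe them to the package's
TSV dialect and place them at `inst/extdata/training_pmhcs.tsv` (the curated
immunogenic/non-immunogenic training pMHCs) and
`inst/extdata/benchmark_pmhcs.tsv` (the independent epitope/non-epitope
benchmark)
activate the corresponding acceptance tests and `scripts/acceptance.R`
entries: murine/human benchmark AUC (published: 0.69 and 0.61), triage
fractions (≈ 38% of candidates discarded while retaining ≈ 86% of
epitopes), and 3-fold × 25-rep cross-validated AUC (≈ 0.65 with ≈ 66% / 44%
positive-score fractions). Without those files the corresponding test
fails with a message naming them: the reproduction is reported as not run,
never silently skipped.

## Known limitations

* 9mers only; no length generalization.
* The bundled enrichment scores are a transcription of the published score
  table; the transcription is exercised by a frozen hand-summation check of
  the worked example, but cannot be re-derived without the original
  training spreadsheet.
* $I(p) = 0$ at positions 1, 2 and 9 even for alleles whose masks leave
  them open (see above).
* The bundled mask table contains only the default rule and HLA-B\*08:01;
  other non-standard alleles require a user-supplied mask
  (`--mask` on the command line, or `anchor_mask()` programmatically).
* Whether the published tool rescales $I(p)$ before summing is not
  documented; raw divergences are used here.
* For mixed-length peptide pairs, redundancy overlap is measured relative
  to the shorter peptide; all in-scope peptides are 9mers, so this choice
  is currently moot.
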