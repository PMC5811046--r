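---
title: "Methods: polyproline stalling motifs, their nulls, and their evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyproline stalling motifs, their nulls, and their evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppstall)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
show about real data.

## Motif model and strength classification

A polyproline motif is a *maximal* run of n ≥ 2 consecutive prolines together
with its flanking context X(−2)X(−1)–nP–X(+1). A run of k prolines is one
motif with n = k, never k − 1 overlapping diprolines; the overlapping-word
convention is used only inside the Markov word test, where it is the natural
counting unit. All coordinates are 1-based inclusive, and the motif anchor
used by every positional analysis is the first proline of the run — the
stalling event happens at the prolines, not in the upstream context.

Strength classification is driven by a rule table with two layers:

* an *effect class* (weak / medium / strong) for every standard residue at
  each of the three flank positions, anchored on the experimentally
  established contexts — APP, D/PP/D, G/PP/G, PPW, PPN and PPP arrest
  strongly; L/PP/L, CPP and HPP pause only weakly; at X(−2), H, K, Q, R and W
  pronounce the arrest while C, G, L, S and T attenuate it;
* a *combination rule* over (run-length category, effect triple): n ≥ 3 is
  always STRONG (PPP is itself a strong arrester); for a diproline the base
  class is the strongest effect among X(−1) and X(+1), promoted one rank by a
  strong-effect X(−2) and demoted one rank by a weak-effect X(−2), clamped to
  [WEAK, STRONG].

The packaged table (`inst/extdata/stalling_rules.yaml`) enumerates the full
54-key rule grid so no lookup can fail; `validate_rule_table()` enforces
totality. Residues without direct experimental characterisation sit in the
neutral (medium-effect) class; the table is a serialisable user-replaceable
input, not hard-wired behaviour.

Two edge policies matter in practice. Motifs whose present flanks include a
non-standard letter (X, B, ...) are `UNCLASSIFIED`: counted in raw occurrence
totals, excluded from every strength-stratified analysis. Motifs at a
sequence terminus have missing flanks; excluding them would silently bias the
N-terminal ramp analysis, so by default a missing X(−1)/X(+1) contributes the
weak-effect base and a missing X(−2) contributes no modulation (a nonexistent
residue can neither pronounce nor attenuate the arrest). The alternative
policy (`missing_policy = "exclude"`) is available for sensitivity analysis.

## Null models

**Shuffle null.** Each sequence is permuted uniformly at random, preserving
its exact composition; the fold change is N_obs divided by the mean motif
count over R replicates (default R = 1000). Counts are summed over all
sequences *within* a replicate before any ratio is formed: per-sequence
ratios are undefined for motif-free sequences, and population-level figures
require the aggregate. The vector of R ratios N_obs/count_r supports
Mann–Whitney–Wilcoxon comparisons between two sequence populations. Note a
property inherent to this design: the rank-sum test compares replicate noise
against the *realised* difference between two populations, so at large R it
will detect even a chance difference in realised motif density; calibration
tests therefore use populations with identical sequence content, and effect
tests use planted effects well above realisation noise. Empirical p-values
use the pseudocount form (1 + k)/(R + 1) so p = 0 is unattainable. Replicate
r of sequence i draws its seed deterministically from (root seed, r, i)
through a multiplicative mixing scheme (`derive_seed`), making every run
bit-reproducible.

**Markov M0 null.** For region-level tests the null is a zero-order Markov
(i.i.d.) model whose letter frequencies are estimated from the exact
sequence set under test — whole proteome for proteome-level tests, the
extracted segments for region tests — and the statistic is the overlapping
count of the diproline word PP (a run of m prolines contributes m − 1). For
one sequence of length L the expectation is (L − 1)f_P²; the variance adds
the lag-1 self-overlap covariance, Var = (L−1)f_P²(1−f_P²) +
2(L−2)(f_P³ − f_P⁴), summed over sequences. Below a configurable total
length (default 2000 residues) the p-value is computed exactly by a dynamic
program over (count, trailing-run-length) states, convolved across
sequences; above it, a Gaussian approximation with continuity correction is
used. The exact distribution is validated against exhaustive enumeration;
the Gaussian tail differs from the exact one by at most ≈ 0.02 near the
distribution's mode in the regimes the tests probe (the skew a normal cannot
represent), which is immaterial for the significance calls made from it.

The fold-change ratio in `region_enrichment` uses the same overlapping word
count in the numerator; a maximal-stretch count over an i.i.d. null
expectation would calibrate to (1 − f_P)², not 1.

## Pan-proteome comparison

An orthologous group is core iff it has at least one member in every strain
under consideration — paralog multiplicity is deliberately ignored, since
presence, not copy number, defines the core. Proteins in no group are
accessory by definition. Core/accessory motif occurrence is compared per
strain (each strain's proteome is shuffle-normalised independently), with
strength strata available through classified counting.

## Evolution of stalling states

Leaves of each group's tree carry one of four states,
NONE < WEAK < MEDIUM < STRONG, taken from the strongest motif overlapping a
*motif-bearing aligned region*: each motif's proline stretch is mapped
through the gap structure to alignment columns and overlapping column
intervals from different sequences are merged transitively, so a stretch that
is split or shifted across orthologs still lands in one comparable region. A
leaf whose only overlapping motifs are unclassifiable contributes NONE; a
motif fragmented by internal gaps is flagged. Region extraction requires ≥ 1
shared column between motif and region.

Trees arrive with branch lengths (tree inference is upstream) and are
midpoint-rooted: the root bisects the longest leaf-to-leaf path, ties broken
deterministically toward the lexicographically smallest leaf pair, with all
pairwise path lengths preserved (the edge search is implemented here; the
actual edge-splitting surgery uses `phytools::reroot`).

Reconstruction uses the symmetric 4-state Mk model — the minimal assumption
when only "maximum likelihood" is specified — with transition probability
p_same(t) = 1/4 + (3/4)e^(−4αt). The single rate α is maximised by bounded
one-dimensional search over log α in [10⁻⁶, 100] (the likelihood plateaus at
high rates, where a linear-scale golden-section search can stall), per
region by default. Internal nodes take the state of maximal marginal
posterior under a uniform root prior; ties go to the weaker state, a
conservative choice against inferring gains. Ordered-state (stepwise) models
are out of scope.

A branch whose child outranks its parent carries a gain, the reverse a loss;
terminal branches count like internal ones. PSEC is the difference between
the gain and loss propensities: B_g/B_cg − B_l/B_cl, where a branch is
gain-capable iff its parent is not already STRONG and loss-capable iff its
parent is not NONE (a branch can be both); a zero denominator contributes 0,
keeping PSEC defined on saturated trees. PSEC ∈ [−1, 1]; negative values
mean the stalling effect tends to be lost.

One bias is worth knowing about: when leaf states are close to random on a
small tree, the ML rate saturates, marginal posteriors flatten toward
uniformity, and the weak-state tie-break plants weak ancestors under strong
leaves — which reads as gains. Reconstruction-based PSEC on *unbiased*
simulations therefore averages slightly above zero (≈ +0.04 at 10 leaves,
α = 0.25). The generator-symmetry calibration consequently evaluates PSEC on
the recorded true histories, while reconstruction itself is validated
exactly against brute-force enumeration, and directional *recovery* is
tested where direction is identifiable (dominant root state; see below).

## Positional analyses

The N-terminal ramp test cuts each protein at residue 50 (configurable); a
motif belongs to the segment containing its anchor; each segment population
is shuffled within itself so each has its own composition-matched null.
Inter-domain linkers span [end+1, start−1] between consecutive domains and
are extended *downstream* (into the next domain) to a minimum of 5 residues,
clipped at the protein end — so abutting domains still yield a 5-residue
linker.

Boundary profiles count motif anchors at offsets relative to anchor
instances (domain starts/ends, TMH starts); offset 0 is the anchor residue
itself, negative offsets upstream. Frequencies are normalised by the number
of instances whose protein covers each offset and smoothed with a 3-point
moving average (edges average the available points).

TMH site intervals follow the convention their definition forces: positive
offsets are 1-based positions counted from the TMH start (+1 = the start
residue), negative offsets upstream (−1 immediately before the start), no
offset 0 — site I = −17..−1 abuts the start and site II = 23..32 begins just
past a canonical 21-residue helix. A site instance is located "in TMH" if
its midpoint residue lies inside any annotated helix (robust to partial
overlap); instances extending beyond the protein are dropped. The 21-residue
typical TMH length is a description of the annotation, never an input to
computation. The transmembrane-vs-soluble motif-bearing proportion uses a
2×2 chi-squared test without continuity correction (counts in the hundreds).

## Expression coupling

Translation efficiency is the exact ratio abundance/transcription, computed
on the genes present in both tables (intersection semantics). "Motif
density" is motifs per 100 residues — length normalisation prevents protein
length from confounding the correlation; a raw-count mode exists. Spearman's
rank correlation is used as is (log transforms would not change it).
Profiling concordance is the fraction of genes above a stall-score threshold
(2, 3, 5) that carry at least one MEDIUM or STRONG motif; genes missing from
the motif table count as motif-free.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with ground truth
recorded, under a single seed that fully determines the output:

* **Proteomes** — i.i.d. sequences with the E. coli K-12 amino-acid
  composition (f_P ≈ 0.044), lognormal lengths with median 300 residues
  (sdlog 0.35, floor 60), 4500 proteins by default: a typical bacterial
  proteome. Motif planting *overwrites* letters (lengths and the length
  distribution stay intact; the small composition perturbation is accepted
  and visible to the shuffle null) at non-overlapping anchors, with flank
  recipes realising each requested strength class under the packaged rules.
  Incidental stretches arising by chance are part of the recorded truth.
* **Pan-genomes** — default 43 strains (the strain count of the reference
  system); core groups in every strain, accessory groups in random subsets.
  A core motif deficit is planted as *retention*: equal planting everywhere,
  then each core stretch kept with probability `core_density_factor` (a
  disrupted stretch keeps one proline), emulating evolutionary loss while
  leaving composition nearly unchanged — additive density differences would
  be largely cancelled by the composition-matched null.
* **State histories** — pure-birth trees (`ape::rphylo`; one parameter is
  enough for reconstruction tests) with a 4-state continuous-time jump
  process from the root, optional directional rate bias, every transition
  recorded.
* **Annotations** — two ~80–110-residue domains per sufficiently long
  protein; TMHs with length mode 21 on a configurable fraction of proteins,
  spaced so that downstream sites fall in inter-helix space; optional
  planting into boundary windows or site III.
* **Expression** — a Gaussian copula on normal scores of the density ranks
  with Pearson parameter r = 2·sin(πρ/6) hits a target Spearman ρ (default
  −0.105); transcription is lognormal and abundance = TE × transcription, so
  the efficiency ratio is exact. Ties from zero-motif proteins shrink the
  attainable |ρ| slightly; planting weak motifs at 0.3/100 aa in the
  correlation tests keeps the tie mass small.

What the generators do **not** emulate: real homology (group members are
independent sequences, not diverged copies), indels and alignment
uncertainty beyond simple planted gaps, real domain architectures and signal
peptides, codon-level effects, and correlated measurement error in
expression data. Passing tests demonstrate that the estimators recover known
structure under the stated stochastic models — not that real proteomes
satisfy those models.

## Problem sizes and numerical choices

The test suite and the acceptance script scale the study conditions to
desk size, chosen once: scanner/oracle agreement on 10,000 random sequences;
exact-distribution checks at total length ≤ 12 over a two-letter alphabet;
brute-force reconstruction oracles on ≤ 6 leaves; null calibration on
250–1000-protein proteomes with 59–100 shuffle replicates; planted-recovery
runs at 500 orthologous groups / 2 strains (R = 99), 100 simulations for
positional detection, 500 regions for PSEC symmetry, 200 replicates of
43-leaf loss-only histories (α = 0.05 — low enough that the dominant root
state remains identifiable, high enough that nearly every tree records an
event), and 100 expression draws at n = 1743. Other constants: rate bounds
[10⁻⁶, 100]; exact-p-value threshold 2000 residues; posterior tie tolerance
10⁻¹²; frequency-sum tolerance 10⁻⁹; all-zero-branch-length trees are rooted
at a deterministic leaf and flagged.

## Known limitations

* The rule table's residues without direct experimental support default to
  the neutral class; classifications are only as sharp as the table.
* The symmetric Mk model ignores the ordering of stalling states; an ordered
  model would borrow strength across adjacent ranks at the cost of extra
  assumptions.
* Reconstruction-based PSEC carries the saturation bias described above;
  cohort comparisons between strata (core vs accessory) share the bias and
  remain interpretable, absolute values near zero do not.
* The Markov machinery covers homopolymer proline words only — that is the
  statistic of interest here, not a general pattern engine.
* Rank-sum comparisons of shuffle-ratio vectors grow arbitrarily sensitive
  with R (they test the realised difference); treat their p-values as
  evidence about the dataset at hand, not about a sampling universe of
  proteomes.
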