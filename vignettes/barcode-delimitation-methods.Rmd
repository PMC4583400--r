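---
title: "Methods: distance- and tree-based OTU delimitation in barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance- and tree-based OTU delimitation in barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

barcodegap delimits operational taxonomic units (OTUs) from aligned
mitochondrial COI barcodes and confronts the molecular partitions with
morphospecies labels.  This vignette explains the models, the numerical
choices behind them, and what the synthetic-data generator does and does
not emulate, so that results can be interpreted with the right caveats.

## Distances

All distance work uses the Kimura 2-parameter model with *pairwise
deletion*: for a pair of sequences only the columns where both carry an
unambiguous base (A, C, G, T) are used.  With transition proportion $P$
and transversion proportion $Q$ over those columns,

$$d = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q).$$

Three edge policies matter and are deliberate:

* **Zero overlap** (two fragments that share no columns) gives an
  *undefined* distance stored as `NA`.  A distance is never invented;
  clustering treats such pairs as "above any threshold" and tree
  builders refuse matrices containing them.
* **Saturation** ($1-2P-Q \le 0$ or $1-2Q \le 0$) gives `Inf`, flagged,
  with the same downstream meaning.
* Ambiguity codes and `N` are missing data everywhere, matching the
  pairwise-deletion convention of the distance tools commonly used for
  barcode surveys.

The whole-matrix kernel computes transition/transversion/overlap counts
for all pairs at once from indicator-matrix cross-products, so a
~2800-sequence alignment takes seconds; the per-pair closed form is kept
as an independent code path and the two are cross-checked in the tests,
together with `ape::dist.dna` as an external reference.

Haplotype collapsing removes a record when a kept record agrees with it
on every shared unambiguous column *and* covers at least its sequenced
columns, so short fragments collapse into compatible longer sequences.
Among mutually identical records the first in input order wins, making
the operation deterministic and idempotent.  Because fragment-overlap
semantics differ between deduplication tools, counts on real data should
be treated as approximate to within a few sequences.

## Objective clustering and the distance histogram

Objective clustering at threshold $t$ returns the connected components
of the graph with an edge wherever $d_{ij} \le t$ (single linkage).  The
boundary is *inclusive*; this choice is declared because published
cluster counts depend on it.  Undefined and saturated pairs never create
edges.  Sequences whose every pair is undefined can either remain as
singletons (default) or be dropped (`missing = "drop"`), since tools
differ in how they count such sequences.

The threshold sweep is monotone by construction (components only merge
as $t$ grows), and the pairwise-distance histogram reports the raw
material of the "barcode gap": a band of empty bins between the
within-species and between-species modes.  Genus-scale surveys typically
show *no* clean global gap — the local, per-group gap is what ABGD
exploits.

## ABGD-style gap discovery

The automatic barcode gap discovery procedure published with the web
tool leaves several internals unspecified, so this implementation fixes
and exposes them in `abgd_config()`:

* the candidate gap is the first spacing between consecutive ranked
  distances exceeding `X` (default 1.5) times the trailing local average
  spacing, estimated over a sliding window of `max(10, n/100)` ranked
  pairs;
* only spacings ending above the prior `P` (the maximal prior
  intraspecific divergence) qualify — the gap must lie above the
  within-species region the prior asserts;
* a spacing after a run of ties (local average zero) always qualifies;
* when no gap is found the partition falls back to components at
  $d \le P$, so a prior sweep is total; the fallback is recorded in the
  partition's provenance.

The initial partition takes components under $d < \text{gap}$; with
recursion on (default), gap inference is re-applied inside each group on
its internal distances until no group splits.  The recursive partition
always refines the initial one.  Note the interplay with the prior:
priors *below* the actual within-species variation license recursive
splitting of genuine species — that is the documented behaviour of
recursive ABGD at small priors, and the reason published prior sweeps
report high counts at the small end.  Recovery of a planted species
count should be expected only for priors between the within-species
variation and the gap.

## Single-threshold GMYC

For a rooted ultrametric tree, the generalized mixed Yule-coalescent
model places a threshold age $T$ between consecutive branching times:
nodes older than $T$ are diversification events among entity-level
lineages, younger nodes are coalescences within entities.  Each
waiting interval contributes an exponential density with total rate

$$\lambda_1\,k(t)^{p_1} + \lambda_2 \sum_j n_j(t)\,(n_j(t)-1)^{p_2},$$

with $k(t)$ entity lineages and $n_j(t)$ lineages inside entity $j$;
each branching event contributes its own class's rate evaluated with
the configuration of the interval on its tip-ward side (the
coalescent-style bookkeeping, which keeps the first split inside an
entity at a positive rate).  For fixed exponents the rate MLEs are
closed-form, so each class is profiled with a one-dimensional search
over its exponent (interval `p_range`, default `[0, 5]`).

Design choices that required a decision:

* **Exponents are free by default.**  The single-process null must be
  able to mimic a coalescent ($b \propto n^2$-ish) as well as a Yule
  ($b \propto n$) clock; pinning $p = 1$ makes every single-species
  coalescent tree reject the null, which destroys the test's
  calibration.  `fixed_p = TRUE` restores the pinned variant.
* **The null is the all-diversification threshold**, so the alternative
  nests it and the likelihood ratio is non-negative by construction.
* **The LR is referred to $\chi^2_3$** (two extra parameters plus the
  threshold), the classic choice for this test.  On simulated
  single-species coalescent trees the empirical false-positive rate at
  $\alpha = 0.05$ is about 0.02 — mildly conservative, as reported for
  this test in the delimitation literature.
* **Zero-height clades are collapsed before fitting.**  Identical
  haplotypes contribute zero-length waiting intervals whose profiled
  rate diverges, letting the "likelihood" of a threshold isolating them
  grow without bound.  Clades with crown height numerically zero are
  therefore reduced to one representative tip (the delimitation-scale
  analogue of fitting GMYC to unique haplotypes) and re-attached to the
  representative's entity afterwards.
* **Remaining tied branching times are spread**, deterministically, over
  a quarter of the gap down to the next distinct age (parents staying
  older than children).  An additive epsilon jitter was rejected: it
  creates epsilon-length intervals whose log-likelihood contribution is
  $-\log \varepsilon$, and the ML threshold then locks onto the tie
  boundary as $\varepsilon \to 0$.
* When the null is not rejected the tree is consistent with one
  species; `n_meaningful_entities` reports 1 in that case while the ML
  entity count is still available.

The 2-log-likelihood window over thresholds gives the reported
confidence set of entity counts.

## Maximum-likelihood PTP

The Poisson tree process models within-species and between-species
branch lengths of a rooted phylogram as two exponential classes.  A
delimitation is an antichain of species-root nodes covering all tips;
edges strictly inside a species subtree are "within", stems and backbone
are "between".  Rates profile out, so a delimitation's log-likelihood is
$\sum_c N_c(\log(N_c/L_c) - 1)$ over the two classes.

The search is a seeded greedy hill climb (split a species root into its
children / merge a complete sibling set into its parent, best strictly
improving move first) from many starts: the single-class fit, the
all-singletons fit, antichains cut at a grid of subtree-height
quantiles, and random antichains.  The cut starts matter: on trees with
hundreds of tips the root and tip starts alone stall in local optima
far below the species partition.  The accepted-move trace within a
climb is non-decreasing, and the best final likelihood wins.

Branch lengths below `min_branch` (default $10^{-4}$ substitutions/site)
are floored before fitting, because a class consisting of zero-length
branches has an unbounded rate estimate — the same degeneracy as in
GMYC, handled the same way as the minimum-branch-length options of
standard PTP implementations.

Two caveats belong with any PTP reading.  The unpenalised ML criterion
is known to oversplit: on trees simulated exactly from the two-rate
model (within $\sim$Exp(100), between $\sim$Exp(5), 8 species of 5
tips) the *global* ML partition differs from the generating one in
roughly a quarter of replicates — verified here by checking that the
fitted likelihood strictly exceeds the true partition's in every such
case.  And on distance-derived trees (UPGMA/NJ rather than an ML
phylogram) the branch lengths only approximate substitution counts, so
PTP tends to return the highest OTU count of all methods — the same
ordering the published genus-scale surveys report.

## Trees

Neighbor joining is delegated to `ape::nj` on a fully defined matrix;
the additive-recovery and order-invariance properties are asserted in
the tests.  Negative NJ branches are clamped to zero with the deficit
moved to the sister branch, preserving path lengths through the parent
— a convention documented because it changes lengths, never topology.
UPGMA (average linkage, node height = half the between-cluster mean)
supplies the rooted ultrametric trees GMYC needs; any user-supplied
ultrametric newick works equally, and on real surveys a clock-dated
tree is the better input where one is available.  Bootstrap support
resamples alignment columns with replacement, drops replicates whose
resampled matrices contain undefined pairs (counting and warning), and
reports integer percent occurrence of each reference bipartition.

## Comparing partitions with morphospecies

Name propagation follows the survey convention for sequences identified
only to genus level: a group with exactly one named morphospecies
donates its name; a group with none receives one fresh `cluster_xxx`
code (or adopts the group's single existing informal code); a group
with two or more named species is flagged as a conflict and its
genus-only members stay unnamed.  Species-level identifications are
never renamed.

A named species is *discriminated* when no OTU containing its sequences
also contains a different named species; a species split over several
pure OTUs still counts.  Because the literature is ambiguous about
whether informal (group-code) morphospecies belong in the denominator,
both rates are reported.  Divergence summaries give per-species and
per-species-pair tables plus global figures; the global mean
intraspecific divergence is the *unweighted* mean over species of
within-species means (matching the within-groups table convention),
with the pooled pair-weighted mean alongside, and the mean
interspecific divergence is reported both over sequence pairs and over
species-pair means, since published tables rarely state which was used.

## The synthetic-data generator

`sim_config()` defaults describe a genus-scale COI survey:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 121 | morphospecies on the species tree |
| `yule_rate` | 35 | birth rate (per subs/site of depth) of the species tree |
| `stem_floor` | 0.05 | minimum extra terminal-branch length (subs/site) |
| `theta` | 0.023 | expected within-species pairwise distance |
| `zipf_exponent`, `min_n`, `max_n` | 1.4, 1, 430 | skewed barcodes-per-species law |
| `seq_length`, `min_length` | 658, 507 | alignment width; truncation floor |
| `full_length_prob` | 798/2790 | fraction kept at full length |
| `kappa` | 8 | transition/transversion rate ratio |
| `codon_rates` | 0.35, 0.08, 2.57 | relative rates of codon positions |
| `base_freqs` | AT-rich pos. 3 | per-position equilibrium composition |
| `genus_only_fraction` | 1242/2790 | labels downgraded to genus level |

Branch lengths are in expected substitutions per site throughout, so
`theta` reads directly as a within-species distance.  The `stem_floor`
exists because a pure birth process yields arbitrarily recent splits,
whereas morphologically recognised species are not that young; without
it a large fraction of simulated sister species are molecularly
indistinguishable, which no morphospecies inventory would mirror.  The
`yule_rate`/`stem_floor`/`theta` defaults were calibrated once so that
the *observed* K2P structure of a default draw matches the statistical
shape such surveys report — mean intraspecific divergence near 2%,
mean interspecific near 16% with a maximum in the mid-20s, a strongly
AT-biased third position near 87.6%, and several thousand sequences
with 1–430 barcodes per species — and are not meant to be revisited
per analysis.

Within-species genealogies are neutral coalescents grafted onto
terminal branches (rescaled to fit when deeper than 95% of the branch,
which bounds within-species divergence on short stems).  Sequences
evolve under an HKY-like process with per-codon-position rates and
frequencies; in-frame stop codons of the invertebrate mitochondrial
code are then repaired, emulating the purifying selection that makes
reading frames detectable in real barcodes.  Note the deliberate model
mismatch: data are generated AT-biased and rate-heterogeneous but
analysed with K2P, exactly as real COI is; third-position saturation
therefore compresses large observed distances relative to the true
divergence.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show about real data: misidentified or synonymous
morphospecies (simulated discrimination is typically 100%, real surveys
lose a few percent to taxonomy, e.g. misidentifications and synonyms),
cryptic species complexes with 20%+ "intraspecific" divergence,
introgression and incomplete lineage sorting (one locus, no gene-tree
conflict), NUMTs and contamination, indels, and geographic population
structure.  A single simulated locus also carries one realised ancestral
composition, so per-dataset base composition wobbles around its
equilibrium with a standard deviation near two percentage points.

## Problem sizes

The test suite runs entirely on simulated data: property checks use
3–50 sequences, the delimiter recovery studies use 20 replicates of
10-species (50-tip) trees and 100 single-species coalescent trees, and
the pipeline checks use 5-species alignments — sizes chosen so the
whole suite stays fast while every code path is exercised.  The
acceptance script runs the full pipeline once at the default study
scale (~2500–3100 sequences, 121 species) in about a minute.
Replication checks against the published survey require its
2790-sequence supplementary alignment, which cannot be redistributed
with the package; place it at
`inst/extdata/DS-TABAC_alignment.fasta` (or set
`options(barcodegap.study_alignment = ...)`) and the corresponding
tests run against it.

## Known limitations

Single-threshold GMYC only (no multiple thresholds); ML PTP only (no
Bayesian support values); no GTR-family distances; no alignment
construction; the BIN/refined-single-linkage OTU system of the
reference databases is out of scope.  UPGMA is a deliberately crude
stand-in for clock-dated trees, and delimitation counts from it should
be read as method-family indications, not point estimates.
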