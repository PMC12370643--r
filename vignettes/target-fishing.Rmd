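---
title: "Similarity-centric target fishing and the role of the similarity threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-centric target fishing and the role of the similarity threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tanifish)
```

## The problem

Most bioactive small molecules have incompletely characterised target
profiles.  Computational target fishing (TF) inverts the virtual-screening
question: given a query molecule, which proteins is it likely to bind?
Similarity-centric TF answers it with the similar-property principle --
structurally similar molecules tend to share targets.  Each candidate
protein is represented by its known ligands in a curated bioactivity
library; the query is compared against every reference ligand with a 2D
fingerprint, and each target is scored from the similarities of its
ligands to the query.  The ranked target list is the prediction.

A bare ranking, however, carries no notion of *confidence*: a target can
be ranked first simply because nothing in the library resembles the query.
tanifish therefore implements, alongside the baseline models, the
confidence machinery that turns a ranking into a defensible shortlist:
fingerprint-specific similarity thresholds, precision/recall/F1 sweeps,
binned precision profiles, and enrichment-rate statistics.

## Reference-library curation

Raw records (ligand, SMILES, target, activity type, value, unit, source)
are pooled per ligand-target pair across activity types (IC50, Ki, Kd,
EC50) and sources after harmonisation to nM.  A pair is retained only when
its measurements agree within an order of magnitude -- operationalised as
max/min <= 10, inclusive -- and the median of the concordant set (for even
counts, the mean of the two central values) is the definitive activity.
Only potent pairs (median < 1 µM, strict) enter the library.  Discordant
order of application matters: concordance is tested before potency, so a
weak pair must first be internally consistent to be classified as weak.

Structures are standardized before identity checks (largest organic
fragment, canonical SMILES via OpenBabel; optional neutralization of ±1
charges), and ligand identity is taken at the identifier level: two
accessions with identical structures remain distinct ligands.  This
matters for leave-one-out evaluation, where `excludeBy = "structure"` is
available precisely to remove such twins when desired.  Censored values
("> 10 µM") are not modelled; the input schema carries exact values only.

Targets whose every pair is discarded stay in the target table flagged
unpredictable, so the library remains an honest record of what was seen.
Curation is idempotent and invariant to record order.

## Fingerprints and scoring schemes

Eight 2D fingerprint families are supported, all 1024-bit except MACCS
(166 predefined substructure keys):

| kind | feature family | implementation |
|------|----------------|----------------|
| ECFP4 | circular environments, radius 2 | OpenBabel ECFP4, folded 4096 to 1024 |
| FCFP4 | circular environments over functional classes | package graph-hashing |
| AtomPair | atom pairs with topological distance | ChemmineR descriptors, folded |
| Torsion | four-atom topological torsions | package graph-hashing |
| Path | linear fragments up to 7 atoms | OpenBabel FP2 |
| Layered | paths typed in bond/element/ring layers | package graph-hashing |
| Avalon | hashed path and feature-class enumeration | package graph-hashing |
| MACCS | 166 substructure keys | OpenBabel MACCS |

The graph-hashing implementations work on a kekulized molecular graph with
approximate perception (implicit hydrogens from default valences adjusted
by formal charge; an atom is "aromatic" when it sits in a ring and either
carries a double bond or is a ring N/O/S).  These approximations only
affect the four hand-built families and shift which bits are set, not the
determinism or the similarity structure the package relies on; the
OpenBabel-backed families use OpenBabel's own perception.

Similarity is the Tanimoto coefficient Tc = |A∩B| / |A∪B|.  Two all-zero
fingerprints score 0, not 1: a featureless fragment is no evidence of
similarity.  Targets are scored by

* **MaxTc** -- similarity of the nearest reference ligand,
* **KNNTc** -- mean over the K nearest (K falls back to all available
  ligands for sparse targets, so MaxTc ≡ KNNTc(1) and MeanTc ≡ KNNTc(∞)),
* **MeanTc** -- mean over all ligands of the target.

Ranking is deterministic: score descending, ties broken by target id.
Every prediction entry carries `best_similarity`, the top-1 Tc to that
target, because the threshold machinery filters on the nearest ligand
regardless of the scoring scheme.

## Ensembles

Two fusion rules combine prediction lists from different fingerprints.
The similarity ensemble z-standardizes each member's per-target scores --
(x − µ)/σ with σ the *population* standard deviation over the scored
targets (σ = 0 degenerates to all-zero z-scores) -- and sums them.  The
rank-order ensemble sums ordinal ranks; smaller sums are better, so the
fused list is ranked ascending.  Fusion applies to targets scored by all
members; `enumerateCombinations()` enumerates the 2^8 − 8 − 1 = 247
multi-fingerprint subsets.  Member scores default to MaxTc, the scheme the
single-fingerprint analysis adopts.

## Validation design

Evaluation uses a leave-one-out-like CV rather than n-fold CV so the
reference library stays intact for every event.  The validation set is
scaffold-stratified: per target, ligands are grouped by Bemis-Murcko
scaffold (ring systems plus linkers after pruning acyclic side chains;
atoms double-bonded to the framework are kept; acyclic molecules share one
"acyclic" group).  Targets with fewer than 70 distinct scaffolds
contribute ceiling(30% of scaffolds) -- ceiling, with the minimum of one
ligand per target -- and targets with 70 or more contribute 20, one ligand
per sampled scaffold.  A ligand selected for several targets becomes a
single event carrying all its known targets.  Sampling requires an
explicit seed and is fully reproducible.

For each event the query is removed from every target's ligand list by
identifier (default) or by identical standardized structure, and the rest
of the library is scored.  A target whose only ligand was the query is
unpredictable for that event; events whose every known target is
unpredictable are retained and contribute false negatives.

Metrics are micro-averaged: TP/FP/FN are pooled over events before
computing RE_n = TP/(TP+FN), PR_n = TP/(TP+FP) and their harmonic mean F1
(precision is defined as 0 with nothing retained, F1 as 0 when both terms
are 0).  Events with more known targets than n cap achievable RE_n below
1; the formula is kept as defined, with no renormalisation.  Recall folds
over random picking are RE_n / (n/T).  Stratified reports split by query
promiscuity, by cumulative reference-ligand-count baskets ("targets with
at least x ligands"), or by target class; per-target strata restrict the
known pairs, so class recalls recombine exactly to the global recall as a
weighted mean.

## Similarity thresholds

`applyThreshold()` drops entries whose best similarity falls below τ and
deliberately does *not* renumber ranks: "top-10" always means the top 10
of the unfiltered ranking, then filtered, which keeps threshold analyses
comparable across τ.  `thresholdSweep()` evaluates the 0.01-step grid on
[0, 1], reports the precision-recall curve, and extracts two calibrated
thresholds:

* **τ_TP**, the true-positive onset: the lower edge of the first 10-bin
  precision-profile bin containing any true positive (or exceeding a
  configurable precision floor).  Below it, a predicted target is noise
  regardless of rank.
* **τ_F1**, the balanced threshold: the smallest grid point attaining the
  maximum F1, reported at the 0.01 resolution of the grid.

The improved enrichment rate quantifies what a threshold buys: at matched
recall the number of targets that must be picked per true positive is the
inverse precision, so the fold reduction relative to no threshold is
PR_n(τ) / PR_n(0).  It is 1 at τ = 0 by construction.  Only RE_n and the
retained-prediction count are guaranteed monotone in τ; PR_n is not, and
the test suite asserts exactly the documented monotonicities.

## The synthetic fixture generator

Real TF libraries are built from large public bioactivity databases, whose
scale and licensing make them unsuitable as test fixtures.  The generator
instead produces miniature libraries with the *structure* the method
assumes: each target family decorates a distinct parent ring system
(benzene, pyridine, thiophene, cyclohexane, ...); scaffold variants link a
second family ring through alkyl chains; ligands are combinatorial
substituent decorations from a fixed alphabet (halogens, alkyl, hydroxy,
amino, methoxy, nitro).  Within-family fingerprint similarity is therefore
high and cross-family similarity low by construction.  Promiscuous ligands
are assigned to extra targets; replicate activities are multiplicative
log-normal with the median pinned per pair, discordant pairs get one
injected >10x outlier, and weak pairs draw medians above 1 µM -- so the
discordant and weak fractions are met exactly and every pair carries a
ground-truth curation label.

Default conditions: 5 targets × 4 scaffold variants × 5 ligands (100
ligands), 10% promiscuous ligands binding 2 targets, up to 3 replicates,
5% discordant and 5% weak pairs, activities log-normal around 50 nM
(sdlog 0.8).  Held-out analog queries are new decorations that do not
occur in the library, with an answer key for stratified tests.

What the fixture does *not* emulate: realistic property distributions,
target-class proportions, activity cliffs, or the scale of public
libraries.  Passing tests therefore demonstrate correctness of the
machinery and recoverability under clean separation -- not the absolute
recall levels reachable on a real reference library, which depend on
library density and are out of scope here.

## Numerical choices

* Tie-breaks: ranking ties by target id; nearest-ligand ties by ligand id.
* Tc of two empty fingerprints is 0 (pessimistic).
* z-scores use the population SD; σ = 0 yields all-zero z-scores.
* Precision bins are half-open [lo, hi) with the last bin closed at 1.
* Validation sampling uses ceiling with a one-ligand minimum per target.
* K > available ligands falls back to all available.
* All randomised steps take explicit seeds; CLI manifests record them.

Problem sizes in the shipped tests and acceptance script (5-target
fixtures, 25-50 held-out queries, 28-247 ensemble combinations) were
chosen as the smallest sets on which the similarity structure is stable;
the whole suite runs in well under a minute per file.

## Known limitations

* The four graph-hashed fingerprint families are this package's own
  hashed variants of the named feature classes, not bit-compatible with
  other toolkits' implementations of the same names.
* Aromaticity and implicit-hydrogen perception in the internal graph layer
  are approximate (see above).
* Scaffold definitions differ slightly across toolkits; since scaffolds
  only drive validation-set sampling, this affects which ligands are
  sampled, not how they are scored.
* No machine-learned secondary filter is provided; the package is the
  similarity-centric baseline such filters sit on top of.
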