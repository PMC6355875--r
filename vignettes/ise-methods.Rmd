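---
title: "Descriptor-range filter models for virtual screening: methods and design"
author: "iseScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-range filter models for virtual screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iseScreen)
```

# The screening problem

Given a few hundred confirmed actives against a protein target and a
large library of commercially available molecules, the task is to rank
the library so that the handful of molecules one can afford to test
contains as many true actives as possible. iseScreen approaches this
with two ideas that deliberately avoid scaffold similarity. First,
molecules are represented purely by physico-chemical descriptors (2D
properties such as molecular weight, cLogP, H-bond donor/acceptor
counts, ring and rotatable-bond counts), so structurally novel
chemotypes can score well. Second, candidate molecules that survive the
descriptor model are docked into reference crystal structures and
accepted on *geometric* grounds — reproducing the contact pattern the
crystallographic ligands make — rather than on docking energies, whose
force-field approximations are unreliable at ranking.

# The filter model

## Filters and the balanced MCC

A filter is a conjunction of `k` closed intervals over named
descriptors; a molecule passes when every value lies inside its
interval, boundaries included. Closed intervals matter: clause bounds
are empirical quantiles of the actives, so the extreme actives sit
exactly on a bound and must pass.

Filters are scored on a labeled training set by a class-balanced
Matthews correlation. With `nA` actives and `nI` inactives, the
inactive-side counts are rescaled by `s = nA/nI` (`FP' = s FP`,
`TN' = s TN`) before the usual MCC formula. This is algebraically the
MCC of a dataset where each active row is replicated `nI` times and
each inactive `nA` times — a property the test suite asserts over
random confusion tables — and it stops a 10- to 25-fold excess of
inactives from drowning the sensitivity term. A zero factor in the
denominator yields 0 by the usual convention, so a filter that passes
(or rejects) everything scores 0, never `NaN`.

## Iterative stochastic elimination

The space of filters is combinatorial: with `p` descriptors, `C(p, k)`
subsets times all range assignments. ISE searches it by attrition:

1. sample `filtersPerIteration` random filters (descriptors uniform
   without replacement, ranges drawn from the quantile grid), score
   them;
2. attribute to each descriptor the mean balanced MCC of the sampled
   filters containing it, and remove the worst `elimFraction` of the
   pool (at least one, ties broken by name order, never below `k`);
3. repeat until `C(|pool|, k)` is at most `exhaustiveMax`, then
   enumerate every remaining k-subset, optimizing each subset's range
   assignment over the quantile grid by coordinate ascent (clauses
   start at the actives' full span; each clause in turn moves to the
   grid pair maximizing the filter's MCC until a sweep changes
   nothing);
4. deduplicate (two filters agreeing on more than `dedupOverlap` of the
   molecules' pass/fail outcomes are one filter; the higher MCC wins)
   and keep every filter with MCC at least `(1 - bandFraction)` times
   the best.

All randomness flows through one seed recorded in the model file, so a
training run is exactly reproducible.

## Parameter defaults and why

* **`k = 4`** clauses per filter. Small conjunctions keep filters
  interpretable and their sensitivity high; with per-clause sensitivity
  `t`, a k-clause filter retains about `t^k` of the actives, which
  already argues against large `k`.
* **`quantileProbs = deciles`.** Clause bounds are drawn from the
  actives' empirical deciles. A coarse grid bounds the search space and
  regularizes: bounds can only sit where the actives have mass.
* **Stochastic-phase ranges are wide quantile pairs** (spanning at
  least 80% of the grid). This is the one place the package is
  opinionated about sampling. The sampled filters exist to *attribute
  quality to descriptors*, not to be the final model. With narrow
  random ranges, a conjunction of four of them keeps almost no actives,
  every filter scores near zero, and the per-descriptor mean that
  drives elimination degenerates into noise — in our experiments this
  reliably eliminated truly informative descriptors once the pool got
  small. With near-full spans, every added informative clause keeps
  sensitivity near 1 while multiplying the false-positive rate down, so
  filter MCC grows monotonically with the number of informative clauses
  it contains and the attribution stays sharp. The exhaustive phase is
  unaffected: it searches *all* grid pairs.
* **`filtersPerIteration = 500`.** At a 50-descriptor pool this gives
  every descriptor about 40 appearances per iteration, enough for a
  stable mean; the cost is negligible next to the exhaustive phase.
* **`elimFraction = 0.2`.** A fifth of the pool per iteration reaches a
  small pool in under a dozen iterations without betting everything on
  one noisy ranking.
* **`exhaustiveMax = choose(k + 2, k)`** (15 for `k = 4`), i.e.
  elimination runs until only `k + 2` descriptors survive. Elimination
  is the informative step of the method; the exhaustive enumeration is
  blind. A large threshold stops eliminating while many weakly
  informative descriptors remain, and because the final band keeps
  everything within 20% of the best MCC, filters built from two strong
  and two weak clauses then flood the model. Running elimination to the
  end keeps the final model on the descriptors the data actually
  support. Users who want larger models on rich descriptor sets can
  raise the threshold explicitly.
* **`bandFraction = 0.20`.** The model keeps filters down to 80% of the
  top MCC — wide enough for an ensemble, narrow enough that members are
  individually strong classifiers.
* **`dedupOverlap = 0.99`.** Filters that classify more than 99% of
  molecules identically carry no independent signal.

## MBI scoring and its weights

A screened molecule gains `w_i` for every filter passed and loses `w_i`
for every filter failed. The package's default weight is the *rate*
ratio `w_i = TPR_i / FPR_i`, with the FPR floored at `1/(2 nI)` when a
filter has no false positives (the usual continuity correction at half
a count). The alternative reading — raw counts `TP_i / FP_i` — is
available as `weightMode = "count"`; the two coincide up to the factor
`nI/nA`, so rankings are identical on a fixed training set, but rates
are invariant to dataset size, which makes weights comparable across
models. This choice is deliberately exposed because the index's
original description does not disambiguate it. An optional
normalization by the filter count (`mbiNormalize`) is provided for
comparing scores across models of different sizes; it defaults to off,
and the package does not constrain the numeric range of MBI scores.

Positives at a report border are defined as `score >= border` (closed
at the border).

# Curation

* **Fingerprints** are Open Babel FP2: hashed linear paths of 1-7
  bonds folded to 1024 bits. Similarity is the Tanimoto ratio
  `|a AND b| / |a OR b|`, defined as 0 when both bitsets are empty.
  The package promises the path-fingerprint contract, not a specific
  bit layout; all similarity thresholds are applied to its own
  fingerprints. Molecules with no bonds cannot carry a path fingerprint
  and are rejected at ingest with a report.
* **Diversity pruning** walks molecules in input order and drops any
  molecule at Tanimoto ≥ `T` (default 0.8) to an already-retained one.
  The first-come rule is a documented, deterministic choice: the
  retention order of a similar pair is otherwise arbitrary, and
  determinism makes curation reproducible. The post-hoc invariant — no
  retained pair at or above `T` — is asserted in the tests.
* **Applicability domain.** Presumed inactives are sampled from a large
  pool only inside the actives' `mean ± 2 sigma` box on the four
  Rule-of-Five descriptors (`lip_acc` = all N+O, `lip_don` = all OH+NH,
  `cLogP`, `MW`), with `sigma` the sample standard deviation (n-1).
  Sampling random molecules from the same gross region of chemical
  space as the actives forces the model to learn distinctions finer
  than "looks drug-like".

# Descriptors

The descriptor module computes 46 2D descriptors from Open Babel
property estimates, SMARTS counts, element counts and simple graph
statistics. The four applicability-domain descriptors are semantically
pinned by name; everything else is an open, documented set. The method
itself is descriptor-agnostic — filters are learned over whatever
numeric columns the table provides — so tables computed elsewhere can
be used unchanged, and no attempt is made to match any proprietary
descriptor implementation numerically.

# The geometric pose filter

Contact profiling of a reference complex types every residue by two
heavy-atom distance rules: hydrogen bond when some N/O-N/O pair is
within 3.3 Å, van der Waals contact within 3.9 Å (an H-bond therefore
always implies a contact). Aggregating profiles over several complexes
of the same target gives the consensus sets: residues contacting more
than 3 of the ligands or H-bonding at least one are *important*;
residues H-bonding every ligand are *crucial to H-bonds*. An
alternative rule — important = contacting at least 70% of the ligands —
is selectable.

A pose is accepted when it lies closer than 3.5 Å to at least 2 crucial
residues and closer than 5.0 Å to at least 7 important ones, both
strict inequalities; the contact-typing cutoffs are "maximum distance"
rules and therefore closed. "Distance to a residue" is the minimum over
all residue heavy atoms, backbone included — the source procedure never
restricts the atom set, and the whole-residue minimum is the documented
choice here, applied identically at both thresholds. Hydrogens are
ignored throughout: donor-acceptor distances are heavy-atom by
definition and pose files rarely carry reliable protons. A molecule is
accepted when any of its at most 30 poses passes (more are truncated to
the 30 best energies), the selected pose being the lowest-energy
passing one with ties broken by pose index; across several receptor
structures the default vote requires acceptance by all.

# Synthetic data: what it does and does not show

`genDescriptorDataset()` draws class-conditional normals: informative
descriptors separate actives from inactives by `shift` standard
deviations, noise descriptors are identically distributed in both
classes. The default preset — 200 actives, 2000 inactives, 5
informative among 50 descriptors, shift 3, fixed seed — mirrors the
class imbalance and descriptor dimensionality of a desk-scale campaign
while keeping an analytic oracle: the balanced MCC of any given clause
follows from the normal CDF, which the tests use to validate the
generator itself. Normality and descriptor independence are
deliberately idealized; real descriptor tables are correlated, heavy
tailed and multimodal, so passing recovery tests here demonstrates the
machinery (elimination finds the informative subspace, the band keeps
strong filters, MBI ranks held-out data) — not that any particular real
screen will enrich equally well.

`genToyComplex()` realizes an arbitrary per-pose distance plan by
anchoring poses 100 Å apart and giving every residue one contact atom
per pose at exactly the planned distance (plus a backbone-like N atom
further out, so H-bond typing is exercised). These single-residue,
glycine-like placeholders are synthetic fixtures for file parsing and
the distance rules, not chemistry. Random plans avoid a ±0.05 Å guard
band around the 3.5/5.0 Å thresholds so that the 0.001 Å precision of
the PDB format can never flip a verdict.

# Numerical and format choices

* Quantiles are type-7 (R's default interpolation).
* Zero-denominator MCC is 0; enrichment with `FP = 0` is undefined and
  reported as `Inf`, printed `"-"`.
* A constant descriptor collapses its clause to the single value
  (zero-width closed interval).
* Coordinate ascent in the exhaustive phase runs at most 3 sweeps and
  takes the first maximizer on ties (the widest range, given the pair
  ordering), which keeps subset optimization deterministic.
* Model JSON stores bounds with 17 significant digits — the minimum
  guaranteeing bit-exact double round-trip — and confusion counts as
  integers; MCC values and MBI weights are re-derived on load, so a
  saved model can never drift from its counts.
* Training-set sizes in the test suite (60/300 for unit tests, the
  200/2000 preset for end-to-end recovery) were chosen so the whole
  suite exercises every path in well under a coffee break on one CPU.

# Known limitations

* Descriptor semantics beyond the four pinned RO5 names follow Open
  Babel's estimators; cLogP in particular is an estimate and will not
  match other software numerically.
* The stochastic phase's wide-range sampling assumes unimodal actives'
  descriptor distributions; strongly bimodal actives would be served
  better by a finer quantile grid (configurable).
* Filter count in the final model depends on the surviving pool size;
  with elimination run to `k + 2` descriptors the model is compact
  (tens of filters, not hundreds). Raise `exhaustiveMax` for larger
  ensembles on descriptor-rich data.
* The pose filter trusts the docking program's pose geometry and energy
  ordering; it triages poses but cannot rescue a docking run whose
  poses never enter the binding site.
* Consensus residue derivation needs complexes superposable onto a
  common frame; the package measures distances in the frame it is
  given and does not superpose structures itself.
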