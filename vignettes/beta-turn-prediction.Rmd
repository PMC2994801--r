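---
title: "Assigning and predicting beta-turns from backbone geometry and sequence profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning and predicting beta-turns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaturn)
```

## The problem

Roughly a quarter of the residues in globular proteins sit in beta-turns:
four consecutive residues i..i+3 whose C-alpha atoms at i and i+3 come
within 7 Angstrom while the two central residues are not helical. Turns
reverse the chain direction, sit on solvent-exposed surface, and are
enriched in molecular-recognition sites, which makes residue-level turn
prediction useful well beyond structure annotation. Within the class,
nine types are distinguished by the phi/psi dihedrals of the two central
residues: I, I', II, II', VIII, VIa1, VIa2, VIb, and the catch-all IV.

`betaturn` implements the full path from coordinates to prediction:

1. **Assignment** — geometric beta-turn and turn-type assignment from
   backbone coordinates (`read_backbone()`, `compute_torsions()`,
   `assign_turns()`).
2. **Encoding** — sliding-window feature vectors built from sequence
   profiles plus predicted secondary structure and relative surface
   accessibility (`feature_track()`, `encode_windows()`).
3. **Learning** — a two-layer ensemble of small feed-forward networks:
   a general turn/not-turn predictor, four turn-position predictors and
   nine type predictors in the first layer; second-layer networks that
   consume the cross-validated first-layer outputs (`train_layered()`,
   `predict_chain()`).
4. **Evaluation** — residue-level confusion metrics, ROC/AUC, threshold
   sweeps and an AUC-difference test (`metric_set()`,
   `threshold_sweep()`, `auc_difference_test()`).
5. **Dataset tooling** — chain ranking, pairwise identity, Hobohm-1
   homology reduction and composition statistics.
6. **Synthetic fixtures** — a fully seeded generator producing backbone
   chains with planted turns and label-correlated tracks, so every stage
   is testable without downloading structures or running external
   predictors.

## Turn assignment rules

A candidate window i..i+3 becomes a turn when CA(i)-CA(i+3) < 7 A, the
central residues are non-helical (helicity is an input mask, so any
secondary-structure source can veto), and the central torsions are
defined. Its type is the first entry of the canonical table whose four
angles are all within 40 degrees, with at most one deviation above 30
degrees, and whose cis-proline requirement (types VIa1/VIa2) is met; a
window matching no definition is type IV. Deviations are measured on the
circle, so -179 and +179 degrees are 2 degrees apart.

Design points that were genuinely open and how they were fixed:

* **Canonical angle table.** The standard Hutchinson--Thornton /
  PROMOTIF-convention centers are the default
  (`canonical_turn_table()`); the table is an argument everywhere, so a
  different convention is a one-line change.
* **Tie-breaking.** When several types match, a fixed precedence order
  (I, I', II, II', VIII, VIa1, VIa2, VIb) decides; `best_fit = TRUE`
  switches to smallest total circular deviation. Reference assigners do
  not document their rule, so both are provided.
* **Cis/trans.** A peptide bond is cis when |omega| < 30 degrees
  (configurable). VIb is not required to be cis-proline by default,
  matching the tabulated definitions; a flag flips that.
* **Overlap.** Overlapping instances are first-class: a residue covered
  by two turns can be position 1 of one and position 2 of the other, and
  the per-position label tracks reflect that.

## Network model

Each residue is encoded with 25 values: 20 logistically squashed profile
log-odds, one out-of-chain indicator (1 only on virtual window slots
beyond the termini, where every other value is 0), three secondary
structure probabilities and the RSA. A sliding window of 5--13 residues
(always odd) is presented to a one-hidden-layer feed-forward network
with two logistic output neurons; the reported score is the positive
share of the two outputs. Training is online gradient descent on squared
error with per-epoch reshuffling; after each epoch the Matthews
correlation coefficient on the held-out fold (threshold 0.5) is
measured, and the weights of the best epoch are kept. The full study
grid crosses windows {5,7,9,11,13} with hidden sizes {50,75,100,125}
under 10-fold chain-level cross-validation (200 networks per label
track); the first-layer ensemble keeps the best half by leave-out MCC
and averages member scores, the second layer keeps the single best
network per fold.

Defaults the sources leave open, fixed here and exposed in
`train_config()`: learning rate 0.01, 300 epochs (tests and the
acceptance script use 40--100), uniform(-0.1, 0.1) initialisation, no
momentum or weight decay (both available), no class re-balancing (the
natural ~25% positive rate is kept). The per-example update loop is
compiled code with its own deterministic generator, so a run is fully
reproducible from `(seed, data)`. An undefined fold MCC during epoch
tracking (a degenerate confusion table early in training) ranks as 0 for
epoch selection only; reported metrics keep `NA` explicitly. Epochs with
equal test MCC are tie-broken by lower training error: on imbalanced
data the network can rank residues well for many epochs before any
score crosses 0.5 (a long all-negative plateau with MCC pinned at 0),
and the tie-break keeps the most-trained weights of such a plateau
instead of the initial ones.

The second layer consumes per-residue channel tracks composed by setup
letter A--M; the final-method default M is the four position scores, the
general score, the three secondary-structure probabilities and RSA (nine
channels plus an out-of-chain indicator). Type-specific second-layer
networks additionally receive their own first-layer type score. All
second-layer training inputs are out-of-fold first-layer scores: each
chain is scored only by networks whose training folds excluded it, which
`audit_no_leakage()` verifies mechanically. On small sets a rare turn
type can end up with a single-class fold split; such type tracks are
skipped with a message and predicted as `NA` rather than trained on an
undefined objective.

## What the synthetic generator emulates

`synth_dataset()` draws chains (default 50 chains of 80--120 residues,
six planted turns each, about 24% turn residues) with:

* real backbone geometry built from internal coordinates (standard bond
  lengths/angles), extended-strand flanks, canonical turn windows with
  uniform jitter (default 15 degrees, always < 30 so the plant stays
  inside the base tolerance), cis-prolines where the type calls for
  them;
* "opener" phi/psi values on the outer turn residues i and i+3. These
  angles affect neither the planted window's closure nor its
  classification, but they keep the windows straddling the plant
  boundary above 7 A, so the truth recorded at construction equals what
  the assignment rules find. The values were fixed by a worst-case
  numeric search; only the window after a VIa2 plant is inherently
  compact (its cis bond), where the generator resamples the jitter a
  bounded number of times. VIa2 plants also cap their phi(i+1) jitter at
  +15 degrees: beyond +20 the planted window additionally satisfies the
  VIa1 definition and the precedence rule would relabel it;
* profiles that are integer noise (sd `sigma`, default 1) except for a
  `+delta` shift (default 4) on the five turn-favoring columns
  (Gly/Asp/Ser/Pro/Asn) of turn residues, plus raised coil probability
  (+0.25) and RSA (+0.2) there. Turn residues also draw their letters
  from a Gly/Asp/Ser/Pro/Asn-enriched distribution, which
  `composition_stats()` recovers.

What it does **not** emulate: side chains, packing and clashes, helices
(the helix veto is exercised through the mask, not through generated
helices), real profile correlations along the sequence, database-search
artefacts, or assignment noise. The default effect size makes the
planted signal strong -- cross-validated AUCs on the synthetic set
saturate at 1.0 -- so passing the learning tests shows the machinery
(encoding, training, ensembling, fold hygiene) is correct, not that
real-data performance would match published benchmarks; those require
real structure sets and full-scale profiles, which are deliberately out
of scope. One consequence of the ceiling: the second layer can only
match, never exceed, a perfect first layer, so the noise-filtering gain
that layering buys on real data has no headroom to show up here, and the
corresponding strict-improvement check is expected to tie.

## Numerical choices

* Angles are degrees in (-180, 180], residues 1-based; torsions use the
  IUPAC sign convention (cross-checked against bio3d in the tests).
* The builder uses N-CA 1.458, CA-C 1.525, C-N 1.329 A and standard
  backbone angles; round-trip error is below 1e-4 degrees.
* Scores at exactly the call threshold count positive.
* ROC/AUC groups tied scores (half credit), making the trapezoidal AUC
  identical to the normalized Mann-Whitney U.
* The AUC-difference test combines Hanley--McNeil standard errors as two
  independent samples; identical inputs return z = 0, p = 1.
* Chain ranking uses the monotone surrogate resolution x
  sequence_length / pdb_length (lower is better); the ranking function
  is a parameter of `hobohm1()`, as is the identity function
  (Needleman--Wunsch BLOSUM62, gap 11/1, identity over alignment length
  by default).
* Fold assignment shuffles chains under the seed, then greedily fills
  the lightest fold, bounding the residue imbalance by the longest
  chain.

## Problem sizes used by tests and the acceptance script

The shipped tests and `scripts/acceptance.R` run a reduced study: 2
windows x 2 hidden sizes (5/9 x 10/20), 5 folds, 40 epochs, on the
default 50-chain synthetic set -- the smallest configuration that still
exercises ensembling, per-fold selection and both layers. The full grid
is one argument away (`grid = architecture_grid()`, `k = 10`) and scales
linearly in networks trained.

## Known limitations

* The assignment reproduces the published dihedral rules but not every
  idiosyncrasy of the reference assigner's merging of consecutive turns.
* Type-specific predictors need every fold to contain positives of that
  type; rare types on small sets are skipped (reported as `NA`).
* Hobohm-1 is quadratic in accepted records with alignment cost on top;
  for thousands of chains supply a cheaper identity function or
  pre-cluster.
* The length-corrected identity threshold variant is not implemented;
  the threshold is a plain percentage argument.
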