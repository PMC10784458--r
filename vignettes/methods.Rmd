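---
title: "Methods: distance-descriptor state annotation of GPCR conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-descriptor state annotation of GPCR conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrstates)
```

## The model

Class A GPCRs switch between inactive and active conformations of the
transmembrane bundle; activation is dominated by the outward displacement
of TM6 relative to TM3/TM5/TM7 and by rearrangements of conserved
microswitch clusters (DRY, NPxxY, CWxP, PIF, sodium pocket). This package
classifies a conformation from geometry alone:

1. **Descriptor.** An ordered vector of Euclidean distances (Å) between
   the *side-chain geometric centers* of configured residue pairs. The
   side-chain center is the unweighted centroid of the residue's
   side-chain heavy atoms — everything except backbone N, CA, C, O, OXT
   and all hydrogens — with the Cα position as the glycine fallback. This
   atom-set convention is a package decision: "geometric center of the
   side chain" admits several readings, and the heavy-atom centroid is
   deterministic across force fields and protonation variants. The
   descriptor is invariant under rigid motion and atom reordering (tested
   properties), and its component order is defined by the pair list, never
   inferred.

2. **Pair list.** The shipped default (`default_pairs()`,
   `inst/extdata/activation_pairs.txt`) has 38 pairs spanning the
   activation pathway: TM5/TM6 packing and the G-protein coupling region
   (e.g. 5x62:6x37, whose distance swings from ~6 Å to ~15 Å between
   active- and inactive-like μ-opioid receptor structures), the
   hydrophobic lock (5x58:6x40, 5x55:6x41), PIF, CWxP, the sodium pocket,
   NPxxY and DRY. Twelve of these pairs are fixed by the motif literature
   this design follows; the remainder were compiled from the same
   activation-pathway motifs and should be treated as a replaceable
   stand-in rather than a canonical set — the file format is one pair per
   line and nothing in the code assumes 38 entries.

3. **Residue identification.** Pairs are named with GPCRdb generic
   numbers (`SxNN`; position 50 is the most conserved residue of each
   helix). Computing generic numbers from sequence is out of scope; the
   package takes a plain-text mapping table (label → author residue
   number, optional chain and residue name) as input, so builds are
   reproducible offline. Both `x` and the typographic `×` separator are
   accepted on input; `x` is canonical on output. When a mapping row has
   no chain, the structure must have exactly one protein chain —
   receptor–G-protein complexes must disambiguate explicitly.

4. **Classifier.** Default family is a random forest (100 trees, Gini
   splits, per-node `mtry = ⌊√p⌋` feature subsampling, unlimited depth),
   scored as the mean leaf active-class fraction; gradient-boosted trees
   (logistic loss, Newton leaf steps, depth 3, 100 rounds, learning rate
   0.1) and a linear squared-hinge SVM with Platt-calibrated scores are
   available behind the same interface. The tree code is implemented in
   the package (C++): no suitable tree-ensemble library is assumed at run
   time, and owning the trees gives exact, auditable decision paths
   (`explain_state_model()`) and impurity-decrease importances that sum
   to 1. Exact published hyperparameters for this methodology are not
   available; the defaults above are conventional and configurable, and
   no numeric equality with any external implementation is claimed.
   The SVM's Platt calibration is fitted on the training decision values
   rather than a held-out split — a simplification; only the [0, 1] score
   contract depends on it, not any acceptance quantity.

## Dataset construction and leakage control

Training data are state-labelled MD trajectories. The default sampling
plan mirrors short production runs: 20 ns sampled every 100 ps, i.e. 200
snapshots per trajectory taken at t = interval, 2·interval, …, length
(the t = 0 starting structure is *not* a snapshot; with `floor(length /
interval)` frames this reproduces the 200-frame count, and the convention
is documented rather than guessed). Thirty-eight trajectories under the
default plan give a 7,600 × 38 matrix. Frames inherit the starting
structure's label; runs are assumed short enough not to cross states, and
frames are never relabelled (the binding-site RMSD tools can be used as a
sanity screen).

Adjacent MD frames are near-duplicates, so random frame-level splits
overstate performance. Every trajectory is therefore one *fold*; folds
are assigned to train/test partitions (default 28/10) by seeded random,
label-stratified draws, and cross-validation inside the train partition
is *grouped* 5-fold over whole trajectories. Zero trajectory overlap
across partitions and across every CV iteration is asserted
programmatically (`check_no_leakage()`, exhaustive tests). Which
trajectories land in which partition is seeded-random because no
canonical membership list exists; the seed is recorded in the model
metadata.

## Scores, thresholds, and trajectory verdicts

* Frame rule: active iff raw score > θ, default θ = 0.375 — the printed
  operating threshold of the methodology this package implements, treated
  as an opaque default and overridable per run.
* Trajectory rule: active iff active-frame ratio > δ (default 0.5).
* Both inequalities are **strict** ("larger than"), so boundary frames
  and boundary ratios classify inactive; this tie-break is deliberate and
  documented so users can audit boundary cases. `classify_trajectory()`
  is monotone in δ by construction.
* Smoothing (`smooth_scores()`, default window 5) is a centered moving
  average with truncated edge windows. It exists for plotting and
  reporting only; classification always uses raw scores.

## Metrics

`compute_metrics()` reports the confusion counts and precision, recall,
F1, accuracy, MCC, with "active" as the positive class. Zero-denominator
cases (e.g. no predicted positives) return a flagged 0 sentinel with a
classed warning instead of NaN, keeping batch evaluations alive while
remaining detectable. The MCC denominator is computed as the square root
of the product of the four marginals in double precision — computing it
as a product of four square roots can push a perfect score to 1 + 2·10⁻¹⁶
and out of the valid range.

## Binding-site RMSD analysis

A binding site is the union, over reference structures, of receptor
residues with any heavy atom within the cutoff (default 8 Å, boundary
inclusive) of the selected entity — ligand heteroatoms (waters excluded)
or a G-protein helix selection. Site RMSD between two structures is
computed on the site residues' Cα atoms after least-squares (Kabsch)
superposition on those same atoms; the Cα convention is a package
decision, as is per-frame averaging over multiple references. Group
comparison of active- vs inactive-labelled frames uses the two-sided
Mann–Whitney rank-sum test (`stats::wilcox.test`, normal approximation
with continuity correction) plus group medians.

## The synthetic-ensemble generator

The generator exists so that every pipeline stage is testable offline
with known ground truth. It emulates exactly one feature of real data:
*two states separated by a TM6 displacement*. Templates place
pseudo-residues (1–5 dummy heavy atoms each, including glycine-pattern
residues that exercise the Cα fallback; side-chain offsets sum to zero so
centroids are exact) such that:

* TM6-involving pair distances differ by ≥ `separation` between the
  templates — the TM6 cluster is displaced orthogonally to every
  TM6-involving pair vector, making the guarantee exact arithmetic, not a
  sampling claim;
* the anchor pair (5x62:6x37 when present) sits at `anchor_distance`
  (default ⅔·separation) in the active template, and at
  `anchor_distance + separation` in the inactive one — with
  `separation = 9` this reproduces the familiar ~6 Å vs ~15 Å TM5/TM6
  motif;
* all other pair distances are identical across templates.

Frames are `λ_t·active + (1 − λ_t)·inactive` plus per-atom isotropic
Gaussian noise. Default σ = 0.25 Å — side-chain centers of a
well-equilibrated binding pocket fluctuate on the few-tenths-of-an-Å
scale, and this value keeps the two states unambiguous, which is what a
labelled *training* ensemble is supposed to be; it was chosen once, up
front, and is swept upward explicitly in the noise-degradation test. What
the generator does **not** emulate: bonded geometry, membrane and solvent,
correlated collective motions, intermediate states beyond linear
interpolation, and ligands. A green test on synthetic data therefore
establishes the *pipeline* (I/O → mapping → descriptor → split → model →
thresholds) and the separability behaviour of the learners — it does not
certify accuracy on real receptors, which depends on the real training
ensembles used.

## File formats and numerical conventions

* PDB: fixed-column ATOM/HETATM parser/writer. Alternate locations are
  resolved at read time (highest occupancy, ties → altloc "A");
  insertion codes are part of residue identity; elements fall back to
  name-derived symbols when columns 77–78 are blank. mmCIF is not
  supported.
* DCD: standard CHARMM/NAMD record layout. One deliberate convention:
  the header delta field is written and read directly in picoseconds
  (not AKMA units); third-party DCDs load correctly apart from the time
  scale, which can be overridden with `interval_ps`.
* Model bundles are single-file JSON with the estimator state serialized
  and base64-encoded, so reloaded models reproduce scores bitwise; the
  pair list is stored verbatim and validated at scoring time — descriptor
  misalignment is an error, never a silent reorder.
* All randomness flows through explicit integer seeds (R RNG for data
  and splits, a Mersenne Twister in the C++ tree code); seeded runs are
  bitwise reproducible, and generator RNG is isolated from the caller's
  RNG stream.

## Known limitations

* The non-canonical portion of the default pair list (see above) is a
  literature-informed stand-in; users reproducing a published feature set
  should supply their own pair file.
* Accession-based checks against deposited μ-opioid receptor structures
  require network access and are replaced in the test suite by synthetic
  mimic structures that encode the printed 6.07/15.09 Å motif by
  construction; they validate the computation path, not the deposited
  coordinates.
* The linear SVM is not a kernel SVM; for non-separable real data the
  tree families are the recommended defaults.
* No hyperparameter search beyond user-supplied values; no deep-learning
  trajectory models; no ligand-aware features (the descriptor
  deliberately does not "see" ligands).
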