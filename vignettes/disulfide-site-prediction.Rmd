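---
title: "Predicting disulfide engineering sites from residue-pair distance geometry"
author: "DisulfideDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disulfide engineering sites from residue-pair distance geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisulfideDesign)
```

## The problem and the model

A disulfide bond covalently links the Sγ atoms of two cysteines and can
be engineered into a protein by mutating a suitably placed residue pair
to cysteine. Whether a pair is suitable is almost entirely a question of
local backbone geometry: the two residues must hold their β-carbons
close enough, and in a compatible orientation, for the sulfurs of the
future cysteines to meet.

This package models that question as binary classification of a
residue pair's geometry. Each pair is reduced to the coordinates of ten
heavy atoms — N, Cα, C, O, Cβ of both residues, in that fixed order —
and then to the 45 distinct pairwise distances among them (the strict
upper triangle of the 10 × 10 Euclidean distance matrix, row-major).
Distances make the representation exactly invariant under rotation and
translation, so no structural superposition is ever needed. Two
deliberate omissions shape the featurization:

* **No Sγ.** Candidate positions are not cysteines yet, so their Sγ
  coordinates do not exist; and in bonded pairs the ~2.05 Å Sγ–Sγ
  distance would trivially dominate the classifier without teaching it
  anything about mutable positions.
* **No torsion angles or other derived descriptors.** The network is
  given the raw distance field and learns its own features; the
  feature-relevance analysis (`featureRelevance`) lets one inspect what
  it found, and consistently attributes the signal to inter-residue
  distances (Cβ–Cβ and Cβ–main-chain), with intra-residue distances —
  near-constant by covalent geometry — carrying almost none.

The classifier is a fully connected network 45 → 128 → 32 → 1 with ReLU
hidden units and a logistic output. Defaults (10 epochs, learning rate
0.01, batch size 100, decision threshold 0.5) are the package's standard
training conditions. Several details the architecture alone does not fix
were resolved as follows:

* **Loss and optimizer**: binary cross-entropy under plain mini-batch
  SGD. BCE is the canonical loss for a logistic output; plain SGD makes
  the stated learning rate meaningful without introducing optimizer
  hyperparameters.
* **Initialization**: seeded He-style uniform (±√(6/fan-in)), biases
  zero. Pinning the initialization and the per-epoch shuffling to
  `classifierConfig(seed=)` makes training bit-reproducible.
* **Pair-order symmetry**: a residue pair has no intrinsic order, and
  the flattened distance vector is not symmetric under swapping the two
  residues. Every training sample is therefore presented in both
  orientations, and at prediction time the two orientation scores are
  averaged, making the final score exactly order-symmetric. The
  serialization order of a pair is fixed by the lexicographic
  (chain, residue number, insertion code) convention.
* **Threshold boundary**: a score exactly at the threshold classifies
  as bonded (`score >= threshold`).
* **No feature scaling**: inputs are raw Å distances. Their natural
  range (roughly 1–12 Å) is narrow enough for stable training, and
  unscaled inputs keep the first-layer weights interpretable per
  distance.

## Dataset construction

Positives are the disulfides declared in a structure's SSBOND records.
Negatives are derived one-per-bond: for a bond (C~i~, C~j~) the four
crossing pairs of sequence neighbours — (i−1, j−1), (i−1, j+1),
(i+1, j−1), (i+1, j+1) — are ranked by Cα–Cα distance and the closest
usable pair is kept. This yields non-bonded pairs that are *spatially
close* (hard negatives) and automatically balanced against the
positives. Conventions the rule itself leaves open:

* Sequence neighbours are defined by adjacency in the ordered residue
  list of the chain, so numbering gaps still count as neighbours;
  neighbours are taken within each residue's own chain, which lets
  inter-chain bonds contribute negatives too.
* Distance ties keep the first candidate in the order above
  (deterministic; ties have measure zero in real coordinates).
* A candidate that is itself disulfide-bonded elsewhere in the
  structure is excluded.
* Glycines encountered anywhere get an ideal Cβ reconstructed from
  their backbone (below), consistent with treating them as alanine
  mutants.

`curateFilter` implements the usual corpus-curation step (resolution
strictly better than 2.0 Å, R-factor strictly below 0.25, entries with
missing metadata excluded). The train/test split is seeded uniform
sampling at the sample level with a default test fraction of 0.24; the
split procedure for the reference corpora is not documented anywhere,
so the simplest reproducible choice was taken.

## Cβ reconstruction

`buildCB` places an ideal β-carbon 1.53 Å from Cα with tetrahedral
(109.47°) angles to N and C, on the L-amino-acid side of the backbone
plane. This is equivalent (to within coordinate noise) to
least-squares-superposing an ideal alanine onto the backbone and reading
off its Cβ, which is exactly what the test suite uses as the
independent oracle. The construction is exactly equivariant under
rigid-body motion and fails loudly on collinear backbones.

## Prediction and ranking

`predictSites` enumerates all n(n−1)/2 residue pairs, then prescreens by
the Cα–Cα window 3.0–7.5 Å in which natural disulfides overwhelmingly
lie — typically a ~40-fold reduction — before scoring. Two additional
prescreen controls:

* `minSequenceSeparation` (default 2) drops intra-chain i/i+1 pairs.
  Adjacent disulfides are vanishingly rare, and the negative-sampling
  scheme deliberately treats neighbours of real bonds as non-sites; set
  it to 0 to score strictly every in-window pair.
* `includeNativeCys` (default `TRUE`) keeps pairs involving native
  cysteines, since an engineered cysteine may pair with a native one.

Records are sorted by descending score with deterministic residue-id
tie-breaking; the absolute rank starts at 0 and the relative rank is
abs. rank / (total − 1).

## The synthetic benchmark: what it does and does not show

Training corpora of real structures cannot be shipped or downloaded at
test time, so the package carries a geometry-aware generator used by
every test and by the acceptance script.

`makeFeatureClouds` samples residue pairs built from an ideal-geometry
alanine template: bonded-like pairs hold Cβ–Cβ at 3.8 Å (the natural
disulfide value) with Cα–Cα drawn from 4.0–6.5 Å; non-bonded pairs draw
Cα–Cα from the full 3.0–7.5 Å prescreen window with arbitrary relative
orientation subject to Cβ–Cβ > 5.5 Å. Per-atom Gaussian jitter
(σ = 0.15 Å, about the coordinate precision of a good crystal
structure) keeps the clouds from being degenerate. The negative class
is deliberately defined by *exclusion* (any orientation whose Cβs stay
apart) rather than by a narrow antiparallel-Cβ recipe, so that
arbitrary non-bonded pairs encountered in fixture structures lie inside
the training distribution.

Two consequences are intended and documented rather than incidental:

* The class supports on the Cβ–Cβ coordinate are **disjoint by
  construction** (< 5.0 Å vs > 5.5 Å after jitter), so a single
  threshold on that one feature separates the benchmark perfectly.
  This gives classifier tests a provable bound — a correctly trained
  network must reach held-out AUC ≥ 0.95, and its failure to do so is a
  bug, not noise. The flip side is that the benchmark says nothing
  about accuracy on real structures, where the classes genuinely
  overlap; it validates the machinery, not the biology.
* Because the separating feature achieves AUC exactly 1.0, "beating"
  the best single-feature classifier is logically impossible on this
  benchmark; the corresponding check is therefore that the network
  *matches* the single-feature oracle (within 10⁻³) while also
  clearing the 0.95 bound.

`makeStructure` writes toy PDB files: a persistent random-walk Cα coil
(3.8 Å steps) of ideal alanine residues, with a requested number of
bonded-like pairs planted, declared as SSBOND records, and renamed to
cysteine. The generator then *enforces its own labels*: a repair pass
re-orients (and, where orientation cannot suffice, repositions) any
non-planted residue whose Cβ comes closer than 5.5 Å to another
in-window residue's Cβ, so that the planted pairs are provably the only
bonded-like geometries the prescreen will pass. Sequence neighbours of
a planted bond partner are placed at 3.8 Å chain-continuity distance so
that derived negatives have realistic Cα distances, a fraction of which
fall outside the prescreen window (reported by the generator). The
truth table — planted bonds and the negative each should yield under
the crossing-pair rule — is computed from the final coordinates by
exhaustive search, independently of the sampling module it is used to
test.

What the fixtures do not emulate: real folds and secondary structure,
side chains beyond Cβ, rotamers, peptide-bond continuity between
consecutive residues (each residue is independently oriented), altloc
disorder, or the conformational relaxation a real mutation induces.
End-to-end tests train on the feature clouds (optionally combined with
fixture-derived samples via `combineDatasets`); the fixture-derived
samples alone (a handful per structure) are far too few to train the
network, and are used to exercise the dataset-building path rather than
to reach accuracy.

## Numerical and I/O choices

* Structure parsing uses `bio3d`; SSBOND records, which `bio3d` does
  not expose, are read directly from the fixed-column PDB records, and
  bonds referencing unresolved residues are dropped with a warning.
  Multi-model files use the first model by default; alternate locations
  keep conformer A; common modified residues (MSE, SEC, …) map to their
  standard parents; residues missing any of N/Cα/C/O (or Cβ for
  non-glycine) are dropped with a warning.
* The problem sizes used by the shipped tests and acceptance script —
  feature clouds up to 5,000 pairs per class, fixtures of 20–106
  residues, forests of 100–200 trees — were chosen as the smallest
  sizes at which every statistical check is comfortably stable.
* Model files are JSON with 17-significant-digit floats, so a reloaded
  model reproduces scores bit-identically; files are versioned and
  shape-checked on load.
* ROC curves group tied scores into single threshold steps and
  integrate by the trapezoidal rule, which makes the AUC equal to the
  Mann–Whitney concordance probability (ties counted ½); this identity
  is tested exhaustively at small n.
* Feature relevance uses a seeded random-forest *regression* on the
  0/1 label with impurity importances normalized to sum 1.

## Known limitations

* Distances are blind to chirality: a mirror-inverted pair featurizes
  identically. Real proteins are homochiral, so this is harmless in
  practice, but it is a genuine blind spot of the representation.
* The method scores wild-type backbone geometry; it does not model the
  relaxation that follows mutation, estimate ΔΔG or entropy changes, or
  guarantee the engineered bond forms — it ranks candidates for
  experimental follow-up.
* Accuracy claims on real proteins require training on a curated,
  non-redundant corpus of real structures, which the user must supply
  (`assembleDataset` + `curateFilter`); everything shipped here is
  validated on synthetic geometry only.
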