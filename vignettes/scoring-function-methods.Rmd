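---
title: "Building and stress-testing target-specific scoring functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and stress-testing target-specific scoring functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structure-based virtual screening ranks a chemical library by predicted
binding to a receptor structure. Docking engines produce plausible poses,
but their native scoring functions are only weakly predictive of activity.
When a target has enough measured bioactivity data, a *target-specific*
machine-learning scoring function — a supervised model trained on
featurized docked complexes of that one target — usually ranks actives far
better than a generic score. `mlscreen` implements that protocol end to
end: bioactivity curation, featurization of docked poses, model training
with Bayesian hyperparameter search, and early-enrichment evaluation,
together with a synthetic-data generator that makes the whole pipeline
testable without any external download or docking run.

This vignette explains the scientific choices in each stage, the defaults
and their units, what the synthetic fixtures emulate (and what they do
not), and the numerical conventions.

## Bioactivity curation

Input tables follow the shape of a ChEMBL activity export: compound id,
SMILES, standard relation, activity value in nM, and an assay-kind
annotation (`biochemical`, `cellular`, or `binding`). Curation proceeds:

1. Rows with missing SMILES or non-positive/non-numeric values are dropped
   and counted.
2. Only relations `=` (certain values) and `>` (censored above; inactive
   candidates regardless of value) are retained.
3. Potencies transform as `pIC50 = -log10(IC50 * 1e-9)` with IC50 in nM,
   so the 1 µM activity threshold sits at exactly pIC50 = 6.
4. Replicated `=` measurements of one compound and assay kind are
   averaged. The default averages IC50 on the nM scale and then
   log-transforms; averaging on the pIC50 scale is available via
   `average = "pic50"`. Replicates are kept only when their dispersion is
   below 2. We compute that dispersion as the *population* standard
   deviation on the pIC50 (log) scale: a threshold of 2 on raw nM would be
   vacuous for micromolar measurements, whereas 2 log units is a
   meaningful (if permissive) reproducibility bound. Both scale
   (`sd_scale`) and threshold are arguments.
5. A compound is *active* iff its certain pIC50 is at least 6. Every
   inactive used for regression carries a target of pIC50 = 2 — a
   deliberately low pseudo-potency that pushes regressors to separate
   inactives from the 6–9 range of true actives.
6. Compounds whose rows disagree on the structure are rejected, never
   silently overwritten.

The split is assay-aware rather than random: training takes compounds with
biochemical but no cellular measurements; the test set takes compounds
with cellular measurements. A test compound counts as active only if both
its cellular and biochemical potencies are in the active range, while test
*inactivity* is decided by the cellular value alone — cell-inactive
compounds often retain biochemical potency, and treating them as actives
would reward models for the wrong thing. Binding-affinity-only (Kd)
compounds are excluded from both partitions by default because the
partitions are IC50-defined; `include_binding_only` flips that.

Structure standardization (`standardize_structure()`) keeps the largest
organic fragment, neutralizes simple charged sites when chemically valid,
canonicalizes tautomers, and emits Open Babel canonical SMILES. The
tautomer step is a bounded breadth-first enumeration of 1,3-hydrogen
shifts over acyclic C/N/O triads (at least one heteroatom end), capped at
32 states, with the lexicographically smallest canonical SMILES as the
representative. The representative is therefore canonical, not
thermodynamically preferred; ring tautomers and longer shifts are out of
scope. This is sufficient to make equivalent input spellings collide,
which is all curation needs.

## Featurization

Three schemes encode a docked complex, all built on one primitive:
deterministic circular atom-environment identifiers. The depth-0
identifier of an atom hashes (element, heavy degree, total hydrogen count,
formal charge, aromatic flag, ring membership); the depth-d identifier
hashes (d, the atom's depth-(d−1) identifier, the sorted list of (bond
order, neighbor identifier) pairs). Hashing is 32-bit FNV-1a over
byte-serialized tuples — never a process-seeded hash — so fingerprints are
bit-identical across sessions and platforms, and identifiers are invariant
to atom order by construction.

* **Morgan fingerprints** (`morgan_fp()`): unique environments over depths
  0..radius, deduplicated by the standard rules (identical identifiers,
  and environments covering an already-seen bond set, are dropped; among
  atoms sharing a bond set the smallest identifier is the canonical
  representative, which keeps the bit set independent of atom order),
  folded modulo `n_bits`. Defaults: 512 bits, radius 2 as model features;
  2048 bits, radius 2 wherever similarity is computed.
* **PLEC fingerprints** (`plec_fp()`): for every ligand/protein heavy-atom
  pair within the contact cutoff, ligand environments at depths
  0..`depth_ligand` (default 1) are paired with protein environments at
  depths 0..`depth_protein` (default 5), hashed, and folded modulo 4092.
  The contact cutoff (4.5 Å) and the full cross-product pairing are the
  reference library's conventions; a diagonal pairing mode exists behind
  a flag. A contact-free complex legitimately yields the zero vector.
* **GRID features** (`grid_features()`): a 2052-long count vector —
  512 folded environment counts of all heavy atoms within a spherical
  neighborhood of diameter `voxel_width` (16 Å) around the ligand
  centroid; three 512-long blocks of folded contact-pair counts binned by
  distance into (0, 2], (2, 3] and (3, 4.5] Å; three hydrogen-bond counts
  in the same bins; and one salt-bridge count. Only the 2052 total is
  externally fixed; the block decomposition (2^9 + 3·2^9 + 3 + 1) is this
  package's documented convention. The neighborhood is a sphere rather
  than a cube so the features are exactly invariant under rigid
  rototranslation. Hydrogen-bond typing is rule-based (N/O with a
  hydrogen donates; N/O with a lone pair accepts) and a salt bridge is a
  formally charged N+/O− pair within 4.0 Å; no partial charges are used,
  which is the honest choice given that receptor protonation is not
  reproduced here.

Because PDB files carry no connectivity, receptor bonds are inferred with
a covalent-distance rule (heavy pairs under 1.9 Å, S–S under 2.1 Å, all
single order). Protein-side environments therefore see consistent, if
simplified, graphs. Aromatic flags are taken from the source format (bond
order 4); structures arriving through canonical SMILES are deterministically
kekulized, so flags are consistent within any one pipeline run.

## Models and tuning

Five algorithms, each as binary classifier and as regressor: random
forest, extreme gradient boosting, support-vector machine, a
single-hidden-layer neural network, and a deep network with at least two
hidden layers. The first four wrap the standard R implementations
(`randomForest`, `xgboost`, `e1071::svm`, `nnet`); the deep network is a
compact Adam-trained multilayer perceptron implemented in the package
(ReLU hidden layers, sigmoid or linear output, inverted dropout), since no
multi-hidden-layer framework is part of this stack. Classification scores
are probabilities of activity; regression scores are predicted pIC50;
higher is better in both modes, so ranking code never needs to know the
mode. SVM feature scaling is disabled: per-column standardization of
near-constant fingerprint bits is meaningless and destabilizes otherwise
deterministic fits.

Hyperparameters are tuned by a tree-structured Parzen estimator
(`tpe_optimize()`) written for this package: after a random start-up
phase, observations split into a best-quantile set and the rest,
candidates are drawn from a Parzen (Gaussian-mixture or smoothed
categorical) model of the good set, and the candidate maximizing the
good/rest density ratio is evaluated next, independently per dimension.
The cross-validated objective is 1 − PR-AUC for classification and RMSE
for regression, over 5 folds; `max_evals` defaults to 50. The search
spaces in `search_space()` cover the usual axes per learner (tree counts
and depths; cost, kernel and kernel width; layer sizes, learning rate,
dropout); their exact ranges are this package's defaults, documented in
the function. Given one seed, the entire tune → fit → score chain is
reproducible to the bit.

The evaluation protocol repeats training `n_runs = 10` times with
consecutive seeds on the fixed split and reports the median NEF1%; the
representative run for curves is the one with NEF closest to the median,
ties broken by a seeded draw. Learners with no internal randomness (the
SVM) legitimately produce ten identical runs.

## Enrichment evaluation

EF1% is computed in the recall-over-fraction form: with
`n_top = floor(0.01 · N)` (minimum 1), `EF = (actives in top n_top / A) /
0.01`. This variant is adopted because it exactly reproduces the maxima
attainable on inactive-enriched test sets of this shape (e.g.
`min(34, 67)/67/0.01 = 50.75` for 3443 molecules with 67 actives, and
59.65 for the 3426/57 composition), where the precision-ratio form with
an integer top bin gives 51.39; the precision form remains available via
`form = "precision"`. NEF1% divides by that maximum, lies in [0, 1], and
equals `1/maxEF` (0.020 and 0.017 on the two compositions above) for a
random ranking. Decoys and experimentally confirmed inactives are pooled
as negatives. Ties in scores are broken by compound id for determinism
(or by a seeded shuffle on request). Precision-recall curves are
integrated by steps, not trapezoids, matching the convention of the usual
scikit-learn implementation.

The dissimilar-test-set stress test removes every test molecule (decoys
included) whose maximum Tanimoto similarity to any training molecule
(Morgan, 2048 bits, radius 2) reaches 0.70; the strict `< 0.70` retention
matches the protocol's wording. Retrieved-hit diversity is summarized by
single-linkage clustering at similarity ≥ 0.70 (connected components, so
a chain a~b~c clusters together even when sim(a, c) is low) and by each
hit's nearest training molecule with its label — the "negative nearest
neighbor" check. Group comparisons of NEF distributions run Shapiro-Wilk
per group and then Welch's unequal-variance two-sided t-test; constant
groups are flagged rather than tested for normality.

## The synthetic study generator

`fixture_spec()` + `gen_activity_table()` / `gen_benchmark()` generate
complete, seed-controlled studies. Design points:

* All randomness flows from one master seed through a counter-based
  splitter (`split_seed()`), so any artifact can be regenerated in
  isolation.
* Molecules are connected, valence-respecting acyclic C/N/O/S graphs with
  3D coordinates from an incremental embed (bond lengths 1.3–1.6 Å).
  They emulate the *shape* of screening data — sizes, heteroatom content,
  donors/acceptors — not medicinal chemistry: no rings, no aromatics, no
  stereochemistry. Consequently, passing tests demonstrate pipeline
  correctness, not chemical realism.
* Activity tables realize an exact composition (largest-remainder
  allocation, or explicit counts) with planted stressors whose counts are
  recorded: missing-SMILES rows, `<`-relation rows, and over-dispersed
  replicate sets that the dispersion filter must reject. Test inactives
  receive biochemical potencies better than their cellular ones, so the
  cellular-decides-inactivity rule is genuinely exercised.
* Decoys are property-matched to their template active on heavy-atom
  count, donor and acceptor counts (each within ±1) with Tanimoto < 0.4
  to the template — a minimal stand-in for graph-generative decoy
  construction, deliberately not equivalent to it.
* Pocket complexes place amide-like pseudo-residues on a shell around the
  ligand (two within the contact shell, the rest at 5–8 Å). Every
  molecule carries a standard amide "warhead" substructure; when a
  complex is signal-positive, an anchor triad is added at exact offsets
  in the warhead's local frame, so every anchor-warhead distance — and
  therefore every interaction-fingerprint bit the anchor contributes — is
  identical across complexes. The anchor contains the receptor's only
  sulfur atom, so its environment identifiers cannot arise from random
  pocket geometry; random shell amides still contaminate nearby bit
  space, which keeps the task non-trivial.
* `signal_strength` s maps to label flips with probability (1 − s)/2:
  s = 1 is deterministic signal, s = 0 is exact independence (the
  negative control), s = 0.9 — the default study condition — leaves 5% of
  labels contradicting the features, which also plants signal-positive
  decoys at realistic nuisance rates.

## Numerical conventions and degenerate inputs

Coordinates are Å throughout; atom indices are 1-based in R structures
and in file serializations. Contact boundaries are closed (distance equal
to the cutoff counts). A complex with no contacts featurizes to a zero
PLEC vector rather than erroring. `n_top` uses floor with a minimum of 1,
so enrichment is defined for screens smaller than 1/f; the maximal-EF
identity `maxEF · A · f = min(floor(f·N), A)` holds whenever the top bin
is nonempty. Replicate dispersion uses the population (divide-by-n)
standard deviation, since a replicate set is the complete set of
measurements, not a sample. Identical groups in the Welch comparison
return p = 1; constant groups return NA normality with a flag.

## Problem sizes used in the shipped checks

The test suite exercises the full study composition for the bookkeeping
checks (1565 training molecules, 93 + 3350 test molecules) because those
counts are the point; model-level checks run on planted-signal benchmarks
of about 2100 molecules (200 training, decoy ratio 20) with 10-run
medians, which this package treats as its standard desk-scale study — a
full-scale docking campaign (thousands of database records, real docked
poses) is exactly what the generator stands in for. Headline enrichment
values from full-scale real data are therefore *not* reproduced here;
what is reproduced is every quantity that depends only on the protocol:
maxima, baselines, dimensionalities, composition arithmetic, and the
qualitative recovery of a planted signal well above its analytic random
baseline.

## Known limitations

* Tautomer canonicalization is bounded and acyclic-only; it standardizes
  common keto-enol/amide-imidol pairs but not ring tautomers.
* Receptor protonation, partial charges and water networks are not
  modeled; hydrogen-bond and salt-bridge typing is rule-based.
* Aromaticity is taken from the input format; kekulized inputs hash as
  alternating single/double bonds. Fingerprints remain internally
  consistent but are not interchangeable with toolkit fingerprints.
* The deep-network variant is a compact MLP; it makes no claim to match
  a GPU framework's throughput or regularization repertoire.
* Docking is consumed, never performed: pose quality is outside the
  package's control and outside its tests.
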