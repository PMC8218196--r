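---
title: "Hybrid model quality estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid model quality estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the scoring model, the assumptions behind each component, the parameters
that matter, what the synthetic benchmark does and does not emulate, and
the choices we made where the design was genuinely open.

## The estimation problem

Given a target amino-acid sequence of length $L$ and one or more candidate
3D models, the package estimates, for every target position $i$, how close
the model's residue is likely to be to its position in the (unknown) native
structure, and composes these local estimates into global accuracy scores
used for ranking and confidence assessment. All residues are indexed on the
target sequence: models are mapped by exact substring offset or, failing
that, by global alignment (match +1, mismatch −1, linear gap −2), and model
residues that do not align are excluded from all scoring. This shared frame
is what makes partial and renumbered models comparable.

## Observed-quality oracles

Two complementary observed scores serve as training targets and evaluation
references when a native structure is available.

**S-score.** After rigid superposition, a residue with Cα deviation $d$
(Å) scores $s = 1/(1 + (d/d_0)^2)$ with $d_0 = 3.5$ Å, so $d = d_0$ gives
$s = 0.5$, and the inverse $d = d_0\sqrt{1/s - 1}$ converts similarities
back to Å. The superposition is iterative: starting from a Kabsch fit on
all shared residues, the fit is repeated on the residues deviating by less
than $d_0$, up to 10 rounds, keeping the (fit, scores) pair with the best
mean similarity among the iterates. The $d_0$ cutoff doubles as the core
definition so "well-modelled" means the same thing in the fit and in the
score. A consequence worth knowing: when a single residue sits exactly at
the cutoff, the best-mean rule may retain a compromise fit in which part of
the displacement is absorbed — the reported score is always exactly
$s(d_i)$ under the retained fit.

**lDDT.** Superposition-free: every reference atom pair in different
residues closer than the inclusion radius $R_0 = 15$ Å, with both atoms
present in the model, is checked for preservation of its distance within
each threshold (0.5, 1, 2, 4 Å); a residue's score is the mean over
thresholds of the preserved fraction of pairs touching it. Both all-atom
(default) and Cα-only modes are provided, since which of the two a trained
combiner should target is a user decision; the implementation is verified
against an independent brute-force enumeration in the test suite.

## Pure-single scores

**Contact-distance agreement (CDA).** The contact channel's intent is
agreement between sequence-predicted residue contacts and distances
realised in the model; the functional form here is this package's contract:
contacts with probability ≥ 0.5 and sequence separation ≥ 5 are considered,
a contact is satisfied when the Cβ–Cβ distance (Cα for glycine; ideal
reconstruction from N/Cα/C when Cβ is absent, to avoid mixing Cα and Cβ
geometry across models) is ≤ 8 Å, and a residue's score is the
probability-weighted satisfied fraction over the considered contacts
touching it. Residues touching no considered contact take the neutral score
0.5 — "no evidence" rather than "bad". All four numbers are exposed as
parameters (`cda_params()`); the 8 Å / separation-5 / p ≥ 0.5 values are
the standard contact-prediction conventions. The same operation is
instantiated three times (CDA, CDA_DMP, CDA_SC) with contact files from
different predictors.

**Secondary-structure agreement (SSA).** The model's observed 3-state
structure is assigned from backbone torsions: residues inside the helix box
(φ ∈ [−120, −30], ψ ∈ [−80, −5]) in runs of ≥ 4 become H, inside the strand
box (φ ∈ [−180, −45], ψ ∈ [45, 180] ∪ [−180, −170]) in runs of ≥ 3 become
E, all else C; at chain termini the defined angle alone must be in the box.
The torsion-box assigner replaces a hydrogen-bond-based program so the
package has no external binary dependency; the boxes are generous enough to
accept ideal and moderately distorted geometry. SSA itself is a pure
lookup: the predictor's probability of the observed state.

## Quasi-single scores

These compare the model against a reference ensemble built for the same
sequence (in production on the order of 135 models from a tertiary
structure predictor; any directory of PDB models works, and the package's
tests use 8).

* **MF5s** averages the iterative-superposition S-scores of the model
  against each usable reference (references sharing < 3 residues are
  skipped).
* **MFcQs** is superposition-free:
  $q_i = \langle \exp(-(d^{model}_{ij} - d^{ref}_{ij})^2 / 2\sigma_{ij}^2)\rangle_j$
  with Cα distances and $\sigma_{ij} = |i-j|^{0.15}$, following the
  Levitt–Gerstein Q convention for the separation-dependent tolerance;
  the exponent is a parameter.
* **DBA** compares sequence-predicted disorder with the ensemble's
  positional fluctuation. RMSF is computed about the per-residue mean after
  superposing every reference onto the first (a stable, documented frame —
  not an iterative mean structure), then squashed to (0, 1) by a logistic
  with midpoint 3.5 Å and unit steepness, so fluctuation at the S-score
  distance constant reads as 0.5 "disorder-likeness"; DBA = 1 − |disorder −
  fluctuation|. Both logistic parameters are exposed. Note DBA depends on
  the disorder prediction and the ensemble only — it is the same for every
  assessed model of a target, and consequently does not shrink when a model
  is truncated.

## The neural-network combiner

A sliding window of half-width 2 over the 13 tracks gives 65 inputs per
residue (5 offsets × 13 methods, offset-major ordering, documented and
serialized with the model); positions outside 1..L replicate the nearest
valid position (replication avoids fabricating zeros at termini) and
missing scores are imputed with the neutral 0.5. The network is a
single-hidden-layer perceptron, 65–33–1, logistic sigmoid throughout,
trained by full-batch gradient descent on mean-squared error. Plain batch
descent was chosen over stochastic or quasi-Newton optimisers for exact
reproducibility: the same seed and data give bit-identical weights. The
defaults (1500 epochs, learning rate 2.0) are sized for the 0–1 scaled
inputs and outputs; the training loss curve is recorded on the model
object, and training aborts with an informative error if the loss goes
non-finite. Two variants are trained — S-score targets and lDDT targets —
and predicted similarities are converted to Å errors via the inverse
S-score function, capped at 99.99 Å for output formats.

The canonical track order is serialized inside the combiner JSON, so a
trained model cannot silently be applied to misordered inputs; foreign or
reordered files are rejected at load time. Serialization keeps full double
precision (17 significant digits) and round-trips predictions
bit-identically.

Methods without an available track (for example the external single-model
programs when their outputs are not supplied) enter as all-missing tracks,
i.e. constant neutral 0.5 after imputation. The combiner then simply learns
to ignore those inputs; supplying the real tracks at prediction time only
makes sense for a combiner trained with them.

## Global scores, ranking and confidence

Every method's global score is the mean of its local scores with the
*target length* as denominator, so missing coverage counts as zero: a model
covering 70% of the target can score at most 0.7. This makes "fair
comparison of partial models" concrete and is checked end-to-end in the
acceptance suite (a 30% truncation must cost at least 25% of every
model-dependent global score; DBA is exempt by construction, see above).

Three global variants are convex combinations of component globals, with
weights user-overridable and validated to sum to 1: the ranking-optimised
variant averages the NN-S-score global with the two reference-comparison
globals (MF5s, MFcQs), whose strong model-selection behaviour it inherits;
the correlation-optimised variant averages the two NN globals, which are
trained to track the observed metrics; the balanced variant averages all
four. The exact compositions are a design choice of this package — the
variant names promise an intent, not a formula — and are the first thing to
re-tune against a real decoy benchmark.

Confidence is an empirical add-one upper-tail P-value against a null sample
of poor-model global scores, $p = (1 + \#\{null \ge g\})/(1 + n)$, with
tiers CERT/HIGH/MEDIUM/LOW/POOR at strict cutoffs 0.001/0.01/0.05/0.1. The
packaged default null is 999 balanced-variant globals of synthetic decoys
at 3–6 Å noise from three synthetic targets (regenerable with
`scripts/make_null_calibration.R`); with 999 values the smallest attainable
P-value is 0.001, i.e. HIGH. The null is synthetic and should be replaced
by a user-supplied sample of genuinely poor models for real-world
calibration.

## The synthetic benchmark

The generator builds everything the pipeline consumes, deterministically
from one seed:

* **Natives** with ideal backbone geometry (N, Cα, C, Cβ) from fixed bond
  lengths/angles and fold-specific torsions — helix (−57, −47), extended
  (−120, 130), or mixed: alternating helix (8) and strand (7) runs joined
  by 2-residue tight turns so the chain folds back on itself and genuine
  long-range contacts exist (an open ideal-geometry chain has almost none,
  which would leave the contact channel uninformative). Glycine and proline
  are excluded from the sampled sequences so every residue carries a real
  Cβ and the torsion boxes apply uniformly.
* **Decoys** by isotropic Gaussian coordinate noise (σ per noise level,
  default ladder 0/0.5/1/2/4 Å, 3 decoys per level), optionally truncated
  to fabricate partial models. Gaussian noise is simple and controllable
  and gives the monotone quality degradation the validation relies on, but
  it is locally unrealistic: real model errors are spatially correlated,
  preserve stereochemistry, and concentrate in loops. Passing tests on this
  benchmark demonstrates the pipeline's mechanics and calibration, not
  performance on real decoys.
* **Reference ensembles** as perturbed natives cycling through 0.5/1/2 Å
  noise — emulating a usable but imperfect reference set. Production
  defaults assume ~135 reference models; tests and the acceptance script
  use 8 (the methods average over the ensemble, so the statistic is the
  same, only noisier).
* **Predictions** with controllable fidelity: true native Cβ contacts are
  emitted with probability `contact_fidelity` at p ~ U(0.7, 1), false pairs
  at rate 1 − fidelity with p ~ U(0.5, 0.8); secondary structure puts the
  fidelity mass on the native state; disorder is one minus the
  logistic-normalised native contact count. The default fidelity 0.9
  represents good modern predictors.
* **External-track stand-ins**: the six ingested single-model methods are
  emulated as noise-corrupted copies of the observed S-score (sd 0.06–0.12),
  with the template-based error stand-in written in Å to exercise the
  distance-ingestion path. These are labelled synthetic throughout; they
  make the 13-input layout non-degenerate but encode no independent
  information channel.

## Numerical choices and degenerate inputs

* Kabsch superposition uses the SVD construction with explicit reflection
  correction; fewer than 3 points or collinear point sets are errors
  (second singular value below 1e−8 of the first).
* Distance matrices are computed densely; at the intended problem sizes
  (hundreds of residues, ≤ a few thousand atoms) this is well within
  memory.
* Score tracks validate values into [0, 1] with a 1e−9 slack for float
  noise and clamp; missing is `NA`, never 0.
* Ties in ranking break by mean local similarity, then model id, making
  rankings invariant to input order.
* An all-missing track yields a global score of 0 with a warning; an empty
  contact set yields a neutral CDA track with a warning rather than an
  error, since downstream imputation handles both.
* PDB output echoes input ATOM records byte-for-byte outside the b-factor
  column (trailing whitespace trimmed), so coordinates survive annotation
  round-trips exactly; b-factors clamp to 99.99.

## Problem sizes used in validation

The test and acceptance runs use 40-residue mixed-fold targets, 15-decoy
noise ladders, reference ensembles of 8, four training targets
(≈ 2400 windowed training examples) and one held-out target. These sizes
were chosen so the full suite exercises every pipeline stage end-to-end at
interactive speeds; all of them scale up through `fixture_spec()` without
code changes.

## Known limitations

* The synthetic decoy model (isotropic Gaussian noise) does not emulate
  real error modes; conclusions about real-data accuracy require real
  benchmarks.
* Single-chain models only; the first chain with ATOM records is used.
  mmCIF, insertion-code arithmetic and NMR multi-model files (beyond the
  first MODEL) are out of scope.
* The torsion-box secondary-structure assigner is cruder than
  hydrogen-bond-based assignment, particularly for distorted strands.
* The global variant compositions and the confidence null are package
  contracts, not fitted to external data; both are designed to be
  overridden.
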