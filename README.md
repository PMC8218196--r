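# modfoldkit

Hybrid per-residue and global quality estimation for 3D protein models.

## The problem

Structure-prediction pipelines routinely emit dozens of alternative 3D models
for one protein sequence, and even the best of them contain local errors.
Before a model is used for downstream biology, three questions need answers:
which of the candidate models is best, how good is it, and *where* are its
errors? Model quality assessment (QA) methods answer these without access to
the experimental structure. `modfoldkit` implements a hybrid QA pipeline for
single models in the ModFOLD lineage: it combines **pure-single** scores
(computed from one model plus sequence-based predictions) with
**quasi-single** scores (computed by comparing the model against a reference
ensemble of models built for the same sequence), and stacks them with a small
neural network into per-residue and global accuracy estimates.

The package is aimed at structural bioinformaticians who need reproducible
local/global quality estimates, annotated models and CASP-format QA files
from R, plus a fully synthetic, seed-deterministic benchmark generator for
training and validating the combiner without any external data.

## The method

Thirteen per-residue score tracks, each a value in [0, 1] per target
position, feed the combiner:

* **CDA, CDA_DMP, CDA_SC** — contact-distance agreement: the
  probability-weighted fraction of predicted residue contacts (three
  independent contact sources, CASP RR format) that the model satisfies with
  a Cβ–Cβ distance ≤ 8 Å at sequence separation ≥ 5.
* **SSA** — secondary-structure agreement: the predictor's probability of the
  3-state secondary structure the model actually realises (torsion-box
  assignment from φ/ψ).
* **ProQ2, ProQ2D, ProQ3D, ProQ4, VoroMQA, ResQ** — ingested external
  single-model scores (plain `pos score` tables; Å-valued tracks are
  converted through the inverse S-score function).
* **DBA** — disorder/B-factor agreement: 1 − |predicted disorder −
  logistic-normalised RMSF of the reference ensemble|.
* **MF5s** — mean per-residue S-score of the model against each reference
  model under iterative superposition, where
  `s = 1 / (1 + (d/d0)²)`, `d0 = 3.5 Å`.
* **MFcQs** — superposition-free Q-score:
  `q_i = mean_j exp(−(d_ij^model − d_ij^ref)² / 2σ_ij²)`, `σ_ij = |i−j|^0.15`.

A sliding window (size 5) over all 13 tracks gives **65 input neurons**,
feeding an MLP with **33 hidden** sigmoid units and **1 output**: the
predicted per-residue similarity. Two variants are trained — one against
observed S-scores, one against observed lDDT — and predicted similarities are
converted to per-residue Cα error estimates in Å via the inverse S-score
function `d = 3.5 √(1/s − 1)`. Global scores are means of local scores over
the full target length (so partial models are penalised by missing
coverage), and three composed global variants are reported: a
ranking-optimised score, a correlation-optimised score, and a balanced
score, each a convex combination of component globals. An empirical add-one
P-value against a null sample of known-poor models yields confidence tiers
(CERT/HIGH/MEDIUM/LOW/POOR).

Observed-quality oracles are included for training and evaluation: the
S-score under iterative Kabsch superposition, and a superposition-free lDDT
(inclusion radius 15 Å; thresholds 0.5, 1, 2, 4 Å; all-atom or Cα-only).

## Worked example

Everything below is synthetic and deterministic in the seeds: a 40-residue
mixed α/β target, decoys at coordinate noise σ = 0…4 Å, a reference ensemble
of 8 perturbed models, and contact/secondary-structure/disorder predictions
at 0.9 fidelity.

```r
library(modfoldkit)

bench <- generate_benchmark(fixture_spec(L = 40, seed = 11, refset_size = 8))
cfg_s <- combiner_config(target_metric = "sscore", seed = 7, epochs = 600)
cfg_l <- combiner_config(target_metric = "lddt",   seed = 7, epochs = 600)
td_s  <- collect_training_data(bench, "sscore", cfg_s)
td_l  <- collect_training_data(bench, "lddt",   cfg_l)
comb_s <- mlp_train(td_s$features, td_s$targets, cfg_s)
comb_l <- mlp_train(td_l$features, td_l$targets, cfg_l)

test <- generate_benchmark(fixture_spec(L = 40, seed = 12, refset_size = 8))
res  <- score_models(test$target, test$decoys[c(1, 7, 13)], test$contacts,
                     test$ss, test$disorder, test$refset, comb_s, comb_l,
                     external_tracks = test$external)
rank_models(res)
#> # A tibble: 3 × 8
#>    rank model_id       modfold8 modfold8_rank modfold8_cor mean_local p_value tier
#>   <int> <chr>             <dbl>         <dbl>        <dbl>      <dbl>   <dbl> <chr>
#> 1     1 decoy_01_s0_r1    0.837         0.826        0.905      0.943   0.001 HIGH
#> 2     2 decoy_07_s1_r1    0.699         0.711        0.755      0.849   0.001 HIGH
#> 3     3 decoy_13_s4_r1    0.204         0.234        0.171      0.226   0.656 POOR
```

The σ = 0 decoy ranks first with a high global score and a confident
P-value; the σ = 4 Å decoy falls in the null range of poor models. Comparing
predictions with the observed S-scores against the native:

```r
evaluate_predictions(res, test$observed_sscore[c(1, 7, 13)])
#> # A tibble: 1 × 4
#>   n_models global_pearson_r residue_pearson_r mean_abs_global_diff
#>      <int>            <dbl>             <dbl>                <dbl>
#> 1        3            1.000             0.991                0.116
```

Per-residue error profiles (`autoplot(res)`), b-factor-annotated PDBs, a
per-model error TSV and a CASP QA (QMODE 2) file are written with
`write_result_bundle(res, models, "outdir/")`. A thin command-line wrapper
(`exec/modfoldkit`) exposes the same pipeline as `simulate`, `train`,
`score`, `observed`, `score-single` and `score-quasi` subcommands.

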