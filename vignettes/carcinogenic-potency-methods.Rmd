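---
title: "Predicting carcinogenic potency: models, labels and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting carcinogenic potency: models, labels and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Animal carcinogenesis bioassays are slow and expensive, so experimentally
characterized carcinogens number only in the low thousands. `carcipred`
implements a structure-based predictor of *continuous* carcinogenic potency:
given a molecule, it predicts the log-reciprocal TD50, the dose-rate
(mg/kg body weight/day) at which the probability of remaining tumor-free is
halved. Using a continuous dose-rate target instead of a binary carcinogen
label preserves the orders-of-magnitude differences in potency that matter
for real exposure assessment, and sidesteps the maximum-tolerated-dose
problem in which compounds carcinogenic only at physiologically implausible
doses receive the same label as potent carcinogens.

## Labels: from per-experiment TD50s to a training target

Under the proportional-hazards dose model
$\lambda(t, d) = (1 + \beta d)\,\lambda_0(t)$, the TD50 equals
$\log(2)/\hat\beta$, with $\beta = 0$ meaning no dose–tumor relationship.
Databases report several experiments per compound; `aggregate_td50()` takes
the **harmonic mean** over the experiments with a finite TD50, which biases
the aggregate toward the low values — the experiments that did demonstrate
carcinogenicity. The rationale: one positive experiment indicates the
compound can be carcinogenic under some conditions. Experiments with no
tumor response never enter the mean.

The training target is $y = \log_{10}(1/\mathrm{TD50})$: higher = more
potent. Molecules whose experiments were all negative receive a sentinel
label, $-1.62$ by default, placed below the observed potency range so the
regression also learns the carcinogenic/non-carcinogenic distinction; the
sentinel is configurable and flagged in all outputs. The log base (10) is a
package choice — only "log reciprocal" semantics are inherent to the scale.

`estimate_td50_hazard()` closes the loop for simulated bioassays: it
maximizes the binomial likelihood of dose-group tumor counts under the
hazards model (cumulative baseline hazard normalized to 1 at the assay
horizon) and recovers TD50 as $\log(2)/(\hat\lambda_0\hat\beta)$.

## Model

Two feature streams are concatenated into one input block:

* **Fingerprints** — 2048-bit circular (Morgan/ECFP, radius 2 by default,
  the ECFP4 equivalent), 2048-bit path (linear substructures of 1–7 bonds),
  and the 166-key structural-key catalogue plus one padding bit (167). The
  structural keys are kept at their native 167 bits rather than padded to
  2048; the fingerprint block is therefore 4263 bits.
* **Graph embedding** — a message-passing encoder over the molecular graph
  (atom features: atomic number, mass, formal charge, degree, aromatic and
  ring flags; bond features: order, aromatic and ring flags). Each of $L$
  rounds computes $m_i = \sum_{j \in N(i)} (A h_j + B e_{ij})$ followed by
  $h_i = \sigma(W m_i + b)$; sum aggregation with an edge-conditioned linear
  map is the package's choice where the message construction is open. A
  scaled-dot-product attention block over **all** nodes follows the final
  round — attention deliberately ignores edges, extending the receptive
  field beyond bonded neighborhoods — and mean pooling produces a
  fixed-length embedding. Scores are scaled by $\sqrt{d_\text{head}}$ by
  default; an `attn_scale = "d"` variant (dividing by the head width
  itself) is exposed because both conventions appear in the literature.
  The encoder is used **frozen** with a seeded random initialization, as a
  fixed structural featurizer; `load_external_embeddings()` accepts
  precomputed per-molecule embeddings from any stronger pre-trained
  embedder in its place.

The predictor head is a 5-layer MLP (dropout 0.1, batch normalization, ReLU
at every layer) with two linear outputs sharing the trunk: a
carcinogenicity regression head (MSE on log-potency) and a mutagenicity
classification head (logistic link, binary cross-entropy). Sharing the
trunk while keeping separate output layers is what lets alternated training
transfer representation without sharing the task-specific read-out.
Hidden widths default to 1024–512–256–128–64; depth and dropout rate are
structural, widths are configuration.

## Multi-round pre-training

Mutagenicity (Ames-type) data are roughly an order of magnitude more
abundant than carcinogenicity data but noisier and only ~70% concordant
with animal carcinogenicity. `multi_round_pretrain()` alternates
early-stopped phases — mutagenicity, then carcinogenicity — for `rounds`
cycles (default 3, where gains saturate), always ending on
carcinogenicity. Weights carry across phases; the Adam optimizer state is
reset at each boundary. Early stopping monitors validation loss with the
best **post-epoch** checkpoint returned (the untrained incoming model is
never a candidate), patience 10 by default.

## Splitting, sweeps, ensembling

All splits group molecules by canonical SMILES first
(`dedup_split()`), so alternative spellings of one structure can never
appear on both sides of a split — the data-leakage failure mode of naive
random splits. `sweep_configs()` ranks hyperparameter settings by mean
validation Pearson over threefold CV, and `build_ensemble()` averages the
predictions of the top three.

## Evaluation statistics

Pearson correlation and MSE for the continuous task; ROC AUC (midrank
Mann–Whitney formula, ties counting one half) and PR AUC (step-wise
interpolation, chosen over linear interpolation to avoid optimistic bias)
for binary external validation, using raw continuous predictions as scores.
Uncertainty is the SD over 1000 paired bootstrap resamples. ROC AUCs of two
models on the same test set are compared with the one-sided DeLong test
(classical structural-components variance estimator; identical score
vectors return p = 0.5, and exactly separated score pairs are decisive);
per-seed metric vectors are compared with a two-sided t-test.

## Dataset distances

Tanimoto similarity over binary circular fingerprints is the kernel for the
unbiased empirical maximum mean discrepancy between dataset partitions
(within-set means exclude the diagonal; the estimator can be negative and
is reported unclamped, including on the diagonal of a partition matrix).
`diversity()` reports the mean pairwise Tanimoto distance within a set.

## Counterfactual interpretability

To explain a prediction, `sample_subspace()` generates a cloud of nearby
valid molecules by random string edits of the tokenized SMILES — atom
substitutions, branch insertions from a fragment library that includes
toxicophore-bearing groups, and branch/terminal deletions — with 1–3 edits
per sample and aggressive validity filtering (parse + valence audit +
canonical deduplication). This is the package's own design for local
chemical-subspace sampling: rather than relying on a mutation-robust string
encoding, it guarantees validity by filtering, which keeps the sampler
dependency-free; the accepted cost is attrition (typically 30–50% of
attempts survive). A *positive counterfactual* is the minimal-Tanimoto-
distance sample whose prediction exceeds an upper threshold; a *negative*
one falls below a lower threshold. Default thresholds are the base
prediction ± 1 SD of the model's training-set predictions, since no
canonical threshold exists; absolute thresholds are supported.

`enrichment_table()` then compares toxicophore frequencies (seven classical
structural alerts shipped as a SMARTS catalogue: nitroso, aliphatic halide,
aromatic nitro, aromatic amine, three-membered heterocycles, azo,
heteroatom–heteroatom) between originals and their counterfactuals:
frequencies in percent, the frequency ratio relative to originals (the
convention used in published enrichment tables; cross-product odds ratios
are also emitted), two-sided Fisher exact tests, and Benjamini–Hochberg
adjustment across toxicophores within each group.

## The synthetic benchmark

`make_benchmark()` builds a fully synthetic three-role benchmark so every
pipeline stage is testable offline:

* **Molecules** are assembled from alkyl/cycloalkyl/benzene scaffolds with
  random chains, branches and neutral decorations; with probability
  `planted_fraction` (0.35) a toxicophore fragment — nitroso or aromatic
  nitro, both strong and easily SMARTS-detectable — is grafted at a
  valence-legal site by template substitution, which guarantees validity
  without a generic editing engine.
* **Potency**: latent log-potency $z$ = baseline ($\mu = -1.2$, molecule-
  level SD 0.4) + 2.0 log-units per planted toxicophore. Each of 1–4
  experiments per molecule is non-carcinogenic with probability
  $\text{logit}^{-1}((z_{nc} - z)/s)$ ($z_{nc} = -0.8$, $s = 0.4$),
  keeping the sentinel path exercised, and otherwise reports
  $\mathrm{TD50} = 10^{-z}$ with 0.3 log-units of experiment noise.
* **Mutagenicity** labels flip the binarized ground truth independently
  with probability 0.3, hitting the ~70% concordance regime.
* The **external test set** takes the extremes of the latent potency
  spectrum from a fresh molecule pool (deduplicated against training by
  canonical SMILES), mimicking expert-panel test sets selected from either
  end of the carcinogenicity spectrum — which is also why its inter-class
  MMD exceeds the training set's.

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, activity cliffs, assay batch effects, or
toxicophores the fingerprints cannot see. Passing benchmarks here shows the
pipeline is correct and that the training signal flows as designed — not
that real-data performance will match.

## Benchmark problem sizes and the ablation

The packaged ablation (`ablation_experiment()`) runs at deliberate desk
scale: 1500 training molecules, 3000 mutagenicity molecules, 400 external
test molecules, a 512-bit circular fingerprint, a 32-dimensional frozen
encoder (L = 2, width 32, 4 heads), and a narrow 64–32–32–16–8 trunk
trained with Adam (lr 1e-3, batch 256, ≤25 epochs/phase, patience 4).
Embedding columns are standardized on the training set before entering the
MLP — raw atom features span orders of magnitude (atomic mass), and
unscaled random projections would drown the binary fingerprint block.
Training/validation/holdout are carved 60/20/20 from the training role with
the dedup split. Across 20 matched seeds the mean holdout Pearson
reproduces the qualitative ablation ordering: multi-round pre-training >
single pre-training round > fingerprint-only, with the frozen encoder
contributing a smaller additive gain.

## Numerical choices and degenerate inputs

* Canonical SMILES are implementation-defined (OpenBabel's algorithm);
  within-run consistency is guaranteed, cross-toolkit string equality is
  not.
* Invalid SMILES at dataset load are skipped and logged by default
  (`strict = TRUE` fails fast); the valence audit rejects structures the
  permissive parser accepts (e.g. pentavalent carbon).
* Batch-norm batches of size 1 are skipped during training; eval mode uses
  running statistics and is batch-composition invariant.
* Tanimoto is undefined for two all-zero vectors and raises an error;
  single-molecule partitions cannot enter MMD (the unbiased estimator
  divides by $n(n-1)$).
* Ties in counterfactual selection resolve to the first minimal-distance
  sample in a stable order; Fisher tests are two-sided; BH adjustment is
  applied per counterfactual group across the seven definitions.

## Known limitations

The frozen random-init encoder is a structural featurizer, not a learned
chemical representation; the plug-in embedding slot exists precisely so a
pre-trained embedder can replace it. The SMILES-edit sampler cannot reach
ring-rearranged neighbors easily, so counterfactual subspaces are biased
toward substituent chemistry. Stereochemistry, tautomers and 3D conformers
are out of scope throughout.
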