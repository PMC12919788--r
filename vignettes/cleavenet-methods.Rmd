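---
title: "Modeling PIWI cleavage rates from duplex geometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PIWI cleavage rates from duplex geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cleavenet)
```

## Scope

`cleavenet` is a regression framework for pre-steady-state cleavage rates
$k$ of piRNA-guided PIWI endonucleases, measured per target variant of a
guide in high-throughput in vitro assays. The package covers the full
desk-scale pipeline: interaction-centric feature encoding, the hybrid
convolution/attention predictor with hand-written backpropagation,
training with a composite MAE–Pearson objective, leave-one-guide-out
(LOGO) evaluation, ablation variants, classic-regressor baselines over
alternative encodings, gradient-saliency and counterfactual positional
analyses, and a synthetic variant-library generator with a known rate law
for validation by parameter recovery.

## The interaction encoding

The central modeling commitment is that cleavage is governed by the
*geometry of the guide–target duplex*, not by the two sequences in
isolation. Each guide position $i \in 1..L$ (default $L = 26$) carries

$$X_i = [\,G_i \in \{0,1\}^4,\; m_i \in \{0,1\}^2,\;
        e_i \in \{0,1\}^4,\; d_i \in \{0,1\}\,] \in \{0,1\}^{11}$$

with channel order A, C, G, U for both $G$ and $e$. Exactly one of the
three pairing states is active per position: a Watson–Crick match,
recorded *by mode* in $m$ (A–U pairs form two hydrogen bonds, C–G three,
so the two modes carry different stabilities); a mismatch, recorded by
*target-nucleotide identity* in $e$ (a structurally mild G–U wobble and a
disruptive A–A clash are different inputs — a binary mismatch flag would
conflate them); or a deletion ($d_i = 1$, no paired target nucleotide).
Wobbles are always encoded as mismatches: partial stability is something
the model can learn from the identity channels, not a pairing state of its
own. Insertions between guide positions are boundary events, so they live
in a separate binary vector $I \in \{0,1\}^{L+1}$ (slot 0 is 5′ of g1,
slot $j$ immediately 3′ of position $j$). Several inserted nucleotides at
one boundary collapse to a single flag, and inserted-base identity is not
represented — a known limitation of this encoding.

Two printed-layout ambiguities in the source material were resolved in
favor of internal consistency: the per-position input is fixed at 11
channels (4 + 2 + 4 + 1), and the regression head's hidden width is fixed
at 64 (matching the output layer's input dimension). The A–U/C–G match
channel order and the A,C,G,U identity order are conventions chosen once
for reproducibility; no result depends on them.

## Predictor architecture

Per position, $h_i^{(0)} = W_G X_i + b_G$ with $W_G \in R^{11 \times d}$,
$d = 16$; a learnable positional table $p_i \in R^d$ is added, giving the
model an explicit notion of *where* in the guide an interaction occurs. A
1D convolution (16 filters, kernel 3, zero padding so length is
preserved) detects trinucleotide-scale motifs such as contiguous pairing
across the catalytic core; a 3-layer post-LN transformer encoder (4
heads, feed-forward width $4d$, ReLU, dropout 0.1) contextualizes each
position against the whole duplex, capturing effects such as a distal
bulge perturbing cleavage. The insertion vector is embedded separately
($z = W_I I + b_I$, $d' = 8$) and concatenated with the flattened
attention output before a 64-unit ReLU head predicts $\hat k$ in
z-score-normalized rate space.

Transformer internals are not fully pinned down by the reference
description; the blocks here are the common small-encoder default
(multi-head self-attention with residual connections and layer
normalization after each sublayer, position-wise feed-forward of width
$4d$). None of the package's claims depend on these internals.

No autodiff framework is involved: forward and backward passes are
written out analytically (base R, with an RcppArmadillo kernel for
batched attention). This is verified two ways in the test suite — the
forward pass against an independently written naive per-position
implementation, and all gradients against central finite differences
(relative error $\le 10^{-5}$ for parameters, $\le 10^{-4}$ for the
saliency pathway).

### Ablation variants

`model_config(ablation = ...)` builds four reduced models: `NO_POSITION`
drops the positional table; `PURE_CNN` removes the transformer and
flattens the convolution output directly; `SIMPLE_PAIRING` collapses
$m$ and $e$ to one binary match channel (6 input channels); `NO_INSERT`
removes the insertion branch. These are structural changes to the
parameter set, not masks, so parameter counts differ accordingly
(`count_parameters`).

## Training objective and protocol

The loss is $\alpha \cdot \mathrm{MAE} + (1-\alpha)(1 - \mathrm{PCC})$
with $\alpha = 0.8$: absolute-error accuracy for quantitative rate
prediction, plus a correlation term that preserves variant ranking.
Numerical choices:

- Inside the loss the correlation uses population (divide-by-$N$)
  standard deviations with an $\varepsilon = 10^{-8}$ guard added to each
  SD; a constant prediction batch is then maximally penalized
  (Pearson term $\approx 1$) rather than NaN. Reported metrics use the
  ordinary sample correlation and raw-rate MAE.
- Rates are z-scored with moments fitted on training records only;
  leakage is asserted by test (perturbing held-out rates changes nothing).
- Optimization is AdamW (reference settings: lr $10^{-4}$, decoupled
  weight decay 0.1 applied to all parameters, batch size 128), with the
  learning rate halved after 5 epochs without validation-loss improvement
  and an early stop when it falls below $10^{-6}$. The final incomplete
  minibatch is kept; a size-1 tail is merged into its predecessor so the
  Pearson term stays defined.
- Initialization: uniform fan-in for weight matrices, zero biases,
  Normal(0, 0.02) positional table; every build is a pure function of
  its seed.

Epoch selection uses an inner validation split (a seeded 10% of the
training records). By default the returned model carries the weights of
the best-validation-MAE epoch directly; `train_config(retrain = TRUE)`
instead retrains on the full training set for that many epochs (the
two-stage protocol). Best-epoch checkpointing was made the default
because it is the standard equivalent and halves the compute of every
cross-validation fold; both paths are tested.

LOGO cross-validation holds out *all* records of one guide per fold —
the only protocol that measures transfer to unseen guide sequences.
Folds are keyed by sorted guide id, so fold membership is invariant to
record order. The pooled "mixed" protocol (75/25 random split) measures
within-guide interpolation instead. Repeated runs differ only in the
training seed; paired two-sided t-tests compare per-seed scores, with
the conventions $p = 1$ when all paired differences are zero and
$p \to 0$ for a nonzero constant difference.

## Interpretability

Saliency is the plain batch-averaged absolute gradient
$S_i = E_B[\sum_d |\partial \hat k / \partial G_{id}|]$ — not
gradient×input and not a smoothed variant, so it matches a direct
finite-difference probe of the model. The counterfactual impact
$\Delta_i$ replaces a mismatch at position $i$ with the perfect
Watson–Crick match implied by the guide base (A/U → A–U channel, C/G →
C–G channel), leaving everything else untouched, and averages the
prediction change over the records mismatched at $i$; the sign
convention (matched − original) makes positive $\Delta_i$ mean "the
mismatch was deleterious". Deletions are deliberately *not* pooled into
$\Delta_i$: substituting a deletion is a different intervention. Both
profiles default to the evaluation set as the averaging batch, carry NA
(never silent zeros) at unsupported positions, and aggregate across seed
models as mean ± SD. Both scale linearly with the final layer — a
covariance property asserted by test.

## The synthetic generator

`generate_benchmark()` emulates the structure of systematic cleavage
assays: per guide, a perfect-complement target, all three mismatch
identities at each scanned position g2–g20, optionally all consecutive
double mismatches, single deletions, single insertions, and optional
perfect-match replicates. Rates follow a multiplicative law on $k$
(additive on $\log k$):

$$\log k = \beta_0 - \sum_{i \in \mathrm{mm}} w_i\, \mathrm{mtype}[g_i, t_i]
 - \sum_{i \in \mathrm{del}} w_i\, \mathrm{del}
 - n_{\mathrm{ins}}\, \mathrm{ins} + \varepsilon,\qquad
 \varepsilon \sim N(0, \sigma^2)$$

with $w$ unimodal (maximum inside g9–g11, intermediate over the seed
g2–g8, near zero from g20), wobble pairs given the mildest type
multiplier, and $\sigma = 0.2$ by default — large enough that the task is
nontrivial, small enough that the signal is recoverable at the default
library size (~266 records/guide). A multiplicative law was chosen
because rates are positive and mismatch effects present as rate
reductions; no claim is made that this is the true biochemical law. The
generator does **not** emulate guide-specific rule deviations (available
as an optional perturbation flag), heteroscedastic measurement error,
sequence-composition biases, or the kinetic-fitting stage upstream of
$k$ — so passing recovery tests demonstrates correctness of the
machinery, not real-data performance.

Because the law is linear in the flattened interaction basis *within one
guide* (mismatch penalties couple guide and target identity), per-guide
ordinary least squares on noiseless data is an exact brute-force oracle:
residuals and recovered penalty products agree to $10^{-6}$, grounding
all downstream recovery tests.

### Desk-scale study conditions

The validation experiments run at deliberately small scale, with sizes
chosen once as the package's study conditions:

- *Recovery*: 4 guides × 266 records (default design), LOGO-CV, 3
  training seeds, lr $3\times10^{-3}$, 30 epochs. At a few hundred
  minibatch steps the reference learning rate of $10^{-4}$ cannot move
  the parameters appreciably, so the small-benchmark runs use the larger
  rate; the reference settings remain the config defaults. Measured on
  this benchmark: held-out-guide PCC ≈ 0.78–0.80 and Spearman agreement
  ≈ 0.97–0.99 between the counterfactual profile and the true $w$.
- *Pairing-detail ablation*: the `wobble_sensitive` rule maximizes the
  spread of mismatch-type multipliers; under it the full encoding beats
  `SIMPLE_PAIRING` on every paired seed (the binary encoding faces
  irreducible within-position variance).
- *Insertion ablation*: tested on an insertion-rich library balanced
  with 27 perfect-match replicates per guide. The balance matters: with
  a single perfect-match record, nearly every all-match input pattern in
  training *is* an insertion variant, so an insertion-blind model loses
  almost nothing by predicting the insertion-class mean; replicated
  perfect-match controls force it to misfit both classes. Differences
  per seed sit within split noise at this scale, so the assertion is on
  the paired mean over 3 seeds.

## Baselines

The encoding-by-regressor benchmark grid pits the interaction encoding
against three sequence-based strategies (concatenated one-hot, k-mer
counts with $k = 3$, and a small trained convolutional feature extractor
over stacked guide/target one-hots: 16 filters, width 3, ReLU, global
max-pool, fitted end-to-end with a linear head on the training records
and then frozen). Regressors go through the standard packages: glmnet
(ridge), randomForest (random forest; bagging = forests with
mtry = p), ranger (extra trees), xgboost (both gradient-boosting
settings), nnet (MLP), caret (kNN). AdaBoost.R2 is implemented over
rpart trees because no installed package offers AdaBoost regression; the
FFNN baseline reuses the package's own optimizer. Targets in guide
coordinates are reconstructed from the pairing specification (deletions
as gaps, insertions unrepresentable), which is exactly the information
loss these baselines are meant to expose: k-mer features cannot separate
positional anagrams, and concatenated one-hots carry no pairing
information at all.

## Degenerate inputs and edge conventions

- A guide with fewer than 3 nt, a mismatch annotation equal to the guide
  complement, non-positive rates, and malformed pairing strings are all
  rejected with the offending token or row named.
- A LOGO fold whose guide has a single record reports PCC as missing,
  never fabricated.
- Constant training rates make z-scoring undefined and error out.
- Replicated records in one batch produce identical predictions;
  agreement across different batch placements holds to BLAS row-blocking
  precision (~$10^{-15}$ relative), which is a floating-point
  associativity effect, not state leakage.

## Known limitations

The model is validated here only against synthetic libraries; real
CNS-seq-style data differ in noise structure, dynamic range and
guide-sequence diversity. Inserted-base identity is not encoded. The
transformer internals and the cnn-embed extractor are reasonable
defaults, not tuned architectures. MAE is reported in raw rate units,
which are only meaningful relative to the assay's time units.
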