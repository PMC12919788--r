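# cleavenet

Position-aware modeling of PIWI-mediated RNA cleavage rates from
guide–target duplex geometry.

## The problem

PIWI-clade Argonaute proteins (e.g. mouse MILI and MIWI), guided by a bound
piRNA, cleave complementary RNA targets. Unlike miRNA- or siRNA-guided
silencing, PIWI targeting is flexible: mismatches are tolerated at almost
any position, yet pairing at the catalytic core (guide positions g9–g11) is
critical. High-throughput in vitro assays measure a pre-steady-state
cleavage rate k for thousands of target variants of one guide — single and
double mismatches, deletions, insertions — but each guide/protein
combination is a major experimental effort. `cleavenet` learns the mapping
from duplex geometry to cleavage rate so that cleavage behavior can be
predicted for variants and guides that were never assayed, and so that the
learned model can be interrogated for position-specific pairing rules.

## The model

Each guide position i is described by an 11-dimensional interaction vector
`X_i = [G_i, m_i, e_i, d_i]`:

- `G_i ∈ {0,1}^4` — guide nucleotide one-hot (A, C, G, U);
- `m_i ∈ {0,1}^2` — Watson-Crick match by mode (A–U vs C–G, which differ
  in thermodynamic stability);
- `e_i ∈ {0,1}^4` — target-nucleotide identity at a mismatch, so a G–U
  wobble is distinguishable from an A–A clash;
- `d_i ∈ {0,1}` — deletion flag (no paired target nucleotide);

plus a binary insertion vector `I ∈ {0,1}^{L+1}` over the boundary slots
between guide positions. The predictor is

    h_i = W_G X_i + b_G + p_i                  (embedding + positional table)
    H_local  = ReLU(Conv1d(H, kernel 3))       (local duplex motifs)
    H_global = Transformer(H_local)            (long-range context, 3 layers,
                                                4 heads)
    z = W_I I + b_I                            (insertion embedding)
    k̂ = W_2 ReLU(W_1 [Flatten(H_global) ∥ z] + b_1) + b_2

trained with AdamW on the composite objective

    L = α · MAE(k, k̂) + (1 − α) · (1 − PCC(k, k̂)),   α = 0.8

on z-score-normalized rates. Evaluation uses leave-one-guide-out
cross-validation (every record of one guide held out per fold) and a pooled
75/25 split. Four ablations (NoPosition, PureCNN, SimplePairing, NoInsert)
isolate the contribution of each component. Gradient saliency
`S_i = E[Σ_d |∂k̂/∂G_id|]` and counterfactual mismatch impact
`Δ_i = E[f(matched at i) − f(original)]` turn the fitted model into
per-position pairing rules. The forward pass and its analytic
backpropagation are implemented in base R with an RcppArmadillo kernel for
batched multi-head attention; gradients are verified against central finite
differences in the test suite.

A synthetic variant-library generator with a known parametric rate law
(position weights peaking at g9–g11, mismatch-type multipliers with mild
wobbles, indel penalties, log-normal noise) provides an end-to-end testbed:
models trained on simulated libraries must recover the planted positional
importance.

## Worked example

```r
library(cleavenet)

# simulate a 4-guide benchmark (~1,000 records) with a known rate law
bench <- generate_benchmark(n_guides = 4, seed = 11)
bench$data
#> <cleavage_dataset> 1064 records, 4 guide(s): guide1, guide2, guide3, guide4
#>   k range: [0.06902, 1.432]

# leave-one-guide-out cross-validation of the full model
cv <- leave_one_guide_out(bench$data, model_config(),
                          train_config(lr = 3e-3, max_epochs = 30),
                          seed = 101)
cv
#> Leave-one-guide-out cross-validation
#>  fold guide_id n_test       pcc       mae
#>     1   guide1    266 0.7716085 0.1357538
#>     2   guide2    266 0.8387966 0.1190464
#>     3   guide3    266 0.7599027 0.1331692
#>     4   guide4    266 0.7550054 0.1284746
#>   mean held-out PCC 0.781, mean MAE 0.1291
```

A held-out-guide PCC near 0.78 means the model predicts cleavage rates for
variants of a guide it never saw during training. The counterfactual
profile recovers the generator's positional importance:

```r
prof <- counterfactual_profile(cv$models, bench$data)
cor(prof$scores, bench$rule$w, method = "spearman", use = "complete.obs")
#> [1] 0.9877193
profile_report(prof)[9:11, ]   # catalytic-core rows g9-g11 score highest
#>    position     score         sd support         region
#> 9        g9 1.1409762 0.08173321      84 catalytic_core
#> 10      g10 0.8976045 0.06092910      84 catalytic_core
#> 11      g11 1.1366233 0.04641223      84 catalytic_core
```

Positive `Δ_i` means a mismatch at position i was predicted deleterious;
on the default benchmark the profile peaks at g9–g11 and decays toward the
guide 3' end, mirroring the planted rule.

A single fit with the classic modelling interface:

```r
fit <- cleavenet(bench$data, model = model_config(),
                 training = train_config(lr = 3e-3, max_epochs = 30),
                 seed = 1)
summary(fit)
predict(fit, bench$data[1:5])   # de-normalized rates
```

A thin command-line wrapper (`inst/cli/cleavenet-cli`) exposes
`simulate`, `train`, `crossval`, `benchmark`, `explain` and `predict`
over TSV cleavage tables; see `?run_cli`.

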