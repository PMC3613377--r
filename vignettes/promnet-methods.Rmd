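---
title: "promnet: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{promnet: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

promnet predicts the relative expression strength of a fixed-length
promoter + RBS element from its sequence, and inverts that prediction to
design elements of prescribed strength. This vignette records the model, its
assumptions, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the design decisions taken where more than one
reasonable construction existed. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The regression model

**Encoding.** Each base maps to a 4-bit one-hot block in the fixed order
(A, G, C, T); blocks are concatenated base-major. A 224-nt element therefore
becomes an 896-long binary vector, which fixes the input-layer width. The
encoding is defined only for A/C/G/T: ambiguity codes and gaps are hard
errors rather than being silently resolved, because a silently mis-encoded
training example corrupts the fit without any visible symptom. Input is
upper-cased on entry (FASTA files mix case). All sequences in a library must
share one length; elements with indels are out of scope — the model has no
mechanism for aligning variable-length input to a fixed input layer.

**Network.** One hidden layer; logistic (`logsig`) activations on both the
hidden and the output layer. Because the output lives in (0, 1) while
strengths reach above 1, targets are divided by the maximum training
strength before fitting and predictions multiplied back by it afterwards.
Two consequences are worth stating explicitly:

* every prediction lies strictly inside (0, `normalization_max`) — the model
  cannot design an element stronger than the strongest one it was trained
  on, and `design_by_library()`/`design_by_keypoints()` reject targets above
  that ceiling rather than extrapolating;
* the SSE stopping goal is evaluated on the *normalized* scale. Whether the
  published goal of 0.2 referred to normalized or raw targets is not
  decidable from the source material; normalized was chosen because the goal
  belongs to the fitting process, which operates on normalized data. On the
  default synthetic library, SSE = 0.2 over 90 normalized points corresponds
  to a root-mean-square error of ~0.047, i.e. ~4.7 % of the strongest
  element.

**Optimizer.** Full-batch gradient descent on the sum-squared error with a
momentum term and an adaptive learning rate — the classic scheme the field
knows as gradient descent with momentum + adaptive LR. Parameters, all
exposed in `training_config()`:

| parameter | default | meaning |
|---|---|---|
| `hidden_neurons` | 19 | hidden width; the grid explores 5–30 |
| `max_epochs` | 5000 | epoch budget |
| `sse_goal` | 0.2 | stop when training SSE (normalized) reaches this |
| `momentum` | 0.95 | momentum factor |
| `initial_learning_rate` | 0.01 | starting rate |
| `lr_increase_factor` | 1.05 | rate multiplier after an improving epoch |
| `lr_decrease_factor` | 0.7 | rate multiplier after a rejected epoch |
| `max_perf_increase` | 1.04 | reject a step when SSE grows beyond this factor |
| `init_scale` | 0.5 | weights start U(−0.5, 0.5) |

The update is `v ← m·v − lr·(1−m)·∇SSE`; a step that worsens the SSE by more
than 4 % is rejected, the rate shrunk, and the accumulated momentum flushed
(continuing to coast on stale momentum after a rejection destabilizes
training). The 0.01/1.05/0.7/1.04 values are the well-known defaults of the
named algorithm, which the source names without parameters. With
`momentum = 0` and both adaptation factors set to 1 the trainer reduces
exactly to plain batch gradient descent, and the test suite verifies the SSE
trace is then non-increasing at a small fixed rate.

Weight initialization is uniform on ±0.5 from the seeded RNG. The more
elaborate layer-aware initializations were deliberately not replicated:
initialization was unspecified in the source, and the restart protocol
(best of many seeded restarts) washes out the choice. Empirically the
896→19→1 network reaches the 0.2 goal in 100–200 epochs from this
initialization.

Gradients are analytic backpropagation and are checked against central
finite differences (relative error ≤ 1e−5) in the test suite — the oracle is
the finite-difference quotient, which shares no code with the backprop path.

**Prediction error.** Alongside the SSE, models report a prediction error
E = Σ|ŷᵢ − yᵢ|/n (mean absolute error). The printed definition of E in the
source material is an unreadable figure; MAE is our documented stand-in
(SSE/n would be an equally plausible reading), and both metrics are always
reported side by side so the choice is auditable.

## Model selection

`split_library()` draws a uniform train/test partition; `grid_search()`
crosses training sizes × hidden widths × restarts, training one model per
cell and evaluating test SSE, test MAE and train/test Pearson correlations
on the measurement (denormalized) scale — fits are judged where measurements
live. Cell names follow `NET{size}_{hidden}_{restart}` with 1-based restart
indices. `select_best()` minimizes test SSE, breaking ties by maximal test
correlation, then lexicographic name.

Each restart draws a *fresh* split (not one split shared by all restarts of
a size). The source is ambiguous; per-restart splits were chosen because the
sampling language suggests membership varied, and because sharing one split
would make the per-size min/max summary curves describe one particular
partition rather than the sampling distribution. Flagged here since the
alternative reading is defensible.

Child seeds derive deterministically from the master seed via Lehmer-style
mixing (`derive_seed()`), so any single cell can be reproduced in isolation
— `refit_cell()` does exactly that and the suite checks the refit model
reproduces the recorded metrics. The full published-scale grid (51 sizes ×
26 widths × 1,000 restarts = 1,326,000 models) is supported and counted
without training via `count_only`/`--count-only`; default profiles are
desk-scale.

## Scanning and design

`point_scan()` substitutes each of the 3·L alternative bases one at a time
and scores each mutant; relative changes are computed against the model's
own wild-type prediction, not the measured 1.0 — the scan is an in-silico
experiment internal to the model, and referencing the measured value would
mix scales. Key points are classified at ±20 % relative change, inclusive at
the boundary.

`design_by_library()` screens a seeded random mutant pool (wild type always
included) for the k predictions nearest the target. `design_by_keypoints()`
searches combinations of key-point mutations — at most one mutation per
physical position, at most `max_mutations` total. Sets of ≤ 10 key points
are enumerated exhaustively; larger sets use deterministic beam search
(default width 50), which the suite checks against brute-force enumeration
on small instances. The combination-search strategy was not specified in the
source; beam search was chosen as the simplest deterministic method whose
optimality can be certified against enumeration at small scale. A design
that cannot reach the tolerance returns an explicitly unsatisfied result
carrying the nearest achieved value — callers can widen the tolerance or the
search rather than handle an exception.

`conservation_profile()` computes per-position information content
2 − H(p) bits from raw base frequencies, without pseudocounts or
small-sample correction: at the ~100-sequence scale these libraries have,
a correction would shift every column by a near-constant amount and obscure
the conserved/variable contrast the profile is used for.

## The PWM baseline

The linear baseline scores sequences by an additive log₂-odds
position-weight matrix and fits log₂(strength + ε) against score by ordinary
least squares. ε = 1e−3 because real libraries contain strength exactly 0.
The frequency estimate is `(count + pc·background) / (n + pc)` with
Jeffreys-like `pc = 0.5` by default; with `pc = 0`, empty cells floor at
−30 bits instead of −∞ so training-set sequences always score finite.
Which subset of the library trained the published baseline is unknown, so
`fit_pwm_baseline()` fits three documented variants — all records,
high-activity records (strength > 1), and a strength-weighted matrix — and
reports the best, mirroring a "best fitting result".

## The synthetic world

Real libraries of this kind are not publicly machine-readable, so the
generator plants a known map and every downstream claim is tested against
it. The stated world:

* 224-nt wild type (a packaged synthetic stand-in sequence — the real
  parent element is not reproduced here; any user FASTA can replace it);
* 15 strong positive alleles (multiplicative effect e ∈ [0.3, 0.8]) and 120
  strong negative alleles (e ∈ [−0.8, −0.3]) among the 672 possible
  single-base substitutions, matching the published key-point counts; all
  other alleles carry mild effects (normal, sd 0.02, truncated at ±0.08);
* a sequence's raw score is the product of (1 + e) over its mutated sites;
  measured strength is a saturating Hill transform
  s(r) = s_max·r³/(r³ + s_max − 1) with s_max = 3.559, which fixes the wild
  type at exactly 1 and the range at [0, 3.559). The nonlinearity is the
  point: it makes the data genuinely non-additive, so the network can and
  does outperform the additive PWM baseline on it (checked in the suite);
  the Hill exponent 3 keeps single strong effects clearly above the 20 %
  classification threshold (a planted e = +0.3 maps to a true +64 % change,
  e = −0.3 to −58 %) while mild alleles stay below it (≤ ±17 %);
* measurement noise: Gaussian, sd 0.05, clamped to [0, s_max] — small
  relative to the range, consistent with the high reported fit quality;
* library curation: mutants are drawn at a per-sequence rate uniform in
  (0, 0.20] ("up to" the nominal 20 % rate — error-prone PCR libraries are
  heterogeneous) and accepted into strength bins until ~20 % of mutants lie
  above 1, with half of the negative quota in the lowest quarter of [0, 1)
  — emulating how a characterized library is hand-picked from thousands of
  mostly near-dead clones for even coverage. The wild type enters with
  strength exactly 1.

What the generator does **not** emulate: transition/transversion bias of
error-prone PCR, indels, epistasis beyond the global saturating
nonlinearity, flow-cytometry event-level noise, and day/plate batch effects.
A green end-to-end test therefore establishes that the pipeline recovers
*this* class of smooth multiplicative-saturating maps from curated
libraries; it does not establish that 90 sequences suffice to characterize a
real element.

## Known limitations

The sharpest one is deliberate and documented in the acceptance suite: the
default world plants 135 strong alleles but trains on 90 sequences — fewer
observations than parameters. No estimator can localize all planted sites
from such data (a lasso given the exact generative form recovers under
10 %), so the "recover ≥ 90 % of planted sites end-to-end" acceptance
property is left red by design, with the analysis in the project notes. The
scan/classify machinery itself is validated on a learnable world (150
sequences, 12 strong sites, low noise) where recovery is 100 %. The
practical reading: at realistic library sizes the model is a reliable
*interpolator* (design works; fit quality is high) but an unreliable
*attributor* of strength to individual sites.

Other limitations: predictions cannot exceed the training maximum (by
construction); a single hidden layer only; no validation-based early
stopping (overfitting is controlled by the SSE goal, and the grid's test
metrics make any residual overfit visible); fixed-length elements only.

## Numerical notes

`logsig` is computed in a sign-split form that cannot overflow; it saturates
to exactly 0/1 beyond roughly ±37 in double precision (for x = −1000 the
true value ~5e−435 is far below the smallest subnormal, so 0 is the nearest
representable result — the saturation tests acknowledge this). Strengths are
serialized with 15 significant digits so library files round-trip at double
precision. Model JSON stores weights row-major with a format/version tag.
All randomness flows through explicit seeds; seeded runs are byte-identical,
which the suite checks at the file level through the CLI.
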