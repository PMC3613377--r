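# promnet

Quantitative, model-driven design of bacterial regulatory elements.

## The problem

A promoter plus its ribosome binding site (RBS) — here one fixed-length
224-nt DNA element — sets how strongly a downstream gene is expressed.
Pathway engineers need elements of *prescribed* strength, not just "strong"
or "weak". Given a mutant library of one parent element whose members have
been fluorescence-characterized (relative strength, wild type ≡ 1), promnet
learns the sequence→strength map and inverts it: it proposes new sequences
predicted to hit any desired strength within the measured range.

## The model

Each sequence is one-hot encoded, 4 bits per base in the order (A, G, C, T):

```
A = {1,0,0,0}  G = {0,1,0,0}  C = {0,0,1,0}  T = {0,0,0,1}
```

so a 224-nt element becomes an 896-long 0/1 vector *x*. A single-hidden-layer
feed-forward network with logistic activations on both layers maps it to a
normalized strength:

```
ŷ = σ( W₂ · σ(W₁ x + b₁) + b₂ ),   σ(z) = 1 / (1 + e⁻ᶻ)
```

Targets are divided by the maximum training strength s_max (the logistic
output lives in (0,1)) and predictions multiplied back by s_max. Training is
full-batch gradient descent on the sum-squared error SSE = Σ(ŷᵢ − yᵢ)² with
momentum 0.95 and an adaptive learning rate (×1.05 after improving epochs;
step rejected and rate ×0.7 when the SSE grows >4%), stopping at SSE ≤ 0.2
(normalized scale) or 5,000 epochs. Model selection grid-searches training
size × hidden width × random restarts; cells are named
`NET{size}_{hidden}_{restart}`.

On top of the trained model:

* `point_scan()` — in-silico saturation mutagenesis: all 3·L single-base
  substitutions, scored by the model;
* `classify_key_points()` — mutations changing the predicted strength by
  ≥ 20 % relative to the wild type (positive/negative key points);
* `design_by_library()` — screen a random in-silico mutant library for
  sequences nearest a desired strength;
* `design_by_keypoints()` — exhaustive/beam search over combinations of
  key-point mutations;
* `build_pwm()` / `fit_log_activity()` — the linear position-weight-matrix
  baseline (log₂ activity vs additive log-odds score);
* `make_ground_truth()` / `generate_library()` — a seeded synthetic library
  generator with a planted, nonlinear sequence→strength map, so the whole
  pipeline is testable end to end without wet-lab data.

## Worked example

```r
library(promnet)

# 1. a synthetic 100-member mutant library with a planted ground truth
gt  <- make_ground_truth(seed = 1)            # 224-nt element, 135 key sites
lib <- generate_library(gt, n = 100, mutation_rate = 0.20, seed = 2)
print(lib)
#> strength_library: 100 records, 224 nt, 100 with measured strength
#>   strength range [0.000, 3.346]; 20 records > 1
#>   wild type: WT

# 2. split 90/10 and train the 896 -> 19 -> 1 network, best of 20 restarts
sp <- split_library(lib, train_size = 90, seed = 3)
X  <- encode_library(sp$train$sequence)
models <- lapply(1:20, function(r)
  train_network(X, sp$train$relative_strength,
                training_config(hidden_neurons = 19, seed = r)))
best <- models[[which.min(vapply(models, `[[`, numeric(1), "final_sse"))]]
print(best)
#> ann_model: 896 -> 19 -> 1 (logsig), normalization max 3.346
#>   trained 141 epochs, final SSE 0.1887 (reached goal 0.2)

pearson_r(predict_strength(best, sp$train$sequence),
          sp$train$relative_strength)
#> training R = 0.985

# 3. scan all 672 single-point mutations and classify key points
kp <- classify_key_points(point_scan(best, gt$wt_seq), threshold = 0.20)
print(kp)
#> key_point_set: 104 positive, 177 negative (|delta| >= 20% of wt)

# 4. design a sequence with desired strength 2.5
des <- design_by_library(best, gt$wt_seq, desired = 2.5, tolerance = 0.05,
                         n = 10000, seed = 4)
print(des)
#> design_result (library): target 2.500 +/- 0.050, 10 candidate(s)
#>   10 candidate(s) within tolerance
head(des$candidates[, c("predicted_strength", "n_mutations")], 3)
#>   predicted_strength n_mutations
#> 1           2.499951          44
#> 2           2.503556          47
#> 3           2.496351          33

# 5. the PWM baseline fits the same data worse than the network
pwm <- fit_pwm_baseline(lib)
pwm$fits[[pwm$best]]$r
#> 0.644   (vs ANN R = 0.899 over the full library)
```

Reading the numbers: training stops as soon as the normalized SSE crosses
0.2, which on this library corresponds to R ≈ 0.98–0.99 between predicted and
generated strengths. The key-point scan flags far more sites than the 135
truly planted ones — with 90 training sequences and 672 alleles the model
interpolates rather than identifies individual effects (see the methods
vignette). Design nevertheless works: screening 10,000 in-silico mutants
finds ten sequences within ±0.05 of the 2.5 target. The additive PWM
baseline tops out at r ≈ 0.64 on the same (deliberately nonlinear) data.

## Command line

```sh
Rscript -e 'promnet::promnet_cli()' simulate --n 100 --rate 0.2 --seed 1 --out-prefix lib
Rscript -e 'promnet::promnet_cli()' train --fasta lib.fa --strengths lib.tsv \
    --hidden 19 --restarts 20 --seed 2 --out model.json
Rscript -e 'promnet::promnet_cli()' scan --model model.json --wt lib.fa --out scan.csv
Rscript -e 'promnet::promnet_cli()' design --model model.json --wt lib.fa \
    --mode library --target 2.5 --tol 0.05 --seed 3 --out-prefix design
Rscript -e 'promnet::promnet_cli()' grid-search --sizes 40:90 --hidden 5:30 \
    --restarts 1000 --count-only      # reports 1,326,000 planned cells
```

Every command writes a `*_manifest.json` with seeds and md5 hashes of its
outputs; identical invocations are byte-identical.

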