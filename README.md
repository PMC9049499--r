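# mvgat

Semi-supervised node classification on **multi-view networks** — one shared
node set observed under several edge sets, as in multi-evidence
protein–protein networks (physical interaction, co-expression, …) or
citation corpora paired with a text-similarity graph. Each view carries
different, differently reliable information; `mvgat` learns from all of them
and learns *how much to trust each one, per node*.

## The model

Every view is encoded by a stack of multi-head neighborhood-attention
layers: within a head with parameters (W, a), neighbor j's importance to
node i is

    alpha_ij = softmax_{j in N_i}( LeakyReLU( a' [W x_i || W x_j] ) )

and node i's update is `sum_j alpha_ij W x_j`; hidden layers concatenate
heads, the output layer averages them. A second attention with parameters
(T, b) then scores the k per-view representations against each other,
per node, and fuses them into a global representation
`Z_v = sum_j gamma_j(v) x_v^(j)` — a learned convex combination whose
weights reveal which view the model trusts where. Z feeds a softmax (or
sigmoid, for multilabel tasks); training is full-batch Adam on the
cross-entropy over labeled nodes, and the returned predictions are those of
the iteration with minimum selection loss.

The whole computation is organized as a **coupled membrane (P) system** of
k+4 cells: an input cell decomposes the network, k identical sub-cells
encode the views in a synchronized maximal-parallel step, a fusion cell
builds Z and predicts, and a loss cell selects and finally emits the labels
to the environment. Objects move only along wired, audit-logged channels,
and sub-cell results are independent of execution order by construction.

The package also ships plain-text readers/writers (two-column edge lists
and the `id feat... label` content dialect), a cosine-similarity view
builder, a multi-view planted-community (SBM) generator with controllable
per-view informativeness, the SV/MMV ablation variants, and standard
metrics.

## Worked example

```r
library(mvgat)

# A 120-node, 3-community benchmark: view 1 is informative
# (p_in = 0.25, p_out = 0.02), view 2 is pure structural noise (0.08, 0.08).
net <- informative_plus_noise_benchmark(seed = 1)
res <- fit_mvgat(net, default_config())

metric_report(net, res$labels)$test
#> $accuracy
#> [1] 1
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $f1
#> [1] 1

res$best_iteration
#> [1] 172

# What did fusion learn? The informative view's mean weight on labeled nodes:
st <- res$state
fwd <- mvgat:::model_forward(st$model, st$nd, training = FALSE)
mean(fwd$fusion_cache$marginal[net$masks$train | net$masks$val, 1])
#> [1] 0.8128609
```

All 72 test nodes are classified correctly, and the learned fusion weight of
the informative view (0.81) is far above the uniform value 0.5: the view
attention has discovered which view matters. Dropping it for a plain mean
(`ablation_run(net, "mmv", ...)`) still works here; training on the noise
view alone (`ablation_run(net, "sv", ..., sv_view = 2)`) collapses toward
chance.

A command-line front end wraps the same functions:

```sh
Rscript scripts/mvgat-cli.R generate --n 120 --classes 3 --seed 1 --out data/
Rscript scripts/mvgat-cli.R train --config data/config.yaml --out run/
```

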