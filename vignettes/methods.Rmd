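---
title: "Knowledge-graph-enhanced demand forecasting: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph-enhanced demand forecasting: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgdemand)
```

## The problem

Weekly pharmaceutical demand is shaped not only by a drug's own history
(seasonal disease cycles, trends) but by its *relations to other drugs*:
substitutes compete for the same prescriptions, and co-prescribed
(interacting) drugs move together. `kgdemand` forecasts one-step-ahead weekly
demand per drug with a hybrid model: a drug knowledge graph supplies the
relations, a clipped graph convolutional network (GCN) embeds the target drug
together with its neighbourhood, and an LSTM maps the sequence of embeddings
to the next week's demand.

## The knowledge graph

Nodes are catalog items. Two relations define undirected edges:

* **substitution** — two drugs whose ATC codes share the first five
  characters (the level-4 chemical subgroup, e.g. `J01CA`) are treated as
  substitutes;
* **combination** — a drug-drug interaction (DDI) record whose endpoints both
  appear in the cleaned catalog (a strict intersection).

Both relations get the same unit weight in the adjacency matrix `M`; how much
each related drug actually matters is learned by the GCN weight matrices, not
encoded in the graph. A pair related both ways still has adjacency 1 (both
labels are kept in the edge table). Medical devices and consumables carry no
ATC code and no chemical interactions, so they are isolated nodes; DDI rows
touching a device are dropped at edge construction, which keeps the
"devices are isolated" rule an invariant of every assembled graph rather
than an assumption about the input tables.

Name matching is table-driven: product names are reduced to a core name
(lower-cased; dosage/strength tokens such as "500 mg" or "120 mg/5 ml" and
pack counts removed; whitespace collapsed), mapped to an International
Nonproprietary Name (INN), and the INN to an ATC code. Both lookup tables are
inputs — there is no live database call — and unmatched names are returned,
never silently dropped.

## From transactions to training samples

1. **Weekly aggregation.** Transactions are summed per drug per ISO-8601
   week. Unrecorded drug-weeks are filled with zero: absence of sales is read
   as zero demand, not missing data, which preserves a gapless week axis.
2. **History filter.** Drugs with fewer than 40 *valid* weeks (weeks with at
   least one transaction) are removed. The boundary is "keep iff valid weeks
   >= 40"; the threshold is a configurable argument.
3. **Outlier correction.** Within a sliding window, values deviating from the
   window mean by more than three population standard deviations are replaced
   by that window's mean (statistics always from the original values, single
   sweep, stride 1). The window length is tied to the 16-week sample window
   — the least arbitrary reading of a per-window rule — and by default the
   correction is applied *inside each assembled sample window*, so no
   statistic ever uses information from after the forecast anchor (no
   test-set leakage).
4. **Chronological split.** The final 8 weeks are the test set, the 4 weeks
   before them the validation set, everything earlier the training set.
5. **Scaling.** Each drug's series is min-max scaled with the transform
   fitted on training weeks only; forecasts are inverse-transformed before
   any metric is computed, so reported errors are in raw units. A constant
   training range maps to zero by convention.
6. **Window assembly.** For each target drug, its 2-hop graph neighbourhood
   (the receptive field of the two-layer GCN) is extracted and a 16-week
   window slides over the series with stride one week. Each anchor yields 16
   node-feature snapshots; snapshot *s* carries every subgraph node's demand
   over the 16 weeks ending at the snapshot's week. Two readings of the
   snapshot content are supported: `padding = "causal"` (default) truncates
   at the sample window's left edge and zero-pads, so one sample touches
   exactly 16 raw weeks ("each 16-week sequence is one sample" taken
   literally); `padding = "full"` uses true earlier weeks, so a sample spans
   up to 31 raw weeks. Both give 16-dimensional node features and identical
   parameter counts; the choice is exposed because the sample definition
   admits both readings. The label is the target drug's demand one week
   after the anchor; a length-`L` unbroken series yields exactly `L - 16`
   samples.

## The model

For one snapshot with node features `X` (N x 16) and adjacency `M`:

* self-loops: `M' = M + I`; degrees `D'_ii = sum_j M'_ij`;
* propagation operator `A_hat = D'^{-1/2} M' D'^{-1/2}` — symmetric, all
  finite (every degree >= 1 after self-loops), spectrum in [-1, 1], which
  keeps repeated aggregation numerically stable;
* two GCN layers, ReLU at both: `H1 = relu(A_hat X W0 + b0)`,
  `H2 = relu(A_hat H1 W1 + b1)`, both 64 units wide;
* **clip**: only the target drug's row of `H2` is kept. After two layers that
  row has already aggregated the 2-hop neighbourhood; discarding the other
  rows concentrates the temporal model on the prediction target. Two
  architectural facts follow and are asserted as tests: the output is
  invariant to perturbing any node more than two hops from the target, and
  invariant to node permutations (tracking the target index).

The 16 clipped embeddings feed a single-layer LSTM (hidden size 64) with the
standard gates: forget, input and output gates are sigmoids of affine maps of
the current input and previous hidden state; the candidate state is the tanh
counterpart; `c_t = f_t * c_{t-1} + i_t * candidate`;
`h_t = o_t * tanh(c_t)`. The final hidden state passes through a bias-free
64-to-1 linear head with ReLU — demand is non-negative and min-max-scaled
targets stay non-negative, so the clamp is consistent. Training minimises
mean squared error.

### Parameter accounting

The block structure is pinned down by exact trainable-scalar counts, which
the package reproduces and tests:

```{r}
count_parameters(model_config())
```

Three accounting decisions are forced by these counts rather than by the
gate equations as usually printed:

* the LSTM carries **recurrent weight matrices** and exactly **one bias
  vector per gate**: 4 x (64 x 64 + 64 x 64 + 64) = 33,024. A recurrence-free
  LSTM would count 16,640 and the two-bias dialect of some frameworks
  33,280. The recurrence-free form remains reachable: with all recurrent
  matrices zero the implementation reproduces the input-only gate equations
  exactly (a tested property);
* the GCN layers carry biases (16 x 64 + 64 = 1,088 and 64 x 64 + 64 =
  4,160);
* the head has no bias (64, not 65) and is a single linear map — no hidden
  layer.

### Initialisation, dropout, optimisation

Weights start uniform in ±1/sqrt(fan-in); biases at zero. The head weights
take the non-negative half of the range: with a ReLU head, an initialisation
whose pre-activation is negative for every training sample receives zero
gradient forever, and a non-negative dot product with near-symmetric hidden
states avoids that degenerate start without biasing it. Dropout (default
rate 0.2) is applied during training to each GCN layer's output and to the
final temporal feature; placement is a design choice, the rate is the
selected optimum. Training is full-batch Adam (learning rate default 0.001),
with early stopping: after every epoch the validation loss is evaluated with
dropout off, the best weights are retained, and training halts after
`patience` epochs (default 500) without an improvement greater than 1e-8 (a
float-noise guard), or at `max_epochs` (default 5000). Validation *loss*
drives early stopping; validation *SMAPE* drives grid search — the two are
deliberately kept distinct. Grid-search ties break by enumeration order.

One model is trained per target drug ("for a given target drug A"); a
shared-weights multi-target mode is out of scope. Test weeks are scored as
eight rolling one-step forecasts using true observed history (teacher
forcing); recursive multi-step forecasting is available behind a flag but is
not the default, because the evaluation protocol reads most naturally as
one-step.

### Ablation variants

`build_variant()` reshapes the architecture: 1-3 GCN layers (clip retained),
a no-clip variant (node embeddings mean-pooled per snapshot — pooling is a
choice, sum pooling is exposed as an alternative, because "keeping all
relational features" does not specify an aggregation), LSTM hidden sizes 16/
32/64, an LSTM-only model fed the raw target window, a variant with the LSTM
replaced by a one-hidden-layer 64-unit ReLU perceptron over the mean
snapshot embedding (a flattened input would inflate the block far beyond its
64-unit description), and a single-node variant that keeps the architecture
but discards all graph relations. On an isolated drug the single-node and
full variants are the same network — a tested identity.

## The synthetic pharmacy simulator

Real pharmacy sales tables are proprietary, so the package ships a generator
whose *statistical structure* exercises exactly the mechanisms the knowledge
graph encodes:

* **group seasonality** — each ATC group follows
  `base * (1 + a * sin(2*pi*t/52 + phase))` times a log-normal AR(1)
  fluctuation (disease waves persist across weeks, so a group's current
  level is informative about next week);
* **substitution** — within-group market shares follow a logistic-normal
  random walk (shares always sum to one), so one member's gain is its
  substitutes' loss;
* **combination** — each DDI pair carries two Poisson co-prescription count
  streams with AR(1)-persistent intensities (prescription episodes), scaled
  by the coupling strength kappa; one stream is led by each endpoint, the
  leading drug dispensed in the prescribing week and the partner **one week
  later** (a dispensing lag). The lag is what makes the relation
  *forecast-relevant* rather than merely correlated: a simultaneous shared
  count is noise that no forecaster, graph-aware or not, could exploit, and
  the mechanism would not be statistically identifiable by a forecasting
  comparison; with one stream led by each endpoint, both endpoints gain
  genuine predictive value from their partner. The per-stream share
  (`coupling_share`, default 0.12) keeps each drug's own sales mostly its
  own while the episode streams remain the dominant cross-drug signal at the
  default kappa = 2; DDI pairs are kept disjoint so each stream is
  identifiable;
* **observation noise** — negative-binomial counts (demand is a count, and
  pharmacy sales are overdispersed relative to Poisson), multiplicative
  outliers injected at a small rate, and randomly zeroed "missing" weeks;
* **devices** — independent seasonal log-AR(1) Poisson series, no relations;
* **a sparse drug** — active in only ~30 weeks, below the 40-valid-week
  floor, so the history filter always has something to remove. Sparse drugs
  are chosen outside the DDI endpoints so coupling pairs survive filtering.

The defaults (12 drugs, 3 ATC groups, 2 DDI pairs, 120 weeks, kappa = 2)
define the study conditions used by the test suite and the acceptance
script. The matching *relation-free* condition sets kappa = 0, zero share
drift and zero group-level noise, which makes the drug series statistically
independent given their deterministic seasonal means — the setting in which
the knowledge graph must add nothing over a single-node model. What the simulator does *not* emulate — price and promotion effects,
epidemic shocks, calendar effects, cold starts, cross-group substitution —
bounds what passing tests show: they demonstrate that the implementation
recovers relational signal *when it is present by construction*, not that
the model wins on any particular real dataset.

## Problem sizes and numerical choices

* The experiment scale used by `run_experiment()` in the acceptance script
  and acceptance tests is the generator default (about 11 drugs surviving
  the filter, 120 weeks, ~92 training samples per drug) with three seeds and
  a per-fit schedule of learning rate 0.005 (inside the search grid),
  `max_epochs = 200`, `patience = 40` — full-batch Adam on ~90 samples takes
  large, stable steps, so this converges reliably at desk scale while the
  package defaults remain the selected optimum (0.001 / 5000 / 500).
* Population (divide-by-n) standard deviation in the outlier rule; fixed for
  reproducibility since the estimator is unspecified in per-window form.
* Constant outlier windows (zero standard deviation) never fire.
* The ReLU subgradient at zero is taken as 0.
* All oracle comparisons in the test suite use tolerance 1e-6; gradient
  checks compare the hand-derived backward pass against central finite
  differences at 1e-4 (biases are jittered off the ReLU kink in those
  tests, where the two-sided difference would otherwise measure the
  subgradient midpoint).
* Every source of randomness flows from named integer seeds: the simulator
  from its config seed, weight initialisation and dropout from the training
  seed, per-drug seeds derived from each experiment seed by one
  `sample.int()` draw. Identical (configuration, seed) pairs reproduce
  bit-identical artifacts, which the test suite asserts end to end.

## Known limitations

* The knowledge-graph advantage over the LSTM-only ablation is a stochastic,
  panel-dependent quantity: a GCN aggregates its neighbourhood
  permutation-equivariantly, so it cannot selectively ignore a single
  misleading neighbour (for example a group-mate whose sales carry a large
  co-prescription stream), and on some simulated panel realisations that
  interference outweighs the relational gain. The packaged comparison is
  run on the generator's default panel with three training seeds.
* Univariate demand input: no prices, holidays, weather or epidemiological
  covariates.
* Per-drug models do not share statistical strength across drugs; for large
  catalogs this costs both compute and sample efficiency.
* The 2-hop neighbourhood default matches the two-layer GCN's receptive
  field, but "indirectly related" admits deeper readings; `hop` is
  configurable.
* Grid search is exhaustive over a small grid; no adaptive hyperparameter
  optimisation.
* The ReLU head cannot represent negative forecasts, which is correct for
  demand but makes the model unsuitable for differenced or centred series.
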