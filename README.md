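# khopdiff

Multi-class disease diagnosis on heterogeneous electronic-health-record
graphs. Patients (P), drugs (D) and procedures (O) form a tripartite graph
with four directed relations (P-D, D-P, P-O, O-P); each patient carries one
disease label, and the task is to predict it from graph structure alone.

The model combines two branches:

* **A k-hop hierarchical Transformer.** For each patient, a fixed number of
  neighbours is sampled with replacement from every exact-k-hop frontier
  (k = 1..4, following the P-D-P / P-O-P meta-path templates). Each hop's
  sequence is encoded by its own Transformer layer; hop-level attention
  aggregates it into z_v^(k); a hierarchical Transformer contextualizes the
  hop sequence, and multi-head attention with a residual fuses it into the
  structural embedding
  h_v^HHGAT = W_out · concat_m [ h_v + Σ_k β_k^(m) (z̃_v^(k) W_V'^(m)) ],
  with β^(m) = softmax_k[(h_v W_Q')(z̃_v^(k) W_K')ᵀ / √d_h].
* **A dual-view latent diffusion denoiser.** Two auxiliary patient-patient
  graphs are composed from the P-D-P and P-D-P-O-P meta-paths; a shallow GCN
  encodes each into clean embeddings h₀; the forward process
  h_t = √ᾱ_t h₀ + √(1−ᾱ_t) ε perturbs them under a linear β schedule, and a
  shared 3-layer graph-convolutional denoiser (cross-conditioned on the other
  view's noisy state and a time embedding) reconstructs them by deterministic
  DDIM sampling; the two reconstructions are averaged into h^diff.

The fused embedding LayerNorm(λ h^HHGAT + (1−λ) h^diff) feeds a linear
softmax classifier trained with label-smoothed KL loss plus the diffusion
loss, optimized jointly by Adam. Micro-F1 (= accuracy here) and macro-F1 are
the evaluation metrics.

Real cohorts of this shape come from access-restricted clinical databases,
so the package ships a synthetic EHR-graph generator with planted
class-conditional drug/procedure propensities and tunable spurious-edge,
edge-dropout and label-noise rates; every component is tested against it.

## Worked example

```r
library(khopdiff)

sim <- simulate_ehr_graph(synth_spec(seed = 1))   # 600 patients, 3 classes
print(graph_stats(sim$graph, metapaths = FALSE))

cfg <- khopdiff_config(d = 32, heads = 4, per_hop = 8, k_max = 4,
                       batch_size = 256, gcn_hidden = 32, d_t = 8,
                       max_epochs = 25, patience = 10, seed = 1)
fit <- khopdiff(sim$graph, sim$labels, cfg)
print(fit)
```

```
Heterogeneous graph statistics
  nodes     P: 600  D: 90  O: 45
  edges     P-D: 4241  D-P: 4241  P-O: 1724  O-P: 1724
  sparsity  0.9264
khopdiff model (variant: full)
  600 patients, 3 classes (1, 2, 3)
  trained 25 epochs; best validation macro-F1 0.9502 (epoch 15)
  test micro-F1 0.9339, macro-F1 0.9327
```

The sparsity line is the bipartite density complement
1 − ΣE / (2·|P|·(|D|+|O|)): 93% of possible patient-drug/procedure links are
absent, the regime typical of real prescription graphs. The fit report shows
the early-stopping epoch chosen on validation macro-F1 and the held-out test
scores; with 90% planted signal and 5% noise rates, a correctly working model
recovers the three planted classes well above the 1/3 chance level. `plot(fit)`
draws the loss and validation curves, `predict(fit, type = "prob")` returns
per-patient class probabilities, and `summary(fit)` adds per-class F1.

Ablation variants (`variant = "my_gcn"`, `"my_onlytrans"`, `"my_onesub"`,
`"my_onlydiff"`) toggle the branches as configuration switches.

A thin command-line front end lives at `inst/cli/khopdiff-cli.R`
(subcommands `simulate`, `stats`, `train`, `evaluate`, `ablate`; JSON config
mirroring `khopdiff_config()`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the sparsity worked
examples from the two reference cohorts' printed structural counts (both must
round to 0.9875), then generates the default synthetic cohort, fits the full
model, and prints the graph statistics and test report. The JSON report it
writes is an empty object.

See `vignettes/khopdiff-methods.Rmd` for the model's assumptions, the
parameter defaults and their provenance, what the synthetic generator does
and does not emulate, and the numerical design choices.
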