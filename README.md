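# grnfusion

Gene regulatory network (GRN) inference by multimodal graph-transformer
link prediction, in pure R.

## The problem

A GRN is a directed graph of regulator → target interactions between genes.
Reconstructing it from expression data alone is limited by noise, dropout
in single-cell counts, and indirect correlations. `grnfusion` frames GRN
inference as supervised link prediction and fuses three per-gene views
before scoring gene pairs:

- **Expression embeddings** *Z* ∈ ℝ<sup>n×d</sup>: a variational
  autoencoder over gene profiles, trained by maximizing the evidence lower
  bound
  ELBO = E<sub>q(z|x)</sub>[log p(x|z)] − KL[q(z|x) ‖ N(0, I)],
  with the reparameterization z = μ + σ ⊙ ε. The exported embedding is the
  posterior mean μ.
- **Global embeddings** ξ ∈ ℝ<sup>n×d</sup>: C prior inferred networks
  G₁…G<sub>C</sub> over the same genes are sampled into random-walk
  "sentences" (each starting with `[CLS]`), and a masked-node transformer
  encoder — softmax(QKᵀ/√d<sub>k</sub>)V attention plus a ReLU
  feed-forward, trained to recover 20% masked tokens by cross-entropy —
  learns a token embedding matrix whose gene rows are ξ.
- **Positional encodings** λ ∈ ℝ<sup>n×p</sup>: eigenvectors of the
  symmetric normalized Laplacian Δ = I − D<sup>−1/2</sup>A D<sup>−1/2</sup>
  of the known regulatory graph, trivial (zero-eigenvalue) vectors
  discarded.

Each view is affinely projected to a common width and summed
(h = Ẑ⁰ + ξ̂⁰ + λ⁰, "fusion by summation"). Stacked graph-transformer
layers update h with multi-head attention restricted to graph
neighborhoods, w<sub>ij</sub> = softmax<sub>j∈N(i)</sub>(Qh<sub>i</sub> ·
Kh<sub>j</sub>/√d<sub>k</sub>), followed by a 2d-wide ReLU FFN, residual
connections and normalization. An MLP on the concatenation
[h<sub>i</sub>; h<sub>j</sub>] scores the directed pair i → j.

The package also ships the full evaluation protocol (AUROC as the
Mann–Whitney statistic, step-integrated AUPRC, network-topology
diagnostics with Pearson agreement, log–log degree distributions, modality
and transformer-component ablation harnesses) and a synthetic benchmark
generator, so the whole pipeline is testable without downloads.

## Worked example

```r
library(grnfusion)

# A planted benchmark: 100 genes, scale-free GRN (300 edges), 200 cells
# with dropout, and 3 corrupted prior networks at 80% edge fidelity.
bench <- make_benchmark(seed = 1)
bench
#> <benchmark_bundle> 100 genes, 200 cells, 300 true edges, 3 priors (seed 1)

fit <- grnfusion(log_transform(bench$X),
                 true_edges = which(bench$A_true != 0, arr.ind = TRUE),
                 priors = bench$priors, seed = 1)
fit
#> Multimodal graph-transformer GRN model
#>   genes: 100 | modalities: expression+global+positional | width: 32
#>   held-out AUROC 0.8940 | AUPRC 0.6539 (test split, 30 positives)
```

The held-out AUROC is measured on test regulatory links never seen by
training or message passing, against frozen sampled non-edges: 0.89 means
a random true link outranks a random non-link 89% of the time. Downstream:

```r
scores <- predict(fit)                    # n x n link probabilities
net <- binarize_scores(predict(fit, type = "link"), 300)
network_characteristics(net)              # vs network_characteristics(bench$A_true)
plot(fit, type = "roc")
```

A command-line front end (`inst/scripts/grnfusion`) exposes the stages
(`simulate`, `preprocess`, `embed-expression`, `integrate-priors`,
`graph-pe`, `train`, `predict`, `evaluate`, `ablate`) over YAML configs;
every stage writes a resolved-config snapshot and is bit-reproducible
under its seed.

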