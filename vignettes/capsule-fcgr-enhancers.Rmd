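---
title: "Enhancer classification from FCGR images with a capsule network: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer classification from FCGR images with a capsule network: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the encoding, the
model, the parameters that matter, what the synthetic data does and does
not emulate, and the numerical and design choices that were genuinely open.

## The problem

Enhancers are short non-coding DNA elements that amplify transcription of
associated genes by binding transcription factors, often at a distance.
Sequence-only enhancer prediction is a two-stage binary classification:
first enhancer vs non-enhancer, then — for enhancers — strong vs weak
regulatory activity. The widely used benchmark for this task consists of
200 bp sequences (1484 enhancers / 1484 non-enhancers for stage 1, 742
strong / 742 weak for stage 2, with an independent test set of 100 strong,
100 weak and 200 non-enhancers); its best-documented class contrast is GC
content, ordered strong > weak > non-enhancer.

## Encoding: CGR and its frequency discretisation

The chaos game representation (CGR) assigns the nucleotides to the corners
of $[-1,1]^2$ — A $(-1,+1)$, C $(-1,-1)$, G $(+1,-1)$, T $(+1,+1)$ — and
iterates the midpoint map from the origin:

$$(x_i, y_i) = \tfrac12\left((x_{i-1}, y_{i-1}) + \mathrm{corner}(s_i)\right).$$

The corner assignment is the one consistent with reading the T quadrant's
sub-squares clockwise as TT, GT, CT, AT: the GT cell is the one nearest the
G corner. Rotations/reflections of this convention exist in the literature;
class separability is invariant to the choice, but stored images from other
tools may differ by a flip.

Point $i$ lies in the dyadic sub-square indexed by the last $k$ residues,
so binning all points on an $N \times N$ grid with $N = 2^k$ gives the
k-mer count table. The package makes that exact and testable:

* `kmer_suffix_cell()` is the closed-form suffix-to-cell map (last residue
  = most significant bit; x-bit 1 for G/T, y-bit 1 for A/T).
* For every sequence, the FCGR restricted to points $i \ge k$ equals the
  brute-force sliding-window counts of `kmer_counts()` cell for cell, and
  the full image differs by at most $k-1$ (the walk-in points, which we
  keep: they are deterministic and bounded, and discarding them would make
  the image depend on $k$).

Binning is half-open (`floor((x+1)/2 N)`, clamped), row 1 at the top so
rendered images have the T quadrant upper right. Boundary hits are possible
only for the first few points and go to the higher-index cell; they are
covered by the $k-1$ bound. The default $N = 64$ (6-mer resolution)
balances specificity against sparsity at 200 bp — with only 200 points in
4096 cells the image is sparse, which is why counts, not densities, are
stored (`normalization = "raw"` keeps the image integral and lossless;
scaling happens at the network boundary).

Non-ACGT handling: case-folded, U mapped to T; the default `strict` policy
errors with the offending character and position (ambiguity codes usually
indicate a data problem worth surfacing), `skip` drops the character
without emitting a point.

## The classifier

The network is deliberately small, in the classic capsule-network shape:

1. **Frontend** — one valid convolution (ReLU). Package default: 32 filters,
   9x9, stride 1 (the classic geometry); the *small preset*
   (`caps_config_small()`) used in all shipped experiments: 8 filters,
   stride 2.
2. **Primary capsules** — a second convolution (9x9, stride 2) whose
   channels are reshaped into $L$ capsules $u_i \in \mathbb{R}^m$ and
   squashed:
   $$\mathrm{squash}(s) = \frac{\|s\|^2}{1+\|s\|^2}\,\frac{s}{\|s\|}.$$
   The zero vector maps exactly to zero by a piecewise definition — no
   epsilon in the forward pass, and the backward pass uses the true
   Jacobian (which vanishes at the origin).
3. **Routing** — prediction vectors $\hat u_{j|i} = W_{i,j} u_i$ are routed
   for $r$ rounds into $J = 2$ type capsules: logits start at zero, each
   round computes $c_{i,\cdot} = \mathrm{softmax}(b_{i,\cdot})$ (softmax
   *across type capsules*, the original formulation),
   $S_j = \sum_i c_{i,j}\hat u_{j|i}$, $V_j = \mathrm{squash}(S_j)$, and on
   all but the last round $b_{i,j} \mathrel{+}= \hat u_{j|i}\cdot V_j$.
4. **Readout** — $p_j = \|V_j\|$: independent class probabilities in
   $[0,1)$, not a softmax pair.

Defaults where the natural choices were open: $m = 8$, $n = 32$ (the type
capsules are 32-dimensional in the full geometry; 16 in the small preset),
$r = 3$; all are tunable grid axes. The loss is the canonical capsule
margin loss with $(m^+, m^-, \lambda) = (0.9, 0.1, 0.5)$ and no
reconstruction decoder. Input images are divided by their per-image maximum
before the frontend: FCGR counts are small sparse integers whose scale
grows with sequence length, and per-max scaling keeps inputs in $[0,1]$
independent of length (`per_total` and `none` are available).

Training is minibatch Adam (batch 32). The learning-rate default is
`1e-3`: at `0.1` this margin loss frequently diverges, which the trainer
detects (non-finite loss) and aborts with the epoch and rate named; `0.1`
remains available and sits in the default tuning grid. Epoch defaults:
100 for a full run, 30 in the shipped experiments (sufficient for the
synthetic contrast; the loss plateaus well before).

The forward pass and its gradients are compiled (RcppArmadillo, im2col
convolutions). Gradients are exact reverse-mode derivatives with the
routing loop unrolled — not the stop-gradient approximation — and are
verified against central finite differences in the test suite. Everything
is single-threaded and deterministic: one seed fixes initialisation and
minibatch order, and identical runs are bit-identical.

### Ablation

`caps_config(head = "dense")` replaces prediction vectors, routing and type
capsules with a sigmoid dense layer on the flattened primary-capsule
activities, leaving every other component (encoding, loss, trainer,
evaluator, CLI) untouched. This reproduces the published ablation *design*
(capsule layer vs multilayer perceptron head). We deliberately treat the
published ablation table's numbers as non-targets: its full-model MCC
values contradict the main results tables, so only the experiment's
runnability is claimed here.

## Two-stage semantics

Both stages consume identical FCGR images. `predict_two_stage()` has two
modes: **chained** (deployment — stage 2 only on stage-1 positives, so
stage-1 false positives propagate) and **independent** (benchmark — both
stages on all records, which is how strong/weak test sets are scored in
the literature). Stage-1 outputs are identical in both modes. The decision
rule is argmax of capsule lengths, ties to the negative class; AUC uses the
positive capsule length as the score.

## Metrics

Accuracy, sensitivity, specificity (reported as percentages), MCC (its
natural scale), and AUC computed as the Mann–Whitney probability with
midrank tie handling — identical to brute-force pair enumeration, which the
tests verify alongside an independent ROC implementation. Zero-denominator
metrics are reported as `NA`, never silently as 0. Cross-validation is
stratified (the benchmark's protocol does not say; stratification is the
defensible default and is documented here), and grid-search winners are
reproducible: per-cell training seeds derive from the top-level seed,
independent of evaluation order, with ties broken by grid order.

## Synthetic data: what it does and does not show

The generator draws positions i.i.d. with $P(G)=P(C)=\mathrm{gc}/2$,
$P(A)=P(T)=(1-\mathrm{gc})/2$ and can plant fixed k-mer motifs at uniform
random offsets — the simplest mechanism matching the benchmark's documented
class contrast (GC content) plus a k-mer-resolution signal that is
independent of GC. Default profiles: non-enhancer GC 0.40, weak 0.55,
strong 0.65 — ordered as documented for the real data; the real GC
*distributions* are not numerically published, so these are qualitative
stand-ins, chosen once. Enhancer training sets are an even strong/weak mix,
mirroring the benchmark's composition.

Passing the shipped experiments therefore shows that the pipeline recovers
a composition contrast of realistic magnitude from realistic-length
sequences, and that it finds nothing when there is nothing (the GC-gap-zero
negative control stays inside the 95% binomial band around chance). It does
*not* show performance on real enhancers: real sequences have dinucleotide
structure, repeats, and positional motif grammar that the i.i.d. generator
deliberately omits. Reproducing the published benchmark numbers requires
the external dataset and the original tuned training budget, and is out of
scope for the test suite.

Shipped problem sizes, chosen once for single-CPU runs: 300 sequences per
class for training, 100 per class held out, 200 bp, $N = 64$, the small
network preset, 30 epochs. With the default 0.2 GC gap this yields held-out
accuracy at or near 100% and AUC above 95%.

## Known limitations

* The routing variant (softmax axis, per-example logit reset, $r$) follows
  the canonical formulation; the benchmark paper's own supplementary
  routing algorithm was not available, so equivalence to that exact
  variant is an assumption, flagged as such.
* FCGR orientation may be a flip of other tools' output (see above).
* The generator's i.i.d. background understates real genomic correlation;
  accuracy on it is an upper bound on what the same contrast would give in
  real data.
* Checkpoints are RDS containers with a schema version; they are runtime
  artifacts, not an interchange format.

## Reproducibility contract

Every stochastic operation requires an explicit seed (the CLI refuses to
run without one); datasets carry replayable manifests; checkpoints carry
their config; file writers are atomic. A published result of this package
is regenerable from its config, seed, and input files alone.

```{r}
library(enhancaps)
train <- sim_two_class(300, seed = 7, id_prefix = "tr") |> fcgr_encode(n = 64)
test  <- sim_two_class(100, seed = 507, id_prefix = "te") |> fcgr_encode(n = 64)
model <- caps_train(train, caps_config_small(), epochs = 30, seed = 7)
caps_evaluate(model, test)
autoplot(model)            # loss trajectory
autoplot(train$fcgr[[1]])  # one FCGR image
```
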