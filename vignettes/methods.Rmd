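---
title: "Knowledge-graph embeddings and siamese scoring for drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph embeddings and siamese scoring for drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siamdr)
```

## The model

`siamdr` predicts therapeutic drug–disease associations in two stages.

**Stage 1: a typed knowledge graph, embedded.** The drug–disease
knowledge graph (DDKG) has 11 node types — the drug and disease entities
plus five drug feature types (chemical substructures, target proteins,
protein domains, side effects, ATC codes) and four disease feature types
(genes, classes, types, semantic types) — connected by 14 typed
relations in three groups: seven intra-drug, five intra-disease, and two
inter-side relations (`has_treatment`, and `has_encoded` wiring genes to
the targets they encode). Each triplet ⟨h, r, t⟩ is serialized as a
three-token sentence, and a continuous bag-of-words (CBOW) model with
negative sampling embeds every entity *and relation* token into one
k-dimensional space. The working assumption is distributional: entities
that occur in similar triplet contexts (a shared target, a shared gene)
receive nearby vectors, and because relations are tokens too, drugs and
diseases end up in a space where cross-side regularities are
representable.

**Stage 2: a dual-channel (siamese) scorer.** A drug channel
f: R^k → R^h and a disease channel g: R^k → R^h (stacks of dense
ReLU + dropout layers) project both entities into a shared latent
space; the merge ε_h = |ε_r − ε_p| makes the head's decision a function
of where the two projections *disagree*. A dense layer and a sigmoid
unit turn ε_h into an association probability. Drugs and diseases are
different kinds of object, so the default (*heterogeneous*) mode gives
the channels independent weights; the *homogeneous* mode ties them and
exists as an ablation — with shared weights, identical inputs provably
give ε_h = 0.

The training loss is mean binary cross-entropy plus λ times a
symmetrized Kullback–Leibler divergence between the channels'
softmax-normalized outputs, which pulls the drug and disease latent
distributions toward one another. The divergence between the two
channel maps is stated in the source line of work as an integral of a
log-ratio, which is not by itself a well-defined divergence between two
vector-valued maps; the implementable reading adopted here is
½·[KL(P‖Q) + KL(Q‖P)] with P and Q the exponentially normalized channel
outputs. λ (default 0.1) and the scope (all pairs vs positive pairs
only) are configurable precisely because neither is pinned down by the
method description; the loss is affine in λ by construction and λ = 0
recovers plain cross-entropy, both of which the test suite asserts.

## Labels and leakage control

Positives 𝔄 are known indications filtered to a status (default
`"approved"`). Negatives 𝔈 follow the adverse-reaction rule: ⟨r, p⟩ is a
presumed negative when p occurs among r's recorded side effects and the
pair is not a positive. This requires the side-effect and disease
vocabularies to share a normalized identifier space; matching is exact
string equality on the local identifier (node identifiers are namespaced
`type:local_id` internally, so the two vocabularies never collide in the
embedding vocabulary while still being comparable by local id).

A fixed test split — ⌊0.1·|𝔄|⌋ positives and as many negatives, sampled
with a seed — is extracted *before* embedding, and for every held-out
pair both the `has_treatment` triplet and (for negatives) the
identity-mapped `has_side_effect` triplet are removed from the graph.
The embedding therefore never sees the evidence it is later asked to
predict. By default the embedding is trained once on this cleaned graph
and cross-validation folds only monitor training; a stricter
`per_fold_embedding` mode also removes each validation fold's edges and
re-embeds per run, at a proportional cost. Rebalancing is applied to
training folds only; validation and test class counts are never touched.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `vector_size` | 1024 | embedding dimension at production scale; desk-scale runs use 16–64 |
| `window` | 2 | covers a whole 3-token sentence from any position |
| `epochs` (CBOW) | 50 | passes over the corpus; small corpora need more (see below) |
| `min_count` | 1 | guarantees every drug and disease token is embedded |
| `negative` | 5 | noise words per prediction, unigram^0.75 distribution |
| `layer_widths` | 512-256-128-64 | channel stack; h = 64 latent dimensions |
| `dropout_rate` | 0.2 | applied after every dense layer |
| `head_width` | 32 | merge head hidden layer |
| `kl_weight` λ | 0.1 | channel-divergence penalty |
| `learning_rate` | 5e-5 | Adam step size at production scale |
| `batch_size` | 32 | minibatch size |
| `early_stop_patience` | 20 | epochs without validation-accuracy gain |
| `lr_reduce_factor` / patience | 0.5 / 10 | plateau schedule |
| `smote_ratio` | 0.9 | SORU minority/majority target before undersampling |
| `k_neighbors` | 5 | SMOTE neighbourhood |
| `test_fraction` | 0.1 | held-out share of positives |
| `folds` × `repeats` | 5 × 4 | cross-validation layout |

Classification uses the strict rule ŷ > 0.5 (a probability exactly at
the threshold is a negative call). F1 defaults to the standard harmonic
mean 2PR/(P+R); a `half_harmonic` variant PR/(P+R) is available for
comparability with write-ups that use that form, whose reported values
are only consistent with the standard definition.

## The synthetic benchmark

`generate_synthetic()` does not try to copy real database marginals; its
job is *controllable signal*. Drugs, diseases and all feature
vocabularies are partitioned into latent mechanism clusters. Feature
edges prefer within-cluster items (`p_in` = 0.25 vs `p_out` = 0.04);
treatments occur at `treat_prob_in` = 0.5 within a cluster and
`treat_prob_out` = 0.05 across; gene→target `has_encoded` edges wire
disease genes to drug targets within clusters (the mechanism the model
must find); and side-effect draws prefer disease-mapped terms of *other*
clusters (bias 0.8), so adverse-reaction negatives are truly
non-associated. Half of the side-effect vocabulary is identity-mapped to
disease identifiers so the negative rule can fire at all. The default
scale — 60 drugs, 25 diseases, 4 clusters — keeps a full pipeline run
under about ten seconds on one CPU.

The matched null (`null_synthetic_config`) sets both treatment rates to
the cluster-averaged rate of the planted configuration *and* zeroes the
side-effect cross-cluster bias. The second change matters: with biased
negatives and uniform positives, the label would still correlate with
cluster membership and a "no-signal" run would drift away from
chance-level AUC even though treatments carry no cluster information.

What passing the synthetic benchmark does **not** show: robustness to
the heavy-tailed degree distributions, vocabulary sizes (thousands of
side-effect and substructure terms), missingness patterns and annotation
noise of curated databases, nor calibration of the predicted
probabilities on real pairs. The generator's clusters are a best-case
mechanism; real mechanisms overlap and leak across indications.

## Numerical and procedural choices

* **CBOW determinism.** Training is single-threaded with an internal
  xorshift RNG seeded from the config, so tables are bit-reproducible;
  vocabulary order is frequency-descending with lexicographic
  tie-breaks. Input vectors initialize uniform in ±0.5/k, output vectors
  at zero; the learning rate decays linearly from `alpha` to
  `min_alpha`.
* **Corpus-size scaling.** A desk-scale graph yields a few thousand
  sentences, three orders of magnitude fewer token updates per epoch
  than a production corpus; the desk presets therefore run 200–300 CBOW
  epochs (`synthetic_pipeline_config()` fixes 48 dimensions × 300
  epochs), which costs well under a second.
* **Cross-entropy clamping.** `bce_loss` rejects probabilities outside
  the open interval (0, 1) and clamps inside it to [1e-7, 1 − 1e-7]
  before the logarithm — documented, not silent.
* **KL gradients.** The divergence is computed from stable log-softmax
  values with probabilities floored at 1e-12; analytic gradients are
  checked against central finite differences in the test suite.
* **Glorot-uniform initialization** for all dense layers, seeded through
  R's RNG (`withr::with_seed`), so initialization, shuffling and dropout
  are all reproducible from one integer.
* **Merge non-smoothness.** |ε_r − ε_p| has a kink at zero; the
  subgradient sign(0) = 0 is used, which is the standard choice.
* **Ties in ranking** are broken lexicographically by drug identifier so
  repeated runs produce identical lists.
* **Degenerate inputs.** Single-class metric inputs return the threshold
  metrics and `NA` for AUCs/MCC with a warning; an MCC denominator of
  zero yields 0; empty pair sets propagate as empty results rather than
  errors.
* **SORU reading.** "Oversample positives by 90 %" is implemented as a
  target minority/majority ratio of 0.9 after SMOTE, followed by random
  undersampling of the majority to parity — the sampling-strategy
  semantics of the resampling library family this mirrors.
* **ATC hierarchy.** ATC codes are hierarchical; `expand_atc_codes()`
  turns one code into one feature node per level (prefix lengths 1, 3,
  4, 5, 7). It is an explicit preprocessing step on the input tables
  rather than an implicit part of `build_kg`, keeping graph construction
  a pure schema operation; the synthetic generator emits flat code
  tokens and does not need it.
* **Reported statistics.** Cross-validation reports mean ± sample
  standard deviation over all (fold × repeat) runs on the fixed test
  set, plus an *ensemble* metric report computed from the average of the
  runs' predicted probabilities — individual fold-models on desk-scale
  data are noisy, and the ensemble is the stable headline number.
* **Null-calibration reading.** Chance-level behaviour of the null
  benchmark is asserted on the *mean* test AUC over seeds: a desk-scale
  test set has ~50 pairs, where a per-seed AUC band of [0.4, 0.6] would
  be dominated by binomial noise rather than by the generator.

## Known limitations

* The CBOW implementation is deliberately minimal (no dynamic window
  subsampling, no frequent-word downsampling, no hierarchical softmax);
  at production scale a mature word2vec implementation would be faster.
* Training runs on one CPU core via base matrix algebra; the
  architecture is small enough that this is adequate, but there is no
  GPU path.
* The embedding is transductive: entities absent from the training graph
  have no vector, so genuinely new drugs or diseases cannot be scored
  without re-embedding.
* Hyperparameters are exposed but not searched; the defaults encode the
  reference configuration, not a tuned optimum for any particular graph.
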