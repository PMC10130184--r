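---
title: "Scoring candidate metabolic reactions from network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring candidate metabolic reactions from network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automatically reconstructed genome-scale metabolic models (GEMs) are
incomplete: reactions are missed wherever gene annotation fails, and the
resulting gaps propagate into wrong phenotype predictions. Most gap-filling
tools need phenotypic data to detect inconsistencies. `rxngap` instead scores
candidate reactions *purely from the topology* of the metabolic network, so a
draft model can be prioritised for curation before any experiment is run.

The network is treated as an undirected hypergraph `H = {V, E}`: metabolites
are nodes, and each reaction is a hyperlink joining every metabolite that
participates in it. Stoichiometric coefficients and reaction direction are
deliberately ignored — only participation matters — and a metabolite on both
sides of a reaction counts once. Compartment-qualified identifiers (`atp_c`
vs `atp_e`) are distinct nodes, following the conventions of curated model
collections. The n x m incidence matrix **H** records participation:
`H[i, p] = 1` iff metabolite i takes part in reaction p. Only *known*
(positive) reactions contribute columns, so candidates never leak into the
features they are scored against.

## The scoring model

A candidate reaction is scored in four stages.

**Feature initialisation.** Each metabolite's incidence row `h_i` (its
participation pattern across all training reactions) passes through a
one-layer encoder, `x_i = hard_tanh(W_enc h_i + b_enc)`, with
`hard_tanh(x) = max(-1, min(1, x))`. This is transductive: features exist
only for metabolites seen in the training network, and candidates containing
unseen metabolites are flagged as unscorable rather than guessed at.

**Feature refinement.** The hypergraph is decomposed into disjoint cliques,
one complete subgraph per reaction over its members. Two clique-nodes
originating from the same metabolite share the same initial feature but are
processed independently per clique. Within a clique of size s, features are
graph-normalised per dimension j:

x'_ij = gamma_j (x_ij - alpha_j mu_j) / sigma_j + beta_j,

where mu_j and sigma_j are the mean and standard deviation over the clique's
nodes, and gamma, beta, alpha are learnable (alpha controls how much of the
mean is retained). An alpha-dropout layer (SELU-compatible: dropped entries
go to the SELU negative-saturation constant and the tensor is rescaled to
preserve mean and variance) follows during training. The features are then
convolved with a Chebyshev spectral filter of size K on the clique:
`z^(1) = x`, `z^(2) = L~ x`, `z^(k) = 2 L~ z^(k-1) - z^(k-2)`, and
`x^ = hard_tanh(sum_k W_k z^(k))` (no bias), where
`L~ = (2/lambda_max) L - I` is the rescaled symmetric normalised Laplacian of
the clique.

**Pooling.** Two symmetric functions aggregate the clique's node features per
dimension: the Frobenius (l2) pool `sqrt(mean_i x_ij^2)` and the max-min pool
`max_i x_ij - min_i x_ij`. They are complementary: the first measures overall
feature magnitude, the second the spread across members.

**Scoring.** The two pooled vectors, concatenated in the order (max-min,
Frobenius), pass through an affine map and a logistic sigmoid, giving a
confidence score strictly in (0, 1).

**Training.** Fake "negative" reactions are sampled 1:1 with the positives:
a negative keeps `ceiling(s/2)` members of a real size-s reaction and
replaces the remaining `max(1, floor(s/2))` with uniform draws from the rest
of the node set — half of a real reaction plus random metabolites is
extremely unlikely to be another real reaction. The model minimises the
ranking loss

Loss = mean over positives e of softplus( mean_F(S_f) - S_e ),

which pushes each positive score above the average negative score, using
full-batch Adam. With sigmoid scores the softplus argument is confined to
(-1, 1), so the loss can never drop below `softplus(-1) ~ 0.3133`; loss
values approaching that floor indicate saturated separation, not
overfitting of the loss itself.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d_enc` | 256 | encoder feature dimension |
| `d_conv` | 128 | convolutional feature dimension |
| `K` | 3 | Chebyshev filter size (hops of mixing within a clique) |
| `p_drop` | 0.1 | alpha-dropout probability (training only) |
| `lr` | 0.01 | Adam learning rate |
| `epochs` | 100 | full-batch Adam steps |
| `negative_ratio` | 1 | negatives sampled per positive, each epoch |

The first five form a universal set used for all networks; performance is
insensitive to them within reasonable ranges, so no per-model tuning is done.
Gap-filling adds a confidence floor (0.9995), a candidate budget
(`top_k = 200`) and score averaging over 5 training repeats.

## Numerical and design choices

* **Population standard deviation, floored.** sigma_j in the graph
  normalisation is the divide-by-s form and is floored at 1e-5, so singleton
  and constant cliques stay finite. With alpha = 1 a singleton clique
  normalises to beta exactly.
* **Singleton cliques.** For s = 1 the degree matrix is singular; `L~` is
  defined as the 1 x 1 zero matrix, the limit that keeps the recursion
  well-defined (the convolution reduces to its k = 1 term).
* **Closed-form lambda_max.** Reaction cliques are complete graphs, whose
  normalised-Laplacian spectrum is {0, s/(s-1) with multiplicity s-1};
  lambda_max = s/(s-1) is used exactly rather than estimated numerically.
  After rescaling, `L~` has spectrum {-1, +1}: 0 maps to -1 and lambda_max
  to +1.
* **Negative sampling rounding.** Odd-size reactions keep the majority
  (`ceiling(s/2)`); the floor of one replacement guarantees a negative never
  equals its source, including singletons. The replacement pool is the
  node set of the same hypergraph (an external metabolite pool can be
  supplied). Sampled negatives are *not* checked against the remaining real
  reactions; collisions are possible in principle and rare in practice.
* **Negatives are resampled each epoch** with derived seeds: standard for
  negative-sampling losses, and it prevents memorising one fixed fake set.
* **Full-batch training.** Networks of 10^2-10^4 reactions fit comfortably
  in memory, and one Adam step per epoch keeps the trajectory exactly
  reproducible.
* **Tie handling.** Top-k ranking uses a stable sort (score descending,
  input order on ties); candidate pools are deduplicated as member sets
  against the training reactions before ranking, so known reactions cannot
  inflate recovery. The max-min pool routes gradients to the first extremal
  row on exact ties.
* **Normalisation parameters are shared across cliques** (one gamma / beta /
  alpha vector), which keeps the parameter count independent of network
  size.
* **Dropout is disabled at prediction time**, the standard evaluation-mode
  convention; evaluation-mode scoring is a pure function of its inputs.
* **Gap-fill similarity.** The dissimilarity ranking needs a correlation-like
  measure between a candidate and the model's reactions; the maximum Jaccard
  index of member sets is the default (bounded, parameter-free), with
  Pearson correlation of binary incidence columns as an alternative. Ranked
  candidates are ordered least-similar-first, on the rationale that
  dissimilar reactions are more likely to complement the existing network.
* **No flux screening.** Energy-generating-cycle checks and any other
  flux-based filtering are out of scope; the ranker's output is meant to
  feed such downstream tools.

## What the synthetic generator emulates — and what it does not

All tests run on seeded synthetic hypergraphs from `generate_gem()`. The
generator reproduces the features of real metabolic networks that this
method's inputs depend on:

* a few **currency hubs** (3% of metabolites) joined by 60% of reactions,
  giving the heavy degree skew of ATP/water/protons;
* **reaction sizes 2-8**, uniform;
* **pathway-like modules**: non-hub metabolites are partitioned into 12
  modules and each reaction draws its non-hub members from one home module
  with probability 0.8. This locality is essential, not cosmetic: if
  reactions were independent uniform member sets, held-out reactions would
  share no predictable structure with the training network and no scorer —
  however good — could separate them from sampled negatives much beyond the
  hub-attachment signal alone. Module co-membership is what makes missing
  reactions recoverable from topology, mirroring the pathway structure of
  real GEMs;
* **connectivity**: generation is retried until the hypergraph is connected
  with no isolated metabolite.

It does *not* simulate stoichiometry, reaction direction, thermodynamics,
gene-protein-reaction rules or biomass composition. Passing tests therefore
demonstrate that the implementation learns and ranks planted topological
structure correctly at desk scale; they do not certify accuracy on any
particular organism's GEM, where performance is known to be model-dependent.
Decoy pools for recovery experiments are built with the same
negative-sampling operator applied to randomly chosen real reactions
(`generate_decoys()`), i.e. realistic sizes with broken pathway coherence;
decoys drawn from the generator itself would be statistically
indistinguishable from true held-out reactions and would make recovery a
coin flip by construction.

## Validation protocols

**Type 1 (threshold classification).** Reactions are split 60/40 into
train/test over Monte-Carlo runs; test positives are mixed 1:1 with derived
negatives and classified at the 0.5 threshold; AUROC, recall, precision and
F1 are aggregated over runs. An untrained-model control sits at chance, as
does a label-permutation control.

**Type 2 (top-k recovery).** Reactions are split 90/10; the held-out 10%
joins a candidate pool, everything is ranked by score, and the fraction of
removed reactions inside the top 25 / 50 / 100 / N is reported (N = number
removed). A fixed score threshold is useless against large pools — many pool
reactions have near-identical confidence — hence the rank-based cutoffs.

**Problem sizes.** The study conditions used by the acceptance experiments
are 200 metabolites and 600 reactions, with 10 runs x 50 epochs (type 1) and
5 runs against a 500-decoy pool (type 2); unit tests use smaller networks
(60-120 reactions) with reduced feature dimensions. These sizes were chosen
so the full pipeline runs in minutes on one CPU while keeping enough test
reactions (240 and 60 per run) for stable rates.

## Known limitations

* Transductive: candidates with metabolites absent from the training network
  are unscorable by construction, and are reported rather than scored.
* Direction-blind: gaps caused by wrong reaction directionality cannot be
  found, and reactions identical up to direction are indistinguishable.
* The confidence floor (0.9995) is calibrated to sigmoid saturation on real
  model collections; on small synthetic networks trained briefly, scores may
  not reach it, in which case the ranker correctly returns an empty list
  with a warning.
* Scores are relative within one trained network; they are not calibrated
  probabilities comparable across organisms.
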