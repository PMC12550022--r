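---
title: "Sparse positive similarity embeddings from odd-one-out judgments: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse positive similarity embeddings from odd-one-out judgments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sposer)
```

## The choice model

The triplet odd-one-out task shows three stimuli and asks which one is least
similar to the other two. Picking item $k$ as the odd one out is the same
event as judging the pair $\{i, j\}$ the most similar pair, so a natural
model scores each candidate odd item by the similarity of the two items it
leaves behind. With stimuli embedded as non-negative weight vectors
$w_1, \dots, w_n \in \mathbb{R}^K_{\ge 0}$ and similarity measured by the
dot product $s_{ab} = \langle w_a, w_b \rangle$, the choice probabilities
are a softmax over the three pairwise similarities:

$$
p(\text{odd} = k \mid \{i,j,k\}) =
  \frac{e^{s_{ij}}}{e^{s_{ij}} + e^{s_{ik}} + e^{s_{jk}}}.
$$

An all-zero embedding yields the uniform distribution (1/3 each); growing
$s_{ij}$ while the other two similarities stay fixed strictly raises the
probability that $k$ is the odd one out. Both properties are tested.

The learner (the SPoSE family: sparse positive similarity embedding)
minimizes the mean cross-entropy of observed choices plus an L1 penalty,

$$
L(W) = -\frac{1}{B}\sum_{t=1}^{B} \log p(\text{choice}_t)
  \;+\; \lambda \, \frac{\sum_{a,d} W_{ad}}{n},
$$

subject to $W \ge 0$. Because the weights are non-negative, the L1 norm is
just the sum of entries and the penalty gradient is the constant
$\lambda / n$ per coordinate. The $1/n$ scaling keeps a given $\lambda$
comparable across catalog sizes. Non-negativity plus sparsity is what makes
the surviving dimensions interpretable: each stimulus either expresses a
dimension (positive weight) or does not (exact zero).

## Training procedure

`spose_train()` initializes an $n \times K_{\text{init}}$ matrix uniformly
in $[0, 1)$, splits trials 90/10 into training and validation parts, and
runs mini-batch Adam, clipping weights at zero after every step (projected
gradient). Training stops at `max_epochs` or once the validation loss has
gone `window` consecutive epochs without improving. After training,
dimensions whose column sum is strictly below `prune_threshold` (default
0.1) are removed and the survivors are sorted by descending total weight —
the number of surviving columns is the *effective dimensionality*
$k_{\text{eff}}$. Held-out accuracy is the argmax-probability prediction of
the observed odd-one-out on the validation trials (ties broken toward the
lowest screen position; the tie frequency is reported, and is essentially
zero away from the zero matrix).

Full-scale defaults (`spose_config(profile = "paper")`): $K_{init} = 100$,
$\lambda = 0.008$, learning rate $10^{-3}$, batch 128, up to 500 epochs,
patience 50. The `"reduced"` profile ($K_{init} = 30$, 200 epochs,
patience 25) is sized for the simulation studies in this package (tens of
items, tens of thousands of choices); all tests and the acceptance script
use it so the whole pipeline runs on one CPU in minutes.

Numerical choices: all softmax reductions subtract the maximal score before
exponentiating (log-sum-exp); batches are contiguous slices of a per-epoch
Fisher–Yates shuffle driven by a Mersenne Twister seeded from the
configuration, so a fit is bit-reproducible given its seed; the analytic
gradient is verified against central finite differences to $10^{-6}$
relative error, and the R and compiled objective implementations are
checked against each other.

## Designing the triplet experiment

`build_design()` assembles three blocks. The *exhaustive* block enumerates
all $\binom{m}{3}$ triplets of a small $m$-item subset (optionally several
passes) — at full scale this anchors the online cohort against a laboratory
pilot. The *repeat* block samples a fixed number of distinct triplets
uniformly from all $\binom{n}{3}$ (by unranking random combination indices,
so nothing is enumerated) and repeats each a fixed number of times; repeated
triplets are what make the choice-consistency estimate possible. The *main*
block visits every unordered stimulus pair exactly `pair_coverage` times,
completing each pair with pairwise-distinct third items — infeasible, and
rejected, when `pair_coverage` exceeds $n - 2$. All trials are interleaved
at random, screen positions are re-randomized per trial (uniform over the 6
orders, including for repeated triplets), and the sequence is packed into
consecutive sets of `set_size`; a non-divisible total leaves one short
final set and a warning.

At the full scale (768 items, 48-item subset twice, 1,000 × 40 repeats,
coverage 4, sets of 32) the arithmetic gives 1,252,704 trials in 39,147
sets, with a 1,178,112-trial main block — `design_plan()` computes this
without materializing anything.

## Quality control

Two worker-level exclusion rules, then one trial-level filter:

* a set is *fast* if at least 12.5% of its responses are under 900 ms
  **and** at least 50% are under 1200 ms; workers with three or more fast
  sets are excluded;
* workers with six or more sets in which a single screen position accounts
  for at least half the choices are excluded as deterministic responders.
  Position (not stimulus identity) is the unit here: stimuli change every
  trial, so only a positional habit can be deterministic;
* afterwards every remaining trial with a reaction time strictly below
  900 ms is dropped (a 900 ms response survives).

Choice consistency is computed on repeated triplets: per triplet, the
fraction of unordered response pairs choosing the same *stimulus* (screen
position is resolved first), averaged over triplets so unequal repeat
counts weigh equally; chance is 1/3 for three alternatives. A modal-choice
variant (`method = "modal"`) is exposed because the field's consistency
statistics are not always pairwise; the default is pairwise agreement.

One behavior of the deterministic rule is worth knowing: a worker choosing
positions uniformly at random has a per-set probability of about 0.07 of
showing a 50% position majority in a 32-trial set, so the rule is only
sound for workers with a modest number of sets. Real crowdsourced
collections have exactly that shape (thousands of workers, a handful of
sets each), and the simulators follow it: the recovery study spreads 941
sets over 120 workers (~8 sets each).

## The synthetic-data generator

`generate_ground_truth()` draws non-negative weights as
Exponential(mean = `scale`) entries masked to exact zeros with probability
`sparsity` (rows are redrawn if they end up all-zero), giving positive,
sparse, scale-controllable targets of the same character as fitted
embeddings. `simulate_dataset()` plays a design through the softmax model:
sets are assigned round-robin to worker profiles; compliant workers answer
from the model with an optional uniform lapse; speeders answer uniformly
with log-normal reaction times around a 600 ms median; position-biased
workers click their preferred position with probability 0.8; compliant
reaction times are log-normal around 2.5 s (sdlog 0.35). Worker
heterogeneity beyond these three archetypes is deliberately not modeled —
the profiles exist to exercise the QC rules, not to be a cognitive model of
crowd workers. Simulated data also lack everything else real data have:
item-specific response biases, learning and fatigue within a session,
heavy-tailed reaction times, and semantic structure in which triplets are
hard. Passing tests on these simulations therefore validate the *pipeline*
(that the estimator recovers a known generating structure under its own
model class), not the substantive conclusions one would draw from human
data.

Study conditions for the recovery experiment
(`simulate_recovery_dataset()`): 60 items, 6 true dimensions, sparsity 0.7,
scale 1, pair coverage 17 (30,090 choices — the 30k-choice regime), 120
compliant workers. These were fixed once as a realistic desk-scale version
of the full experiment and are not tuned per run.

## Choosing the sparsity parameter

`grid_search()` implements the standard protocol: train one model per
(λ, seed) pair over an inclusive arithmetic grid (`lambda_grid()`), average
the optimized validation losses per λ across seeds, and report the argmin
(`best_lambda`). At full scale this is 13 values from 0.006 to 0.012 in
steps of 0.0005 with 10 seeds — 130 runs.

For *dimensionality recovery* the argmin rule has a known blind spot, which
we observed directly on the recovery study: near the optimum the validation
loss is almost flat in λ, because a dimension split into several correlated
copies predicts choices almost as well as the consolidated one, while the
effective dimensionality varies enormously (here from 30 at λ = 0.005 to 6
at λ = 0.02 with mean validation losses within ~0.01 nats). The result also
carries the usual lasso-style selection bias toward under-penalization.
`grid_search()` therefore additionally reports `lambda_1se` — the largest
(sparsest) λ whose mean validation loss is within one standard error of the
minimum, the one-standard-error rule familiar from cross-validated lasso —
and `tune_and_train(rule = "1se")` uses it for the recovery study. The SE
in that cutoff is pooled across λ values: the run-to-run loss variance
comes from the random validation split and the random initialization,
neither of which depends on λ, and a pooled estimate over all runs is far
more stable than the few seeds behind any single λ. The
final fit at the selected λ gets a longer budget (2,000 epochs, patience
300): consolidating redundant dimensions under L1 is a slow saddle
crossing, and 500 epochs over 27k trials is far fewer parameter updates
than 500 epochs over 1.25M trials. Those problem sizes are this package's
choices for the simulation scale.

`seed_stability()` re-trains at a fixed λ across seeds and summarizes the
spread of $k_{\text{eff}}$; on the recovery data the standard deviation is
small (≤ 2), mirroring the stability analysis run at full scale.

## Interpretation and RSA

`top_ranking_items()` and `dimension_profile()` export the two standard
views of a fitted embedding: the highest-loading stimuli per dimension, and
one stimulus's weights across all dimensions (the data behind a circular
"rose" bar plot; rendering is out of scope). Dimension ratings on the
7-level typicality scale map to $[0,1]$ as: "not at all" $\to 0$, level
$\ell \to (8-\ell)/7$, averaged across raters — so "very untypical"
(level 7) keeps a small positive value distinct from "not at all". The
rating-based and weight-based similarity matrices are pairwise Pearson
correlations over items (weights first min–max scaled per dimension across
the selected items; a dimension constant over the selection is flagged and
mapped to zero), and `compare_rsa()` correlates their strict lower
triangles. The randomization test shuffles the item labels of one matrix
(joint row/column permutation), recomputes the RSA correlation `n_perm`
times, and reports the plain proportion of permutations at least reaching
the observed value — so p can be 0 when the observed correlation beats
every shuffle, and the test's resolution is $1/n_{\text{perm}}$. No
confidence interval is attached by default; if one is needed, Fisher-z on
the lower-triangle correlation is the documented choice, with the caveat
that matrix entries are not independent.

## Curation

The stimulus-database construction steps that are computable are
reimplemented as-is: per video, keep the softmax vector of the frame with
the highest correct-class probability (ties to the lowest frame index);
average best-frame vectors within categories; compute pairwise cosine
dissimilarities ($1 - \cos$, in $[0,1]$ for non-negative vectors); cluster
agglomeratively (linkage configurable among single/complete/average;
default average, as no linkage is canonical here, and the flat cut is
exposed as `k`/`h` since the meta-cluster cut is a judgment call); and
exclude categories whose mean naming accuracy is below 0.7 **and** that
have at least two exemplars individually below 0.7 — a rule that is monotone
in every exemplar's accuracy. The manual curation steps (merging gendered
category variants, dropping niche sport terms) are editorial, not
algorithmic, and are out of scope.

## Degenerate inputs and edge behavior

Zero embeddings give uniform choice probabilities and a loss of
$\ln 3 \approx 1.0986$; pruning everything returns a 0-column matrix with a
warning (and chance-level predictions); zero-variance feature rows make
Pearson similarities undefined and are flagged as `NA` rather than patched;
cosine dissimilarity refuses zero vectors; triplets with duplicate or
unknown stimuli, infeasible pair coverage, empty designs/batches, and
out-of-range rating levels are argument errors. All stochastic operations
take an explicit seed and are bit-reproducible under it.

## Known limitations

* The embedding is identified only up to dimension permutation, splits and
  merges; recovery is therefore scored on the pairwise dot-product
  similarity structure plus the effective dimensionality, not on weight
  matrices entrywise.
* Validation-loss argmin tuning under-penalizes when the goal is
  dimensionality; the one-SE rule is the package's documented answer, but
  any rule of this kind trades a little predictive fit for parsimony and
  sits on a knife edge when the between-λ loss gaps are themselves about
  one SE, as they are at the recovery study's scale. Across simulation
  seeds the selected λ is usually 0.015–0.02 (k = 6 ± 1) but occasionally
  falls back to 0.01, leaving k ≈ 9–12 redundant-split dimensions; the
  similarity-structure correlation stays ≥ 0.98 either way, which is the
  robust quantity.
* The effective dimensionality depends on the optimization budget: too few
  epochs leave redundant dimensions above the pruning threshold.
* Reaction-time and bias models are archetypes for QC testing, not
  psychology; consistency estimates from simulations should not be read as
  forecasts of human consistency.
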