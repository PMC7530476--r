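---
title: "Methods: network diffusion, joint embedding and negative-bagging prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network diffusion, joint embedding and negative-bagging prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`netonco` scores unlabelled proteins for their resemblance to the proteins
of known oncogenes, using only multi-channel protein association networks
and a positive label list. This vignette documents the model, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
benchmark does and does not establish.

## The positive–unlabelled setting

Only oncogene-encoded proteins are labelled; everything else is unlabelled,
not confirmed negative. The pipeline nevertheless *treats* unlabelled
proteins as negatives during training ("negative samples" by convention) and
relies on two mitigations: (i) bagging over many negative parts, so that any
latent positives contaminating one part affect only one model; and (ii)
never scoring a protein with the model whose training set contains it, so
each score is an out-of-bag quantity.

## Stage 1 — channel networks

One undirected weighted network per evidence channel. An edge exists iff the
channel score is strictly positive; the raw integer score (0–1000) is the
weight. Scores are deliberately not rescaled: the random-walk step
normalizes by neighbour strength, so only relative weights within a node's
neighbourhood matter. Self-loop records are dropped (with a warning);
symmetric duplicate records must agree or parsing aborts — silently keeping
one of two conflicting measurements would be worse than failing. The
`combined_score` column is dropped by default because it is a Bayesian
combination of the other channels and would enter the model twice.

## Stage 2 — random walk with restart

For channel $j$ with column-stochastic transition matrix $T_j$ (entry
$(u,v)$ = weight$(u,v)$ / strength$(v)$) and restart probability $\alpha$,
the diffusion profile of seed $i$ is the fixed point of

$$p \leftarrow (1-\alpha)\, T_j\, p + \alpha\, e_i .$$

Because $(1-\alpha)T_j$ has spectral radius $\le 1-\alpha < 1$, the
iteration is a contraction; we iterate from $p = e_i$ until the max-norm
change is below `tol` (default `1e-8`, budget 1000 iterations) and verify in
tests that the result matches the direct linear solve
$(I-(1-\alpha)T_j)\,p=\alpha e_i$ to ten times the tolerance.

- **alpha** (default 0.5): the restart probability balances local
  neighbourhood (large $\alpha$) against global topology (small $\alpha$).
  0.5 is the convention of the multi-network embedding literature this
  pipeline follows; the seed's own probability grows monotonically with
  $\alpha$ (property-tested).
- Nodes with no edges in a channel receive **no profile** in that channel
  rather than a degenerate vector; the embedding objective simply has no
  term for that (channel, node) pair. This is how proteins that occur in
  only some channels are handled throughout.

## Stage 3 — joint embedding

All channels are fused by one shared set of node vectors
$X \in \mathbb{R}^{n\times d}$ with per-channel contexts
$W_j \in \mathbb{R}^{n\times d}$, minimizing

$$\frac{1}{n}\sum_j \sum_{i\,\text{covered in}\,j}
  D_{KL}\!\left(V_j^i \,\big\|\, \tilde V_j^i\right),
\qquad
\tilde V_{jk}^i = \frac{\exp(X_i^\top W_{jk})}{\sum_{k'}\exp(X_i^\top W_{jk'})}.$$

The softmax denominator runs over **all** $n$ nodes, so every context row
receives gradient (through the denominators) even for nodes absent from the
channel; what absent nodes do not contribute is a KL *term*. Node vectors of
proteins covered by no channel at all are never updated and are flagged in
the `uncovered` attribute of `feature_matrix()`.

Numerical and optimization choices:

- **Softmax** is computed with max-subtraction; reconstructions sum to 1 to
  `1e-12` (tested on extreme logits).
- **Initialization**: independent $\mathcal N(0, 0.1^2)$ draws under the
  configured seed; the fit is bit-reproducible.
- **Optimizer**: full-batch gradient descent with per-step backtracking — a
  step that fails to decrease the objective is rejected and the working rate
  halved, then regrown gently (×1.05 per accepted step, capped at 8× the
  configured rate). The objective trace is therefore non-increasing by
  construction. Analytic gradients are verified against central finite
  differences (relative error < `1e-5`) in the tests.
- **learning_rate** (default 10): this is the step applied to the gradient
  of the $1/n$-scaled objective. Because of that scaling, classic
  "small" rates in the 0.01–0.1 range move the parameters by $O(10^{-4})$
  per epoch and the fit stalls; 10 descends cleanly on desk-scale problems,
  and the backtracking guard makes the default safe on others.
- **Stopping**: `max_epochs` (default 1000) or earlier when a checkpoint
  interval (default every 20 epochs) improves the objective by less than a
  relative `1e-7` — the embedding is meant to be trained to convergence,
  not to an epoch count.
- **d** (default 600): on the full-scale human networks the average of
  AUROC and AUPRC peaks at 600 dimensions, which is why that is the
  package default; desk-scale analyses in the tests use $d = 16$ (and
  $d = 8$ on smaller fixtures), which is ample for a two-block synthetic
  structure. `dimension_sweep()` re-runs the whole evaluation per candidate
  dimension and picks the argmax of (AUROC+AUPRC)/2, with ties going to the
  smaller dimension (cheaper, less noisy).

This is an exact implementation of the objective at desk scale; the
large-scale SVD-type approximation used by released multi-network embedding
tools is deliberately out of scope.

## Stage 4 — negative-bagging random-forest ensemble

With $n_{pos}$ positives and $n_{neg}$ unlabelled proteins, the unlabelled
pool is shuffled (seeded) and split round-robin into
$P=\lfloor n_{neg}/n_{pos}\rfloor$ parts (minimum 1; sizes differ by at most
one), so each part approximately matches the positive count and every
training set is roughly balanced. With the study's counts (18,766 vs 481)
this gives $P = 39$. One random forest is trained per part (all positives
labelled `pos`, the part labelled `neg`).

- **Forests**: 10 trees (the study's setting), `mtry` defaulting to
  $\lfloor \log_2 d\rfloor + 1$, bootstrap sampling; implemented with
  `ranger`, single-threaded with per-model seeds `seed + k` so results are
  bit-reproducible.
- **Model probability** = fraction of trees voting `pos` (vote averaging
  over the majority-voting ensemble), so with 10 trees each single-model
  probability is a multiple of 0.1.
- **Level value** of an unlabelled protein = mean probability over the
  $P-1$ models whose training part does not contain it. In the degenerate
  $P=1$ case (balanced classes) the exclude-own-model rule would leave no
  scorer, so the single model is used and `models_used` records 1.
- Ranking is by decreasing level value with lexicographic id tie-break, so
  output order never depends on input order.

## Evaluation

Each positive is singled out in turn, added to the unlabelled pool (pool
size $n_{neg}+1$), the pool is re-partitioned with a fresh seed derived from
the positive's rank, $P$ models are trained, and the singled-out protein is
scored by the $P-1$ models not containing it. Re-partitioning per positive
follows the described procedure exactly rather than reusing one partition;
it also decorrelates the per-positive scores at the cost of $P$ forest fits
per positive, which is the dominant cost of the pipeline and the reason the
desk-scale conditions below keep $n$ at a few hundred.

Curves sweep the threshold over all distinct scores with the **strict**
prediction rule (level value $> t$): the published candidate counts are only
consistent with strict inequality (a rank-8 value of 0.8053 must enter the
0.8-threshold set of size eight). AUROC is the trapezoidal area and is
verified to equal the tie-corrected pairwise statistic; AUPRC uses the
step-wise rule (precision at each recall increment) because trapezoidal
interpolation over-estimates PR area — a flag switches to trapezoids for
comparison with tools that use them. When nothing is predicted positive,
precision is reported as 1 by convention and flagged. Percentages in
reports are rounded half-up to two decimals to match conventional
formatting.

## The synthetic benchmark

`sim_spec()` defines a two-block stochastic-block-model world observed
through several independent channels: block 1 (the planted, oncogene-like
module) has within-block edge probability `p_in = 0.3`, the background
`p_out = 0.02`; weights are uniform integers in 100–1000 (the STRING score
scale); half of block 1 is labelled positive; each node drops out of each
channel with probability 0.05, exercising the partial-coverage logic. The
default condition is $n = 200$ nodes (50 + 150), 3 channels, $d = 16$,
floor-rule $P$, 10 trees — sizes chosen so the full pipeline, including the
jackknife, runs in seconds while leaving the planted structure
statistically unmistakable. `simulate_null()` draws the same graphs but
labels uniformly at random, giving a matched no-signal control; the test
suite checks that the pipeline's jackknife AUROC exceeds 0.9 on the planted
condition and stays near chance (0.35–0.65 mean over ten seeds) on the
null.

What this does **not** show: real STRING channels have heavy-tailed degree
distributions, strongly correlated channels, score-dependent edge
reliability, and positives that are not a single dense module. Passing the
synthetic benchmark demonstrates that the machinery (diffusion, embedding,
bagging, jackknife) propagates label-correlated structure faithfully — not
that the biological ranking on real data has any particular accuracy.

## Known limitations

- The jackknife retrains $P$ forests per positive; at the full human scale
  (481 positives × 39 models) this is compute-heavy, and this package makes
  no attempt to approximate it.
- Exact full-batch embedding requires $O(n^2)$ memory per channel for the
  profiles; it is intended for networks up to a few thousand nodes.
- No calibration of level values is attempted; they are ranking scores, not
  probabilities of being an oncogene.
- Gene-symbol mapping, species handling and retrieval of external candidate
  lists are out of scope; inputs are opaque protein IDs.
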