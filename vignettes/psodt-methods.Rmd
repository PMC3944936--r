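---
title: "Gene selection with a binary particle swarm and a C4.5 fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection with a binary particle swarm and a C4.5 fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psodt)
```

## The model

psodt treats gene selection as a search over bit vectors
$x \in \{0,1\}^n$, one bit per gene, scored by how well a decision tree
classifies samples using only the flagged genes. Two components carry the
science:

**Binary PSO.** Each particle holds a position $x$, a real velocity $v$,
and the best position it has visited (`pbest`); the swarm shares the best
position any particle has visited (`gbest`). Per iteration and dimension
$d$:

$$v_{id} \leftarrow w\,v_{id} + c_1 r_1 (p_{id} - x_{id})
  + c_2 r_2 (g_{d} - x_{id}), \qquad
  x_{id} \leftarrow \mathbf{1}\!\left[\sigma(v_{id}) > U(0,1)\right],$$

with $\sigma(v) = 1/(1+e^{-v})$, $r_1, r_2$ fresh per-dimension U(0,1)
draws, and $v$ clamped to $[v_{\min}, v_{\max}]$ after each update. Because
$\sigma$ maps velocity to an activation *probability*, position updates
stay stochastic even at the clamp: $\sigma(4) \approx 0.982$, so no bit
ever freezes — the swarm keeps a basal mutation rate of about 1.8% per bit,
which is what lets it escape local optima in mask space.

**C4.5 fitness.** The fitness of a mask is the mean held-out accuracy of a
C4.5 tree over a stratified $k'$-fold split of the training data restricted
to the mask. The tree tests `value <= threshold` on single genes, with
candidate thresholds at midpoints between consecutive distinct sorted
values; a split is chosen to maximize gain ratio (information gain divided
by the entropy of the branch-size split) among candidates with positive
gain and at least `min_samples_leaf` samples per branch. Leaves predict the
majority class. The all-zero mask is scored as the majority-class
proportion — the accuracy of the best constant classifier — so degenerate
particles are dominated without being an error case.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w` | 0.4 | inertia: memory of the previous velocity |
| `c1`, `c2` | 2, 2 | pull toward personal / global best |
| `vmin`, `vmax` | −4, 4 | velocity clamp; bounds per-bit activation in (0.018, 0.982) |
| `max_iter` (T) | 100 | iteration cap; early stop at fitness 1 |
| `n_particles` | `max(2, round(n/100))` | swarm size; the classic reports scale it with the gene count |
| `init_one_prob` | 0.5 | bits initialize by `U(0,1) > 0.5` |
| `min_samples_leaf` | 2 | split admissibility in the tree |
| `k` / `inner_k` | 5 / 3 | outer evaluation folds / fitness folds |

The swarm-size default follows the tabulated convention of roughly one
particle per hundred genes; the narrative convention of one per ten genes
is also seen in the literature, so the value is fully user-settable.
Everything that consumes randomness takes an explicit seed, and every
seeded routine saves and restores the caller's RNG state, so composed
pipelines are replayable bit for bit.

## The evaluation protocol

Classic wrapper-selection reports are ambiguous about what data the
selection sees relative to the reported cross-validation. psodt makes the
choice explicit:

* **nested** (default): an outer stratified $k$-fold loop; within each
  fold, the swarm runs on the training portion only, with fitness from an
  internal stratified $k'$-fold on that portion; a final tree is trained on
  the training portion under the selected mask and scored once on the
  held-out fold. Each fold's selection is a pure function of its training
  data and a per-fold seed derived from the master seed, which is what the
  leakage test exploits: deleting a fold's test samples and re-running that
  fold reproduces its mask exactly.
* **naive**: fitness is the $k$-fold CV accuracy on the *whole* dataset and
  the reported accuracy is the best mask's fitness. This is the most
  literal reading of many published wrapper results and is optimistically
  biased; it exists for comparison, not for reporting.

Repeated runs derive one seed per run from a master seed and are summarized
as per-run accuracy % and selected-gene count (the union of the run's fold
masks — a stated convention, since published per-run counts rarely define
one) with mean and sample (n−1) standard deviation. The frequency table
counts, per gene, the number of fold-level selection events across runs;
genes at or above the threshold (default 4) are flagged.

## The synthetic generator

`synth_data()` emulates the *shape* of small expression studies: $n$
samples, $p$ genes, Gaussian background $\mathcal N(\mu_0, \sigma^2)$ with
$\mu_0 = 8$, $\sigma = 1$ (log2-intensity-like; cosmetic), and a planted
set of informative genes, each shifted by $\delta\sigma$ in one assigned
"up" class (round-robin over classes). Class sizes are fixed by
largest-remainder rounding of the requested proportions and then shuffled,
so the majority baseline is exact — which makes the null-calibration check
sharp. Informative indices are sampled uniformly, not a prefix block.

What it does **not** emulate: probe-level noise, batch effects,
heteroscedasticity, gene–gene correlation, multi-class marker patterns.
Passing the desk-scale checks therefore demonstrates that the search,
fitness and harness work as specified — not that the method will match any
particular accuracy on real microarray data.

## Numerical choices

* Entropies in bits (log base 2) in double precision; candidate scores are
  compared with an absolute tolerance of 1e−12, and ties break
  deterministically: higher gain, then lower gene index, then lower
  threshold. Fitness is therefore identical across platforms.
* `sigmoid()` uses the two-branch form, finite for |v| in the hundreds.
* Leaf majority ties resolve to the earliest class level.
* Pessimistic pruning (off by default; it is not part of the fitness loop)
  replaces a subtree by a leaf when the leaf's pessimistic error count —
  $n$ times the exact binomial (Clopper–Pearson) upper confidence limit
  `qbeta(1 - confidence, e + 1, n - e)` at the default confidence 0.25 —
  does not exceed the sum over the subtree's leaves. Note this bound *keeps*
  a perfect split that isolates 1 sample from 20 of the other class
  (leaf bound 2.59 vs subtree bound 2.09): error-reducing splits survive,
  error-neutral ones collapse.
* Zero-gene datasets (the empty mask) train to a single majority leaf
  rather than erroring, so the optimizer can traverse degenerate states.
* Missing values are load-time errors; the package does not impute.

## Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen
once as the smallest sizes at which every claim is statistically sharp:
the split-scoring oracle runs 1000 random micro-datasets (≤ 6 samples,
≤ 3 genes, values in {1,2,3}); the end-to-end recovery and null-calibration
experiments use 60 samples × 100 genes with 5 planted markers
($\delta = 3$), a swarm of 20 particles, 30 iterations, nested 5×3 folds,
10 seeds each. On these conditions the median outer accuracy sits around
0.91 (theoretical ceiling for a single marker at $\delta = 3$ is
$\approx 0.93$), median planted-marker recall around 0.8–0.9, and the
no-signal runs stay within the 99% binomial band of the 50% majority rate.

## Known limitations

* At desk scale the frequency filter is blunt: masks keep roughly half of
  100 genes, so most genes exceed frequency 4 within a few runs. The filter
  becomes informative at realistic gene counts (10^3–10^4), where selected
  fractions are small.
* Precision of marker recovery is intrinsically low for a wrapper with a
  tree fitness: genes that are never tested by any split are selectively
  neutral, so the swarm has no gradient to drop them. Recall, not
  precision, is the meaningful recovery metric; the tree and the frequency
  table provide the shortlist.
* `naive` mode inflates accuracy by construction; it is labelled as such
  and excluded from headline claims.
* Trees are binary with threshold tests only; categorical attributes,
  fractional missing-value splits and rule post-processing are out of
  scope.
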