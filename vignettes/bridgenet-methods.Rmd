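---
title: "Bridge networks and bridgeness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridge networks and bridgeness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgenet)
```

## The scientific problem

Cellular metabolite homeostasis is regulated by a relay: *metabolic
sensors* (e.g. the nuclear receptor FXR for bile acids) detect intracellular
metabolite levels, and *metabolic enzymes* catalyze the reactions that
change those levels. Proteins that are neither sensors nor enzymes but that
carry regulatory information between the two layers — *bridge proteins* —
are candidate disease markers: a defect in a relay disturbs the whole
regulatory loop even when sensors and enzymes themselves are intact.

`bridgenet` operationalizes this idea as a network analysis. It builds a
directed, weighted interaction network around a chosen sensor set $S$ and
enzyme set $T$, scores every intermediate protein by how strongly it
bridges $S$ to $T$, and then evaluates the top-scoring proteins as
discriminative and prognostic markers in expression and survival data.

## Network construction

**Integration.** Protein–protein interactions (PPI) are undirected and
contribute two antiparallel directed edges; protein–DNA interactions (PDI)
are directed from a transcription factor to its target gene and contribute
one edge. Self-loops are dropped; duplicate directed edges are merged, and
a merged edge supported by both kinds is labelled PDI.

**Edge distances.** Each edge $(i, j)$ receives the co-expression distance

$$d_{ij} = 1 - r_{ij}^2,$$

where $r_{ij}$ is the Pearson correlation of the two genes' expression
across the co-expression panel samples. Strongly co-expressed pairs of
either sign are "close" ($d \to 0$); uncorrelated pairs are maximally
distant ($d = 1$). Edges whose endpoints are missing from the panel, or
whose correlation is undefined (zero variance), are set to $d = 1$ rather
than dropped: an unmeasurable functional link should be penalized, not
silently removed. Distances are invariant under sample permutation of the
panel.

**Node filtering.** Interactome databases carry tissue-agnostic edges, so
nodes can be filtered by relative target-tissue expression: for each gene
the ratio of its mean expression in the target-tissue columns of a tissue
panel to its mean across all panel columns is computed, and genes below the
40th percentile of the ratio distribution are removed (the percentile is a
parameter; 40 is the default cutoff at which the marker set's
discriminative p-value shift is strongest). Three choices deserve note:

* sensors and enzymes are exempt — removing them would make the bridgeness
  sum degenerate;
* the percentile is computed over genes present in both panel and network,
  so the cutoff adapts to the analyzed gene universe rather than the whole
  panel;
* ratios are computed per sample, not per tissue type. A per-tissue-type
  average is a defensible alternative when the panel is strongly unbalanced
  across tissues; with only a couple of target-tissue columns the two
  conventions differ negligibly.

**Reference extraction.** Roles (`sensor`, `enzyme`, `intermediate`) are
assigned — a gene listed in both sets is treated as an enzyme — and a node
is retained iff it is a sensor/enzyme or it lies on some directed
sensor-to-enzyme walk (reachable from a sensor and reaching an enzyme along
edge directions, PDIs being one-way). Extraction is idempotent, and with
$S = T =$ all nodes it is the identity, which is exactly how the
"whole-network" comparison variant is produced: the glycolysis and
whole-network variants are configuration (different $S$, $T$ inputs), not
separate code paths.

## The bridgeness score

For an intermediate node $i$,

$$B_i = \sum_{s \in S} \sum_{t \in T} \frac{d(s,t)}{d_i(s,t)},
\qquad d_i(s,t) = d(s,i) + d(i,t),$$

where $d(\cdot,\cdot)$ is the shortest-path distance on the directed
weighted graph and $d_i(s,t)$ is the shortest path from $s$ to $t$
constrained to pass through $i$. Each addend lies in $[0, 1]$: it equals 1
exactly when $i$ sits on a shortest $s$–$t$ path and decays toward 0 as
$i$ moves away from it; pairs that cannot be connected at all (infinite
distance, through $i$ or otherwise) contribute 0. Hence
$0 \le B_i \le |S|\,|T|$, with the ceiling attained only by a node on a
shortest path of every reachable pair when all pairs are reachable.

Numerical conventions:

* the ratio form $d(s,t)/d_i(s,t)$ is isolated in one internal function so
  that an alternative decay (e.g. exponential in $d_i - d$) is a one-line
  change;
* the degenerate case $d(s,t) = d_i(s,t) = 0$ (chains of perfectly
  correlated genes) contributes 1 by convention and is capped there;
* sums run over ordered sensor→enzyme pairs only, consistent with the
  one-way semantics of PDI edges;
* negative edge distances are rejected (impossible for $1 - r^2$, but
  guarded);
* ranking ties break by ascending gene symbol, so results are reproducible
  across runs and platforms.

`bridgeness_bruteforce()` recomputes the same contract with every distance
obtained by exhaustive enumeration of simple paths (refusing networks of
more than 12 nodes). It exists purely as an independent oracle for the
Dijkstra-based implementation and is exercised against it on hundreds of
random digraphs in the test suite.

For comparison reports, `standard_centralities()` returns degree, harmonic
closeness (mean of inverse distances, so unreachable pairs contribute 0)
and weighted betweenness; zero-distance edges are raised to $10^{-12}$ for
betweenness, which requires strictly positive weights.

## Discriminative evaluation

Expression is gene-wise Z-score normalized (constant genes become zero
rows and are flagged). Per-gene discrimination between two tissue classes
uses the classical pooled-variance Student t-test (Welch available as a
flag); genes with zero pooled variance get $p = 1$ rather than an
undefined value. Whether a ranked marker set is collectively more
discriminative than background is tested with a one-sided two-sample
Kolmogorov–Smirnov test of whether the set's p-values are stochastically
smaller (left-shifted) than the background's; `choose_marker_count()`
scans a grid of top-$k$ cut-offs (default 10–100 by 10) and returns the
count with the smallest KS p-value, ties toward the smaller count.

Multivariate discrimination uses cumulative feature selection down the
bridgeness ranking: for each count $k$, a logistic-regression classifier on
the top-$k$ genes is evaluated by stratified 5-fold cross-validation with 5
repeats, accuracy = correct/total pooled over folds and averaged over
repeats. The logistic fit carries a small fixed ridge penalty
($\lambda = 10^{-3}$, documented constant) so that linearly separable
training folds do not diverge; predictions threshold the fitted probability
at 0.5, and accuracy is invariant to gene order within a fixed top-$k$
set. Random-feature baselines redraw $k$ genes (without replacement) 100
times, evaluate each draw with the same cross-validation, and report the
mean with a normal-approximation 95% confidence interval over the draw
means (the CI method is a design choice, as is fold stratification, which
protects small classes). All fold assignments derive from one integer
seed.

## Prognostic evaluation

Patients are subgrouped by agglomerative hierarchical clustering on
Euclidean distances between their marker-gene expression profiles
(complete linkage by default — the classical default of the statistical
environments of the microarray era — exposed as a parameter), and the tree
is cut into $k = 3$ groups. Group survival is compared by Kaplan–Meier
estimation with the $k$-group log-rank test (delegated to the `survival`
package; the test suite re-derives product-limit and log-rank values by
hand on small tables to pin the conventions).

"Poorest prognosis" is operationalized as the subgroup with the smallest
restricted mean survival time — the area under the KM curve up to the last
observation time common to all groups — with ties to the smallest group
label; a fixed-horizon KM alternative is available. The supervised
classifier then takes the mean marker profile of the poorest training
subgroup as a *reference profile* and labels a patient *poor* when the
Pearson correlation of their marker expression with the reference exceeds
a threshold (strict inequality).

The threshold is selected by repeated cross-validation on the training
cohort: per repeat, a random 5-fold split; per fold, the reference profile
is rebuilt from the fold's training portion alone (re-clustering and
poorest-group identification on that portion, so the held-out patients
never influence their own reference); held-out correlations are pooled
across the 5 folds, a two-group log-rank p-value is computed at every grid
threshold (default $-0.95$ to $0.95$ by $0.05$), and the repeat's best
threshold is the arg-min p with ties toward the smaller (more inclusive)
threshold. The final threshold is the mean of the per-repeat bests
(default 100 repeats). Pooling before the log-rank, rather than testing
each ~30-patient fold separately, keeps the per-threshold test stable;
re-clustering inside each fold, rather than freezing a training-wide poor
group, is the stricter reading of the cross-validation design — the
alternative would leak the full-cohort subgrouping into the folds.

Clinical covariates (mutation status and the like) plug into the same
machinery: any categorical per-patient label can be passed to
`evaluate_prognosis()` in place of predicted labels.

## The synthetic-data generators

All tests run on generated inputs with known ground truth.

* `simulate_interactome()` plants a relay layer: every sensor connects to
  every bridge by a PDI and every bridge to every enzyme by a PPI, so
  sensors reach enzymes *only* through the planted bridges. Decoy PPI
  edges among non-bridge nodes are proposed at a per-pair probability and
  accepted by rejection: an edge that would open a bridge-free
  sensor-to-enzyme path (checked by reachability) is discarded. This keeps
  the recovery property exact — the planted relays are provably the
  top-scoring intermediates — while still surrounding them with realistic
  clutter. Defaults (2 sensors, 3 enzymes, 3 bridges, 30 decoys, decoy
  edge probability 0.08) give a small sensor/enzyme core inside a larger
  intermediate cloud, the same shape as a curated pathway inside an
  interactome.
* `simulate_expression()` draws a standard-Gaussian background, shifts
  declared differential genes by a chosen effect size in the tumor class,
  and induces within-block correlation $\rho$ through a shared latent
  factor ($x_g = \sqrt{\rho}\, f + \sqrt{1-\rho}\, z_g$), which gives
  exactly pairwise correlation $\rho$ in expectation.
* `simulate_cohort()` assigns each patient a latent poor/good status
  (poor fraction 1/3 by default, echoing a minority high-risk subgroup),
  draws poor patients' signature genes near a fixed alternating ±1.5
  template (an alternating template has variance across genes, which a
  constant shift would not, so correlation-to-reference is well defined),
  and generates proportional-hazards event times (exponential by default,
  Weibull shape exposed) with baseline hazard 0.03/month — median ~23
  months for good-prognosis patients, a realistic recurrence scale — and
  the hazard multiplied by the hazard ratio for poor patients. Censoring
  is independent exponential with the rate chosen so each patient is
  censored with exactly the requested probability (default 0.3).

What the generators do *not* emulate: probe-level microarray noise, batch
effects, heavy-tailed intensity distributions, correlated censoring, or
the marginal distributions of any real cohort. Passing tests therefore
demonstrate that the algorithms recover what they are designed to recover
under their own model assumptions — not that the biological conclusions
transfer to any particular real dataset.

## Problem sizes and reproducibility

The test suite and the acceptance script use deliberately modest problem
sizes — oracle comparisons on 4–8-node digraphs, 38-node planted
interactomes over 20 seeds, 2000-gene null matrices, 1000-cohort null
calibrations with two ~50-patient arms, and 150/150-patient
train/test prognostic cohorts with threshold selection at 10
cross-validation repeats (the function default is 100) — sizes at which
every property is sharply testable while a full run stays in the minutes
range on one core. Every stochastic routine takes a single integer seed
and restores the caller's RNG state; repeated runs are bit-identical.

## Known limitations

* The bridgeness ratio form is the simplest functional form consistent
  with the score's stated limiting behavior; other decays with the same
  limits exist and can be swapped in at one site.
* Shortest-path semantics make the score sensitive to spurious
  zero-distance edges (perfect correlations from degenerate expression);
  such edges are logged and the degenerate addend capped.
* The tissue filter assumes the panel's columns are comparable in scale;
  it performs no within-panel normalization.
* The prognostic pipeline assumes the marker panel is given; it performs
  no marker discovery of its own, and competing signatures are compared
  simply by passing their gene lists as markers.
* Exact classifier accuracies depend on the ridge constant and fold seeds
  at the third decimal; conclusions in the tests are therefore stated as
  bands, never as point values.
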