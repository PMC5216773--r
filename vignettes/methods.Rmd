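---
title: "Fuzzy-measure disease similarity and lncRNA association prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-measure disease similarity and lncRNA association prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmlncsim)
```

## The model in brief

The package rests on one biological assumption: lncRNAs with similar
functions tend to be associated with similar diseases. It therefore needs
a disease–disease similarity that respects how specific the shared
biology of two diseases is, and a way to lift that similarity to lncRNAs
through their associated disease groups.

Disease similarity is built on MeSH Category C. Every disease expands
into the DAG of its descriptor plus all tree-number ancestors. A term
shared by nearly every disease DAG (e.g. a top-level category) says
little; a deep shared term says a lot. Information content captures this:
`IC(t) = -log(N_DAG(t)/TN_DAG)`, zero for universal terms, maximal for
terms unique to one DAG. Densities `FD(t) = cap * IC(t)/max IC` turn each
disease's term set into a fuzzy set, and a Sugeno λ-measure — the unique
non-additive measure consistent with those singleton densities and with
`g(full set) = 1` — scores any subset of terms. The similarity of two
diseases is the measure of their shared terms, evaluated under each
disease's own λ and averaged. Unlike a plain Jaccard-style overlap, this
weights shared terms by specificity and lets the interaction parameter λ
absorb redundancy among overlapping annotations; unlike edge-weight
hierarchical models it needs no per-edge contribution factor.

LncRNA functional similarity is the best-match group average: every
disease in one group is credited with its most similar disease in the
other group, summed both ways and normalized by the total group size.
It is 1 for identical groups and 0 when no cross-group similarity exists.

For prediction, the associations themselves carry signal that the
ontology cannot see, so the model averages each similarity with a
Gaussian interaction-profile kernel computed from the binary association
matrix (and optionally an expression-based Spearman similarity for
lncRNAs). Scoring is Laplacian-regularized least squares in each space,
`F = (I + ηL)^{-1} Y` with the normalized graph Laplacian
`L = I - D^{-1/2} S D^{-1/2}`, averaged across the two spaces.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cap` | 0.999 | scales all densities into (0,1); unitless |
| `logBase` | e | base of the IC logarithm |
| `gammaPrime` | 1 | kernel bandwidth multiplier (per mean squared profile norm) |
| `etaLnc`, `etaDis` | 1 | Laplacian smoothing strength per space |
| `w` | 0.5 | weight of the lncRNA-space scores in the combination |
| `exprRescale` | "shift" | Spearman r mapped to [0,1] by (r+1)/2 |

Why these defaults:

* **Density cap.** The globally rarest term has `IC/max IC = 1` exactly —
  and every disease contains at least one such term (its own heading,
  whenever it appears in no other DAG). A density of exactly 1 makes the
  λ equation rootless on (−1, 0) whenever that term co-occurs with
  others, since `∏(1+λg) − (1+λ)` then stays negative on the whole
  interval. Scaling all densities by 0.999 preserves their ordering and
  ratios while guaranteeing a bracketed root. The package rejects
  `cap = 1` at the density stage rather than failing later in the solver.
* **Log base.** Densities are ratios of ICs, so the base cancels: the
  similarity matrix is provably base-invariant (a property the test suite
  checks to 1e−8). Natural log is used only because a convention must be
  fixed.
* **Normalization scope.** The IC denominator (`max IC`) is taken over
  all terms appearing in the dataset's disease DAGs. Restricting the
  maximum to the dataset's own disease headings could leave a rarer
  ancestor term with a raw density above 1, violating the density
  contract, so the broader term universe is used. `TN_DAG` counts the
  diseases of the loaded association table; the full Category C can be
  used instead by building DAGs for all descriptors.
* **η and w.** With η → 0 the scores collapse to the labels and nothing
  is learned; large η over-smooths. η = 1 and an even two-space split
  w = 0.5 are the neutral settings; both are exposed through
  `fmlncsimConfig()` and recorded in every cross-validation result's
  config snapshot.
* **Spearman rescaling.** Raw rank correlation lives in [−1,1] while all
  other components live in [0,1]; the affine map (r+1)/2 makes the
  "simple average" integration meaningful. A clamp-at-zero alternative
  (`exprRescale = "clamp"`) is provided for users who prefer treating
  anticorrelation as mere dissimilarity.

## Numerical choices and degenerate inputs

* **λ root finding.** The root is bracketed analytically: in (−1, 0)
  when densities sum above 1, in (0, ∞) when below (upper end doubled
  until the residual changes sign), with λ = 0 returned exactly when the
  densities sum to 1 within 1e−12. Brent's method (`uniroot`) at
  machine-level tolerance is followed by up to five guarded Newton steps,
  which in practice drives the residual `|∏(1+λg) − (1+λ)|` to ~1e−14
  even for sets of 30 densities. When many large densities squeeze the
  root against −1 beyond double resolution, the closest representable
  point is returned; its residual is at machine-precision scale. No
  unbracketed Newton is ever used.
* **Singleton density sets.** The λ equation degenerates (any λ solves it
  when FD = 1, only λ = 0 otherwise); λ = 0, the additive limit, is the
  unique continuous choice and is fixed by convention.
* **Empty intersections and empty sets.** The measure of the empty set is
  0, so disjoint DAGs give similarity 0 — the standard fuzzy-measure
  boundary condition.
* **Similarity diagonal.** For a multi-term disease the full-set measure
  is 1 under its own λ by construction, but for a singleton set under the
  λ = 0 convention it would be the (capped) density instead; the diagonal
  is therefore set to 1 by definition, which is also cheaper and avoids
  tolerance noise.
* **Diseases outside MeSH / lncRNAs without scorable diseases.** Their
  semantic or functional rows are NA and the ids are carried in the
  object's `unscored` slot; integration falls back to the Gaussian kernel
  for exactly those rows. Nothing is silently dropped: name mapping is
  exact after whitespace/case normalization only, and misses are
  reported.
* **Graph Laplacian isolates.** An entity whose similarity row sums to
  zero has no edges; its Laplacian row is zeroed so regularization leaves
  its scores at the label values (the identity-similarity limit `F = Y`
  holds for any η).
* **All-zero kernel profiles.** They contribute 0 to the mean profile
  norm but still count in it; a matrix whose profiles are all zero has no
  defined bandwidth and is rejected.
* **Ranking ties.** Candidate lists break score ties lexicographically on
  the lncRNA id, making ranked output byte-reproducible.

## Cross-validation semantics

In global LOOCV each known pair is zeroed in the training matrix and
*every* association-dependent quantity — both Gaussian kernels and the
functional-similarity entries of the affected lncRNA — is recomputed from
the masked matrix before rescoring. This is stricter than recomputing the
kernels alone, but it is the only reading under which no component of the
training input contains the held-out label (the test suite asserts this
masking on every iteration, and separately checks that the incremental
row update matches a full rescoring). The held-out pair is ranked against
all pairs never observed as associated; the AUC is the mean candidate
percentile with half-credit for ties, and the ROC staircase is emitted
with explicit corner points so its trapezoidal area equals that rank
statistic exactly. Repeated k-fold follows the same contract with fold
partitions drawn reproducibly from a single integer seed.

The disease semantic similarity is *not* recomputed per fold: it depends
on MeSH ancestry, not on which pairs are observed, and the disease
universe (hence `TN_DAG`) is held fixed at the association table's
disease set.

## The synthetic generator

`generateCorpus()` emulates the structure the method exploits, not the
statistics of real curation. It grows a seeded MeSH-like forest (dotted
tree numbers, bounded depth and fan-out, one subtree per block), draws
diseases from each subtree so blocks are DAG-coherent, assigns lncRNAs to
blocks round-robin, and samples associations at `withinProb` (default
0.6) inside a matched block against `backgroundProb` (0.02) outside.
Expression profiles are block means plus Gaussian noise. All randomness
flows from one integer seed; fixtures round-trip byte-exactly through the
real ASCII writer and parser, so parser and generator are tested against
each other.

What it does **not** emulate: the heavy-tailed term-frequency
distribution of real MeSH, literature-curation bias (well-studied
diseases have systematically deeper DAGs and more associations),
multi-parent descriptors beyond what random forests produce, and
database-specific name variants. Passing the signal-recovery property
therefore shows the pipeline recovers planted block structure under its
own modelling assumption — it does not certify performance on any
particular curated database, whose snapshots also evolve over time.

## Problem sizes

The default fixture is 40 lncRNAs × 25 diseases in 5 blocks over a
60-term hierarchy (~130 positives), small enough that a full LOOCV —
roughly 130 rescoring passes with kernel and functional-similarity
recomputation — runs in about a second, and the 20-seed signal-vs-null
comparison in under two minutes; axiom checks use 50 corpora of
12 × 10. These sizes were chosen as the smallest at which block structure
is reliably recoverable (mean LOOCV AUC well above 0.75) while keeping
the whole suite quick to iterate on.

## Known limitations

* Converting a DAG to a density set discards the hierarchy's internal
  edge structure; two diseases with the same term multiset but different
  wiring are indistinguishable.
* Research-intensity bias in MeSH annotation propagates directly into IC
  and hence into similarity scores.
* The predictor uses only association, ontology and (optionally)
  expression data; other lncRNA data types are out of scope.
* The Laplacian RLS component follows the standard normalized-Laplacian
  closed form with per-space regularization and averaged combination;
  variant formulations of the same two-space idea exist, and η, w are
  deliberately exposed rather than fixed.
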