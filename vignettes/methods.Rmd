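---
title: "Methods: expression-based two-way diffusion for miRNA-disease ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-based two-way diffusion for miRNA-disease ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdiff)
```

## The model and its assumptions

`mirdiff` ranks unobserved miRNA-disease pairs by diffusing resource through
the known bipartite association network after weighting it with two
similarity matrices. The core assumption is biological: miRNAs whose
expression is distributed similarly across human tissues and cell lines tend
to participate in semantically similar diseases. Everything downstream
follows from that: if the assumption is false for a dataset, the
similarity-weighted diffusion degenerates towards the plain
resource-allocation score, and cross-validated AUC falls towards what the
bare network topology supports.

Three further structural assumptions are implicit:

* the known association list is a *sample* of a denser true network, so a
  zero in the adjacency matrix means "unverified", not "absent";
* Pearson correlation is an adequate summary of expression co-distribution
  (location- and scale-free, but linear and sensitive to heavy tails);
* disease relatedness is captured by shared ancestry in the term hierarchy,
  with relevance decaying geometrically per level.

## Pipeline and notation

With $A \in \{0,1\}^{n_m \times n_d}$ (rows miRNAs, columns diseases),
$SM_{mir}$ and $SM_{dis}$ the two similarity matrices:

1. **Weighted networks.** $A_d = A \cdot SM_{dis}$ spreads each known
   association across similar diseases; $A_m = SM_{mir} \cdot A$ across
   similar miRNAs. With identity similarities both equal $A$.
2. **Shares.** Each weighted network is normalised twice: column shares
   $W(i,j) = A_w(i,j) / \sum_t A_w(t,j)$ and row shares
   $M(i,j) = A_w(i,j) / \sum_t A_w(i,t)$. A zero denominator yields a zero
   share (see numerical choices).
3. **Two diffusion passes.** Step 1 produces a miRNA-by-miRNA resource
   matrix $S_{1,mir} = \alpha W_d A^\top + (1{-}\alpha) W_m A^\top$ and a
   disease-by-disease matrix
   $S_{1,dis} = \beta M_d^\top A + (1{-}\beta) M_m^\top A$. Step 2 feeds
   these back: $S_{2,mir} = \alpha W_d S_{1,dis} + (1{-}\alpha) W_m S_{1,dis}$
   (miRNA-by-disease) and
   $S_{2,dis} = \beta M_d^\top S_{1,mir} + (1{-}\beta) M_m^\top S_{1,mir}$
   (disease-by-miRNA). Step 3 averages the two views:
   $SS = (S_{2,mir} + S_{2,dis}^\top)/2$.

The diffusion is exactly two passes. It is not a random walk run to
convergence; the design trades the stationary-distribution smoothing of
restart walks for a score that stays local to the two-hop neighbourhood of
each node.

### Orientation of the weighted networks

The two matrix products in step 1 of the pipeline are the only assignment of
$\{A \cdot SM_{dis},\; SM_{mir} \cdot A\}$ to $\{A_d, A_m\}$ under which the
share normalisations and both diffusion passes are dimensionally consistent
with a fixed miRNA-by-disease adjacency. The package fixes rows = miRNAs,
columns = diseases everywhere (readers, writers, scores), and all share sums
follow from that single convention. Likewise, on the disease side of both
combination steps the operands are the disease-indexed resources, and the
second pass sends the miRNA-weighted stream through $A_m$'s shares — the
symmetric counterpart of the disease-weighted stream — so that the
$(1-\beta)$ weight has an effect.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha`, `beta` | 0.5 | Convex weights between the disease-weighted and miRNA-weighted streams on the miRNA and disease sides. 0.5 weighs both information sources equally; every score entry is affine in each (tested), so behaviour between endpoints is fully predictable. |
| `delta` | 0.5 | Semantic decay per DAG level, dimensionless in (0,1). Halving per level is the convention of the semantic-similarity literature this measure comes from. |
| `clip_negative_similarity` | `FALSE` | Pearson similarities can be negative; the diffusion shares then lose their probabilistic reading. Default keeps the correlation as computed; the flag zeroes negatives first. Both behaviours are deliberate options because neither is canonical. |
| `treat_constant_as_missing` | `FALSE` | A zero-variance profile has no defined correlation. Default: error naming the miRNA (surfacing a data problem beats silent imputation); flag: route it through the missing-profile mean rule. |
| `lambda_neighbor` | 0.5 | User- vs item-based weight in the neighbor CF baseline. |
| `katz_beta`, `katz_max_length`, `katz_include_direct` | 0.01, 4, `TRUE` | Damping, walk cap and direct-edge term of the Katz baseline. No canonical values exist for this application; 0.01 is safely below the typical inverse spectral radius of these networks (a message is emitted when it is not), and length 4 is the longest walk that still reflects local structure. |
| `cv_folds`, `cv_repetitions`, `seed` | 5, 20, 42 | Cross-validation geometry; repetition $r$ shuffles with `seed + r`. |

## Similarity construction

**miRNA side.** All computable pairs get `stats::cor` of their profiles. Any
pair touching a miRNA without a profile gets one shared value: the arithmetic
mean of all computable *off-diagonal unordered* pairs. Self-similarities are
excluded from that mean — including them would inflate it by a block of exact
1s that carry no information about between-miRNA similarity. The `imputed`
mask records exactly which entries were filled, and the diagonal is forced to
1 and never masked.

**Disease side.** Contributions are computed by breadth-first distance from
the disease term along reversed edges — the dynamic-programming evaluation of
the max-decay recursion in reverse topological order, equal to
$\Delta^{\text{(shortest descending distance)}}$. The test suite keeps an
independent exhaustive path-enumeration oracle and checks entrywise equality
to 1e-12 on random DAG forests. A disease's term set includes its own term
(contribution 1); without it, self-similarity would be below 1 and the
matrix diagonal meaningless. Diseases that appear in the association list but
have no DAG are handled by mirroring the miRNA imputation rule (mean of
computable off-diagonal disease pairs, flagged); this is the only precedent
the data model offers for such diseases, which real MeSH-derived datasets do
contain.

## Evaluation design

* **Candidate pool.** A held-out positive competes against all pairs absent
  from the *full* known set, never against other training positives. This is
  the convention of the link-prediction models this family is benchmarked
  against, and it keeps the pool identical across rounds.
* **Pooling rule.** Overall AUC is the mean over rounds of the per-round
  concordance fraction (ties 0.5, the Mann-Whitney convention). The LOOCV
  ROC curve is the staircase of normalised held-out ranks; its trapezoidal
  area equals that mean exactly, which the tests assert to 1e-12.
* **k-fold geometry.** Fold sizes differ by at most one; each repetition
  reshuffles with a derived seed, so the whole CV result is reproducible from
  one integer. With folds equal to the number of known pairs the procedure
  collapses to LOOCV (tested as an exact identity of the mean).

## The synthetic benchmark

`synthetic_spec()` defaults generate 60 miRNAs in 6 expression clusters over
40 tissues, 30 diseases on a branching-2 depth-4 term tree (exactly 30
non-root nodes, one per disease, assigned depth-first so contiguous disease
blocks occupy neighbouring subtrees), 3 planted associations per miRNA inside
its cluster's block, 10% of associations replaced by uniform noise, Gaussian
expression noise of sd 0.5 around cluster templates, and 10% of miRNAs with
deleted profiles. These sizes keep every cross-validation run in seconds
while leaving enough candidates (~1620) for rank statistics to be stable.

The generator emulates the *statistical structure* the model assumes —
correlated expression within clusters, tree-adjacent disease targets, missing
profiles, label noise. It does **not** emulate: the marginal value
distribution of real expression atlases (templates are Gaussian; Pearson
similarity is location/scale-free so only the correlation structure matters),
the scale-free degree distribution of curated association databases, terms
shared between disease hierarchies of unrelated branches, or curation biases.
Passing recovery tests on this benchmark therefore demonstrates that the
implementation recovers planted structure of the assumed kind — not that the
model attains any particular performance on curated human data.

## Numerical choices

* **0/0 shares.** An all-zero column or row of a weighted network (a disease
  or miRNA isolated by a cross-validation deletion) yields zero shares rather
  than an error: zero flow is the natural continuum limit, and LOOCV must be
  able to isolate nodes.
* **Scale invariance.** Shares are ratios, so rescaling either similarity
  matrix by any positive constant leaves the scores unchanged (tested to
  1e-12). Only the *relative* similarity structure matters.
* **Ties.** Ranking ties (in `rank_disease_candidates`) break by input order,
  which is deterministic because readers preserve first-appearance order;
  AUC ties count 0.5.
* **Exactness tolerances.** Matrix-form diffusion vs the per-element loop
  oracle: 1e-10 over 30 random instances (accumulated float reordering);
  semantic similarity vs path enumeration and AUC vs pairwise concordance:
  1e-12 (identical arithmetic, different algorithm).
* **Degenerate inputs.** An all-zero association matrix scores all zeros; a
  single-class label vector is an error in `roc_auc`; an imputation mean with
  no computable pair is an error; malformed DAGs (cycles, terms that cannot
  descend to the disease term) are errors naming the disease.

## Problem sizes in the test suite

Unit and property tests run on instances up to 25 x 15 with 30-50 random
repetitions per property; recovery tests use the default 60 x 30 benchmark
(180 LOOCV rounds, 20 x 5-fold CV). The full suite and the acceptance script
each complete in well under a minute — sizes chosen so the planted signal is
comfortably detectable and rank statistics stable, while iteration stays
fast.

## Known limitations

* A disease with no known associated miRNA receives only zero or imputed
  flow; the method cannot bootstrap a completely new disease (nor a miRNA
  with neither profile nor associations).
* Damping coefficients are fixed, not learned; the affine-in-alpha/beta
  property means tuning them can only interpolate between the two
  single-stream scores.
* Negative expression correlations sit uneasily in a share-based diffusion;
  both offered behaviours (keep or clip) are pragmatic, not principled.
* The imputation rules collapse all missing-profile miRNAs (and DAG-less
  diseases) to a single similarity value, erasing any identity they might
  have; with many missing profiles the miRNA-weighted stream flattens
  towards uniform flow.
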