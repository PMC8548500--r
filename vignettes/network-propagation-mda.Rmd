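---
title: "Predicting miRNA-disease associations by network propagation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations by network propagation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrwr)
```

## The problem

Experimentally validated miRNA-disease associations are sparse: a typical
curated catalogue covers a few thousand pairs over hundreds of diseases and
miRNAs, so the binary association matrix $A \in \{0,1\}^{n_d \times n_m}$ is
overwhelmingly zero, and most zeros are *unknown* rather than *negative*.
`hetrwr` scores every disease-miRNA pair by propagating a random walk with
restart (RWR) over two heterogeneous networks that join a disease similarity
network, a miRNA similarity network and the (completed) association matrix.
The working hypothesis is the usual guilt-by-association one: miRNAs linked to
similar diseases, and diseases linked to similar miRNAs, are likely to share
further links.

## Similarity layers

**Disease semantic similarity (DSS).** Each disease is a term in an ontology
DAG (in real data, a MeSH-style ancestry graph supplied as a child-parent edge
list). The semantic contribution of ancestor $t$ to disease $d$ is
$D_d(d) = 1$ and $D_d(t) = \max\{\Delta \cdot D_d(t') : t' \text{ child of }
t\}$, i.e. $\Delta^{\mathrm{depth}}$ along the best path, with decay
$\Delta = 0.5$ by default. Two diseases are similar in proportion to the
contribution mass of their shared ancestors:
$$\mathrm{DSS}(i,j) = \frac{\sum_{t \in T_i \cap T_j} (D_i(t) + D_j(t))}
{\sum_t D_i(t) + \sum_t D_j(t)}.$$
The printed form of the base case in the source literature reads "$t$ if
$t = d$"; a contribution must be a number, so the base case is implemented as
$D_d(d) = 1$, the standard Wang-style convention.

**miRNA functional similarity (MFS).** Each miRNA $m_i$ carries the set
$DTT_i$ of diseases it is annotated to. With
$SS(d, DTT) = \max_{d' \in DTT} \mathrm{DSS}(d, d')$, the functional
similarity averages each side's best matches:
$$\mathrm{MFS}(m_i, m_j) = \frac{\sum_{d \in DTT_i} SS(d, DTT_j) +
\sum_{d \in DTT_j} SS(d, DTT_i)}{|DTT_i| + |DTT_j|}.$$
An empty annotation set is an error (it would divide by zero), as is an
annotation term missing from the DSS vocabulary — silent zeros would corrupt
the average.

**Gaussian interaction profile (GIP) kernels.** Rows (diseases) and columns
(miRNAs) of $A$ are binary interaction profiles;
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$ with the data-driven
bandwidth $\gamma = \gamma' / \overline{\lVert x \rVert^2}$ and $\gamma' = 1$.
GIP is computed from the *training* association matrix, and is recomputed from
the masked matrix inside every cross-validation fold to avoid leakage.

**Integration.** Not every disease has a DAG and not every miRNA a useful
annotation set, so the integrated similarities fall back on the GIP kernel
where the primary similarity is absent. "Absent" is judged elementwise as
`primary == 0` by default; an all-zero DSS row (a disease without a DAG) is
then GIP-filled everywhere off the diagonal. An explicit availability mask can
be supplied instead when the caller knows which entities carry side
information, covering the per-entity reading of the rule. The diagonal is
forced to 1 in all cases, which guards against float drift since both
constituents are unit-diagonal by construction.

## WKNKN completion

The weighted K-nearest-known-neighbors step replaces unknown zeros with a
continuous interaction likelihood. For disease $i$, its $K$ most similar
*known* diseases (at least one training association; self excluded; ties by
label) contribute their profiles with decayed, similarity-scaled weights:
$$Y_d(i, \cdot) = \frac{\sum_{t=1}^{K} r^{t-1}\, s(i, n_t)\, A(n_t, \cdot)}
{\sum_{t=1}^{K} s(i, n_t)},$$
and symmetrically on columns for miRNAs. A zero entry becomes
$\min(1, (Y_d + Y_m)/2)$; known 1s are never touched, so the completion is
monotone. The neighbor metric defaults to the integrated similarities; pass
the semantic/functional-only matrices as `sim_d`/`sim_m` to probe the
alternative. A zero normalizer contributes 0 rather than erroring — no
information, no estimate. Defaults $K = 5$, $r = 0.7$.

## Heterogeneous networks

Two degree-weighted adjacencies re-weight the completed matrix
$A^{new}$: the disease-based $ISD \cdot A^{new}$ and the miRNA-based
$A^{new} \cdot ISM$. From them, four transition blocks are built with jump
probability $\varphi$:

* inter-space, disease to miRNA: each row of
  $A^{new} \odot (A^{new} ISM)$ normalized to sum to $\varphi$;
* inter-space, miRNA to disease: each *column* of
  $A^{new} \odot (ISD\, A^{new})$ normalized to sum to $\varphi$;
* intra-space: each similarity row normalized to 1 (the unit self-similarity
  is part of the normalizer, so self-loops carry mass), scaled by
  $1 - \varphi$ for entities with at least one association and left unscaled
  for isolated ones, whose walker cannot jump across.

The assembled matrix is $\bigl[\begin{smallmatrix} W_d & T \\ T^\top & W_m
\end{smallmatrix}\bigr]$, with $T$ the row-normalized block in the
disease-based network and the column-normalized one in the miRNA-based
network — the only dimensionally consistent placement of the published block
layout. The miRNA rows of the disease-based matrix (and vice versa) are *not*
renormalized: the construction is followed verbatim, and the restart term
keeps the walk well defined; connected disease rows of the disease-based
matrix sum to exactly $(1-\varphi) + \varphi = 1$. (The published form of the
isolated-miRNA branch names the disease-space similarity in its denominator;
this is mirrored from the disease equation as the miRNA-space similarity, the
evident intent.) Zero-denominator rows or columns get zero transition mass
rather than an error; after completion they are rare.

## Random walk with restart

Both networks are walked simultaneously for all seeds using the matrix
recurrence
$$P_{t+1} = (1 - \gamma)\, W P_t + \gamma P_0, \qquad
P_0 = \begin{bmatrix} \tfrac{1-\delta}{n_d} I & 0 \\
0 & \tfrac{\delta}{n_m} I \end{bmatrix},$$
with $W$ left-multiplying the state (the published recurrences do not fix the
side; left multiplication is chosen once and the test oracle uses the same
convention). The recurrence unrolls to
$P_t = (1-\gamma)^t W^t P_0 + \gamma \sum_{k<t} (1-\gamma)^k W^k P_0$, which
is the closed form the propagation tests check against; with $\gamma = 0.7$
the neglected tail after ten steps is of order $0.3^{10} \approx 6\times
10^{-6}$ times an already-small state, so ten iterations are effectively
converged (the `t_max = 10` vs `t_max = 50` difference on the default fixture
is below $10^{-6}$ in max norm). Early stopping on the max-norm change is
available via `tol` but disabled by default so runs are exactly reproducible
step-for-step.

The two stationary states fuse as $P = (1-\delta) P_1 + \delta P_2$; the same
$\delta$ weights the seeding and the fusion, matching the single symbol the
construction uses for both roles. Scores are read off the off-diagonal
disease-by-miRNA blocks, averaged with the transpose of the lower block by
default (`symmetrize = FALSE` keeps the top-right block only); no per-column
normalization is applied to $P_1, P_2$ before fusing.

## Parameters

| parameter | meaning | range | default |
|---|---|---|---|
| `k` | nearest known neighbors in WKNKN | integer $\ge 1$ | 5 |
| `r` | WKNKN decay per neighbor rank | $(0, 1]$ | 0.7 |
| `phi` | inter-network jump probability | $(0, 1)$ | 0.9 |
| `delta` | sub-network weight (seeding and fusion) | $(0, 1)$ | 0.7 |
| `gamma` | restart probability | $(0, 1)$ | 0.7 |
| `delta_sem` | semantic decay per DAG generation | $(0, 1)$ | 0.5 |
| `t_max` | propagation iterations | integer $\ge 1$ | 10 |
| `tol` | early-stop tolerance (0 = off) | $\ge 0$ | 0 |

The defaults are the operating point reported for this family of methods on
the curated human association catalogue ($K=5$, $r=0.7$, $\varphi=0.9$,
$\delta=0.7$, $\gamma=0.7$, $\Delta=0.5$, ten iterations); none of them is
re-tuned by this package.

## Evaluation protocols

`eval_binary()` computes ROC and PR curves from first principles by sweeping
every distinct threshold with tied scores grouped; the trapezoidal ROC area is
then exactly the midrank Wilcoxon-Mann-Whitney statistic, and the PR area uses
the conservative rectangular recall-increment rule anchored at recall 0.

`five_fold_cv()` partitions *all* $n_d n_m$ pairs into five folds, masks the
test-fold positives, recomputes everything association-dependent (GIP,
integration, WKNKN) on the masked matrix, and scores the test-fold pairs
against the original binary labels — held-out positives versus never-known
pairs, so training positives never pollute the negative pool. The
semantic/functional similarities are association-independent and enter each
fold unchanged. `completed_eval = TRUE` additionally scores against the
WKNKN-completed training matrix binarized at $> 0$, the alternative reading
of the protocol's matching step. `global_loocv()` masks one known pair at a
time (one full pipeline re-run per positive) and pools the held-out scores
with the full-data scores of all never-known pairs.

## The synthetic study

Because the real catalogue and ontology are external downloads, the package
ships a generator whose defaults define the study used by the tests and the
acceptance script: 60 diseases by 80 miRNAs, 4 planted disease-miRNA
co-clusters, within-block association density 0.3, background 0.01, and an
ontology forest of depth 3 with one tree per block, so the semantic similarity
inherits the planted structure (between-tree similarity is exactly 0).
Annotation sets are derived from the planted associations; an all-zero row or
column is repaired with one forced within-block positive so every entity is
"known". These sizes keep a full 10-seed, 3-arm cross-validation study in the
tens of seconds while leaving roughly 360 planted positives per fixture —
enough for stable fold metrics.

What the fixture does *not* emulate: the extreme sparsity of real catalogues
(~2.9% density there, ~8% here), scale-free degree distributions, ontology
terms shared *between* disease clusters, and annotation noise. Passing the
signal-recovery study therefore shows the pipeline recovers planted
block structure under its stated defaults, not that it attains any particular
performance on curated human data.

## Numerical choices and degenerate inputs

* All computation is dense double precision; at the method's natural scale
  (hundreds by hundreds) dense is simpler and fast, and nothing in the
  pipeline is randomized — seeds affect only fold assignment and fixtures.
* Every ranking breaks ties by score descending, then label ascending.
* Matrix TSVs serialize with 17 significant digits; round trips are exact in
  practice and tested to $10^{-12}$.
* An all-zero association matrix has no GIP bandwidth and is an error; an
  all-zero similarity row yields an isolated, all-zero transition row,
  reported in a diagnostics field rather than raised.
* DAG input is validated for acyclicity (an offending cycle is named); a
  closure term with no path to its disease is a structural error.

## Limitations

* The two cross-validation protocols re-run the full pipeline per fold or per
  held-out pair; LOOCV is linear in the number of positives and is meant for
  catalogue-scale runs, not for matrices with tens of thousands of positives.
* Only the two-space (disease/miRNA) construction is implemented; deeper
  multi-layer networks are out of scope.
* The propagation uses fixed-length iteration rather than a spectral solve of
  the stationary state; that is faithful to the method and cheap at this
  scale, but inexact in the tail (bounded as above).
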