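---
title: "Predicting lncRNA-disease associations with lncDNet: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA-disease associations with lncDNet: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Only a small fraction of lncRNA-disease associations has been confirmed
experimentally, and the confirmed catalogue is tiny relative to the number
of candidate pairs: a typical curated release has on the order of a hundred
lncRNAs, a hundred-odd diseases and a few hundred known associations, so
known positives are outnumbered by unknown pairs roughly fifty to one.
lncDNet ranks the unknown pairs of such a catalogue by fusing several
similarity views of the two entity sets into one heterogeneous graph,
learning node features from type-constrained random walks on that graph,
and scoring pairs with a boosted-tree-to-logistic-regression cascade
trained on a balanced sample.

The package is aimed at computational biologists who have (a) a two-column
association list and (b) a disease-ontology ancestor graph, and want a
ranked candidate list plus honest cross-validated performance numbers. A
synthetic generator with planted structure stands in for the real
downloads, so the entire pipeline is testable offline.

## The similarity layer

**Disease semantic similarity (SSD).** Each disease is a node in an
ontology DAG whose edges point from a disease to its more general parent
terms. The disease contributes 1 to its own semantic value; an ancestor
$u$ contributes
$$C_i(u) = \Delta \cdot \max\{C_i(u')\,:\,u' \text{ a child of } u
\text{ on a path from } d_i\},$$
which a bottom-up evaluation shows equals $\Delta^{h}$ with $h$ the
shortest hop distance from $d_i$ to $u$ (the package's unit tests confirm
this against a brute-force enumeration of all paths). With the semantic
value $C(i) = \sum_{u \in Z(i)} C_i(u)$ over the ancestor closure $Z(i)$,
two diseases are compared through their shared ancestor mass:
$$\mathrm{SSD}(i,j) = \frac{\sum_{u \in Z(i) \cap Z(j)}
\left(C_i(u) + C_j(u)\right)}{C(i) + C(j)}.$$
$\Delta$ (default 0.5) controls how fast ancestral contribution decays:
smaller values concentrate similarity on near-relatives. Values must lie
strictly in $(0,1)$.

**lncRNA functional similarity (FSL).** Two lncRNAs are similar when
their disease sets are semantically close: with sets $DL_1$ ($x$
diseases) and $DL_2$ ($y$ diseases),
$$\mathrm{FSL} = \frac{\sum_{d \in DL_2} \max_{d' \in DL_1}
\mathrm{SSD}(d,d') + \sum_{d \in DL_1} \max_{d' \in DL_2}
\mathrm{SSD}(d,d')}{x + y}.$$
An lncRNA with no known disease would divide by zero; such rows are set
to 0 off-diagonal with a warning, which lets the fusion step (below) fall
back to the interaction-profile kernel. The diagonal is forced to 1 for
lncRNAs with a nonempty disease set — a self-similarity convention the
downstream unit-diagonal invariants require.

**Interaction-profile kernels (GSL, GSD).** A Gaussian kernel on the rows
(columns) of the binary association matrix,
$\exp(-\delta\,\lVert a_m - a_n \rVert^2)$, with bandwidth
$\delta = \delta' / \overline{\lVert a \rVert^2}$, the base bandwidth
$\delta' = 1$ normalized by the mean squared profile norm. An all-zero
matrix has no defined bandwidth and is rejected.

**Fusion (SL, SD).** Elementwise: the semantic/functional value where it
is nonzero, the kernel value where it is zero. Zero here is structural
(no shared ontology ancestry at all), so the test is exact equality, not
a tolerance. The result has unit diagonal and inherits symmetry.

## The heterogeneous network and metagraph walks

The global network is the block matrix
$$U = \begin{pmatrix} SL & A \\ A^{T} & SD \end{pmatrix}$$
over $nl + nd$ typed nodes. Association edges (LD/DL) are exactly the
1-entries of $A$. The similarity blocks are dense, but the walk model is
uniform over neighbours, so they are sparsified: each node keeps its
`top_k` (default 10) most similar positive-similarity neighbours,
symmetrized by union. This preserves local structure while bounding the
degree; raising `top_k` makes similarity layers denser and walks less
selective.

Walks are guided by a *metagraph*: a small DAG over node types with a
source and target of the same type, unrolled recursively (the position
wraps to the source on reaching the target). The default schema is the
diamond L1→D1, D1→L2, D1→D2, D2→L2 — the union of the metapaths L-D-L
and L-D-D-L — because a schema that cannot branch is just a metapath;
users can supply their own with `read_metagraph()`. One step is two-stage
uniform sampling: among the schema-legal edge types with at least one
realized edge, one type is chosen uniformly (probability $1/\mathrm{NUM}$),
then a neighbour of that type uniformly. A walk ends when no legal type
has a realization. `transition_probs()` exposes the exact distribution,
and the tests compare it against a brute-force enumeration on small
graphs as well as against empirical frequencies. Defaults of 10 walks per
source node, maximum length 80, are the conventional scale for walk-based
embeddings of networks with a few hundred nodes.

## Heterogeneous skip-gram embeddings

Each walk is scanned with a window of size $b = 5$; each (center,
context) pair receives a negative-sampling update in which the $U = 5$
noise nodes share the *context's* type — the type-conditioned softmax
approximation, so each type competes only within itself. The loss per
pair is
$$-\log\sigma(\Phi_{v_j}\!\cdot\!\Psi_{v_i}) -
\sum_{u=1}^{U} \log\sigma(-\Phi_{u}\!\cdot\!\Psi_{v_i}),$$
descended in $\Psi$ (input vectors) and $\Phi$ (context vectors). Within
a type, negatives follow the corpus unigram distribution raised to the
3/4 power (standard practice; `noise = "uniform"` switches it off).
Initialization is uniform $(-0.5/d,\,0.5/d)$ for $\Psi$ and zeros for
$\Phi$; the learning rate decays linearly from 0.025 to $10^{-4}$ over
all updates (the word2vec convention) across 5 epochs. Dimension
$d = 64$ is a sensible default for networks of a few hundred nodes.

The inner loop runs in compiled code for speed, drawing from R's RNG so
a seed fixes the result exactly; the identical update rule exists in R
(`sgns_update()`) where a central-finite-difference oracle checks the
gradients to $10^{-5}$ relative error.

## Balanced negatives by K-means

Every unknown pair gets a feature vector of length $2(nl + nd)$: the
lncRNA's SL row, the disease's A column, the lncRNA's A row, the
disease's SD row, in that order. All unknown pairs are clustered with
Lloyd's algorithm ($k = 10$): assign to the nearest centroid, recompute
means, repeat until assignments stabilize. Initial centers are random
draws from the points — the first uniform, the rest weighted by squared
distance to the centers already chosen — because uniform draws sometimes
strand the best-of-restarts objective in a local optimum even on small
instances; ten seed-derived restarts keep the best objective. An empty
cluster is reseeded from the point farthest from its centroid.

The negative sample (one per positive) is then drawn cluster by cluster
with quotas proportional to cluster size (largest-remainder rounding;
`allocation = "equal"` gives flat quotas), uniformly without replacement
within a cluster. Proportional quotas preserve the cluster mass of the
unknown-pair population, which is the point of clustering: negatives that
represent the diversity of unknown pairs rather than one region of it.
Whether sampling should prefer pairs near or far from the centroids is
not determined by the method's description; uniform-within-cluster is
the neutral choice and is not a claim about any original implementation.

## The GBDT-to-LR cascade

Pairs are represented by the Hadamard (elementwise) product of the two
node embeddings (length $d$; `combine = "concat"` concatenates them
instead). The product was chosen over concatenation after measurement:
whether a specific lncRNA-disease pair is plausible lives in the
*interaction* of the two vectors — a weighted dot product is linear in
the Hadamard features, but no linear function of a concatenation can
express it, and shallow trees reconstruct it only partially (on the
planted benchmark the concatenated cascade loses about 0.07 AUC).
Training minimizes the logistic loss
$\log(1 + e^{-y\,\Theta(x)})$, $y \in \{-1,+1\}$:

1. Initialize $\Theta_0 = \tfrac12 \log(\sum y_i / \sum(1 - y_i))$ with
   $y \in \{0,1\}$. The $\tfrac12$ factor halves the conventional
   log-odds; it is kept as defined (the first boosting rounds absorb the
   difference, and on balanced training sets it is 0 anyway).
2. For each of $T = 100$ rounds: residuals
   $r_i = y_i / (1 + e^{y_i \Theta(x_i)})$; a depth-3 CART tree fit to
   the residuals by exact squared-error split search (ties broken by
   lowest feature index then lowest threshold, so structure is
   deterministic); leaf values by the one-step Newton formula
   $c = \sum r / \sum |r|(2 - |r|)$; scores updated with shrinkage
   $\alpha = 0.1$.
3. Each sample is re-encoded as the concatenated one-hot of the leaf it
   reaches in every tree (exactly $T$ ones), and a logistic head with a
   small L2 penalty ($10^{-4}$ — the codes are typically separable) is
   fit on the codes by accelerated gradient descent with a Lipschitz
   step size.

The one-step Newton leaf value deserves a caveat: it is the standard
boosting update (stable under shrinkage, and what production gradient
boosting implementations use), but it is *not* the exact in-leaf argmin
of the loss — one step from the current scores can land far from the
minimizer on small, skewed leaves (e.g. a leaf holding two positives and
one negative at score 0 has argmin $\log 2 \approx 0.693$, while the
one-step value is $0.222$). With shrinkage the ensemble compensates over
rounds; the package deliberately keeps the one-step rule.

Models serialize to JSON at 17 significant digits, which round-trips
predictions bit-exactly.

## Evaluation

Ten-fold cross-validation on the balanced labelled set, stratified by
label by default (`stratified = FALSE` gives the plain random split);
embeddings and negative selection are computed once on the full network
and only the labelled pairs are split, matching the pipeline's stage
order. This means fold metrics share the unsupervised feature stage; a
leakage-strict variant that re-embeds per fold with test positives
masked would multiply runtime by the fold count and is not implemented —
treat the CV numbers as evaluating the classifier given the features,
not the whole pipeline under masking. Metrics at threshold 0.5: accuracy,
recall, F1, Matthews correlation; undefined ratios (zero denominators)
are reported as `NaN` with a warning rather than silently dropped. ROC
and AUC use the full threshold sweep with trapezoids, which with tied
scores grouped equals the Mann-Whitney statistic (ties counted half); a
brute-force pair-counting oracle verifies this exactly in the tests. The
mean ROC across folds is assembled by vertical averaging on a common FPR
grid.

## The synthetic world

`planted_world()` states the conditions under which the method should
work: 112 lncRNAs x 150 diseases (the scale of a real curated release),
4 communities, within-community association probability 0.3, between
0.02, 20% of sampled associations held out as recoverable truth, and a
shallow ancestor forest in which a disease draws 0-3 parents (with
probabilities 0.15/0.6/0.2/0.05 — most real ontology terms have a single
parent) from earlier diseases, 80% of the time from its own community,
with depth capped at 4. The generator emulates exactly the structure the
method exploits: block structure makes profile kernels and functional
similarity informative, and the community-biased forest gives the
semantic similarity the analogous block pattern.

What it does **not** emulate: power-law degree distributions, the
nested/hierarchical ontology topology of real disease vocabularies,
annotation biases (well-studied diseases accumulate associations), or
correlated noise. A green end-to-end test therefore establishes that the
implementation recovers plantable structure at realistic scale — not
that the method attains any particular performance on real catalogues.

## Numerical choices

* Symmetry tolerance for similarity matrices: $10^{-10}$; after
  validation the matrix is symmetrized exactly and clipped to $[0,1]$.
* The `FSL = 0` fusion test is exact, never tolerance-based.
* K-means ties in assignment go to the lowest cluster index; split-search
  ties in trees to the lowest feature then lowest threshold; both make
  reruns bit-identical.
* Degenerate inputs rejected with informative errors: all-zero
  association matrix (kernel bandwidth undefined), single-class labels,
  cyclic ontology edges, unknown configuration keys.
* All randomness flows from one master seed through fixed per-stage
  derivations; library code restores the caller's RNG state.

## Limitations

* Walk transitions are uniform over the sparsified neighbourhood;
  similarity-weighted transitions are out of scope by design.
* The CV protocol shares the unsupervised stages across folds (above).
* lncRNAs/diseases absent from every association can only enter via the
  in-memory interface: a two-column edge list cannot represent isolated
  nodes.
* Very small inputs (a handful of nodes) make the default `top_k`,
  window and tree counts oversized; scale them down together with the
  data.
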