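---
title: "Seed-guided module discovery with nepca: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-guided module discovery with nepca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nepca)
```

`nepca` implements a knowledge-guided pipeline for finding
disease-associated functional modules in protein–protein interaction
(PPI) networks, anchored on a small set of curated seed genes. This
vignette is the package's own account of the method: the models and
their assumptions, the parameters that matter, what the synthetic data
emulate (and what they do not), and the numerical choices made where the
design was genuinely open.

## 1. Differential screen

The screen is a per-gene Welch two-sample t-test on log2 expression
(tumor vs normal) with Benjamini–Hochberg adjustment across all tested
genes. A gene is a DEG when its adjusted *p* is below `adj_p_max`
(default 0.001) and |log2 fold change| exceeds `min_abs_log2fc` (default
1, i.e. |FC| > 2). This is a deliberate stand-in for a moderated-t fit:
the DEG table format (`read_deg_table()`) accepts externally computed
results, so users with microarray data can swap in a moderated analysis
without touching the rest of the pipeline. Probe-to-gene collapsing,
normalization and batch correction are out of scope; real-data users
must pre-process. Genes with zero variance in both groups get *p* = 1
and a flag rather than an error, so degenerate rows cannot abort a run.

The primary network is the input PPI graph induced on the DEG genes plus
the seeds, restricted to its largest connected component. The component
restriction is required by both the random walk (irreducibility) and the
divisive clustering; seeds that fall outside the component are reported,
not silently dropped.

## 2. Node prioritization: random walk with restart

Node ranking iterates

$$p_{t+1} = (1 - r)\,W p_t + r\,p_0,$$

where $W$ is the column-normalized (weighted) adjacency matrix, $r$ the
restart probability, and $p_0$ the restart distribution. Defaults:

* `restart = 0.8` — a high restart keeps probability mass near the
  seeds, which suits prioritization of a disease neighborhood rather
  than global diffusion.
* `p0` uniform over the seed set (1/|seeds| each). The method is
  defined per seed, but ranking is performed against all seeds jointly;
  a per-seed mode with mean aggregation (`per_seed = TRUE`) is provided
  for sensitivity analysis.
* convergence when the L1 change falls below `tol = 1e-10` (iteration
  cap 10,000, error on non-convergence). The tolerance is far below any
  score gap that could affect a ranking, so rankings are stable to
  machine precision.
* `weighted = TRUE` uses interaction confidences in the normalization;
  an unweighted walk is one switch away, since confidence-weighted
  propagation is a modeling choice, not a given.

The fixed point satisfies $p = r\,(I - (1-r)W)^{-1} p_0$; the test suite
uses that direct linear solve as an independent oracle.

The core network keeps the top `top_fraction = 0.10` of *non-seed*
nodes by walk score, together with all seeds and the first neighbors of
seeds ("neighborhoods" is read as attaching to seeds, not to the top
scorers). Ties at the cutoff are broken by score descending, then node
ID ascending — deterministic by construction. Whether the top fraction
should count seed nodes is ambiguous; we exclude them so that the
fraction controls only the candidate genes added.

## 3. Edge prioritization: betweenness, Wang similarity, TFC

Edge betweenness is the fractional count of all-pairs shortest paths
through an edge (Brandes accumulation, hop-count distances by default).
Computing it on the core *before* TFC weighting avoids circularity —
TFC depends on betweenness. Using confidence weights as distances is
exposed (`use_weights`) but off by default.

Functional coherence of an interaction is the Wang-method semantic
similarity of the endpoints' annotation sets. For a focal term $A$,
S-values decay from $S_A(A) = 1$ through the ancestor closure,
multiplying by a relation-type contribution factor at each edge
(`is_a` 0.8, `part_of` 0.6 — the conventional defaults, configurable),
taking the maximum over paths. Term similarity is the shared-ancestor
sum normalized by both semantic values; gene similarity combines the
pairwise term matrix by best-match average (`bma`, default), `max`, or
`avg`. One ontology aspect is assumed per run; which aspect (or
combination) to use is the caller's choice, and genes lacking
annotations propagate `NA` so the edge scorer can apply its documented
fallback (F = 0, flagged) rather than a hidden imputation.

The Topological-Functional Connection of edge $n$ is

$$\mathrm{TFC}_n = 100\,\frac{T^*_n + F_n}{\lvert T^*_n + F_n - 2\rvert},$$

with $T^*_n$ the min–max-normalized betweenness over the scored edge
set. The map $x \mapsto x/|x-2|$ is strictly increasing on $[0, 2)$, so
edges that are simultaneously central and functionally coherent score
highest. Two degenerate cases need decisions: when all betweenness
values are equal, all $T^*_n$ are set to 0 (the topological signal is
uninformative); and the singularity at $T^* + F \to 2$ is capped by
`epsilon = 1e-6` in the denominator, which bounds TFC at $2 \times 10^8$
instead of overflowing. The summation sign in the score's definition is
interpreted as indexing the per-edge family — individual interactions
are ranked by TFC throughout — not as a single network total.

## 4. Consensus community detection

Two complementary algorithms partition the TFC-weighted core network:

* **Weighted Girvan–Newman** (top-down): repeatedly delete the edge of
  highest weighted betweenness, computed with distance = 1/weight so
  that high-TFC edges are "short" and survive longest; record the
  component partition at every split; return the partition maximizing
  weighted modularity $Q = \sum_i (e_{ii} - a_i^2)$. The dendrogram
  stopping rule is not prescribed anywhere, so maximizing Q along the
  full dendrogram is used — it is the standard choice and reduces to
  "no split" (Q = 0) on structureless graphs. Betweenness ties are
  broken by lexicographic edge key, making the algorithm fully
  deterministic. ($e_{ii}$ is implemented as the within-module weight
  fraction, the standard definition that makes Q well-defined.)
* **Seeded label propagation** (bottom-up): seeds start with unique
  labels, everyone else unlabeled; nodes update asynchronously in a
  random order each sweep, adopting the label with the largest summed
  incident TFC weight among labeled neighbors, keeping their current
  label when it is among the maxima and otherwise breaking ties
  uniformly at random; convergence or 100 sweeps. Two ordering
  subtleties matter and were settled by correctness arguments: each
  sweep visits all non-seeds before the seeds, so a seed's label can
  spread into its neighborhood before the seed itself is re-evaluated
  (otherwise a seed adjacent to an already-labeled foreign block can
  lose its label before ever propagating it, merging communities); and
  seeds do participate in updates (permanently frozen seed labels leave
  every non-dominant seed a singleton, splintering modules when a
  community contains several seeds). The entire procedure is a pure
  function of `rng_seed`.

The two partitions are merged by a hypergeometric test on every module
pair (population = all core nodes, successes = the GN module, draws =
the LPA module, upper tail at the observed overlap). Pairs with
*p* < `p_threshold = 0.01` and overlap ≥ `min_overlap = 3` emit their
intersection as a robust module ("common parts" is read as
intersections, not unions of matched modules); `min_overlap` suppresses
spurious one- and two-gene modules that can reach *p* < 0.01 in small
universes. When candidates overlap, each node goes to its smallest-*p*
module. Nodes in no robust module are reported as unassigned rather
than force-assigned.

Robust modules are then assembled into a community network: module-level
nodes, inter-module edges carrying summed boundary TFC, per-module mean
edge TFC, and bottleneck genes — nodes whose incident edges span at
least two robust modules, ranked by modules bridged and then by summed
inter-module TFC.

## 5. Module validation

The module score of a node set $M$ with seeds $C_1$ and non-seeds
$C_2$ is

$$W(M) = \frac{1}{m}\sum_{i \in C_1} f_i \;-\;
  \frac{1}{k}\sum_{(u,v) \in C_2} \Big(\frac{f_u}{d_u} -
  \frac{f_v}{d_v}\Big)^2 \mathrm{MI}(u,v),$$

with $m = |M|$, $k$ the number of interactions inside $M$, $f$ the
−log₁₀ *p* of the per-gene t-test (the logarithm base is configurable
and recorded), $d$ the degree in the primary network, and MI the mutual
information of the two genes' expression profiles. The second sum runs
over *connected* non-seed pairs (the pair sum is tied to the interaction
count $k$, so it is over edges, not all pairs); an empty pair set
contributes 0. MI uses a plug-in estimator on equal-frequency
(quantile) bins, natural log, `bins = 5` by default — a robust choice at
the ~40-sample scale of two-group expression data; rank-based binning
keeps the bins exactly equal-frequency even with ties. At large sample
sizes a finer binning is appropriate (the 5-bin discretization itself,
not the estimator, caps how much dependence can be seen; the package's
Gaussian-oracle test runs 10 bins at n = 10⁴ for that reason).

Significance is an empirical permutation test: `n_perm = 10000` node
sets of size $|M|$ drawn uniformly without replacement from the primary
network, seed status and induced interaction count recomputed per draw,
with the add-one-smoothed *p* = (#{null ≥ observed} + 1)/(n_perm + 1)
(so *p* is never 0 and its minimum is 1/(n_perm + 1)). "Matched size"
refers to the module size; a degree-stratified sampler
(`degree_matched = TRUE`) is provided because naive sampling can bias W
through the degree term. Expression binning, $f$ and degrees are
precomputed once per network, which keeps 10,000 draws in seconds.

Note an honest subtlety visible in the worked example: when the test is
run inside the pipeline, the null draws come from the DEG-restricted
primary network, where *every* gene carries differential signal, so the
seed-evidence contrast is conservative. Against the full interaction
network (as in `scripts/acceptance.R`) the same module is clearly
significant. Both references are defensible; the package reports which
network was used.

## 6. Synthetic data: what it emulates and what it does not

`synthetic_scenario()` fixes the study conditions; all three generators
are pure functions of the scenario and its seed, and every parameter is
recorded in a JSON manifest.

* **Interaction graph** (`make_ppi`): planted-partition blocks
  (default 4 modules × 20 genes, `p_in = 0.9`, `p_out = 0.05`) embedded
  in a preferential-attachment background (80 further genes, 2 edges
  each), because a pure block model lacks the heavy-tailed degree
  distribution real PPI networks show; the tests check the degree Gini
  coefficient against same-density noise. Fragments are bridged so the
  graph is connected.
* **Expression** (`make_expression`): 20 tumor + 20 normal samples;
  background genes i.i.d. normal (SD 0.5); planted-module genes share a
  latent factor giving within-module correlation ρ = 0.6 (so MI is
  informative) and a group-mean shift of |log2FC| = 2 with alternating
  sign across modules — the operating point of the default DEG screen.
  Non-disease planted modules get the shift attenuated by 0.75 (still
  beyond the fold-change threshold): real tumor cohorts concentrate the
  strongest differential signal in the top disease community, and this
  is what gives the seed term of W its contrast.
* **Seeds**: a quarter of each planted module, because curated disease
  genes are known across several functional modules, not only the one
  under study; module 1 is the tracked disease module. (Concentrating
  all seeds in one module makes seeded label propagation correctly
  label the whole core network with one label, which degenerates the
  pairwise consensus test — a structural fact, not a tuning issue.)
* **Ontology** (`make_ontology`): a balanced `is_a` tree (branching 4,
  depth 3) with one depth-1 subtree per planted module; each gene is
  annotated to two leaves, within its module's subtree with probability
  `coherence = 0.9`, otherwise anywhere.

What passing tests on these data do **not** show: robustness to
microarray noise models (probe effects, batch structure), to the
redundancy and multi-aspect structure of the real Gene Ontology, to
scale (real DEG networks are an order of magnitude larger), or to the
ID-mapping and probe-collapsing issues of real expression matrices. The
generators are a controlled testbed for the statistical machinery, not a
simulator of any particular platform.

## 7. Problem sizes and reproducibility

The packaged experiments run at deliberately modest sizes chosen for a
single-CPU workstation: 160-gene scenarios for end-to-end runs, 32-node
planted-partition graphs for the recovery studies (20 replicates),
500-replicate calibration of the permutation test at 200 draws, and
10,000 draws for single-module validation. All randomized procedures
(label propagation, permutation draws, every generator) take explicit
integer seeds, and re-running a pipeline configuration reproduces its
output tables byte for byte. Degenerate inputs have defined behavior
throughout: zero-variance genes are flagged, unannotated genes yield
F = 0 with a flag, equal betweenness collapses $T^*$ to zero, empty
consensus sets produce an empty community network, and non-convergence
of the walk is an error carrying the residual, never a silent result.

## 8. Known limitations

* The divisive clustering recomputes edge betweenness after every
  deletion (cost roughly O(E²V)); beyond a few thousand edges a faster
  community method would be needed, which is outside this package's
  scope.
* The Welch-t screen is anti-conservative relative to a moderated fit
  at very small sample sizes; swap in external DEG tables there.
* Wang similarity is computed per gene pair without cross-pair caching
  beyond the S-value cache; very dense annotation sets would benefit
  from memoizing term pairs.
* The permutation null treats genes as exchangeable (optionally within
  degree strata); it does not preserve the module's internal topology,
  so W's significance is against "random gene sets of the same size",
  not "random connected subgraphs".
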