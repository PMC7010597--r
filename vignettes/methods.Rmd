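---
title: "Methods: measuring organoid-tumor gaps and prioritizing gene cascading paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring organoid-tumor gaps and prioritizing gene cascading paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Colorectal cancer progression is classically modeled as the
adenoma-carcinoma sequence: sequential driver mutations in *APC*, *KRAS*,
*SMAD4*, *TP53* (and often *PIK3CA*) transform normal epithelium into
carcinoma.  Genetically engineered organoids carrying cumulative subsets of
these mutations (types conventionally labeled A, AS, AK, AKST, AKSTP)
approximate tumors increasingly well, yet a measurable biological gap to
real tumor tissue remains even with all five drivers.  `cascadepath`
implements an integrative strategy that (i) quantifies that gap as a set of
pathway activities that differ significantly between an organoid group and
its matched tumor group, (ii) infers *subsequent key genes* — genes whose
network proximity to the dysregulated pathways suggests their mutation
would shrink the gap — and (iii) orders drivers and key genes into *gene
cascading paths* on a functional-coherence network.

Because the original inputs (public organoid microarrays, tumor RNA-seq and
somatic mutations, curated pathway graphs, a protein interaction network,
hallmark signature collections) require downloads, the package ships a
synthetic-data generator that emulates their structure with known ground
truth; every stage is validated against it.

## Rank-based integration

Expression profiles from different platforms are made comparable through a
per-sample rank transform.  Within sample $s$, genes are sorted by
decreasing expression and the gene of rank $i$ among $N$ receives

$$W_s(g_i) = e^{-i/N},$$

so the most highly expressed gene scores just below 1 and the lowest
scores $e^{-1}$.  Only within-sample ranks matter, which removes
platform-specific scale and location effects; any strictly monotone
transform of a sample's expression leaves the scores unchanged (this is a
tested invariant).  $N$ is the size of the common gene universe after
intersecting the two platforms' gene lists, not a fixed constant.  Ties in
expression are broken by gene symbol, keeping the transform deterministic;
average ranks would break the strict monotonicity the downstream scores
assume.

## Functional activity and the dysregulation test

The activity of a function (pathway or gene set) $F$ in sample $s$ is the
normalized-centroid shift

$$\mathrm{FAS}_F(s) = \frac{1}{|F|}\sum_{g \in F} W_s(g)
 - \frac{1}{N - |F|}\sum_{g \notin F} W_s(g),$$

and the gap statistic between organoid group $S$ and tumor group $T$ is
$\mathrm{DFAS}_F = |\overline{\mathrm{FAS}}_S - \overline{\mathrm{FAS}}_T|$,
the absolute difference of group-mean activities.  Group means are
averages of per-sample FAS, which by linearity equal the FAS of the
group-mean score vector — the implementation exploits this to vectorize
the permutation loop.

**Null model.**  Significance comes from gene-label permutation: each of
`n_perm` (default 1000) iterations draws one random relabeling of the gene
universe and applies it to every sample of both groups before recomputing
DFAS.  Two properties motivated applying a *single* relabeling per
iteration rather than an independent relabeling per sample:

* it preserves each sample's score distribution *and* the correlation of
  gene scores across samples (stable per-gene baselines), so the null
  DFAS has the same variance structure as the observed statistic under no
  group difference; per-sample-independent relabeling destroys the
  cross-sample correlation and makes the test severely conservative
  whenever genes have stable baseline expression — which is the rule in
  real data;
* it is equivalent to scoring the observed gene set against random gene
  sets of equal size (a competitive null, as in gene-set-permutation
  GSEA), which gives exactly uniform p-values when the tested set is
  exchangeable with a random set.  The calibration acceptance test
  verifies this empirically.

Empirical p-values use the add-one rule $p = (1 + k)/(n_{perm} + 1)$,
where $k$ counts permuted statistics at least as large as the observed
one, so $p = 0$ is impossible (a plain frequency would produce zeros that
break the downstream Fisher combination).  Benjamini-Hochberg q-values
are thresholded at FDR 0.01 for the dysregulation call.  Functions with
fewer than three genes in the universe are skipped with a warning.  A
binary functions-by-types matrix summarizes calls across organoid types.

If the two groups have *identical* mean score profiles the statistic is
degenerate (every DFAS is zero); the pairwise signature test reports all
p-values as 1 in the analogous situation rather than scoring an arbitrary
tie-broken ranking.

## Signature dynamics

Stepwise comparisons between organoid types use the classical weighted
Kolmogorov-Smirnov running-sum enrichment score.  Genes are ranked by the
difference of group-mean rank scores (the type with more mutations minus
the other; signal-to-noise metrics are unavailable because public organoid
groups can have $n = 1$).  Walking down the ranking, in-set genes add
$|m_g|^p / \sum_{h \in F}|m_h|^p$ (weight $p = 1$ by default, $p = 0$
recovers the unweighted KS statistic) and out-of-set genes subtract
$1/(N - |F|)$; the enrichment score is the signed maximum deviation of the
running sum.  When the maximum positive and negative deviations tie in
magnitude (within $10^{-12}$) the positive one is returned — an explicit
rule, because two summation orders can otherwise disagree on the sign of a
tied extremum.  If every in-set gene has zero metric weight the hit
increments fall back to uniform steps.

The permutation null again relabels gene identities once per iteration,
which here reduces exactly to the gene-set permutation null of classical
GSEA.  Activation takes the upper tail, inactivation the lower, each with
the add-one pseudocount and per-tail Benjamini-Hochberg across signatures
at FDR 0.05; a signature is never called in both directions.  Normalized
enrichment scores are not computed: the procedure compares raw activity
differences against their own permutation null.  Per-sample activity
(single-sample enrichment, ranking each sample by its own scores) and
Pearson correlations of group-mean activity profiles support the
tumor-side comparisons; zero-variance activity vectors yield `NA`
correlations with a warning.

## Key-gene inference by network propagation

For each dysregulated pathway, the seed set is the top 10% of its genes by
degree *within the pathway graph* (at least one; ties at the cutoff break
by gene symbol), dropping seeds absent from the interaction network.
Random walk with restart propagates from the seeds:

$$P_{t+1} = (1 - r)\,W P_t + r P_0, \qquad r = 0.7,$$

with $W$ the column-normalized adjacency (degree-zero nodes receive a unit
self-loop so every column sums to 1 — column-stochasticity makes the
steady state a probability vector), $P_0$ uniform over seeds, and
convergence when the maximum absolute change drops below $10^{-8}$.
A closed-form solve $P = r\,(I - (1-r)W)^{-1}P_0$ is provided as a fast
mode and doubles as an independent oracle; iterative and direct solutions
agree to $10^{-6}$ on random graphs (tested).

Per-gene significance uses 1,000 pseudo-seed sets of the same size drawn
uniformly from the network's nodes (degree-matched sampling is available
as an option, not the default): $p_j = (1 + \#\{P^{rand}_j \ge
P^{obs}_j\})/(n_{rand}+1)$.  The pseudo-seed walks are computed as one
batched sparse fixed-point iteration over all restart vectors — an exact
vectorization of the per-set runs, not an approximation.  Across the $K$
dysregulated functions of an organoid type, Fisher's method combines the
per-function p-values, $\chi^2 = -2\sum_k \ln P_{jk} \sim \chi^2(2K)$
under the null; Benjamini-Hochberg across genes at FDR 0.05 defines
subsequent key genes.  Genes already mutated in the organoid are reported
with their statistics but flagged (`driver_mutated`) rather than called,
so known drivers can still be recognized in the output without being
re-proposed.

## Cascade paths

Functional coherence between two genes defaults to the cosine similarity
of their binary function-membership vectors over the annotation the
pipeline already loads (pathway memberships plus signature sets).  The
measure used in the original strategy is cited to external work and not
fully specified there; the cosine default is a declared substitute behind
a pluggable interface, and this is the package's largest departure from
its source material.  Pairs at or above the threshold 0.4 (inclusive)
form the functional consistency network; each gene then marks its two
highest-coherence incident edges (ties by weight, then alphabetical
neighbor) and the sparse network is the union of marked edges — a node's
final degree may exceed two through its neighbors' selections, but no node
contributes more than two selections (both asserted in tests).

Paths run on the sparsified network.  Each candidate key gene's distance
is the minimum unweighted shortest-path length from any mutant driver
gene; the endpoint is the reachable candidate maximizing that distance
(ties resolve to the smaller key-gene q-value, then alphabetically), and
the reported path is the breadth-first shortest path with alphabetical
neighbor expansion from the alphabetically first mutant achieving the
distance — fully deterministic.  Unreachable candidates are listed
separately and never chosen.  Intermediate nodes may be any network gene;
non-candidate intermediates are visible in the path output.

## Synthetic data: what it emulates and what it does not

* **Network** — preferential attachment starting from an $(m{+}1)$-clique,
  each new node attaching $m = 2$ edges proportionally to degree: a
  connected scale-free graph with $m(n - m - 1) + m(m+1)/2$ edges,
  emulating the heavy-tailed degree distribution of protein interaction
  networks.
* **Pathways** — breadth-first balls around random roots truncated to
  10-25 genes: connected induced subgraphs, as pathway-topology filters
  require.  Roots are resampled so a new pathway shares at most 10% of its
  genes with any existing one; without the cap, a "background" pathway
  heavily overlapping a planted one would be truthfully rejected and the
  specificity of the recovery experiment would be meaningless.
* **Expression** — log-normal: per-gene baseline $\mu_g \sim N(0,1)$
  shared by both groups, per-sample noise $N(0, \sigma)$, $\sigma = 1$.
  Dysregulation is planted by shifting every gene of 10% of pathways by
  $+\delta\sigma$ ($\delta = 3$) on the log scale in the tumor group only.
  Because downstream statistics are rank-based, only the monotone signal
  matters; the log-normal family is a convenience.  Defaults use 10
  samples per group and 3,000 genes — large enough for stable ranks,
  small enough that the full recovery experiment runs in about a minute.
* **Key genes** — planted structurally as non-seed network neighbors of
  the dysregulated pathways' seed hubs, because the key-gene notion is
  propagation-based; recovery therefore tests the random-walk stage
  fairly, not any biological claim.
* **Mutations** — every tumor-group sample carries a `Missense` record
  per declared driver, plus `Silent` decoys (20% of records) so the
  type filter is exercised.

The generator does **not** emulate microarray probe structure, batch
effects, clinical covariates, correlated gene modules beyond the planted
shifts, or realistic mutation spectra.  Passing tests on synthetic data
therefore demonstrate algorithmic correctness and calibration under the
stated generative assumptions, not performance on real cohorts.

## Numerical and design choices

* Empirical p-values are never zero (add-one rule); Fisher combination
  refuses $p = 0$ explicitly.
* All stochastic operations require a seed; the pipeline derives per-stage
  seeds from the master seed keyed by stage name, so adding a stage never
  perturbs earlier stages' randomness, and reruns are byte-identical.
  The run manifest records wall-clock timings and is the one output file
  excluded from the byte-identity guarantee.
* Test problem sizes (2,000-3,000 genes, 200 gene sets for calibration,
  1,000 permutations/pseudo-seed sets, 20 calibration seeds) were chosen
  once as a balance between statistical resolution and a test suite that
  completes in a few minutes on one CPU.
* Duplicate expression rows collapse by arithmetic mean of raw values
  before ranking (probe-level averaging); gene identifiers are
  case-sensitive symbols with no alias mapping.
* Mutation-type filtering matches case-insensitively and keeps unknown
  types; a gene counts as mutated in a sample if any non-excluded record
  exists.
* Disconnected pathway files are rejected at load time, mirroring the
  topology filter applied to curated pathway graphs.

## Known limitations

* The functional-coherence measure is a declared substitute (cosine over
  shared annotations), not a reconstruction of the cited semantic
  similarity.
* Group-label (phenotype) permutation is unavailable by design because
  organoid groups can have a single sample; the gene-label null tests
  set-level signal against the within-sample score distribution, a
  competitive rather than self-contained hypothesis.
* The interaction network is treated as unweighted and undirected;
  directed or confidence-weighted networks are out of scope.
* Key-gene calls at stringent FDR can be empty when each planted gene is
  proximal to only one dysregulated pathway (Fisher combination over many
  unrelated functions dilutes single-pathway proximity); the ranked table
  remains informative, and the cascade stage falls back to the best-ranked
  candidates when no call survives.
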