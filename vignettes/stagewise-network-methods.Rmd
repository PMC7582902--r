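---
title: "Methods: stagewise networks, rewiring and guided pathway walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stagewise networks, rewiring and guided pathway walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

# The problem

Progressive diseases are sampled at discrete clinical stages: controls,
mutation carriers before onset (pre-symptomatic) and manifest patients
(symptomatic). The question this package addresses is not only *which
genes* change per stage, but *how the co-expression structure around
genes changes as the disease progresses*, which pathways those changes
implicate, and which metabolites distinguish the stages. The pipeline
chains six analyses; each is exposed as ordinary R functions so every
intermediate object can be inspected.

# Models and procedures

## Moderated differential expression

Each disease stage is contrasted against controls with a per-gene
two-group linear model on log2 intensities. With group sizes $n_1, n_2$
and pooled residual variance $s^2$ on $d = n_1+n_2-2$ df, the gene
variances are modelled as draws from a scaled inverse-chi-square prior
with df $d_0$ and scale $s_0^2$. $(d_0, s_0^2)$ are estimated by matching
the first two moments of $\log s^2$ (the scaled-F model; the trigamma
moment equation is inverted by Newton iteration), giving the posterior
variance $s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and a moderated t
on $d + d_0$ df. If the moment equations have no positive solution,
$d_0 = \infty$: all genes share the common variance. `fit_de()` exposes
`df_prior` as an override — `df_prior = 0` reproduces the ordinary
t-test exactly, which the tests use as a limit check; the full fit is
cross-checked against an independent implementation of the same
empirical-Bayes model (limma) to 1e-8.

Selection keeps the top `k = 150` over- and under-expressed genes ranked
by ascending p-value, restricted to raw `p < 0.05`. Both raw and
BH-adjusted p-values are reported; the selection rule uses the raw one,
the adjusted column is informational. Ties are broken by larger |logFC|,
then gene id, so reruns are reproducible. Fewer than k eligible genes in
a direction simply selects them all.

## Co-expression networks

Each stage network is built from the stage's selected genes on the
stage's samples *pooled with controls* — the network contrasts "controls
versus stage", so edges reflect co-variation over both phenotypes.
Dependence is measured with the Kraskov k-nearest-neighbour mutual
information estimator (`k = 3`, the customary default for this
estimator family; negative estimates clamp to 0). With ~26 samples the
estimator is noisy for weak dependence but reliably ranks strong
co-expression; the tests verify the bivariate-Gaussian closed form
$-\tfrac12\ln(1-\rho^2)$ within ±0.1 at n = 2000 and decreasing error
with n. Constant genes are jittered with seeded noise of amplitude
1e-10 of the data range so distances are defined.

The CLR background correction standardises each MI value against its two
row backgrounds; we compute row means and (n−1)-denominator standard
deviations over *off-diagonal* entries (the diagonal is 0 by convention
and would otherwise dilute the background). Edges are kept when the
natural log of the CLR score is at least 1 — boundary inclusive, so a
score of exactly e survives. The filtered weight stored on edges is the
pre-log CLR score; the log is used for filtering and export only, so
downstream rewiring sees a single canonical scale. Whether the published
threshold applied to the CLR score or to raw MI is ambiguous; we filter
the CLR score (the natural output of the transform) and keep the log
base configurable.

## Topology

Degree, unnormalised shortest-path betweenness, k-core index and
closeness, all unweighted (edge presence only). Closeness is the inverse
mean shortest-path distance within a node's connected component,
$(m-1)/\sum d$, in (0, 1]; isolated nodes report 0; a harmonic variant
(`sum(1/d)/(n-1)`) is available for heavily fragmented graphs. Coreness
is integer-valued by definition, so fractional "coreness" summaries
sometimes quoted for such networks are not reproducible; we report the
standard definition.

## Rewiring (Dn)

For every node of the union of the stage networks, build one vector per
state over the node's union neighbourhood (entries = edge weights, 0
when absent), normalise each nonzero vector to unit length, and let

$$D_n(v) = \frac{1}{S}\sum_{s=1}^{S} \lVert v_s - \bar v \rVert .$$

Dn is 0 iff the weighted neighbourhood is identical in all states,
invariant to global weight rescaling, and for two states bounded by
$\sqrt2/2$, attained exactly when the two neighbourhoods are disjoint.
This bound has a practical consequence we document prominently: *any*
node whose (possibly single-edge) neighbourhoods are disjoint between
states saturates the score, so sporadic edge turnover ties with a
genuinely rewired hub. Ranks are therefore computed on Dn rounded to
1e-9 — geometrically identical configurations tie instead of being
ordered by floating-point noise — and rank 1 is shared. A raw-weight
mode (`normalize = FALSE`) and a presence/absence mode
(`weighted = FALSE`) are provided; raw mode lets large rewired
neighbourhoods accumulate larger scores but is dominated by weight
jitter on stable hubs, which is why the normalised form is the default.
The central reference network carries Dn, rank and a four-level class
(none / least / high / most, quartiles among Dn > 0).

## Enrichment, completion, clustering

Over-representation is the one-sided hypergeometric upper tail, BH
corrected across pathways. The background defaults to the genes of the
expression matrix (standard ORA practice), not the universe union.
Enriched pathways are completed into a connected pathway network by
greedy pairwise connection: repeatedly join the two closest components
along a shortest reference-graph path (ties: lexicographically smallest
endpoint pair, then path), flagging added nodes as connectors. On trees
the greedy is exact (reaches the Steiner minimum); in general it is a
heuristic, which matches the published behaviour of pathway-completion
tools and avoids NP-hard exact Steiner at no practical cost at this
scale. Communities come from Girvan–Newman edge-betweenness clustering
cut at maximum modularity, deterministic for a fixed vertex order (our
constructors sort vertices).

## Guided walks and the odds ratio

Per iteration: a restart walk (`restart_prob = 0.15`, the community
convention for random walk with restart; `gene_walk_length = 50`) runs
on the weighted gene network from a uniform start; transition
probabilities are proportional to edge weights; nodes with no positive
incident weight return the walker to its start. The pathway memberships
of all visited genes (start included) are tallied and a destination
pathway is drawn proportionally to the tally — implemented as a uniform
draw over the expanded (visit, membership) incidence, which is exactly
proportional sampling. If no visited gene maps to any pathway the
destination is uniform and the event is counted (`unmapped`). The
pathway walker then moves along a shortest pathway-graph path with
uniform tie-breaks per step, incrementing the visit count of every
pathway it *enters* (origin not re-counted; a destination equal to the
current position counts one visit and no traversal; unreachable
destinations teleport and are counted). The walker's position persists
across iterations.

The non-guided baseline replaces destination selection with a uniform
draw over pathways, same iteration count and seed protocol, so total
visits are comparable. The odds ratio
$OR_i = \frac{P_i^G/(1-P_i^G)}{P_i^U/(1-P_i^U)}$ with $P_i = F_i/F_t$
corrects the guided ranking for pathway-graph topology: big central
pathways collect visits under both protocols and cancel. OR ≥ 1 flags
relevant pathways; $P = 1$ maps to $+\infty$ by contract, a pathway
unvisited under both modes has undefined OR (`NA`). 50000 iterations
make the Monte-Carlo noise on OR a few percent for mid-sized universes
(the null suite requires every OR in [0.8, 1.25] with an uninformative
guide).

## Metabolite set logic

Stage pathway sets (the completed pathway networks) map to metabolite
unions with per-pathway provenance; the two stages' unions are split
into exclusive/common parts by exact set algebra; and a bipartite
network links each stage's pathways to metabolite *group* nodes
(exclusive per stage, common), edges weighted by shared-compound counts,
with a flag to drop the common group entirely. Metabolites are opaque
string ids (KEGG compound ids in real use); no name normalisation is
attempted.

# The synthetic-data generator

`sim_config()` defaults emulate the motivating study's shape: 2000
genes; 14 control, 5 pre-symptomatic, 12 symptomatic samples; log2
intensities with baseline N(7, 1) and noise sd 0.5; 150 planted over-
and 150 under-expressed genes per stage with a log2 shift of 2 (the
order of the top reported fold changes in such studies); two 30-gene
co-expression modules whose members share a latent N(0,1) factor
(loading 1) in all groups and are additionally over-expressed in both
stages, so they survive selection and appear in both networks; and a
pathway universe (60 pathways, sizes 10–40, spanning-tree-plus-extras
graph, so the walker can always reach every pathway) whose planted
pathways over-sample the corresponding stage's planted genes
(fraction 0.7), with metabolite sets (pool of 300, 5–20 per pathway)
drawn from one finite pool so exclusive/common partitions are
non-trivial. Each stage's planted pathways are additionally wired to
each other in the pathway graph — disease-relevant pathways cross-talk,
which is the premise of complementary-pathway completion. One measured
side effect is worth knowing: the extra edges raise the planted
pathways' degree and hence their *non-guided* visit share, which
slightly lowers their odds ratios; the walk recovery suite passes
regardless because the guided signal dominates.

The rewired hub is the first gene of module 1. Its coupling follows the
disease progression: full loading on the home module in pre-symptomatic
samples, full loading on the target module in symptomatic samples, and
mixed half-strength coupling to both in controls
(`hub_control_mixing = 0.35`, `hub_commit_gain = 1.5`). The mixed
control coupling is what makes the switch *visible* in networks that
pool controls with each stage: with a hard home/target split the shared
control samples drag home-module correlation into the symptomatic
network and blur the neighbourhood change. The hub also carries a
larger expression shift (`hub_de_gain = 1.5`, log2FC 3 at defaults),
emulating a strongly dysregulated driver and keeping its
higher-variance profile reliably inside the top-k selection.

What the generator does *not* emulate: probe-level artifacts, batch
effects, missing values, heavy-tailed noise, correlated null genes, or
real disease biology. Passing tests therefore demonstrate that the
implementation recovers structure *of the kind it assumes*, not that
the method is robust to everything real microarrays do.

# Test and benchmark conditions

Problem sizes in the test suite are chosen to exercise each property at
the smallest scale that is statistically meaningful: 300-gene
simulations with two 20-gene modules for most network properties, 5000
null genes for type-I calibration, n = 2000 samples for the MI
closed-form check, 20 seeds for recovery rates. Rewiring recovery is
benchmarked at the full study scale (2000 genes, top-150 selection) but
with balanced replication (14/12/12): with only 5 pre-symptomatic
samples the pooled-sample MI route is underpowered for network
inference, and the differential-expression recovery property likewise
specifies balanced 12/12 groups. The paper-shaped default (14/5/12)
remains the generator default for realism.

The full-scale benchmark matters for a structural reason: when the
planted gene count equals k the top-k selection is *binding*, so a gene
enters both stage networks only if it is genuinely differential in both
stages. Small fixtures where every eligible gene is selected admit
cross-stage noise genes whose single spurious edges flip between
networks; such nodes saturate the normalised Dn bound and tie with the
true hub. Binding selection removes them, and the hub then outranks the
partial rewiring of ordinary module genes even when its own
neighbourhoods overlap slightly between stages.

The MI estimator's pairwise loop is implemented in C++ (Rcpp): the
full-scale benchmark needs 300-gene networks (about 45,000 gene pairs
per stage), which the compiled kernel computes in a few seconds. The
kernel is numerically identical to a direct R transcription of the
estimator (the test suite's closed-form checks pin both).

# Numerical choices and degenerate inputs

* Zero-variance genes: variance floored at eps times the squared gene
  mean and flagged; identical groups give logFC 0, p 1.
* MI: k must be below the sample count; constant rows are jittered with
  a seeded amplitude of 1e-10 of the range.
* CLR: rows with zero spread contribute z = 0; scores are symmetric by
  construction to 1e-12.
* Edge filter: inclusive at the threshold; an empty result is a warning
  plus an empty network, not an error.
* Rewiring ranks: Dn rounded to 1e-9 before ranking (see above); ties
  share the minimum rank.
* Odds ratios: n_iterations = 0 is rejected; mismatched pathway sets
  are an error.
* Random seeds: every stochastic function takes an explicit seed and
  restores the caller's RNG state, so identical seeds give identical
  output without perturbing the session.

# Known limitations

* The Dn saturation at √2/2 means single-edge turnover ties with true
  hubs; rank-based hub detection relies on the hub reaching the exact
  bound (disjoint neighbourhoods) and on min-rank tie sharing. Raw mode
  trades this for weight-jitter sensitivity.
* The MI estimator at ~26 samples has limited power for weak
  dependence; the networks should be read as strong-co-expression
  graphs.
* Greedy pathway completion is exact only on trees.
* The guided-walk destination rule (membership-tally sampling, shortest
  paths with uniform tie-break, persistent walker) is a contract of
  this package; published guided-walk tools differ in unspecified
  details.
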