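---
title: "Methods: correlation networks, block-model communities and randomization tests for immune phenotype panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation networks, block-model communities and randomization tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

Given a subjects × immune-measures matrix (antibody titres, serum proteins,
body/spleen measures, cell-activation MFIs, flow-sorted cell percentages,
and in vitro cytokine responses, "CR"), immunet computes all pairwise
Pearson correlations, thresholds them into an unweighted network at the
largest threshold that keeps the network in a single connected component,
partitions the network into communities with a degree-corrected stochastic
block model (SBM) stabilized by consensus clustering, and then asks
targeted questions about the community structure with permutation tests:
do marked node sets (e.g. Th1- or Th2-marker cytokine responses)
concentrate in fewer communities than chance predicts; do three cytokine
communities form a hub-and-two-spokes "chain"; and how much do the
community structures of two networks (e.g. wild versus laboratory animals)
overlap node-by-node?

## Preprocessing

Measures are dropped if explicitly configured or if missing in more than a
configurable fraction of subjects (default 0.5). Subjects missing an
*entire* measure battery (default: the CR category) are removed. In the
composed `preprocess()` the missing-fraction rule runs *after* the subject
exclusion: with realistic whole-battery missingness (about half the
subjects), judging battery measures against the full cohort would push
every one of them over the 0.5 threshold and delete the battery the
analysis is about, so measure quality is assessed on the retained cohort.
Partly missing subjects are kept and their remaining missing cells are replaced by
the per-measure mean of the observed values, computed within each data set
separately — wild and laboratory matrices must never be pooled for
imputation, and `impute_mean()` is exactly mean-preserving and idempotent.
Mean imputation is deliberately minimal (missingness is assumed MCAR): it
shrinks correlations slightly towards zero but introduces no structure.

## Threshold selection

An edge joins measures $i$ and $j$ iff $r_{ij} \ge t$ (for the negative
network: $r_{ij} \le -t$). The working threshold is the *bottleneck*
value: the largest $t$ at which the network is still one connected
component, which equals the minimum edge weight on the maximum spanning
tree and is always an actual matrix entry. We use the closed rule
($\ge$, not $>$): with a strict inequality no "largest possible" threshold
exists, and the closed rule handles tied correlations deterministically.
`build_network()` accepts any threshold, so sub-bottleneck networks can be
explored; `edge_density()` is $2e/N(N-1)$.

## Community detection

### The objective

`description_length()` scores a partition $b$ of a simple undirected graph
under the flat degree-corrected microcanonical SBM with uniform priors,
exactly (no Stirling approximation):

$$\mathrm{DL}(b) = -\!\!\sum_{r<s}\ln e_{rs}! - \sum_r \ln e_{rr}!! -
\sum_i \ln k_i! + \sum_r \ln e_r! + \sum_r \ln\binom{n_r+e_r-1}{e_r} +
\ln\binom{\tfrac{B(B+1)}{2}+E-1}{E} + \ln\binom{N-1}{B-1} + \ln N! -
\sum_r \ln n_r! + \ln N$$

in nats; lower is better; the number of blocks $B$ is selected by the
objective itself. Because the formula is exact, exhaustive enumeration
over all set partitions of a small graph is a valid optimality oracle, and
the test suite uses it on a fixture set of ≤ 8-node graphs. An independent
plain-R implementation of the same formula guards the C++ backend.

### The optimizer

`fit_sbm()` greedily merges from singleton blocks down to one block
(exact $\Delta\mathrm{DL}$ per candidate merge; above 40 blocks only
connected block pairs are candidates), selects the best $B$ along the
path, and refines around it with node-level sweeps: nodes in random order,
strictly improving moves only, stop after a sweep with no improvement,
equal-objective moves keep the current assignment, and moves that would
empty a block are skipped (so $B$ changes only through the merge phase).
Ties among equally good merges are broken uniformly at random. The RNG is
internal (Mersenne Twister seeded by the `seed` argument), so results are
deterministic given the seed and the R session's random stream is
untouched.

### Consensus and the UNASSIGNED state

`consensus_partition()` runs `fit_sbm()` with seeds $s, s+1, \dots$,
builds the node × node co-classification frequency matrix, joins pairs
with frequency ≥ θ (default 0.9; 100 runs by default), and takes connected
components as consensus communities. A node with no stable partner forms
a size-1 component and is labeled UNASSIGNED — the state real immune
networks need (a node that joins a different community in every run).
One structural consequence, documented rather than hidden: a node that is
a stable *singleton block* in every run also ends up UNASSIGNED, because
the rule only links pairs. Where a complete partition is required (e.g.
scoring the consensus against the exhaustive optimum on the star graph,
whose optimum isolates the hub), UNASSIGNED nodes are completed as
singleton communities.

Community labels are canonicalized to `0..K-1` by decreasing size, ties by
smallest member position, so outputs are stable across runs.

## Randomization tests

All tests report the add-one permutation p-value
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\mathrm{null})$
(two-sided variants use distance from the null mean), with
$n_\mathrm{null} = 10{,}000$ by default and an explicit seed.

* **Concentration** (`concentration_test()`): statistic $T$ = the sum of
  the $m$ largest per-community counts of the marked nodes, i.e. how many
  marked nodes fit into $m$ communities. The null redraws the marked
  positions uniformly among assigned nodes with the partition fixed. With
  $m=2$ it operationalizes "Th2 markers sit in just two communities"; with
  $m=3$, the concentration of the 45 CR nodes in three communities. Marked
  nodes must be assigned; collapse near-duplicate nodes first with
  `collapse_node_group()` (e.g. five IL-13 responses into one node).
* **Chain** (`chain_test()`): for a community trio, statistic
  $\max_H [\min(d(H,X), d(H,Y)) - d(X,Y)]$ over hub choices $H$, with $d$
  the inter-community edge density — 1 for a perfect chain, 0 for a
  symmetric trio. The null rewires the induced subgraph with
  degree-preserving double-edge swaps (10 × edges attempts per replicate),
  holding community labels fixed.
* **Community overlap** (`community_overlap()`): common-node counts and
  Jaccard indices for all community pairs of two partitions on their
  shared nodes.
* **Common nodes** (`common_nodes_test()`): two-sided test of the overlap
  of one community from each network when nodes are independently
  re-assigned at random into the given community sizes.
* **Whole-partition similarity** (`partition_similarity_test()`): adjusted
  Rand index against a label-permutation null. The exact statistic the
  original analysis used for this comparison is not published; ARI with a
  permutation null is this package's documented stand-in. Degenerate
  convention: a single-community partition has ARI 0 against anything.

### Calibration and discreteness

Under their own nulls the tests produce approximately uniform p-values,
and the acceptance suite checks this with a Kolmogorov–Smirnov test
(200 repetitions, 200 null replicates, α = 0.01). One subtlety: add-one
p-values of an integer-valued statistic are *superuniform* in proportion
to the statistic's collision probability, so the calibration fixtures are
sized to give the null statistic many distinct values (skewed community
sizes for the concentration test, 15-node trio communities for the chain
test, a ~1000-node universe for the common-nodes test). On very small
fixtures a KS uniformity check would fail for any conservative discrete
test — that is a property of discreteness, not miscalibration.

## PCA comparison

`run_pca()` defaults to covariance (unstandardized) scaling: a raw
spleen-cell count living among percentages and concentrations then
dominates PC1 almost entirely, which is exactly the behaviour the
comparative analysis needs to exhibit (the paper-style "PC1 ≈ 99.6 %"
pattern, reproduced qualitatively on a constructed fixture in the tests).
`detect_outlier_measure()` automates the by-eye removal with a loading
dominance rule (squared PC1 loading and PC1 share both above 0.9 by
default) and `pca_with_outlier_removal()` iterates removal and re-run.
Component signs are canonicalized (largest-magnitude loading positive) so
outputs are bit-stable.

## The synthetic generator: what it emulates, and what not

`generate_dataset()` draws subjects i.i.d. from a zero-mean multivariate
normal built by a nested factor model: measure $i$ is
$\sqrt{\rho_w} F_{b(i)} + \sqrt{1-\rho_w}\,\varepsilon_i$ with unit-norm
factor loadings, so the target correlation matrix is positive semidefinite
by construction (never projected). Block factors share a global background
factor; the three CR-like blocks share a chain factor with a larger hub
loading chosen so hub–peripheral measure correlation equals
`rho_chain_strong` and peripheral–peripheral equals `rho_chain_weak`; the
two NK-like blocks load on a shared factor with opposite signs to realize
`rho_negative`. Feasibility of the requested correlations under this
construction is validated up front with an error naming the offending
field.

Defaults are the package's one-time statement of a realistic study:
460 subjects, the 120-measure six-category panel, seven planted blocks
(two negatively tied NK-like FACS blocks of 14, the remaining FACS, a
mixed antibody/serum/body/MFI block, three CR blocks of 15 in a chain),
`rho_within = 0.7`, `rho_chain_strong = 0.28`, `rho_chain_weak = 0.15`,
`rho_background = 0.05`, `rho_negative = -0.4`, 10 % cell-level MCAR
missingness and a 48 % whole-CR-battery missingness. The chain values were
chosen once so that, at the bottleneck threshold with a few hundred
subjects, the hub–peripheral inter-community densities land near 0.7–0.8
while the peripheral–peripheral density stays below ~0.1 — the qualitative
chain the analysis is designed to detect. The "lab" environment applies a
seed-determined permutation of the measure-to-block map: same mesoscale
structure, different node composition.

Not emulated: assay-specific noise (spillover, detection floors),
non-Gaussian marginals, and non-MCAR missingness. A green end-to-end test
therefore establishes that the pipeline recovers planted mesoscale
structure under Gaussian block correlations with MCAR gaps — not that it
is robust to instrument artefacts.

## Numerical and degenerate-input choices

* Thresholding: closed edge rule; the bottleneck is an exact matrix entry;
  reported thresholds may be displayed rounded but computation never
  rounds.
* Pearson matrix: symmetrized (`(r + t(r))/2`), unit diagonal enforced;
  zero-variance measures are an error naming the measure.
* `fit_sbm()` refuses edgeless networks (degenerate objective);
  `description_length()` refuses partitions with UNASSIGNED nodes.
* p-values can never be 0 (add-one rule); all tests record their seed and
  null-replicate count.
* `adjusted_rand_index()` returns 0 when the chance-correction denominator
  vanishes (e.g. either partition is a single community).

## Limitations

* The SBM optimizer is a greedy heuristic; on small fixtures it attains
  the exhaustively verified optimum, but global optimality is not
  guaranteed on large networks (consensus mitigates run-to-run
  variability).
* Thresholding discards correlation magnitudes; weighted-network
  community detection is out of scope by design.
* The consensus rule cannot express a stable singleton community except as
  UNASSIGNED (see above).
* Mean imputation attenuates correlations when missingness is heavy; the
  battery-exclusion step exists precisely to avoid imputing whole missing
  batteries.
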