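---
title: "Multiscale working-memory connectomics with wmnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale working-memory connectomics with wmnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmnet)
```

## The problem

Working memory relies on a distributed set of cortical and subcortical
regions. `wmnet` analyses the *structural* network connecting those regions:
starting from a whole-brain weighted connectome (a symmetric, nonnegative
379 × 379 matrix of tractography streamline weights in the HCP-MMP1 +
subcortex convention), it extracts the sub-network over 76 working-memory
parcels, aggregates it to 24 bilateral anatomical regions, computes four
weighted nodal graph metrics at both scales, and tests nodewise group
differences between a clinical group (`ALL`, survivors of childhood acute
lymphoblastic leukaemia) and healthy controls (`HC`), with
covariate-adjusted robust regression and false-discovery-rate control.
Finally it classifies each region × metric effect into cross-scale
scenarios: does an effect survive aggregation, exist only at the fine
scale, emerge only after aggregation, or cancel out?

The two-scale design is the point: fine parcels expose focal, subregional
alterations that pooling dilutes, while the coarse regions accumulate
sub-threshold shifts that point in a common direction and reduce the
multiple-comparison burden.

## The node hierarchy

The working-memory node set is fixed and packaged (`wm_hierarchy()`): 35
bilateral cortical areas selected for robust 2-back-minus-0-back task
activation, grouped into 9 bilateral anatomical categories (ACMPC, DLPC,
IFC, IPC, IFOC, OPFC, PCC, PMC, SPC), plus the bilateral caudate, putamen
and thalamus as their own groups — 76 fine nodes in 24 coarse regions.
The premotor group is labelled `PMC` throughout, reserving `PC` for the
participation coefficient.

Matrix node order is not standardised by any convention we could adopt, so
the package fixes one deterministically: coarse-group major (groups in atlas
table order), left hemisphere before right, parcels in table row order
within a group. All 76- and 24-node matrices the package writes are
comparable across runs by construction.

The mapping of the 76 parcels into a 379-row whole-brain matrix differs
between tractography pipelines, so it is an *input*
(`attach_wholebrain_indices()`): a lookup table `(parcel, hemisphere) →
0-based index`. The packaged default,
`wholebrain_lookup_synthetic.tsv`, is a deterministic synthetic convention
(left cortical parcels in 0–179, right in 180–359, subcortex in 360–378)
used by the simulator and the tests; analyses of real connectomes should
supply the lookup of their own pipeline.

## Multiscale construction

Three steps, composed by `build_multiscale()`:

1. **Volume normalization** (`normalize_by_volume()`). Streamline counts
   scale with region size, so edge weights are corrected by the inverse of
   the endpoint volumes. The exact form of "inverse of the volumes" is a
   genuine design choice; the default is the symmetric mean form
   $w'_{ij} = 2\,w_{ij}/(v_i + v_j)$, which reduces to the identity for
   unit volumes and is homogeneous of degree −1 in the volumes. The
   product form $w_{ij}/(v_i v_j)$ is available via `method = "product"`.
   Normalization is applied at the whole-brain scale, before extraction,
   so the fine and coarse scales are consistent by construction.
2. **Extraction** (`extract_subnetwork()`). The 76 × 76 sub-matrix at the
   hierarchy's canonical order.
3. **Coarse-graining** (`coarsen()`). For coarse regions $A \ne B$,
   $W_{AB} = \sum_{i \in A, j \in B} w_{ij}$. Edges *within* a region are
   not placed on the coarse diagonal — the nodal metrics assume loop-free
   graphs — but their summed mass is returned as the `within_mass`
   attribute, so total connectivity is conserved and checkable:
   fine off-diagonal mass = coarse off-diagonal mass + 2 × within mass
   (asserted to 1e−9 relative in the tests).

## The four nodal metrics

All metrics operate on weighted, undirected, loop-free matrices and are
invariant to a global rescaling of the weights. Each has an independent
brute-force oracle in the test suite (triangle enumeration, dense
eigendecomposition, stub-level weighted correlation, per-module
summation), compared to 1e−8 on hundreds of random graphs.

**Clustering coefficient (CC)** — segregation. The Onnela geometric-mean
form with weights rescaled by the matrix maximum
$\hat w = w / \max(W)$:
$$\mathrm{CC}_i = \frac{2}{k_i(k_i-1)} \sum_{j<h}
  (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3},$$
0 when the binary degree $k_i < 2$. The source analyses name the metric
but not the weighted variant; Onnela is the de-facto standard for weighted
undirected brain graphs and is what we implement.

**Eigenvector centrality (EC)** — hubness. The Perron eigenvector of
$W$, unit L2 norm, computed by power iteration (relative tolerance 1e−10,
cap 10 000 iterations) on the shifted matrix $W + cI$ with
$c = 0.05\max_i s_i$; the shift leaves eigenvectors untouched but makes
the Perron eigenvalue strictly dominant, so bipartite-like spectra cannot
stall the iteration. Disconnected graphs are scored on the full matrix
with a warning (one vector per subject beats per-component vectors for
downstream per-node models).

**Local assortativity (LA)** — a nodal decomposition of the global
weighted strength-assortativity $r$. Over ordered pairs with
$w_{ij} > 0$, with strengths $s$, total stub weight $S$, stub-weighted
mean $\mu$ and variance $\sigma^2$ of endpoint strengths:
$$\mathrm{LA}_i = \frac{\sum_j w_{ij}(s_i-\mu)(s_j-\mu)}{\sigma^2 S},
  \qquad \sum_i \mathrm{LA}_i = r.$$
There is no canonical weighted LA in the common toolboxes; this
edge-decomposition form is our reconstruction, chosen because it is
self-validating — the node sum must reproduce the global coefficient,
which the tests check against an independently coded weighted Pearson
correlation over stubs. LA is undefined (an error) when all strengths are
equal.

**Participation coefficient (PC)** — integration. With $s_i(m)$ the
strength of node $i$ into module $m$:
$$\mathrm{PC}_i = 1 - \sum_m \left(\frac{s_i(m)}{s_i}\right)^2,$$
0 for isolated nodes by convention. The module partition is a choice: the
default is the anatomical hierarchy itself — the 24 regions when scoring
the 76-node network, and 4 bilateral systems (frontal, parietal,
posteromedial, subcortical) when scoring the 24-region network — and any
partition can be supplied explicitly.

## Group statistics

Per node and metric, `fit_node_model()` fits
`metric ~ group + age + sex` by OLS, with the group indicator coded
`HC = 0, ALL = 1` so a positive coefficient always reads "ALL > HC".
Inference uses heteroskedasticity-consistent sandwich standard errors —
HC3 by default, the flavour with the best small-sample behaviour at
n ≈ 140 (HC0/HC1 selectable) — and a t reference with $n - 4$ degrees of
freedom, slightly conservative relative to a normal reference at this
sample size. A constant response is flagged degenerate with $p = 1$ by
convention rather than an error, so one flat node cannot abort a cohort
run.

`run_group_analysis()` applies Benjamini–Hochberg FDR correction across
nodes, by default within each (metric, scale) family — matching the
per-metric presentation such analyses use — with a pooled family
available. Calibration is tested by simulation: type-I error of the
robust test within [0.035, 0.065] at 5 000 null replicates, BH equal to
an independently coded step-up oracle, and the FDR-significant fraction
under zero injected effects at or below 0.05 over 20 synthetic cohorts.

`frequency_match()` reconstructs the cohort-assembly step: greedy
group-level frequency matching of controls to cases within ±1-year age
tolerance per sex, hardest-to-match cases first, then trimming to the
largest selection that preserves the cases' exact sex ratio. The matching
*criteria* are given by the study design; the greedy algorithm is our
reconstruction and is validated against exhaustive reasoning on toy
examples.

## Cross-scale classification

`classify_crossscale()` formalises the narrative taxonomy of multiscale
effects as boolean rules over FDR-significant calls, per coarse region ×
metric (hemispheres pooled by default, separable by flag):

| scenario | coarse significant | significant fine nodes |
|---|---|---|
| `consistent` | yes | ≥1 in the coarse direction, 0 opposite |
| `convergent` | yes | mixed directions, or none |
| `fine_only` | no | ≥1, all one direction |
| `cancelling` | no | both directions |
| `null` | no | none |

Two readings were genuinely open. First, a significant coarse region with
*no* individually significant fine nodes: we bin it `convergent`,
interpreting sub-threshold same-direction shifts that sum to
significance. Second, the boundary between `consistent` and `convergent`
when some but not all fine nodes reach significance: we require only that
no significant fine node oppose the coarse direction. The rules live in
one pure function (`classify_cell`) so alternative taxonomies are a
drop-in replacement. `render_summary()` and `autoplot()` produce the
red/blue/grey region × metric × scale summary grid.

## The synthetic cohort generator

Real data for this design are restricted (clinical cohort) or external
(control accession pool), so `generate_cohort()` supplies seeded synthetic
cohorts with the study's *structure*: 70 subjects per group, ages uniform
over 6.2–20.3 years, 40:30 male:female in both groups, one 379-region
whole-brain connectome per subject, and a shared log-normal region-volume
table (unit volumes selectable for normalization-free tests).

The edge model is a planted block structure with gamma weights:

* modules = the 24 WM regions, with the six subcortical nodes merged into
  one striato-thalamic system block, plus 16-node background modules
  tiling the 303 non-WM regions;
* within-module edges always present, mean weight ×3
  (`within_module_boost`) — anatomically adjacent parcels are essentially
  always connected by tractography;
* cross-module edges Bernoulli with `density = 0.2`, mean 1;
* subcortical–cortical edges attenuated by `subcortical_crosstalk = 0.2`,
  concentrating subcortical connectivity within its system;
* weights Gamma(shape 4), right-skewed with coefficient of variation 0.5,
  scaled by the edge's mean multiplier.

Group effects are multiplicative on the ALL group's mean weights:
`effect_subcortical_seg` scales the within-subcortical-system edges and
`effect_cortical_int` scales cross-module edges of the cortical hub
groups (DLPC, PMC). Both default to 1, i.e. the default configuration is
a *null* cohort; the recovery benchmark injects
`effect_subcortical_seg = 1.5`.

The defaults were fixed by a design-stage power analysis, not by the
study data: with uniform sparse background connectivity a ×1.5 boost on
15 edges among 6 nodes moves the clustering coefficient of those nodes by
well under a percent (triangles through the boosted block are a
negligible share of each node's neighbourhood, and the max-weight
rescaling in the Onnela form adds shared per-subject noise), which no
plausible cohort size detects. Dense within-module blocks plus attenuated
subcortical crosstalk concentrate each subcortical node's triangle mass
inside the boosted system, giving a standardized group difference around
0.6–0.9 on coarse-scale subcortical CC at effect 1.5 — detectable at
n = 70 per group, which is the regime the benchmark is meant to exercise.

What the generator emulates, and what it does not: it reproduces the
matrix sizes, symmetry/nonnegativity/zero-diagonal structure, community
alignment with the hierarchy, right-skewed weights, group sizes and
demographics, and the *segregation* side of the published group pattern
(subcortical clustering up, subcortical participation down). It is not a
tractography model: weights are independent gammas rather than spatially
correlated streamline sums, volumes are independent of connectivity, age
has no effect on the network, and — because the within-system boost
raises total subcortical strength — eigenvector centrality of subcortical
nodes *rises* under this mechanism, opposite to the clinical observation.
Passing recovery benchmarks therefore demonstrates that the pipeline
detects and classifies known injected effects correctly, not that it
reproduces any specific clinical result.

Reproducibility: covariates, volumes and each subject's matrix have
dedicated streams derived from the config seed (subject k uses
`seed + 7919k`), so enlarging the cohort leaves earlier subjects'
data bit-identical.

## Numerical choices and degenerate inputs

* Symmetry tolerance on input matrices: 1e−8 relative to the largest
  entry; smaller asymmetries are symmetrized as $(W + W^\top)/2$ (text
  exporters emit such noise), larger ones indicate a directed matrix and
  are an error. Nonzero diagonals are zeroed with a warning.
* Matrix round-trip: `write_connectome()` emits 17 significant digits, so
  write-then-read agrees within 1e−12 relative.
* All-zero matrices: CC returns zeros with a warning; EC and LA are
  errors (undefined).
* Power iteration: relative tolerance 1e−10 on the successive-vector
  change, capped at 10 000 iterations; non-convergence is an error, never
  a silent approximation.
* Degenerate LA subjects in a cohort are recorded as missing (`NA`) with
  a warning and excluded from that node×metric regression, not dropped
  from the cohort.
* FDR families: per (metric, scale); p-values are validated to [0, 1].

## Problem sizes in the packaged checks

The test-suite simulations use cohorts of 70 per group for the
calibration and recovery runs (20 replicates each), 5 000 replicates for
the type-I error of the nodewise model, 1 000 random vectors for the BH
oracle, and 500 random graphs of up to 12 nodes per metric oracle; unit
tests use smaller cohorts (3–12 per group) where only plumbing is at
stake. These sizes make the whole suite run in well under half an hour on
one core while keeping Monte-Carlo error far from the asserted margins.

## Known limitations

* The CC variant (Onnela), the LA decomposition, and the PC partition are
  documented reconstructions; analyses made with other conventions (e.g.
  Barrat clustering, modularity-derived partitions) will differ
  numerically. A modularity-based PC partition can be passed explicitly.
* The whole-brain index convention is pipeline-specific; the packaged
  lookup is synthetic and must be replaced for real data.
* The classifier consumes binary significance calls; it inherits whatever
  FDR family was chosen upstream and does not model effect sizes.
* The generator's realism limits are listed above; in particular it
  cannot be used to estimate real-data power.
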