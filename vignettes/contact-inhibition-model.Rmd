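---
title: "A two-type exclusion model of contact inhibition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-type exclusion model of contact inhibition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`exclusim` simulates two interacting cell populations — "tumor" (type 1)
and "normal" (type 2) — on the vertices of an $L \times L$ square grid.
The biological phenomenon being abstracted is *contact inhibition*: the
slowdown of proliferation as local cell density rises. The model encodes
it geometrically, in the spirit of Widom–Rowlinson hard-core lattice
models. Distance between vertices is the graph metric (the minimal number
of unit lattice edges, i.e. the L1/Manhattan distance), and a
configuration is **admissible** when

* every vertex holds at most one cell,
* every pair of cells of types $i$ and $j$ sits at graph distance at
  least $D(i,j)$, and
* all border vertices are empty (a fixed boundary condition that removes
  edge effects).

The symmetric table $D$ of **exclusion distances** is the model's core
parameter. $D(i,i)$ — the self-exclusion diameter — measures how strongly
type $i$ inhibits itself: the larger it is, the sparser the densest
single-type packing. With the default co-culture parameterization

$$D(1,1) = 1, \qquad D(1,2) = D(2,1) = 3, \qquad D(2,2) = 2,$$

tumor cells may occupy adjacent vertices (full interior packing, density
$\to 1$), while normal cells at $D = 2$ pack at best into a parity
checkerboard (density $\to 1/2$). A cell type that tolerates closer
same-type neighbours — higher *allelophilia* — has weaker contact
inhibition, and the model asks what that asymmetry alone does to a mixed
population.

## Dynamics

Time is discrete. Each step selects one vertex $x$ uniformly among all
$L^2$ vertices (border included; border selections change nothing) and
resolves it:

**Occupied vertex** (cell of type $i$, rates $\alpha_i$ division,
$\delta_i$ migration, $\rho_i$ death). With
$Q = \alpha_i + n_e^{(i)}\delta_i + \rho_i$, where $n_e^{(i)}(x)$ counts
the empty vertices on the ring at distance $D(i,i)$ that can receive the
cell admissibly, the outcome is quiescence with probability $\alpha_i/Q$,
death with $\rho_i/Q$, or migration with $n_e^{(i)}\delta_i/Q$ (the
destination uniform among the receivers).

**Empty vertex.** Let $n_i(x)$ count type-$i$ cells on the ring at
distance $D(i,i)$ (the nearest vertices from which a type-$i$ parent or
migrant may legally relate to $x$), and let $\mathbb{I}(i)$ indicate that
a type-$i$ cell placed at $x$ keeps the configuration admissible
($\mathbb{I} \equiv 0$ on the border). With

$$R = \rho_1 + \rho_2 + \sum_{i=1,2} n_i(x)\,(\alpha_i +
\delta_i)\,\mathbb{I}(i),$$

the vertex stays empty with probability $(\rho_1+\rho_2)/R$, gains a
type-$i$ cell by division with $n_i\alpha_i\mathbb{I}(i)/R$ (the parent
remains in place), or by migration with $n_i\delta_i\mathbb{I}(i)/R$ (the
source, uniform among donors, is vacated). When no type can occupy $x$
the vertex remains empty with probability one.

Defaults are $\alpha = 0.1$, $\rho = 0.01$, $\delta = 0.001$ for both
types; rates are dimensionless sampling weights, and one Markov step is
*not* a unit of physical time — a single vertex is updated per step,
whereas real co-cultures update everywhere in parallel. Fits of logistic
curves to simulation trajectories therefore use step counts as the time
axis and are labelled as such.

### Interpretation choices

Several points are deliberate design decisions of this package:

* **Exact-ring neighbourhoods.** Donor counts $n_i$ use the ring at
  distance exactly $D(i,i)$, symmetric with the receiver definition
  ("empty vertices at distance $D(i,i)$"). An annulus reading (all
  distances in $[D(i,i), D(i,i)+k]$) is conceivable but breaks that
  symmetry and makes the closest admissible parent–daughter separation
  non-minimal.
* **Quiescence is a null event** with weight $\alpha_i$ at occupied
  vertices; division adds cells only through the empty-vertex rule. This
  is the only reading consistent with both per-vertex rules
  simultaneously.
* **Migration placement checks ignore the migrating cell.** Because a
  donor sits at distance exactly $D(i,i)$ from the target, it never
  blocks a same-type placement there, and removing a cell can never break
  admissibility (removal monotonicity — tested); vacating the source
  before re-checking is therefore sound.
* **Stay-empty weight.** The empty-vertex rule uses $\rho_1 + \rho_2$ as
  the inertia weight; this choice avoids extra parameters and is kept
  verbatim.
* **Densities** are reported over all $L^2$ vertices by default; a
  `density_interior` flag switches the denominator to the $(L-2)^2$
  interior (used when comparing against packing capacities, which are
  interior properties).
* **Reproducibility contract.** One RNG stream per run, seeded from the
  parameters; sweep repetitions derive per-repetition seeds from the base
  seed and the (ratio, repetition) indices, so results are independent of
  scheduling. Same seed + same package version gives identical output;
  bit-level agreement across implementations is not claimed.
* **No steady-state auto-detection**: horizons are explicit step counts.

## Initial configurations and synthetic data

`random_admissible_init()` places exact per-type counts
(`round(density * L^2)`, half-up) at uniformly random interior vertices
by sequential insertion with admissibility rejection, placing the
larger-exclusion species first (configurable). Targets above 90% of the
analytic single-type capacity are refused rather than attempted: random
sequential insertion jams well below ordered-packing density. The spatial
law of the initial state is assumed uniform.

`synthetic_point_pattern()` emulates a post-confluence co-culture
micrograph field: dense circular tumor-centroid clusters (default two
clusters of radius 35 µm packed near the jamming density of their 6 µm
hard-core spacing, in a 400 µm field — roughly one 20× objective field)
surrounded by a normal-cell background with a 15 µm hard-core spacing and
an empty 12 µm buffer around clusters. Because the distance signature is
read from the *all-pairs* histogram, the construction must keep the
between-cluster pair mass from competing with the within-cluster peak;
one or two near-jamming clusters per field achieve that by construction,
whereas many sparse clusters would not. These defaults reproduce the
post-confluence signature — the modal tumor–tumor centroid distance
(≈ 30 µm) falls well below the modal normal–normal distance (≈ 200 µm). What the generator does *not*
emulate: nucleus segmentation error, intensity-based misclassification of
cell types, irregular (non-disc) cluster shapes, and density gradients
within a cluster. Tests passing on these fixtures validate the analysis
pipeline's arithmetic, not its robustness to imaging artefacts.

`synthetic_growth_curve()` evaluates the three-parameter logistic
$N(t) = K/(1+e^{-r(t-\tau)})$ (carrying capacity $K$, growth rate $r$,
half-capacity time $\tau$, so $N(\tau) = K/2$) with optional additive
Gaussian noise.

## Pattern quantification

* **Heatmaps** average the per-vertex type-occupancy indicator over a
  snapshot window; they are binarized at 0.5 by default (exposed flag).
* **Cluster labeling** uses 8-connectivity by default (robust to
  single-pixel necks; 4-connectivity available) and drops components
  under 2 pixels.
* **Perimeter** is the count of unit pixel edges between a cluster and
  anything else — unambiguous on a lattice, unlike contour length.
* **Convex-hull ratio** is Area/ConvexArea with the hull taken over the
  corners of pixel squares, so collinear clusters get ratio 1 rather than
  a division by zero.
* **Aspect ratio** is the major/minor axis ratio of the
  second-central-moment ellipse of pixel centres, each pixel contributing
  its 1/12 unit-square variance (the standard regionprops
  operationalization); a single pixel has ratio 1.
* **Unit conversion**: 1 heatmap pixel² ≈ 93 µm², hence
  1 px ≈ 9.64 µm (≈ 10 µm); the scale is a parameter of
  `cluster_features()`.
* **Distance distributions** histogram all unordered same-type pairwise
  centroid distances into bins *centred on multiples of the bin width*
  (default 5 µm for point patterns, 1 for lattice coordinates); the mode
  is the centre of the maximal bin, smallest on ties. The mode
  operationalizes the minimal allowed same-type distance, i.e. the degree
  of contact inhibition.
* **Distance-band profiles** quantify normal-cell density versus distance
  from the tumor compartment: 50 × 50 µm quadrats are assigned to bands
  (default 0–50, 50–100, 100–150 µm) by the distance from quadrat centre
  to the nearest tumor centroid — a deliberate operationalization, since
  "distance from the cluster interface" is otherwise underdefined — and
  per-band mean counts at band midpoints are fitted with
  $A e^{-\lambda d}$ by least squares (log-linear start, Levenberg–
  Marquardt refinement).

## Growth-curve fitting

`fit_logistic()` fits the symmetric three-parameter logistic by nonlinear
least squares (Levenberg–Marquardt), with starting values from the data
maximum, the time nearest half-maximum, and a log-linear regression of
logit-transformed values; standard errors come from the Jacobian at the
optimum. Generalized (Richards-type) forms are out of scope. Noisy
observations may dip below zero near $t = 0$ and are accepted; constant
or all-nonpositive series are rejected. The recovery experiment shipped
with the package (median $|\hat K - K|/K \le 2\%$ at 5%-of-$K$ noise over
200 replicates) uses twice-daily sampling to a clear plateau
($t = 0..10$ by $0.5$): with only nine daily points the estimator's own
sampling variance exceeds that bound, so the denser design is part of the
experiment's definition.

## Problem sizes and numerical choices in the shipped checks

The package's tests and the `scripts/acceptance.R` sweep run at
desk-scale sizes chosen once: kernel-versus-analytic sampling at $10^5$
draws per vertex on a fixed 9 × 9 configuration; admissibility
conservation over $10^6$ steps on a 50 × 50 grid with a full re-check
every $10^4$ steps; capacity runs of $5 \times 10^6$ steps on 40 × 40;
co-culture replication at $10^7$ steps on 100 × 100 over 10 seeds; and
the division-rate sweep at ratios 1–10 on a 60 × 60 grid, 10 repetitions,
$3 \times 10^7$ steps per run — a horizon at which the repetition-mean
final densities have plateaued at that grid size.

Update probabilities are computed exactly per selected vertex (no
rejection sampling, no continuous-time reformulation), and every update
distribution normalizes to 1 within $10^{-12}$ by construction.

## Known limitations

* **Finite-size bias of the competition outcome.** With an established
  macroscopic interface between the two phases (dense tumor block versus
  normal checkerboard), the chain reproduces the expected balance: tumor
  advances at division-rate ratio $\alpha_2/\alpha_1 = 1$, the front is
  near-stationary around ratio 6, and the normal type advances by ratio
  10. From the standard sparse start (tumor density 0.01), however, small
  grids carry only a handful of tumor seeds (36 cells at $L = 60$), and
  during the initial filling race these are enclosed by the
  faster-dividing normal type and extinguished before reaching viable
  cluster size. The repetition-mean equal-density crossing of the
  desk-scale sweep therefore sits near ratio 2 — well below the value the
  same dynamics produce at full scale ($L = 200$, horizons of $10^9$
  steps and beyond), where more seeds and longer horizons let surviving
  clusters take over. Scaled-down sweep summaries should be read with
  this bias in mind.
* Two cell types, square lattices, empty-border boundary conditions only;
  no normal-to-tumor transformation; no mechanical (spring-like)
  interactions — the hard-core exclusion is the infinitely-stiff limit of
  such models.
* `dense_packing()` constructions are defined for self-exclusion
  distances 1 and 2; larger distances have no canonical lattice packing
  here and are refused.
* Experimental micrograph analysis (nucleus detection, type calling) is
  out of scope: the analysis operations start from centroid point
  patterns or simulated configurations.

## A minimal session

```{r example}
library(exclusim)

params <- coculture_params(L = 100, n_steps = 1e6, seed = 1)
run <- run_simulation(params, snapshot_steps = c(0, 1e6))
tail(run$trajectory)

h <- occupancy_heatmap(run$snapshots["1e+06"], type = 1)
feats <- cluster_features(label_clusters(h))
head(feats)

pat <- synthetic_point_pattern(pattern_spec(seed = 1))
distance_distribution(pat, 1)$mode
distance_distribution(pat, 2)$mode
```
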