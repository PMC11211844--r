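---
title: "Models and methods in sdlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sdlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdlineage)
```

## The problem

Spatial lineage tracing experiments grow a cell population from a single
progenitor while (i) CRISPR editing writes heritable marks into K genomic
target sites and (ii) imaging records each cell's 2D position. At the end of
the experiment (time $\tau_{end}$) the surviving cells are sequenced and
located. Given a fixed, known tree topology relating the cells, `sdlineage`
co-estimates by maximum likelihood:

* the time-resolved branch lengths (equivalently, the division times of every
  internal node),
* the cell-motility parameters: a diffusion rate $\sigma$ and per-division
  displacement angles $\theta_u$, with the displacement magnitude $r$ a fixed
  input,
* the barcode-evolution parameters: mutation rate $\lambda$, heritable
  silencing rate $\nu$, and dropout probability $\phi$.

The tree is rooted with a *unifurcating* root: the progenitor needs time to
divide, so the root has a single child and every other internal node has
exactly two.

## The spatial model: symmetric displacement plus diffusion

Under plain phylogeographic Brownian motion each child's position is its
parent's plus isotropic Gaussian noise with per-axis variance
$\sigma^2 \delta_v$, where $\delta_v$ is the branch duration. Live-imaging
data contradict one Brownian assumption: right after a division the two
daughters sit on opposite sides of the parent. The symmetric-displacement
(SD) model makes this explicit. For a division at node $u$ with daughters
$v, w$:

$$x_v = x_u + r\cos\theta_u + \mathcal{N}(0, \sigma^2\delta_v), \qquad
  x_w = x_u - r\cos\theta_u + \mathcal{N}(0, \sigma^2\delta_w),$$

and analogously with $\sin\theta_u$ on the y axis. The first-listed child in
the Newick string is the "+" daughter; this convention is arbitrary but
stable, and swapping the children while adding $\pi$ to $\theta_u$ leaves the
likelihood unchanged (a property the test suite asserts). The root's single
child receives no displacement — the progenitor does not divide at time zero.
At $r = 0$ the model collapses to Brownian motion and the angles drop out.

The leaf positions on each axis are then multivariate normal. The mean of a
leaf accumulates the signed displacements along its root-to-leaf path; the
covariance of two leaves is $\sigma^2$ times the root-to-LCA time, and the
variance of a leaf is $\sigma^2$ times its root-to-leaf time. The x and y
axes share the covariance and are independent given the parameters.

Two evaluation routes are provided. `sd_loglik_dense()` builds the
$N \times N$ covariance and evaluates the two Gaussian densities through a
Cholesky solve (never an explicit inverse); it is the reference. `sd_loglik()`
computes the same value by Gaussian message passing on the tree — each node
sends its parent a Gaussian summary of the data below it — in time linear in
the number of nodes, without materializing the covariance. The two agree to
better than $10^{-8}$ on randomized models; the dense route is the oracle in
the tests, the pruning route is what the optimizer calls.

## The barcode model

Each target site evolves independently as a continuous-time Markov chain on
hidden states $\{0, 1, \dots, M, -1\}$: $0$ is unedited, $1..M$ are edited
outcomes, and $-1$ is a heritably silenced state. From $0$, editing occurs at
total rate $\lambda$ and lands on outcome $a$ with prior $\pi_a$ (uniform by
default); silencing occurs at rate $\nu$ from any non-silenced state; edits
are irreversible and non-modifiable; silence is absorbing. Because the
silencing clock is independent of editing, the transition probabilities have
closed forms (with $e_\lambda = e^{-\lambda t}$, $e_\nu = e^{-\nu t}$):
$P(0\to 0) = e_\lambda e_\nu$, $P(0 \to a) = \pi_a (1-e_\lambda) e_\nu$,
$P(\cdot \to -1) = 1 - e_\nu$, $P(a \to a) = e_\nu$. The tests cross-check
these against the matrix exponential of the generator.

At a leaf, an unsilenced state is read correctly with probability $1-\phi$
and as missing (`?`) with probability $\phi$; the silenced state is always
read as `?`. An observed `-1` in an input matrix is therefore unobservable
under the emission model and is treated as `?` by default (a strict mode
rejects it instead).

The root (progenitor) is unedited at every site. Site likelihoods are
computed by postorder pruning with per-node rescaling, so thousands of cells
and many sites are numerically safe; a brute-force enumeration over ancestral
states (with matrix-exponential transitions) serves as the oracle on trees
with up to seven internal nodes. A column that is impossible under the
parameters — for example all-`?` with $\phi = 0$ and $\nu = 0$ — yields
`-Inf`, not an error.

## Joint inference and the sampling-time constraint

Locations and barcodes are independent given the tree, so the joint
log-likelihood is the sum of the two components; modality `"S"` uses
sequences only, `"L"` locations only. All cells are sampled at the same
moment, so every root-to-leaf time must equal $\tau_{end}$. Rather than
optimizing constrained branch lengths, `fit_lineage()` parameterizes the
internal node times root-down:

$$t_v = t_{parent(v)} + (\tau_{end} - t_{parent(v)}) \cdot
  \mathrm{logistic}(raw_v),$$

with leaves pinned at $\tau_{end}$. Any real vector maps to a valid,
*exactly* ultrametric time assignment, and the map is a bijection (round
trips are tested to $10^{-12}$). The zero vector places each node at the
midpoint of its feasible interval. Positive parameters are optimized on the
log scale, $\phi$ on the logit scale, angles unconstrained and reported
modulo $2\pi$.

Optimization uses L-BFGS-B with box bounds on the transformed scale (the
bounds keep the search away from numerically flat plateaus at extreme values)
and analytic gradients: Gaussian belief propagation gives the spatial
gradient with respect to every branch length, angle, $\sigma$, and the root
location; the inside–outside algorithm gives the sequence gradient with
respect to $\lambda$, $\nu$, $\phi$, and every branch length; the chain rule
through the node-time recursion is accumulated in reverse. Gradients are
verified against central finite differences in the test suite. Default
settings: 10 restarts (restart seeds derived from the config seed; odd
restarts start the angles from a moment estimate — the direction between the
two daughter subtrees' centroids — even restarts from uniform random angles),
convergence at $10^{-8}$ relative function change, at most 2000 iterations.
The fit never returns a point worse than its start, is deterministic given
the seed, and records a per-restart table. At the optimum the pruning spatial
likelihood is cross-checked against the dense route and the discrepancy
stored in the result.

$r$ is never optimized: co-estimating $r$ and $\sigma$ is known to be
systematically biased ($r$ up, $\sigma$ down), so $r$ is a fixed input and
`fit_r_sweep()` refits over a user grid (e.g. $\{0, 1, 3, 5, 7, 10\}$) for
sensitivity analysis.

### Why the reported $\sigma$ carries a degrees-of-freedom correction

The model has one mean-like parameter per division (the angle $\theta_u$)
plus the root location — for $N$ cells that is about $N+1$ parameters fitted
against $2N$ observed coordinates. Exactly as in ordinary Gaussian
regression, each fitted mean parameter absorbs about one dimension of noise,
deflating the ML variance estimate by roughly $(2N - p)/2N$; this is a
Neyman–Scott situation, and the deflation does not vanish with more cells
because the number of angles grows with $N$. We verified the effect
numerically: with everything else held at its generating value, freeing only
the angles shrinks $\hat\sigma$ from an unbiased $\approx 1.5$ to
$\approx 1.0$ at $N = 30$, matching $\sqrt{(2N-p)/2N}$. `fit_lineage()`
therefore reports, alongside the raw ML value (`sigma_ml`), a REML-style
corrected estimate

$$\hat\sigma = \hat\sigma_{ML} \sqrt{\frac{2N}{2N - p}}, \qquad
  p = \#\{\text{free angles}\} + \#\{\text{free root coordinates}\},$$

which is the package's headline diffusion estimate. The correction is exact
for linear mean parameters; the co-estimated node times shape the covariance
rather than the mean and are not covered by it, so a small residual downward
bias (about $-0.14$ at the default study conditions) remains. At $r = 0$
there are no angles and the correction is negligible, so the direction of
the Brownian-misspecification experiment (overestimation of $\sigma$) is
unaffected.

## The simulator and what it emulates

`simulate_topology()` draws a pure-birth (Yule) tree: one progenitor lineage,
divisions at a constant rate until $N$ lineages exist, a final holding time,
then all node times rescaled so the leaves sit exactly at $\tau_{end}$. Real
colony trees are closer to synchronous division waves; the Yule stand-in has
the right gross features (unifurcating root, binary divisions, common
sampling time) but longer terminal-branch dispersion, so recovery results on
it should be read as method checks, not as reproductions of colony-level
numbers. `simulate_locations()` and `simulate_sequences()` draw exactly from
the two models above (angles uniform on $[0, 2\pi)$ per division unless
supplied); their first two moments are tested against the constructed MVN.
`simulate_frames()` discretizes the motion onto a regular frame grid for the
division-angle analysis, with one deliberate convention: a dividing cell's
final frame records it at the division event (in imaging, cytokinesis is what
identifies the division frame). Without that convention the parent's
pre-division drift within the division interval correlates the daughters'
displacement vectors and the Brownian null would not be uniform even in its
own model.

The default study conditions (preset `"paper-default"`) are $\sigma = 1.5$
(variants 0.5 and 3.0), $r = 6.68$, $K = 10$ sites with $M = 2$ edited states,
$\lambda = 0.006$ per frame, $\tau_{end} = 216$ frames, $N = 30$ cells. The
silencing and dropout levels are not part of the published condition set; the
preset fixes $\nu = 0$ (integrase-edited barcodes have no silencing channel)
and $\phi = 0.05$ (modest imaging dropout), chosen once. Note that at these
scales $\lambda\tau_{end} \approx 1.3$, so roughly 70% of site entries are
edited.

## Evaluation utilities

* `mape()` / `branch_mape()` — mean absolute percentage error of branch
  lengths, as a fraction; edges are matched by the leaf set below them, and
  zero-length true branches are an error (the term is undefined).
* `sigma_bias()` — mean and spread of $\hat\sigma - \sigma$ keyed by modality
  and $r$.
* `extract_triplets()` / `dpd_angle()` / `angle_uniformity()` /
  `angle_lag_profile()` — the daughter–parent–daughter division-angle
  analysis. Under pure Brownian motion the two daughters' displacement
  directions are independent and isotropic, so the angle is uniform on
  $[0°, 180°]$; symmetric displacement concentrates it near 180° at short
  lags, decaying toward uniform as diffusion accumulates. The
  distance-from-uniform statistic is the Kolmogorov–Smirnov distance (the
  published analysis is visual; any calibrated statistic serves).
* `r_sweep_report()` — per-$r$ bias and MAPE with the MAPE-minimizing $r$
  (ties resolved toward the smallest $r$).
* `recovery_study()` / `angle_study()` — the scripted simulation studies.

## Numerical choices and degenerate inputs

* Branch-length floor: inside likelihood evaluation a configurable floor
  ($10^{-6}\tau_{end}$ during fitting) keeps the spatial covariance positive
  definite when node times collide; standalone likelihood calls default to no
  floor and raise an informative error on a singular covariance.
* Ultrametric tolerance: inputs are checked at $10^{-6}$ relative; fitted
  trees satisfy the constraint exactly by construction.
* Matrix alphabets are inferred per column from the observed symbols unless
  a sites configuration is given; per-site $M(k)$ may vary.
* Missing data: `?` marginalizes through the emission row; observed `-1` is
  treated as `?` by default (see above).
* All simulators accept a seed and restore the caller's RNG state; identical
  seeds give byte-identical outputs, and the streams for topology, locations,
  and sequences are separated.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to finish quickly while still
exercising the study conditions: oracle equivalence on 200 random trees with
up to 64 leaves (spatial) and 60 trees with up to 6 leaves (sequence);
moment checks with 4000 location replicates per tree; a 30-replicate recovery
study at the default conditions with 2 optimizer restarts per fit; and
pooled division-angle analyses over 20 simulated colonies. The
`scripts/acceptance.R` script reruns the recovery and angle studies from
scratch at those sizes.

## Known limitations

* Topology is fixed; there is no tree search and no ancestral-location
  reconstruction.
* $r$ is an input; only a sweep utility is provided.
* 2D coordinates only; diffusion is isotropic and uncorrelated across axes;
  no crowding, adhesion, chemotaxis, or death/sampling processes.
* A single clock: $\lambda$ is constant over time and across sites; no
  sequencing-error model.
* The corrected $\hat\sigma$ removes the angle/root degrees-of-freedom bias
  exactly but compensates only partially for the co-estimated node times
  (see above); at the default conditions a residual bias of roughly $-0.14$
  remains, shrinking as sequence information about the times grows.
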