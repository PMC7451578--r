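---
title: "Eigenvector alignment: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvector alignment: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenalign)
```

## The model

A subject's resting-state functional network is a symmetric matrix $A$
of Fisher z-transformed ROI-to-ROI correlations.  The package treats the
thresholded matrix as a linear operator and embeds each ROI in the
Euclidean space spanned by its $k$ dominant eigenvectors (default
$k = 3$): ROI $i$'s position vector is
$p_i = (s\,v_{1,i},\, v_{2,i},\, \dots,\, v_{k,i})$, where $s$ is an
optional rescaling of the leading eigenvector.  The *eigenvector
alignment* (EA) between two ROIs is the angle between their position
vectors,

$$\theta_{ij} = \arccos\!\left(\frac{p_i \cdot p_j}{|p_i||p_j|}\right)
  \in [0, \pi],$$

so closely aligned regions — regions that sit in the same dominant flow
structure of the network — have small angles.  Unlike an edge weight,
$\theta_{ij}$ responds to *every* connectivity change in the network,
which is the point: a region can lose raw connectivity without moving
relative to its partners, and can be displaced by changes elsewhere.

Three companion statistics live in the same frame:

* **Eigenvector centrality (EC)** — the entries of the unit-norm leading
  eigenvector (non-negative on a connected non-negative matrix).
* **Communities of dynamical influence (CDI)** — a deterministic
  partition: *leaders* are nodes strictly farther from the origin than
  all of their neighbours; every other node joins the reachable leader
  with the largest position-vector dot product; communities are ranked
  by their maximum member EC.
* **Alignment consistency** $\sigma_i$ — the standard deviation over
  partners $j \ne i$ of the group-mean angles $\bar\theta_{ij}$.

## Cluster-Span Threshold

Weak correlations are mostly noise, so the matrix is thresholded before
embedding.  The Cluster-Span Threshold (CST) scans the sorted unique
positive weights as candidate cutoffs; at each cutoff the binarized
topology's *triples* (a centre node plus two neighbours) are counted as
*clustered* (the neighbours are adjacent; three such triples per
triangle) or *spanning* (they are not).  CST selects the cutoff at which
the two counts balance.  Edges with weight $\ge t$ survive with their
weights; nothing is binarized downstream.

Two decisions deserve justification:

* **The balance is assessed on the normalized gap**
  $|C - S|/(C + S)$, not on the raw integer difference.  Raw counts are
  degenerate: every almost-empty topology scores $|C-S| \le 1$ (a lone
  open triple), so a raw-count minimum is systematically attracted to
  near-edgeless graphs far from the genuine balance crossing.  The
  normalized gap is scale-free: it equals the distance of the topology's
  transitivity ratio $C/(C+S)$ from $1/2$, and near-empty graphs score
  the *maximal* gap of 1.  On every worked example with a clear balance
  the two rules agree; they diverge only where the raw rule picks a
  degenerate sparse graph.
* **Candidates with zero triples are inadmissible**, otherwise the empty
  topology "balances" $0 = 0$ vacuously.  Ties go to the smallest
  threshold — the densest admissible topology — which limits
  disconnection ahead of the eigendecomposition.

Negative Fisher-z weights enter the candidate scan as-is and can never
survive a positive threshold; they are not absolute-valued.

## Which eigenvectors are "dominant"

For a symmetric matrix the spectrum is real but signed, and "the $k$
dominant eigenvectors" admits two readings: the $k$ largest eigenvalues
*in magnitude*, or the $k$ largest *algebraically*.  The package
implements both, and the choice matters more than it may appear:

* A single strong edge $(i, j)$ of weight $w$ contributes an
  *antisymmetric* local mode ($+$ on $i$, $-$ on $j$) with eigenvalue
  near $-w$.  Under magnitude ordering this mode can enter the top
  $k$ and place the two most strongly coupled nodes on *opposite* sides
  of the origin — the tighter the coupling, the larger their angle.
* Under algebraic ordering the embedding uses the smooth, consensus-like
  modes, and a strong mutual edge pulls its endpoints *together* — the
  behaviour the four-node demonstration network
  (`toy_network()`/`toy_alignment()`) exhibits, and the behaviour a
  coupling-strength interpretation of alignment requires.

`dominant_eigenpairs()` defaults to magnitude ordering (the literal
"largest magnitude" reading, with ties broken toward the positive
eigenvalue and then the original index), while the model-level functions
`eigenalign()`, `compare_groups()` and `random_model_null()` default to
`ordering = "algebraic"`.  On dense positive connectivity matrices after
CST the two orderings usually coincide in the top three; on small or
sparse graphs they need not, and the choice is an explicit argument
everywhere.  Eigenvector signs are fixed deterministically (largest-
magnitude entry positive) purely for reproducible serialization — all
angles, leaders and memberships are invariant under sign flips, and the
test suite pins that invariance.

### Scaling the leading eigenvector

For CDI the leading eigenvector is rescaled so that its largest entry
equals the largest absolute entry across the other embedded
eigenvectors ($\times$ a `multiplier`, default 1):
`scale_embedding(space, "cdi", multiplier)`.  This keeps community
designation tied to global rather than local influence, and the
multiplier supports $\pm 10\text{–}20\%$ sensitivity sweeps.  Whether
the alignment angles themselves should be computed in the scaled or the
unit frame is genuinely open; the package defaults to the scaled (CDI)
frame for the full pipeline so that EA and CDI share one geometry, and
the four-node demonstration uses the unit frame, under which its
reference angles are reproduced.  Angles are *not* invariant under this
per-axis rescaling, and a regression test pins that sensitivity so a
scaling-mode change can never pass silently.

### Degenerate cases

* A node with no surviving connections has an exactly zero position; it
  is repaired to $(10^{-12}, 0, \dots, 0)$ and flagged isolated, so its
  angles are defined but carry no information.
* A repeated eigenvalue magnitude at the $k$/$k{+}1$ boundary makes the
  embedded frame basis-dependent; the embedding warns rather than
  pretending the coordinates are canonical.
* Disconnected topologies embed block-by-block and set a
  `disconnected` flag; CDI still guarantees at least one leader per
  component.
* On a perfectly symmetric graph every distance can tie and the strict
  leader rule finds nobody; the component's maximum-distance node
  (lowest index on ties) is promoted and the partition flagged
  degenerate, so a partition always exists.

The cosine passed to `acos` is clamped to $[-1, 1]$: dot products of
perfectly aligned vectors exceed 1 by machine rounding, and an `NaN`
angle for the most aligned pair would be the worst possible failure
mode.  Group mean angles are plain arithmetic means — angles live in
$[0, \pi]$, not on a circle.

## Group comparisons

All group contrasts use Welch's unequal-variance $t$ test with
Welch–Satterthwaite degrees of freedom, two-sided.  Welch is not a
stylistic choice: the key comparisons put a sample of ~10 subjects
against a sample of 200–1000 random-model values, where pooled-variance
assumptions are indefensible.  The implementation is a vectorized closed
form (per-pair grids over thousands of ROI pairs make per-pair calls to
a model-fitting routine the bottleneck) and is pinned against
`stats::t.test` to $10^{-10}$ in the tests.

**Random-model filter.**  Before any alignment comparison, ROI pairs are
screened against sets of connectivity matrices with iid uniform$(0,1)$
weights pushed through the *identical* pipeline (CST by default; a
`raw` switch embeds the uniform matrices unthresholded, since it is not
obvious the original analysis thresholded its null models).  A pair is
eligible when, in every one of (by default) three independent null
sets, either compared group differs from the null at $p \le 0.05$.  The
intersection across sets screens out pairs highlighted by one lucky
draw.  Each pair's null sample is the $R$ per-matrix angles; the subject
side is the per-subject angles (subject-level values, not pooled).

**No multiple-testing correction is applied** — by design, matching the
method this package implements, which relies on the random-model filter
instead.  This is a real statistical caveat: the per-pair type-I rate
among eligible pairs is not controlled family-wise, and on skewed
near-zero angle distributions with ~10 subjects the two-sided Welch
rate itself runs above nominal (the calibration tests quantify this).
Treat per-pair significance as a screening signal, not a confirmatory
p-value.

**Direction vocabulary.**  A *decrease* in angle is an *increase* in
alignment; directions are reported from group 1's perspective.  Per-ROI
counts of significant pairs (each significant pair increments both of
its ROIs) profile which regions realign most.

**ROI substitution.**  `substitute_roi()` transplants one ROI's row and
column from donor subjects into paired host subjects (pairing by
manifest order by default; a permutation argument exists because no
pairing rule is canonical).  Comparing altered hosts against the
original group isolates how much of a region's group difference is
carried by its own coupling profile as opposed to network-wide change.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of resting-state RRC
matrices, not their physiology: no BOLD time series, no hemodynamics,
no autocorrelation, no site or motion artefacts.  Each cohort is built
from

* a **frozen template** of pair-level base couplings — Gaussian draws
  (SD `base_sd = 0.10`) around `mu_in = 0.35` within two *bilateral*
  functional blocks and `mu_out = 0.25` between them — shared across
  cohorts through a separate `template_seed` (same anatomy, different
  subjects);
* **homotopic pairs** $(i, i + n/2)$ coupled at `rho = 0.8`, the
  strongest structure in the healthy matrix, optionally degraded by a
  factor $1 - \delta$ on a chosen subset (`degraded_pairs`);
* per-subject Gaussian edge noise (`noise_sd = 0.1`), added and then
  symmetrized by averaging, with weights clipped to $[-1, 1]$.

Design rationale, in order of how much it mattered:

* **Continuous weight spread.**  With near-constant block weights the
  CST candidate scan sees a bimodal weight histogram and lands in a
  noise band, shattering the graph.  With the Gaussian pair-level
  spread the thresholded subjects stay connected and the CST lands
  around 0.27–0.34, in the range reported for real 132-ROI matrices.
* **Bilateral blocks.**  If blocks are hemispheres, homotopic partners
  sit in opposing blocks and the block pull keeps them apart no matter
  how strong their direct edge — the opposite of real data, where
  left/right instances of one cortical area are among the most aligned
  pairs.  With bilateral functional systems the homotopic edge itself
  carries the tightness, so degrading it loosens the pair.
* **Moderate block contrast.**  The homotopic edge must be the pair's
  dominant alignment mechanism; with very strong blocks a degraded
  pair stays tight through block co-membership alone (at $k=3$ there is
  only one within-block contrast axis, so this failure is silent and
  block-dependent).
* **Subset degradation.**  At $n = 20$, ten homotopic edges at 0.8 are
  a large fraction of the spectral weight; removing all of them
  restructures every eigenvector and *every* pair's angle shifts —
  genuine, holistic EA detections, but useless for measuring
  false-flag rates.  The recovery experiments therefore degrade 4 of
  the 10 pairs and use the remaining 6 as intact controls.

What passing these tests shows — and does not show.  They show the
pipeline recovers a planted, local coupling degradation through the
full CST → embedding → angle → filter → Welch chain at desk scale
(20 ROIs, 10+10 subjects, 3×200-model filters), with high recall and a
decrease-direction false-flag rate near the test's intrinsic type-I
floor.  They do not show anything about hemodynamic confounds, atlas
choice, head motion, or effect sizes in real cohorts, and desk-scale
null filters (R = 200) are noisier than the full-scale 1000-model
filters, which is exactly why filter agreement is itself measured.

### Alignment consistency: two mechanisms

$\sigma_i$ (SD over partners of a ROI's mean angles, diagonal excluded)
separates ROIs with *reproducible* geometry from ROIs whose angles are
noise.  Two mechanisms move it in opposite directions and both are
real: a ROI with consistently tight and consistently loose partners has
systematically *spread* mean angles (large $\sigma$), while a ROI
whose couplings are indistinguishable from noise has its mean angles
inflated *and* scattered by sampling error at small $n$ — in the
package's simulations the noise mechanism dominates at 5 subjects, so
the structured ROI shows the *smaller* $\sigma$.  Interpret $\sigma$
only jointly with the subject count that produced it.

## Problem sizes and runtime

The test suite and the acceptance script run entirely on synthetic data
at the desk scale chosen for the package's own experiments: cohorts of
10+10 subjects with 20 ROIs, random-model filters of 3×200 matrices,
500–1000 random graphs for the combinatorial oracles, and 2000
simulations for Welch calibration.  The full-scale configuration of the
method (132 ROIs, 3×1000-model filters) runs through the same code
paths — `random_model_null(n = 132, R = 1000, n_sets = 3)` — and is the
documented default of `compare_groups()`.

## Known limitations

* Eigenvalue-ordering and scaling conventions change angles; they are
  explicit arguments, but results are only comparable within one
  convention.
* The CDI "path to the leader" condition is implemented as
  same-component reachability — the weakest faithful reading; a
  greedy, edge-wise community growth could differ in multi-leader
  components.
* The Welch tests on angle distributions are anticonservative near the
  $[0, \pi]$ boundaries at small subject counts; the random-model
  filter mitigates but does not calibrate this.
* `read_fc_matrix()` reads delimited text only; binary MAT containers
  must be exported to text first.
* No covariate adjustment (age, education, sex) — group contrasts are
  marginal.
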