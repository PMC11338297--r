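---
title: "Measuring categoricality and representational alignment in free-sort data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring categoricality and representational alignment in free-sort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortalign)
```

## The task and the two key measures

In a free-sort (spatial arrangement) task a participant drags a set of items
around a 2-D canvas until their spatial layout reflects perceived
similarity. When the items carry a latent two-way category structure (call
the categories A and B), two questions arise naturally: *how categorical is
one person's sort*, and *how aligned are two people's sorts with each
other*. `sortalign` implements both measures, the machinery around them
(cluster-number estimation, dyad bridging, condition and mediation models),
and generators for stimuli and synthetic sorters so that every stage can be
exercised end to end without human data.

**Categoricality** of one sort is

$$C \;=\; \log\frac{\bar d_{\text{between}}}{\bar d_{\text{within}}},$$

the natural log of the ratio of the mean Euclidean distance over all
cross-category item pairs to the mean over all same-category pairs. Taking a
*ratio* (rather than a difference) of distances makes $C$ invariant to
rigid motion and uniform rescaling of the whole sort, so participants who
use more or less of the canvas are comparable; the log symmetrises the two
directions around 0. We use the natural log; only the sign and ordering of
scores carry meaning, so the base is a free choice. A sort with tight
clusters that *mix* A and B items scores near zero by design — $C$ measures
category-respecting structure, not clustering per se.

**Alignment** of two sorts is the Spearman rank correlation $\rho$ between
their pairwise item-distance vectors, taken over all $\binom{n}{2}$
unordered pairs in a canonical order (items sorted by id), category-blind,
and reported on the Fisher scale $z = \operatorname{atanh}(\rho)$, which is
approximately variance-stabilising and therefore suitable for averaging and
regression. Because only distance *ranks* enter, alignment is invariant
under independent translation, rotation, reflection, and uniform scaling of
either sort — exactly the transformations of a layout that carry no
similarity information.

Alignment is a dyad-level quantity, and dyads sharing a member are not
independent. The package follows the aggregation route: each participant's
alignment outcome is the *mean z over all of their within-condition dyads*,
and inference is done on that per-participant mean with ordinary linear
models. Cross-condition dyads are never formed.

## Bridging individual and dyad measures

To relate an individual measure (categoricality, cluster count) to
alignment, the pair of individual scores must be reduced to one dyad-level
covariate. The package computes three bridges per dyad — minimum, maximum,
and absolute difference (for scores 1 and 0.4: min 0.4, max 1, absdiff 0.6)
— and averages each over a participant's dyads to give per-participant
bridged covariates. The minimum bridge is the default covariate for
mediation: empirically (and in the synthetic cohorts by construction) the
less categorical member of a dyad acts as the ceiling on how aligned the
pair can be.

## Cluster counts

Each sort's final layout is partitioned by k-medoids (the classic PAM
BUILD+SWAP algorithm, via `cluster::pam`) on raw pixel coordinates — both
axes share units, so no standardisation — for each candidate $k$ in 2..10,
and the $k$ maximising the average silhouette width is selected, ties going
to the smaller $k$. Singleton clusters take silhouette 0 (the conventional
definition). $k = 1$ is excluded: the silhouette is undefined there, and
one-cluster sorts do not occur in practice. PAM is deterministic, but as a
local search it occasionally terminates in a single-swap local optimum that
is not the global medoid configuration; the test suite verifies global
optimality against exhaustive medoid-set search on small instances and, on
the rare non-global draw, verifies that the returned configuration is a true
swap-local optimum.

## Inference and mediation

Condition contrasts are fitted per named pair with OLS on a centered 0/1
condition indicator (centering leaves the slope — the difference in
condition means — unchanged; the package's tests check the closed forms).
Cluster counts use Poisson regression with log link; the 2-cluster
indicator uses logistic regression, with complete separation flagged as a
degenerate fit rather than reported as a finite estimate.

Mediation is operationalised by covariate entry: fit
`alignment ~ condition` and `alignment ~ condition + covariate`, and
classify the outcome at $\alpha = .05$ — *complete* if the raw condition
effect was significant and the adjusted one is not; *partial* if the
adjusted effect remains significant but shrinks while the covariate itself
is significant (a covariate unrelated to the outcome cannot mediate);
*none* otherwise. "Variance accounted" for the covariate is reported as its
squared partial correlation in the adjusted model, $t^2/(t^2 + \nu)$; the
adjusted model's $R^2$ is reported alongside, since either reading of
"variance accounted" appears in the literature.

## The stimulus generator

Stimuli are two family-resemblance shape categories. Each category descends
from a 39-vertex prototype normalised to a unit bounding box; exemplars are
made by adding independent Gaussian noise (mean 0, a per-level SD in
bounding-box units) to the x and y coordinates of *every fifth vertex*
(positions 0, 5, 10, … of the ordered vertex list — the simplest consistent
reading, isolated in one place so the phase can be flipped) and
re-interpolating the closed contour. The contour is a periodic cubic
interpolating spline through the vertices — the standard closed-curve
interpolant — parameterised by vertex index and sampled at a configurable
density; it passes exactly through every vertex.

The irregular-shape design uses 18 exemplars per category split 6/6/6
across SDs 0.25/0.55/0.75 (the split across levels is a design default;
only the total of 18 is fixed by the design). The familiar-shape design
uses a circle and a square outline as prototypes, SD 0.35, 10 exemplars per
category, and no contour (the stimuli are the points themselves). The two
prototypes of the irregular design are built from fixed low-order radial
harmonics, deterministically in code rather than as data files: the
originals of such experiments are hand-drawn and not reproducible, so the
package versions its own pair and labels them as its own synthetic seeds.

The free-sort set takes, per category, 3 previously seen exemplars, 6
unseen exemplars, and the (unseen) prototype — 20 items. The pre-exposure
xAB match-to-sample list pairs, per block, each of 9 A exemplars with each
of 9 B exemplars (81 trials; 3 blocks = 243), prototypes excluded; which
pair member is queried alternates deterministically (the design does not
pin this down), the correct side is counterbalanced to within one trial per
block, and order is seed-shuffled.

## The synthetic sorter cohorts

The simulator emulates the statistical structure of the three-condition
design: cohorts of ~40 sorters per condition arranging 20 items (10 per
category) on a 1024 × 768 px canvas (a typical experiment viewport; no
canvas size is canonical, and every downstream metric is canvas-size
invariant anyway). Strategies:

* `random_uniform` — i.i.d. uniform positions (the null).
* `grid` — an evenly spaced lattice filling the canvas, assignment
  seed-shuffled; two grid sorters with the same assignment align perfectly
  with no clustering, a useful boundary case.
* `categorical` — two cluster centres `center_separation` px apart, each
  item at its category's centre plus isotropic Gaussian noise
  (`within_sd`), reflected at the canvas borders (reflection preserves
  within-cluster spread better than truncation).
* `mixed_clusters` — clusters whose membership interleaves A and B items:
  clustered structure with near-zero categoricality.

The default condition parameterisation gives `baseline` and `no_labels`
identical moderate settings (separation 250 px, within-SD 100 px) and
`with_labels` a higher separation-to-spread ratio (300 px / 90 px). These
values were chosen once so that expected categoricality lands around
0.35–0.4 for the first two conditions and 0.6–0.7 for the third —
magnitudes typical of real cohorts in such designs — and are not tuned
thereafter. Per-participant seeds are derived arithmetically from the
master seed, so cohorts are exactly reproducible.

What the generator deliberately does *not* emulate: drag trajectories and
timing, item overlap geometry, participant-specific canvas use habits,
heavy-tailed individual differences, or any perceptual structure of the
actual shapes (synthetic sorters know only the category labels). Passing
tests on synthetic cohorts therefore validate the *measurement and
inference pipeline* — not claims about human behaviour.

There is also a table-level generator, `simulate_mediated_table()`, that
produces a per-participant table in which the condition shifts
categoricality and alignment responds only to categoricality. It exists to
test mediation recovery: on it, the unadjusted condition effect should be
significant and the adjusted one not, in the vast majority of seeded
replicates (the test suite checks 100 replicates at 200 participants per
condition).

## The random-placement null study

`random_placement_study()` simulates sorters placing all items uniformly at
random, computes all within-cohort pairwise alignments, and aggregates per
sorter. Ranks are computed once per sorter and all dyad correlations
obtained as one matrix cross-product (Spearman = Pearson on ranks; with
continuous coordinates ties have probability zero), so the default study —
3000 sorters, 20 items, 4.5M dyads — runs in a few seconds. Two quantities
summarise it: the maximum over sorters of per-sorter mean alignment
("maximum alignment" is read as the maximum of the per-participant means,
matching the aggregation used everywhere else; the dyad-level maximum is
also reported), and the Pearson correlation between min-bridged
categoricality and mean alignment. Categoricality here uses a fixed nominal
10/10 A/B labelling — random placement is label-exchangeable, so the choice
is immaterial.

Two numerical properties of this null deserve note. First, per-sorter mean
alignment concentrates tightly around 0 (maximum ≈ 0.005 at 3000 sorters),
so observed cohort alignments an order of magnitude larger cannot be
placement luck. Second, the categoricality–alignment correlation in a
*single* cohort is a bounded random variable centred near zero whose
seed-to-seed spread does **not** shrink with cohort size: a sort that
accidentally clusters by the nominal labels genuinely aligns slightly
better with other such sorts, giving per-sorter mean alignment a component
proportional to (own categoricality) × (cohort mean categoricality), and
both that component and the residual noise scale as $1/\sqrt{n}$. The test
suite demonstrates the sign-straddling behaviour across seeds; single-seed
values of either sign up to roughly ±0.1 are expected and do not indicate a
relationship.

## Numerical choices and degenerate inputs

* Fisher $z$ of $\rho = \pm 1$ is infinite; $\rho$ is clipped to
  $\pm(1 - 10^{-6})$ first so identical sorts stay finite and comparable.
* Spearman uses average ranks for ties (coincident items are legal and tie
  into the ranks); Kendall could be substituted behind the same interface.
* A zero-variance distance vector (all items coincident or a degenerate
  layout) makes $\rho$ undefined and is an error, as is a categoricality
  with coincident same-category items ($\bar d_{\text{within}} = 0$).
* RT filtering keeps correct-trial RTs at or above 150 ms and at or below
  the subject mean + 2 SD, with mean and SD computed before exclusion; the
  SD rule is upper-tail only (the floor handles anticipations).
* Participant exclusion applies, where the data exist: incomplete sorts
  (`moved_all = FALSE`), match-to-sample accuracy below 80%, and fewer than
  7 of 9 catch trials correct (exactly 7/9 is kept).
* Condition contrasts are treatment-style per named pair on a centered
  indicator; with three conditions all three pairs are reported, without
  multiplicity correction (none is part of the analysis design).

## Problem sizes

The shipped tests use cohorts of 6–40 sorters per condition for pipeline
checks, 100–500 sorters for Monte-Carlo properties (uniformity,
monotonicity of categoricality in centre separation, null concentration),
the full 3000-sorter null study once, and 100 replicates of the mediation
recovery design at 200 participants per condition — sizes chosen so the
properties under test are sharply resolved while the whole suite stays
quick on a single CPU.

## Limitations

* The measures assume one global 2-D arrangement per participant; sorts
  expressed as explicit groupings (piles) would need a different distance
  model.
* PAM cluster counts depend on the silhouette criterion and the 2..10
  range; other selection criteria (gap statistic, Calinski–Harabasz) are
  out of scope.
* The aggregated per-participant analysis sidesteps dyad non-independence
  but discards dyad-level variance; multiple-membership random-effects
  models are a more conservative alternative and are not implemented here.
* Synthetic cohorts share one item set and exact canvas; the readers
  (`read_sorts()`) validate but do not harmonise heterogeneous item sets.
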