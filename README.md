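# sortalign

Analysis of **free-sort (spatial arrangement) experiments**: tasks in which a
participant drags items around a 2-D canvas so that spatial proximity encodes
perceived similarity. The package is aimed at researchers studying
*representational alignment* — how similar two people's arrangements of the
same items are, and what drives that similarity — in designs where cohorts of
sorters arrange category-structured items (e.g. two family-resemblance shape
categories) under different conditions.

## What it computes

For a sort with item positions $p_1, \dots, p_n$ and a two-way category
labelling:

* **Categoricality** of one sort:
  $C = \log\left(\bar d_{\text{between}} / \bar d_{\text{within}}\right)$,
  the log ratio of the mean Euclidean distance over cross-category item pairs
  to the mean over same-category pairs. $C > 0$ means same-category items sit
  closer together. The ratio makes $C$ invariant to how much of the canvas a
  participant used (rigid motion + uniform scaling).
* **Alignment** of two sorts: the Spearman rank correlation $\rho$ between
  their canonically ordered pairwise-distance vectors (all
  $\binom{n}{2}$ pairs, blind to category), reported as Fisher
  $z = \operatorname{atanh}(\rho)$. Per participant, alignment is aggregated
  as the mean $z$ over all within-condition dyads, which sidesteps dyad
  non-independence.
* **Cluster count** per sort: k-medoids (PAM, BUILD+SWAP) on the raw pixel
  coordinates for $k = 2..10$, choosing the $k$ with maximal average
  silhouette width.
* **Dyad bridging**: an individual score (categoricality, cluster count) is
  carried to the dyad level as the pair's minimum, maximum, or absolute
  difference, then averaged per participant over their dyads.
* **Inference**: OLS condition contrasts on mean alignment and
  categoricality, Poisson regression for cluster counts, logistic regression
  for 2-cluster sorts, and mediation of condition effects on alignment by the
  min-bridged categoricality (covariate-entry; complete vs partial vs none).

The package also generates the experimental materials: two
family-resemblance shape categories built by Gaussian perturbation of every
fifth vertex of a 39-vertex spline-interpolated prototype (exemplar SDs
0.25/0.55/0.75, or 0.35 contour-free), the 20-item free-sort set
(3 seen + 6 unseen exemplars + prototype per category), and the 243-trial
xAB match-to-sample pre-exposure list — plus a synthetic-sorter simulator and
a random-placement null study, so the whole pipeline runs with no external
data.

## Worked example

```r
library(sortalign)
coh <- simulate_cohort(n_per_condition = 40, seed = 1)  # baseline / no_labels / with_labels
fit <- freesort(coh)
summary(fit)
```

```
Free-sort analysis
  120 participants, 3 conditions, 20 items
   condition  n mean_alignment mean_categoricality mean_clusters prop_two_cluster
    baseline 40          0.289               0.552          3.40             0.60
   no_labels 40          0.242               0.506          3.20             0.65
 with_labels 40          0.408               0.687          3.75             0.65

Condition effects on mean alignment:
                    term estimate     se statistic        p
    no_labels - baseline  -0.0466 0.0172     -2.71 8.29e-03
  with_labels - baseline   0.1198 0.0185      6.46 8.26e-09
 with_labels - no_labels   0.1663 0.0180      9.22 4.05e-14
...
Alignment ~ bridged covariate correlations:
          covariate       r        p
     cat_min_bridge  0.9511 4.69e-62
     cat_max_bridge  0.9095 8.61e-47
 cat_absdiff_bridge  0.0418 6.51e-01
     ncl_min_bridge -0.2053 2.45e-02

Mediation by min-bridged categoricality:
  no_labels vs with_labels: raw b = 0.1663 (p = 4.05e-14) -> adjusted b = -0.0047 (p = 0.718): complete
```

The synthetic `with_labels` cohort places its two category clusters further
apart and more tightly than the other two conditions, so it comes out most
aligned and most categorical; alignment correlates strongly with the
*minimum* bridged categoricality (r ≈ .95 here — the less categorical member
of a dyad bounds how aligned the pair can be); and entering that covariate
wipes out the condition effect on alignment (complete mediation), which is
exactly how the cohort was generated. `plot(fit)` draws the
alignment-vs-categoricality scatter behind those correlations.

The null side of the argument:

```r
ns <- random_placement_study(n_sorters = 3000, n_items = 20, seed = 1)
ns
#> <null_study: 3000 random sorters, 20 items>
#>   max per-sorter mean alignment: 0.0052 (max dyad z 0.6775)
#>   corr(min-bridged categoricality, mean alignment): 0.0746
```

Three thousand sorters placing items at random never exceed a per-sorter
mean alignment of ~0.005 — real cohorts' alignments (0.1–0.4) cannot be
placement luck — and categoricality bears essentially no relationship to
alignment under random placement.

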