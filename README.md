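# connplast

Longitudinal structural connectome plasticity analysis in R.

`connplast` is for researchers who track a weighted structural brain
network — here, a bilateral language network of 33 cortical and 5
corpus-callosum (CC) waypoint regions per hemisphere — across repeated
diffusion-MRI sessions (e.g. before, mid-way through, and after an intensive
second-language course) and want to answer, with family-wise error control:

* Is the network lateralized, and does lateralization change?
* Does interhemispheric (cortico-callosal) connectivity change, and in
  which learning period?
* *Which connected subnetworks* change over time, and which track each
  participant's behavioural improvement?

## The statistics at its core

Every retained edge is modelled with a participant random-intercept linear
mixed model,

    y_ij ~ time_j + (1 | participant_i)      (categorical time, REML)
    y_ij ~ score_ij + (1 | participant_i)    (behavioural slope)

and edge-level inference is lifted to the subnetwork level with the
**network-based statistic (NBS)**: edges with p below a primary threshold
(default 0.01) form a graph, its connected components are the candidate
subnetworks, and a permutation null of the *maximal* component statistic —
timepoint labels shuffled within participants, or whole score trajectories
exchanged between participants — yields

    p_fwe = (1 + #{null max >= observed}) / (K + 1)

per component (default K = 5000). Because the permutation schemes leave the
per-participant cross-products of the REML system intact, one precomputed
context scores all edges and all permutations; balanced designs use a
within-subject ANOVA closed form that is exactly the paired t at two
timepoints. Hemispheric summaries (left/right intra-hemispheric strength,
cortico-callosal interhemispheric strength, and the laterality quotient
LI = (L − R)/(L + R)) feed paired t-tests and timepoint contrasts.

A synthetic cohort generator (`sim_config()`, `simulate_connectomes()`,
`simulate_scores()`) reproduces the statistical structure the analysis
assumes — subject random intercepts, left > right asymmetry, planted
period-specific subnetwork effects with individual plasticity differences,
participant dropout (59 → 51 by default), and monotonically improving
proficiency scores optionally coupled to connectivity change — so every
stage is testable without patient data.

## Worked example

```r
library(connplast)
library(dplyr)

regions <- language_parcellation()           # 76 regions, 1716 candidate edges

# a synthetic cohort with a second-period interhemispheric decrease planted
# on strong (high-baseline) cortico-callosal edges, so it survives masking
cfg0 <- sim_config(seed = 11)
strong_cc <- edge_baselines(cfg0, regions) |>
  filter(type == "cortico_cc", baseline > quantile(baseline, 0.7))
dec <- select_connected_edges(strong_cc, 10, seed = 3)
cfg <- sim_config(seed = 11, plasticity_sd = 0,
                  planted_effects = list(planted_effect(dec, "second",
                                                        "decrease", 1.2)))
data <- simulate_connectomes(cfg, regions)   # 59 participants, 51 completers
mask <- group_threshold(data, regions)       # strongest 30%: 515 edges

summary <- run_summary(data, mask, regions)
summary$lateralization
#> # A tibble: 3 × 7
#>   timepoint estimate     t    df        p     n flagged
#>       <dbl>    <dbl> <dbl> <dbl>    <dbl> <int> <lgl>
#> 1         0     147.  44.1    58 2.50e-46    59 FALSE
#> 2         3     148.  45.0    58 8.01e-47    59 FALSE
#> 3         6     147.  39.0    50 4.43e-39    51 FALSE

nbs <- nbs_test(data, mask, nbs_config(n_perm = 1000, seed = 5))
tidy(nbs)
#> # A tibble: 9 × 8
#>   component direction extent intensity statistic_value    p_fwe significant
#> 1         1 decrease       8     52.0                8 0.000999 TRUE
#> 2         2 decrease       1      3.68               1 1        FALSE
#> # ... 7 more single-edge, non-significant components

posthoc_adjacent(data, nbs) |> select(period, direction, extent)
#> # A tibble: 2 × 3
#>   period direction extent
#> 1 0-3    increase       2
#> 2 3-6    decrease       8
```

The lateralization t's are positive at every timepoint (the simulated
network is left-dominant); the omnibus NBS recovers the planted
cortico-callosal subnetwork as the single family-wise-significant
decreased component (8 edges, p_fwe ≈ 0.001), and the post-hoc contrasts
assign all 8 edges to the second learning period. `autoplot()`
on the summary or NBS objects draws the trajectories and the suprathreshold
components.

Real data enter the same way through files: `read_region_table()`,
`read_connectomes()` (long-format TSV/CSV `participant, timepoint,
region_a, region_b, weight`, directed duplicates averaged), and
`run_full_pipeline()` orchestrates everything from a YAML configuration to
a JSON report plus TSV tables.

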