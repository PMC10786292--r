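---
title: "Longitudinal connectome plasticity: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal connectome plasticity: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connplast)
```

## The problem

Intensive skill acquisition — the motivating case is adults learning a
second language over two three-month course phases — is expected to
reorganize the white-matter language network: a left-dominant
intra-hemispheric system, a right-hemisphere complement, and the corpus
callosum (CC) mediating interhemispheric interaction. `connplast` analyses
cohorts of weighted structural connectomes measured repeatedly (baseline,
mid-course, end of course) and asks where connectivity changed, in which
period, and whether the change tracks behavioural improvement.

Tractography cannot robustly estimate direct cortico-cortical connections
across the midline, so interhemispheric connectivity is represented by
cortical-to-CC edges: the CC waypoint regions act as a bottleneck proxy.
The candidate edge set therefore contains intra-hemispheric
cortical-cortical pairs and cortical-CC pairs (a cortical region may pair
with any of the CC subdivisions — thresholding prunes implausible
pairings), and excludes CC-CC pairs and direct cross-hemispheric cortical
pairs. For the packaged 33 + 5 regions per hemisphere this gives
`2 * choose(33, 2) + 66 * 10 = 1716` candidates.

## Thresholding

False-positive streamline connections are suppressed by retaining the
strongest fraction of candidate edges (default 30%). The ranking uses the
mean weight over *all* participant-timepoint matrices pooled, producing a
single group-level mask: longitudinal comparisons then always contrast the
same edge set, which a per-subject or per-timepoint mask would not
guarantee. Pairs absent from a matrix count as weight zero. Exactly
`round(fraction * n_candidates)` edges are kept; ties at the cutoff go to
the lexicographically smallest region pair so the mask is reproducible to
the byte.

## Edge-wise mixed models

Each edge (and each hemispheric summary) is modelled with a participant
random intercept:

* time model — `y ~ time + (1 | participant)`, time categorical with the
  baseline as reference, giving one contrast per later timepoint;
* score model — `y ~ score + (1 | participant)` over the two timepoints at
  which proficiency tests exist.

Estimation is REML. p-values use residual degrees of freedom
`n_obs − rank(X)` by default; Satterthwaite degrees of freedom are
available in `fit_lme()` through lmerTest for users who prefer that
convention (the two differ only slightly at these sample sizes, and the
choice is configurable precisely because conventions differ across
mixed-model software). Participants missing a timepoint contribute their
available observations; a strict-completers analysis is a `dplyr::filter`
away since the data are a long tibble.

Two engines compute the edge statistics:

* **Balanced fast path.** When every participant is observed at every
  timepoint, the REML solution has a closed form: the within-subject
  (subject + time) ANOVA. Its contrast t equals the paired t exactly at two
  timepoints and equals the lme4 t whenever the intercept-variance estimate
  is interior. At the boundary (negative moment estimate) the ANOVA form
  corresponds to the unconstrained compound-symmetry parameterisation; we
  prefer it there because it keeps the classical paired-t equivalence and
  avoids the discontinuity the non-negativity constraint introduces into
  the permutation statistic.
* **Profiled-REML engine.** For unbalanced cohorts (dropout) the REML
  criterion is profiled over the variance ratio
  `theta = sigma_b^2 / sigma_e^2` on a shared grid (`reml_theta_grid()`:
  zero plus 10^−3…10^3 in 0.05 log-steps), then polished with one parabolic
  interpolation step per edge, accepted only if it improves the criterion.
  All edges share the design matrix, so the per-grid-point GLS
  cross-products are computed once and reused across edges — and, because
  the permutation schemes below leave the per-participant ingredients
  intact, across permutations. Against lme4 on non-singular fits the
  resulting t agrees to about 10^−3, and the unit tests assert 10^−2.

Degenerate edges (zero variance) are flagged, reported with p = 1, and
excluded from component graphs rather than aborting a run; a perfect fit
with nonzero effect reports t = ±Inf, flagged.

## The network-based statistic

Edges whose (per-edge, minimal-over-contrasts) p falls below the primary
threshold (default 0.01) and whose t carries the requested sign form a
graph; its connected components are the candidate subnetworks. For the
three-timepoint omnibus model an edge enters if *either* baseline contrast
passes, and its sign is that of the larger-|t| contrast — the post-hoc
adjacent-period contrasts (default edge-level alpha 0.05) then localize
each component's effect in time.

Family-wise error is controlled by permutation (default K = 5000):

* time model — timepoint labels are permuted within each participant,
  respecting that participant's observed timepoints. Given the random
  intercept, observations are exchangeable across time under the null.
* score model — whole score trajectories are exchanged between participants
  with identical timepoint availability. This preserves each participant's
  within-person score ordering (everyone improves) while severing the
  brain-behaviour link, so the universal improvement trend itself is part
  of the null and only individual coupling counts as evidence.

Each permutation records the maximal component statistic pooled over both
signs, giving two-sided control; `p_fwe = (1 + #{null ≥ obs})/(K + 1)`, so
p-values never fall below `1/(K+1)` and a K too small to reach alpha
triggers a warning.

Two component statistics are offered. **Extent** (edge count) is the
classical choice and the default. **Intensity** (sum of suprathreshold
|t|) is continuous, which matters for calibration work: with a 0.01 primary
threshold over a few dozen edges, null maximal extents concentrate on
{0, 1, 2}, and that discreteness makes extent-based FWE conservative (we
measure ≈0.01 at nominal 0.05 on 20-region null cohorts — safely below,
never above, the nominal level). The intensity statistic attains the
nominal rate, so the acceptance suite checks FWE calibration with
intensity and checks extent against the one-sided bound
`FWE ≤ alpha + 2·MC-SE`. For the score analysis we also default our
studies to intensity, because the trend-matched null produces occasional
single strong edges that extent cannot distinguish from coherent coupling.

## What the synthetic cohorts emulate

`sim_config()` defaults encode the reference design: 59 participants at
0/3/6 months with 8 lost during the second period (51 completers,
missing-at-random), nonnegative Gaussian edge weights
(`baseline_edge_mean = 1`, `baseline_edge_sd = 0.3` — arbitrary
connectivity units), a participant random intercept (`subject_sd = 0.25`),
residual noise `noise_sd = 0.2`, and a left intra-hemispheric offset
(`asymmetry_delta = 0.15`) producing strong left lateralization. Planted
effects are connected edge sets with period-specific standardized mean
shifts (in units of `noise_sd`), scaled per participant by a plasticity
multiplier `u_p ~ N(1, plasticity_sd^2)` (default 0.5): individual
differences in how much the network reorganizes are both realistic and the
very signal the brain-behaviour analysis targets. Scores exist at 3 and 6
months; gains are Gaussian (default mean 15, SD 5 on an arbitrary
proficiency scale) floored strictly above zero so *every* participant
improves, and optionally correlated (parameter `coupling`, the target
Pearson r) with each participant's mean change on a designated edge set.
Truncated-Gaussian weights keep planted magnitudes interpretable as
standardized shifts; a log-normal option exists for heavier-tailed
weights.

What the generator does *not* emulate: tractography's weight distribution
and spatial autocorrelation, distance- or size-dependent edge reliability,
scanner or session effects, non-random dropout, and measurement error in
the behavioural scores. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its own assumptions,
not that those assumptions hold for any particular tractography pipeline.

## Simulation studies behind the acceptance suite

Problem sizes were chosen to exercise each property clearly at desk scale:

* *Oracle equivalence*: 100 random balanced two-timepoint cohorts; the
  edge statistic equals `stats::t.test(paired = TRUE)` to 10^−6.
* *Threshold exactness*: 50 random parcellations/cohorts at fractions
  0.1–1.0, including all-tied cohorts for the tie-break.
* *FWE calibration*: 200 null cohorts (20 regions, n = 20, three
  timepoints), K = 200, alpha 0.05, intensity statistic; plus the extent
  bound on 100 cohorts.
* *Power and localization*: an 8-edge connected decrease of standardized
  magnitude 1.2 planted in the second period, n = 40, K = 500, 50
  replicates, full candidate mask (planted edges drawn uniformly from the
  candidates would otherwise be censored by the 30% mask for reasons
  unrelated to the statistics under test); detection, Jaccard ≥ 0.6
  recovery and correct-period localization each in ≥ 90% of replicates.
* *Brain-behaviour recovery*: the pooled score model attenuates
  within-participant coupling — the common gain trend survives trajectory
  permutation — so detectable coupling requires participant-level effect
  heterogeneity. The power study plants an 8-edge increase (magnitude 1.2,
  `plasticity_sd = 2.5`) with gains coupled at r = 0.85 and SD 8, n = 40,
  K = 500, intensity statistic; the uncoupled null is checked against
  `alpha + 2·MC-SE`.
* *Behavioural contract*: 40 cohorts at n = 41 with coupling 0.5; all
  gains positive, mean observed r within 0.05 of the 0.5 target.
* *Determinism*: the full pipeline rerun with one seed reproduces its JSON
  report byte-for-byte (a single global seed fans out additively to the
  simulation, omnibus-NBS and score-NBS stages).

`scripts/acceptance.R` runs a complementary end-to-end demonstration at
the full 76-region design and reports its headline numbers; there, planted
effects sit on high-baseline edges (via `edge_baselines()`) so they
survive the 30% mask, as real plasticity on robust connections would.

## Numerical choices and degenerate inputs

* Symmetrization: directed duplicates average (`(a→b + b→a)/2`);
  tractography is direction-asymmetric but the network is modelled
  undirected.
* Lateralization index: the standard laterality quotient
  `(L − R)/(L + R)`, defined as 0 when both strengths are zero.
* `round()` (IEEE half-to-even, as in base R) fixes the retained edge
  count; the tie-break is lexicographic.
* Permutation reproducibility: every permutation stream is seeded from the
  configuration; identical seeds give identical null distributions.
* All-identical responses are a singular-fit error in `fit_lme()`;
  edge-wise, such edges are flagged with p = 1 instead so one dead edge
  cannot abort a 500-edge screen.

## Known limitations

* Random intercepts only: no random slopes, crossed effects, or nonlinear
  learning-curve models.
* The score model pools within- and between-participant information; with
  a universal improvement trend its slope understates pure
  within-participant coupling (see above), which is a property of the
  model, not of the implementation.
* The CC-bottleneck construction measures cortico-callosal, not true
  cortex-to-cortex interhemispheric, connectivity.
* Extent-based FWE is conservative at sparse thresholds; use intensity
  when calibration matters.
* The exact exchangeability scheme of NBS-for-LME implementations varies;
  results can differ in edge cases from other toolboxes.
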