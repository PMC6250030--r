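---
title: "Reference-free topographic analysis of ERP plasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free topographic analysis of ERP plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoplast)
```

## The problem

In lateralised sensorimotor disorders such as hemiplegic cerebral palsy,
rehabilitation (e.g. constraint-induced movement therapy) may change how the
cortex processes touch.  Scalp ERPs can track such change without requiring
active participation, but ordinary voltage-waveform statistics depend on the
recording reference.  `topoplast` implements the reference-free
("electrical neuroimaging") analysis chain for a within-subject
2 (stimulus: calibrated touch vs. sham) x 2 (stimulated side: more vs. less
affected) x 2 (session: pre vs. post intervention) design:

1. descriptive topographic map sequences;
2. response **strength** statistics (GFP) and topographic
   **configuration** statistics (randomization TANOVA), each sample-wise
   with a minimum-duration criterion;
3. moment-by-moment spatial correlation against a reference condition;
4. topographic clustering into template maps, model selection, and
   single-subject back-fitting with map-duration ANOVAs;
5. brain-behavior correlations of map durations with sensory and
   sensory-motor scores.

Strength and configuration are deliberately separated: a difference in GFP
with identical topography indicates gain modulation of a fixed source
configuration, whereas a topographic difference necessarily implies a
change in the configuration of underlying generators.

## Field metrics

For an average-referenced map $u \in \mathbb{R}^{C}$ (channel mean
subtracted), **global field power** is the spatial standard deviation with
denominator $C$:

$$\mathrm{GFP}(u) = \sqrt{\tfrac{1}{C}\sum_c (u_c - \bar u)^2},$$

invariant to any constant added to all channels, hence to the recording
reference.  **Global dissimilarity** between maps $u, v$ is the RMS of the
difference of the GFP-normalized maps,

$$\mathrm{DISS}(u,v) = \sqrt{\tfrac{1}{C}\sum_c
  \left(\tfrac{u_c}{\mathrm{GFP}(u)} - \tfrac{v_c}{\mathrm{GFP}(v)}\right)^2}
  \in [0, 2],$$

with 0 for identical and 2 for polarity-inverted topographies, and the
identity $\mathrm{DISS}^2 = 2(1-r)$ linking it to the spatial (Pearson)
correlation $r$ across channels.  Every metric subtracts the spatial mean
first, so the "RMS = SD" reading holds exactly; identities are verified in
the test suite to a relative tolerance of $10^{-9}$.  Maps with GFP below
$10^{-12}$ (spatially flat) are *degenerate*: metric operations raise an
error rather than silently returning 0, because division by the
instantaneous GFP is undefined there, and downstream fitting marks such
samples unlabeled.

## Sample-wise GFP ANOVA and the duration criterion

`gfp_anova()` computes each subject's GFP per session x side cell at every
sample and runs the 2x2 repeated-measures ANOVA.  Both factors have two
levels, so every effect has one numerator df and its F equals the squared
paired $t$ of the subject-level contrast; this closed form is exact, and no
sphericity correction is needed at 1 df.  The suite cross-checks it against
an independent explicit sums-of-squares oracle to $10^{-8}$.

Sample-wise testing inflates false positives, so a significant effect must
last: contiguous runs of sub-alpha samples shorter than
`min_duration_ms` (default 20 ms, *inclusive* -- a run of exactly 20 ms is
kept, 19 ms is not) are discarded.  Runs are reported half-open in ms; a
run touching the window edge counts if its observed length reaches the
threshold (no guidance exists for the boundary, and this is the least
surprising choice).  Raising the threshold can only remove runs
(monotonicity, tested as a property).

## Randomization TANOVA

`tanova()` tests configuration differences per sample.  Each
subject-condition map is average-referenced and divided by its
instantaneous GFP, so strength cannot drive the result.  The effect
statistic is the GFP of the relevant contrast of cell-mean maps: the
marginal difference map for a main effect and the double difference
$(x_{11}-x_{12}-x_{21}+x_{22})/4$ for the interaction.  Via
$\mathrm{DISS}^2 = 2(1-r)$ this is a generalized-dissimilarity statistic:
it is zero iff the contrasted topographies coincide.

The null distribution is built by within-subject rearrangements of the
condition labels consistent with the tested effect; subject identity is
never broken.  For a main effect, the two levels of the tested factor are
exchanged (or not) per subject with the other factor fixed.  For the
interaction we first double-center each subject's four maps (removing both
main effects); the residuals satisfy $r_{11} = -r_{12} = -r_{21} = r_{22}$,
i.e. they live in the one-dimensional interaction subspace.  Only four of
the 24 relabelings of the cells -- identity, swap rows, swap columns, swap
both -- map this subspace onto itself and commute with double-centering;
these form the exchange group we sample, and their action is a sign flip of
the subject's interaction residual.  Using the full set of 24 relabelings
instead would send the residual *outside* the interaction subspace and
zero the subject's contribution in two thirds of the draws, diluting the
null toward zero and making the test anti-conservative; the restricted
group gives an exact randomization test, which the suite verifies by
calibration (per-sample type-I error within [0.03, 0.07] at $\alpha=0.05$
over 500 simulated null datasets) and by agreement with full enumeration
of all sign patterns at small $n$.

Because both schemes reduce to per-subject sign flips of a contrast map,
the implementation draws one sign matrix (default 999 permutations, seed
mandatory) and reuses it across time samples, preserving the temporal
structure of the null.  P-values follow the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ and can never be zero.
The same 20 ms duration criterion applies.

## Topographic clustering and model selection

`segment_topographies()` is the package's fitted-model core.  The
group-average ERPs of the four cells are concatenated over the analysis
window (default 250--550 ms), each sample map normalized to unit GFP, and
an **atomize-and-agglomerate hierarchical clustering** (AAHC) run from
singletons downward: at each step the cluster contributing least explained
variance (sum over members of squared GFP-weighted correlation with the
centroid) is dissolved and its members reassigned to the remaining cluster
of highest spatial correlation; centroids are the re-normalized member
means.  AAHC makes no orthogonality assumption about the templates.
A k-means-style alternative was considered and rejected: the agglomerative
scheme is deterministic given the data, which matters for reproducible
pipelines.

**Polarity is meaningful.**  These are evoked responses, not spontaneous
microstates: a map and its inversion reflect different source
configurations, so *signed* spatial correlation is used in reassignment
and in fitting.  Consequently, flipping the sign of the input data yields
sign-flipped templates with an identical labeling (tested).

**Model selection.**  The dispersion curve is
$W(k) = \sum_t \mathrm{DISS}^2(u_t, c_{\ell(t)})$, the within-cluster
dissimilarity of members to centroids.  The Krzanowski-Lai family rescales
it as $D(k) = k^{2/m} W(k)$ with $m$ the map dimensionality (channels
minus one, as average-referenced maps lose one degree of freedom).  The
published "modified" variants of this criterion differ in detail; we use
the second difference $D(k-1) - 2D(k) + D(k+1)$, scaled by $D(1)$, forced
to 0 at the boundary candidates, with the maximum over interior $k$
selecting $k_{\text{opt}}$ and ties broken toward the smallest $k$
(parsimony).  The classic ratio form
$\mathrm{DIFF}(k)/\mathrm{DIFF}(k+1)$ divides by near-zero quantities once
the dispersion curve flattens and is numerically unstable on clean data;
the second-difference (convexity) form targets the same elbow without a
division.  When no interior candidate exceeds zero the criterion is
degenerate and the smallest candidate is returned with a warning.  The
implemented variant is pinned by tests (planted-elbow and geometric
curves, and recovery of three planted templates in at least 90% of
simulated datasets); equivalence with any particular prior software
cannot be asserted and is not claimed.

**Back-fitting.**  `predict()` (or `backfit()`) labels every single-subject
window sample with the template of highest signed correlation --
competitive across all templates, with no temporal smoothing and no
minimum segment duration, since the procedure we reproduce states none.
Flat samples stay unlabeled and are reported as their own fraction, so
fractions always sum to 1.  On an exact correlation tie the previous
sample's label is kept if it is among the tied set (a minimal temporal-
stability bias consistent with the segmentation's intent), otherwise the
lowest map index wins.  Duration fractions then enter a 3-way
within-subject ANOVA (map x session x side), per-map 2x2 ANOVAs and paired
two-sided $t$ contrasts, with partial eta squared reported.  Because
fractions are compositional (they sum to 1 in every cell), the pure
session and side margins are constant by construction; the map-involving
effects carry the signal.  ANOVAs delegate to `stats::aov()` with
within-subject error strata and are oracle-checked against explicit sums
of squares.

## Brain-behavior statistics

`paired_hand_tests()` compares hands per test with a paired one-tailed
$t$ under the directional hypothesis that the less affected hand performs
better; the direction table is: higher-is-better for localization counts,
stereognosis counts, pinch and grip force; lower-is-better for
somatosensory-registration threshold (grams) and two-point discrimination
distance (mm).  `pre_post_change_tests()` runs two-sided paired $t$ of
post vs. pre per hand.  `pooled_hand_correlation()` computes Spearman's
rho over the pooled subject x hand points (durations, or their pre-post
change, against scores or score changes), with average ranks for ties,
exact-permutation p-values up to $n = 8$ complete pairs and the $t$
approximation beyond.  Pooling the two hands assumes their values are
sufficiently independent; the between-hand correlation of the scores is
reported as a diagnostic but never used as a gate, and a
repeated-measures correlation that models the within-subject dependence
explicitly is out of scope here.

## The synthetic-data generator

`simulate_erp_dataset()` generates the full eight-cell design with known
ground truth.  Each condition owns a *timeline*: an ordered sequence of
(template, fraction) segments filling the analysis window.  All subjects
share the condition's segment order -- a deliberate design choice, since
topographic structure that is temporally aligned across subjects is
exactly what group-average clustering assumes; fully randomizing block
order per subject would turn every group-average sample into a template
mixture and make template recovery impossible for *any* group-level
method.  Between-subject variability enters through a Dirichlet jitter of
the segment durations (concentration `kappa` x fraction; `kappa = 40`
gives duration SDs of roughly 7 percentage points, a realistic
between-child spread).  Segment lengths are integerized by largest
remainder, so realized fractions are stored as ground truth alongside the
labels.

Defaults define the study conditions and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| subjects | 10 | cohort size of the emulated design |
| channels / rate | 32 / 250 Hz | desk-scale geometry; 128 / 1000 Hz available via `sim_config()` for the full-scale recording layout |
| epoch | -200..700 ms | baseline plus post-stimulus interval of the emulated recordings |
| analysis window | 250..550 ms | late somatosensory interval carrying the planted condition structure |
| envelope | 0 before onset, ramp to a 5 uV plateau over 100 ms, fall after 600 ms | all conditions share it: the design plants **no** strength differences, so GFP statistics are null by construction |
| noise SD | 2.5 uV (half the envelope peak) | "moderate" regime for all recovery tests |
| behavior links | grip -0.6, pinch -0.6, stereognosis -0.45 | monotone dependence of scores on template-1 duration |

In the `"crossover"` scenario the pre-intervention less-affected condition
and the post-intervention more-affected condition share a "functional"
timeline dominated by template 2, while the other two puff cells share a
"dysfunctional" timeline dominated by template 1, with segment orders
chosen so that the functional and dysfunctional timelines overlap in only
~10% of the window.  This plants the full plasticity signature: a
session x side topographic interaction in 250--550 ms, a reference-
condition spatial correlation that is high only for post/more-affected,
and a template-1 duration that falls after the intervention in the more
affected side and rises in the less affected side.  Sham cells always
share one timeline, so the sham pipeline is null by construction.  The
`"null"` scenario gives all puff cells one timeline for calibration work.

Behavioral scores are generated on each test's natural scale (grams,
counts, mm, psi), with locations and spreads taken from the published
normative-style summary tables of the emulated study.  For linked tests, a
Gaussian copula ties the score to the designated map's realized duration
pooled over subject x hand: the planted rho is recovered in expectation
(a bivariate-normal rank correlation of $\rho$ yields a Spearman of
$\tfrac{6}{\pi}\arcsin(\rho/2)$, i.e. -0.58 for -0.6, well inside the
recovery tolerance), and hand asymmetries in the linked scores emerge from
the duration asymmetry itself rather than being planted twice.  Count
scores are rounded and clipped to their maxima.  Usable-trial counts are
`5 + Poisson(15)` per cell, matching recorded means of about 20 with
occasional cells under the 12-trial inclusion threshold.

**What the generator does not emulate** -- and hence what passing
recovery tests do and do not show: noise is spatially and temporally
white (a configuration hook accepts custom templates and envelopes, but
residual spatial correlation, trial-averaging noise, and channel
interpolation artifacts of real ERPs are absent); template transitions
are instantaneous; the GFP envelope is identical across subjects; and
electrode geometry is a synthetic layout.  Recovery under these
conditions validates the *algorithms*; it does not certify performance on
real pediatric EEG, where lower SNR and inter-subject latency jitter will
degrade all stages.

## Numerical choices

* Degenerate-map tolerance $10^{-12}$ (absolute GFP); identity checks at
  $10^{-9}$ relative.
* Sample $i$ covers the half-open interval $[t_0 + i\,\Delta t, \cdot)$;
  onset $t = 0$ belongs to the post-stimulus period, and all windows are
  half-open, so a 300 ms window at 250 Hz holds exactly 75 samples.
* The trial-inclusion threshold is inclusive (a cell with exactly 12
  usable trials is kept) and exclusion is dataset-wide per subject.
* "Minimally 20 ms" is read as $\ge 20$ ms.
* Permutation seeds are mandatory arguments; every pipeline stage derives
  its seed deterministically from the master seed, so a rerun is
  byte-identical.

The test suite runs the calibration at 16 channels x 50 samples x 500
seeds, segmentation recovery at 32 channels over 50 seeds, back-fit
recovery over 20 seeds and correlation recovery over 50 seeds -- sizes at
which the Monte-Carlo error of each check is comfortably below its
acceptance margin.

## Known limitations

* The laterality flip map must be supplied for real montages (the
  shipped example covers only the synthetic layout), and the choice of
  common anchor hemisphere is a configuration option with no claimed
  default.
* Krzanowski-Lai variants differ across published implementations; ours
  is pinned by tests but not certified equivalent to any particular tool.
* The pooled-hand correlation inherits the within-subject dependence of
  its two points per subject; the diagnostic is reported, not acted on.
* ANOVAs on compositional duration fractions ignore the simplex
  constraint, as does the procedure we reproduce.
* No source localization: all inferences concern scalp-field
  configuration, not anatomical generators.
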