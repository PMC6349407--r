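---
title: "Quantifying saltatory tangential migration of midbrain dopaminergic neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying saltatory tangential migration of midbrain dopaminergic neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltatrack)
```

## The biological problem

During embryonic development, midbrain dopaminergic (mDA) neurons destined
for the substantia nigra (SN) migrate tangentially — laterally, away from
the ventral midline — to segregate from the medially located ventral
tegmental area (VTA). Time-lapse 2-photon imaging of organotypic slices
shows that this migration is *saltatory*: long periods of rest are
interrupted by slow movements and, rarely, by fast laterally directed
spurts. The spurts are strongly associated with a bipolar cell morphology
(at most two processes leaving the soma), and both the likelihood of
spurting and the lateral bias of slow movements depend on Reelin/DAB1
signalling.

`saltatrack` turns 3D+t soma tracks (e.g. TrackMate exports at uniform
10-minute sampling) and per-frame morphology annotations into the
quantities this kind of study reports: per-frame soma speeds, max-speed
migration classes, speed-band phase occupancy, displacement and
directionality, midline-referenced trajectory angles with circular
statistics and a two-sample Kuiper test, morphology-state dynamics, and
mediolateral distribution profiles for fixed sections. A generative model
of saltatory migration supplies ground-truthed synthetic populations for
validation.

## Units, conventions and key definitions

All positions are micrometres, times are hours (`dt = 1/6` hr for 10-min
frames), angles are degrees. The conventions below are fixed across the
package:

* **Instantaneous speed** at frame $k$ is the 3D Euclidean soma
  displacement from frame $k-1$ to $k$ divided by `dt` (backward
  difference). Speeds are 3D; trajectory angles are 2D. That asymmetry is
  deliberate: the z-axis of a slice carries no directional meaning for
  tangential migration, but vertical motion still contributes to how fast
  a soma moves.
* **Speed bands** are half-open: rest $[0, 10)$, slow $[10, 30)$,
  moderate $[30, 60)$ and fast $[60, \infty)$ μm/hr. A value exactly on a
  cutoff belongs to the upper band, so the four bands partition any speed
  series with no gaps or overlaps. The 10 and 30 μm/hr cutoffs are the
  quartiles of a reference max-speed distribution
  (`derive_band_cutoffs()`, linear-interpolated type-7 quantiles); the 60
  μm/hr moderate/fast boundary is a fixed constant — it has no quantile
  derivation, so it is exposed as a configurable number and never derived.
* **Max-speed classes.** A cell is non-migratory, slow, moderate or fast
  according to the band of its *maximum* instantaneous speed. At 10-min
  sampling the 10 μm/hr rest cutoff is equivalent to never moving more
  than 1.7 μm between consecutive frames
  (`frame_displacement_threshold(10, 10, digits = 1)`).
* **Directionality** is total 3D displacement (first to last position)
  divided by path length; 1 means perfectly straight. For a cell that
  never moved the ratio is 0/0: it is reported as `NA` (undefined), never
  as 0, because such cells are non-migratory and excluded from
  displacement analyses anyway.
* **Trajectory angle** is the signed 2D angle between the midline axis
  (image y-axis, 0°) and the net displacement vector, positive toward
  lateral: `atan2(dx_lateral, dy)` in $(-180°, 180°]$. Cells left of the
  midline are mirrored so that "+x = lateral" holds for every cell; without
  this, pooling the two sides of a slice would cancel any lateral
  anisotropy. Which direction along the midline counts as 0° versus 180°
  is slice metadata and must be held fixed within a comparison. A cell is
  "migrating laterally" when its angle lies in the closed band
  $[45°, 135°]$.

## Circular statistics

`circular_summary()` reports the first trigonometric moment of an angle
collection: circular mean $\bar\theta = \operatorname{atan2}(\bar S, \bar
C)$, mean resultant length $R \in [0, 1]$, and the **angular deviation**
$\sigma_{ang} = \sqrt{2(1 - R)}$ (radians, reported in degrees). The
angular deviation — not the circular standard deviation
$\sqrt{-2\ln R}$ — is the spread statistic used for trajectory-angle
distributions in this field (the CircStat convention); it is bounded by
$\sqrt{2}$ rad ≈ 81.03°, reaches 0 exactly when $R = 1$, and stays
defined when the mean direction does not (at $R \approx 0$ the mean is
flagged `NA`).

Two angle distributions are compared with the two-sample **Kuiper test**,
implemented in this package:

$$V = \max_\theta\,(F_1(\theta) - F_2(\theta)) + \max_\theta\,(F_2(\theta) - F_1(\theta)),$$

with the ECDFs evaluated from a common origin. Unlike a linear
Kolmogorov-Smirnov statistic, $V$ is invariant under a common rotation of
both samples — including rotations across the ±180° wrap — which is what
makes it appropriate for circular data with no privileged origin. Ties
enter through the ECDF step heights directly; no jitter is applied. The
p-value uses the asymptotic tail series
$Q(\lambda) = 2\sum_{j\ge1} (4j^2\lambda^2 - 1)e^{-2j^2\lambda^2}$ with
effective size $N = n_1 n_2 / (n_1 + n_2)$ and
$\lambda = (\sqrt N + 0.155 + 0.24/\sqrt N)\,V$, clamped to $[0, 1]$ and
returned as 1 for $\lambda < 0.4$. The approximation is inaccurate when
$\min(n_1, n_2) < 5$; the statistic itself is exact for any size, and the
test suite checks it against a brute-force scan that recomputes the ECDF
differences from every cyclic origin.

```{r kuiper-example}
kuiper_test(c(0, 90, 180, 270), c(45, 135, 225, 315))
circular_summary(c(0, 90))
```

## Morphology dynamics

Per-frame annotations record the number of primary processes arising from
the soma and whether the leading process (LP) is branched. The state rule
is deterministic: more than two soma processes ⇒ `multipolar`; otherwise
`bipolar_branched` if the LP is branched, else `bipolar_unbranched`. Over
time a cell is `constant_bipolar` (every frame bipolar — branched and
unbranched both count), `constant_multipolar`, or `transitionary`.

Two rates are reported per hour of elapsed time $(n-1)\,dt$:

* **Morphology transitions** count switches of polarity class
  (bipolar ↔ multipolar); branched/unbranched flips within the bipolar
  class do not count.
* **Branch transitions** are scored as $\sum_k |\Delta\,\text{branch
  count}_k|$, the reproducible proxy for manually scored appearance and
  disappearance events. A simultaneous appearance plus disappearance
  within one interval is undercounted by this proxy, so an explicit
  per-event annotation table is accepted as an alternative input.

Speed-morphology pairing (`pair_speed_morphology()`) asks how a cell in a
given shape moves, so it uses the *forward* speed (frame $t$ to $t+1$) for
the state at frame $t$; the kinematics module's series uses the backward
convention of the per-timepoint velocity definition. Both conventions are
exposed; forward is the pairing default. Morphology categorisation uses
the first 18 frames by default while LP tracing workflows conventionally
use 19 time-points; the two windows are kept as separate defaults rather
than reconciled, since they reflect different annotation protocols.

The spread of LP lengths between groups is summarised by medians, IQRs and
ranges, with the IQR ratio and an Ansari-Bradley rank test as the
dispersion comparison. No canonical statistic exists for "a broader
distribution with very long and very short LPs"; the rank-based scale test
is a stand-in and is documented as such.

## Fixed-section distribution analytics

For coronal sections, the mediolateral grid is built per section by
dividing the segment from the midline to the most lateral marker-positive
landmark cell into `n_bins = 4` equal bins of normalised position
$u = (x - x_{mid})/(x_{land} - x_{mid})$. Bins are half-open except the
most lateral bin, which is closed at $u = 1$ so the landmark cell itself
is counted; a cell exactly on the midline falls in bin 1. Cells outside
$[0, 1]$ beyond a small tolerance are excluded and reported. Fractions are
invariant under any common affine rescaling of the coordinates, and
left-lateralised sections (landmark medial-negative of the midline) work
symmetrically. Group-level inference on these profiles (two-way ANOVA with
multiple-comparison correction) is deliberately left to standard routines.

## The generative model

`simulate_population()` is validation machinery: the study's raw tracking
data are not redistributable, so the package ships a generative model that
reproduces the *statistical structure* the analysis assumes, with full
ground truth. No claim is made that it reproduces any real dataset; it is
labelled synthetic throughout.

Each cell runs a three-state hidden Markov chain (`rest`, `slow`,
`spurt`) across 27 frames at `dt = 1/6` hr (≈ 4.3 h of imaging, the
default acquisition). The step from frame $k$ to $k+1$ is governed by the
state at $k$:

* **Step length** is `speed * dt` with the speed drawn from the state's
  lognormal distribution. The rest-state distribution is truncated below
  the 10 μm/hr cutoff and the slow-state distribution above it, so the
  hidden states keep the phase semantics of the bands they are named
  after; without truncation roughly a quarter of slow-state steps would
  fall in the rest band and band-based phase estimates could not recover
  the chain's occupancy. The spurt distribution is untruncated to keep its
  heavy right tail.
* **Step direction** in the xy-plane is von Mises with 90° = lateral;
  `kappa = 0` is isotropic. Sampling uses the Best-Fisher rejection
  algorithm. z receives weak Gaussian jitter (σ = 0.5 μm/step) that
  contributes to 3D speed but carries no directional signal; rest-state
  jitter is capped so a resting step can never cross the rest cutoff in
  3D, which makes "every never-migrating cell is classified
  non-migratory" a structural guarantee.
* **Morphology** is emitted per frame from state-specific probabilities
  over the three morphology states, and a per-frame branch-event rate
  drives a ±1 random walk on the branch count. Frames whose forward step
  exceeds `bipolar_speed_min` (default 60 μm/hr) emit a bipolar state
  regardless: fast spurts occur only in bipolar morphology, so the ≥99%
  bipolar occupancy of the fast band is a property of the model, not a
  coin flip. Because emission is otherwise memoryless, almost every
  simulated cell is "transitionary" over a long window — the generator
  calibrates speeds and directions, not morphology-category proportions.
* A fraction of cells is locked at rest for the whole recording
  (`fraction_never_migrating`), and dwell-time parameters are free: no
  published dwell-time distributions exist for rest bouts, so the
  transition rows are documented as uncalibrated in that respect.

### Default parameter sets and their calibration

`default_sim_params()` encodes two conditions. The **control-like** set
was calibrated once, by simulation, so that the max-speed quartiles of a
simulated population fall within ±20% of the quartile quartet observed in
control slices (≈ 12.4 / 23.6 / 48.1 μm/hr; simulated ≈ 14.4 / 23.6 /
43.7 at n = 2000) with a weak lateral bias of slow steps
(`kappa_slow = 0.4`) and strongly lateral spurts (`kappa_spurt = 2.5`).
The **mutant-like** set encodes the Reelin-loss phenotype: lower
spurt-entry probability, a higher never-migrating fraction, an isotropic
slow phase (`kappa_slow = 0`), *unchanged* spurt speed and anisotropy,
less slow-phase exposure, and a higher morphology instability (more
multipolar emission, branch-event rate 0.25 vs 0.10). Its simulated
quartiles (≈ 10.2 / 17.2 / 24.2) sit within ±20% of the mutant quartet
(10.1 / 15 / 29.8). Exact reproduction of the printed population numbers
is explicitly not claimed: they summarise data that are not available.

`set_spurt_entry()` rewrites only the rest→spurt and slow→spurt
probabilities (rescaling the remaining row mass), which is how
"conditions differing only in spurt likelihood" are constructed for
monotonicity checks.

```{r sim-demo}
sim <- simulate_population(default_sim_params("control_like"),
                           n_cells = 200, seed = 7)
an <- analyze_population(sim$population, morph = sim$morphology)
an
recover_parameters(sim)
```

### What the generator does and does not emulate

It reproduces rest-dominated saltatory movement, heavy-right-tailed speed
distributions, state-dependent directional bias, speed-coupled morphology
and never-migrating cells — the features the pipeline's estimators rely
on. It does not emulate tissue geometry, glia, signalling gradients,
cell-cell interactions, tracking errors (missed detections, identity
swaps) or spatially varying behaviour. Tests that pass on simulated
populations therefore validate the *estimators*, not any biological claim
about real slices.

## Pipeline and comparison

`analyze_population()` chains validation (cells absent from any frame are
excluded by default; single interior gaps can be linearly interpolated on
request), kinematics, classification, trajectory angles (migratory cells
only), circular summaries per class, and the morphology metrics when
annotations are present. Non-migratory cells stay in the class counts but
are excluded from displacement, directionality and trajectory summaries —
the same bookkeeping that takes a tracked population of 806 to 680
migratory cells.

`compare_conditions()` reports rank-based Mann-Whitney tests on average-
and max-speed distributions, Kuiper tests on pooled, per-class and
per-phase angle distributions, category-proportion and branch-rate
comparisons. The rank tests and the two-proportion contract are delegated
to `stats`; only the Kuiper test is implemented here. **No
multiple-testing correction is applied across the report's test
families** — the convention in this analysis scheme applies corrections
only to the fixed-section comparisons, which are out of the package's
inference scope — so treat the p-values as per-test.

## Numerical choices and degenerate inputs

* Band and histogram edges are half-open with upper-bin assignment; the
  lateral band is closed; the last mediolateral bin is closed at 1.
* A circular mean with $R < 10^{-9}$ is reported as `NA`; the angular
  deviation is still returned.
* Zero-length xy displacement makes the trajectory angle undefined (`NA`
  with a warning); zero path length makes directionality `NA`.
* Kuiper p-values are clamped to $[0, 1]$ and set to 1 below
  $\lambda = 0.4$, where the tail series is numerically 1.
* The IQR ratio of two all-constant groups is defined as 1 (0/0 case).
* Simulation is bit-reproducible for identical `(params, n_cells, seed)`;
  the caller's RNG state is restored on exit.

## Problem sizes

The bundled tests and the acceptance script use simulated populations of
200-2000 cells at 27 frames, 200 random sample pairs for the Kuiper
oracle, and 1000 random tracks for the kinematic invariants — sizes at
which every stochastic check is stable under its stated tolerance while
the whole suite stays fast on a single core.

## Known limitations

* The asymptotic Kuiper p-value is unreliable below five observations per
  sample; the statistic is still exact.
* Branch-count differencing undercounts simultaneous appear+disappear
  events (use the event-list input for exact annotation).
* The generator's memoryless morphology emission makes morphology-category
  proportions unrealistic over long windows.
* Gap interpolation is linear and only defined for interior gaps; cells
  missing their first or last frame are always excluded.
* TrackMate ingest trusts the file's calibrated physical coordinates; no
  drift correction or re-linking is attempted.
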