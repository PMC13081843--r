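---
title: "Quantifying the maternal-fetal interface in 3D: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the maternal-fetal interface in 3D: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whole-organ light-sheet imaging of the pregnant mouse uterus yields, after
segmentation, three kinds of exported data per implantation site: point
detections ("spots") for trophoblasts and arteries with positions in
micrometres and per-spot volumes; a handful of labelled anatomical landmark
points; and, optionally, traced artery centerlines. The biological questions
— how deep do trophoblasts invade, how strongly do they target spiral
arteries, how many arteries reach the placenta, and how badly do midline 2D
sections underestimate all of this — are questions about *positions relative
to anatomy*, so the first task is a coordinate system anchored to the
anatomy rather than to the microscope stage.

`deciduamap` implements that coordinate normalization and every downstream
quantification, together with a synthetic implantation-site generator that
produces all three data kinds with known ground truth, so each stage can be
validated end-to-end without imaging data.

# The half-dome frame

An implantation site is approximately a half dome sitting on the mesometrial
plane: the placenta and its junctional zone form an inner cap, the decidua
fills the shell between that cap and the myometrium, and the myometrial
muscle wraps the outside. Five landmark classes define the frame:

* `luminal_epithelium` — points at the neighbouring inter-implantation
  sites, on the mesometrial side; their centroid anchors the mesometrial
  cutoff plane and the base of the dome axis.
* `junctional_zone_outer` — points on the placental border (depth 0).
* `myometrium_outer` — points on the myometrial surface (depth 1).
* `front`, `back` — two markers fixing the azimuthal origin.

The dome axis runs from the luminal-epithelium centroid through the
junctional-zone centroid. Both boundary surfaces are modelled as spherical
caps sharing a center on that axis; the center is located by a 1-D least
squares over the two landmark sets jointly (golden-section search, interval
tolerance 1e-8), after which each radius is the mean landmark distance. A
spheroid (independent polar/equatorial radii) option exists for flattened
sites; the sphere is the default because the landmark counts a human
annotator realistically places (~20–30 per surface) do not support more
parameters. Fit quality is reported as the maximum landmark residual, and a
fit in which the outer surface does not strictly enclose the inner one is an
error, not a warning.

Every spot is then described by ray coordinates: depth
$d = (r - r_{jz})/(r_{myo} - r_{jz})$ along its ray from the center (0 on
the placental border, 1 at the myometrium, continuing linearly into the
muscle shell), azimuth $u \in [0,1)$ around the axis with $u = 0$ toward
the front marker, and polar angle $v \in [0,1]$ from apex to equator.
Region flags are exhaustive: `decidua` ($0 \le d < 1$), `myometrium`
($1 \le d \le d_{max}$, default 1.5 so the whole muscle shell stays in
view), otherwise `outside`. Keeping one continuous depth axis through the
myometrium — rather than re-normalizing by muscle thickness — makes
"myometrial invader" a simple threshold ($d \ge 1$) and keeps depth
comparisons meaningful across the boundary. Points mesometrial to the
cutoff plane are excluded outright, because trophoblast and epithelial
signal are indistinguishable there; the exclusion is a plane through the
luminal-epithelium centroid normal to the axis, a deliberate geometric
simplification of what is, in the images, an irregular region.

Because everything is built from centroids, least-squares distances and
ray geometry, the construction is equivariant under rigid motions: rotating
and translating spots and landmarks together changes no normalized
coordinate by more than optimizer noise (~1e-7), which the test suite
asserts at 1e-6.

Spot filtering applies two rules before normalization: an inclusive volume
floor (default 100 µm³, standing in for the light-sheet size-detection
limit; spots with no volume column pass with a logged warning) and the
mesometrial exclusion. The filter report counts each rule separately.

# Density overlap

The spatial association of arteries and trophoblasts is summarized by the
Bhattacharyya coefficient $BC = \int \sqrt{p\,q}$ between the two channels'
3D densities, estimated with a Gaussian product-kernel KDE on a regular
grid (default $50^3$) and integrated as a Riemann sum. $BC$ is 1 for
identical distributions and 0 for disjoint ones; both bounds and symmetry
are exact in the implementation (clipping guards rounding).

Numerical choices worth stating:

* **Bandwidth.** Scott's rule per axis, $h_j = \hat\sigma_j n^{-1/7}$,
  computed *per channel*. Computing a single bandwidth on the pooled
  channels would make $h$ grow with the separation between the channels —
  exactly the quantity $BC$ measures — and systematically oversmooth
  separated channels toward higher overlap; per-channel bandwidths keep the
  estimator's bias independent of the effect size. For two isotropic
  Gaussians with $\sigma = 0.1$ separated by 0.2 (true
  $BC = e^{-1/2} \approx 0.607$) the pipeline lands within ±0.03 at
  $n = 5000$ per channel.
* **Grid.** The grid spans the data bounding box expanded by three
  bandwidths; mass leaking past the edges is folded back by renormalizing
  the Riemann sum to 1. Halving or doubling the resolution moves $BC$ by
  less than 0.01 at moderate $n$.
* **Bootstrap.** Uncertainty is assessed by resampling each channel
  independently with replacement at its original size (the study default is
  1000 replicates), recomputing both KDEs and $BC$, and reporting the
  median and percentile 95% interval. Bandwidths and grid are frozen from
  the original sample across replicates: re-deriving Scott's rule from
  resamples with duplicated points would shrink $h$ spuriously. A single
  seeded generator drives all replicates and the seed is recorded in the
  result, so overlap results are bit-reproducible.
* **Estimator bias at small n.** Two *independent* finite samples from the
  same distribution give $BC < 1$ because their KDE fluctuations
  decorrelate; with Scott bandwidths the bootstrap median saturates near
  0.99 only for several thousand points. Calibration of the interval was
  checked by simulation: for the Gaussian pair above at 600 points per
  channel, a $32^3$ grid and 200 replicates, the 95% percentile interval
  covered the closed-form value in 96% of pilot runs (and ≥ 88/100 is
  asserted in the acceptance suite). At much smaller $n$ the downward
  estimator bias exceeds the interval width and coverage degrades — per-site
  spot counts in realistic data (thousands) are comfortably above that
  regime.
* **Coordinates for densities.** The pipeline estimates densities in
  frame-aligned Cartesian coordinates scaled by the myometrial radius
  (front, side and axis components), not in $(d, u, v)$: azimuth is
  circular, and a Cartesian product kernel on a circular coordinate would
  mishandle the wrap-around.

# Trophoblast localization and artery metrics

Classification is a four-way partition of every in-domain trophoblast:
decidual points are `spiral_artery_adjacent` when their minimum Euclidean
distance (in raw µm) to any artery reference point is at most $r_{adj}$,
otherwise `interstitial`; myometrial points split the same way into
`myometrial_artery_adjacent` and `myometrial_stromal`. The default
$r_{adj} = 20$ µm is one to two trophoblast diameters — "within or
surrounding" an artery, made metric. Artery references are centerline
samples at 10 µm arc-length spacing when trees are available, artery spots
otherwise; distances are point-to-sample, an approximation bounded by half
the resampling step. All outputs record the radius used, and enlarging it
can only grow the adjacent classes (asserted as a property test).

From centerline trees the package computes three counts:

* **Branches entering the decidua** — tree edges crossing the $d = 1$
  surface inward, counted once per entering path (a wiggling branch that
  re-crosses is not double-counted; independent daughters each descending
  from the myometrium are).
* **Envelopment** — per artery, the fraction of its decidual centerline
  samples having a trophoblast within $r_{env}$ (default 20 µm); the artery
  is "enveloped" when that coverage reaches 0.5, a literal reading of
  "through most of its length". Arteries with no decidual segment are
  excluded from the denominator, with a note.
* **Placental connection** — a tree counts as connected when a terminal
  node reaches the junctional-zone surface within a tolerance (30 µm,
  converted to normalized depth by the local shell thickness).

# Virtual sections: what 2D misses

To emulate midline histology, slabs of 70 µm (a typical cryosection) are
taken parallel to the midline plane (the plane containing the dome axis and
the front–back axis) at offsets up to ±240 µm, five sections by default,
with at least three non-empty sections required before a mean is reported.
Each section's invasion read-out is the **maximum normalized depth of the
trophoblasts inside the slab**, and the discrepancy ratio is the 3D maximum
over the mean per-section maximum.

A design note: the package also provides `relative_depth_2d()`, the
standard 2D-section quantification (minimum distance to the placental
border over the section's placenta-to-myometrium span) for analysing real
section data. Virtual sections deliberately do *not* use it: the in-plane
distance convention differs from the 3D ray depth by up to ~1% for
off-center slabs through a curved shell, which would contaminate the 2D-3D
comparison with metric-convention noise. Scoring slabs by the frame's own
depth makes the per-section maximum a subset maximum — provably never above
the 3D maximum — so the discrepancy ratio isolates *sampling* bias: the
sections simply do not contain the deepest cells when invasion is
azimuthally uneven. Under isotropic invasion the ratio sits near 1 (1.07 on
average across pilot seeds, the residual reflecting that a subset maximum
underestimates slightly); it rises monotonically with azimuthal
concentration of the invading cells, reproducing in kind the several-fold
underestimation that motivates 3D quantification.

# Group statistics and expression

`group_compare()` wraps the omnibus and pairwise tests used for
per-implantation-site readouts (one-way ANOVA with Tukey, Welch's t,
pairwise Mann–Whitney, Kruskal–Wallis with Dunn's rank-based post-hoc, and
pairwise Kolmogorov–Smirnov), with Bonferroni adjustment
$p_{adj} = \min(1, m\,p)$ over the number of pairs. Dunn's z statistics are
computed from the joint ranking with tie correction; the family-wise type-I
error of the Kruskal–Wallis-gated, Bonferroni-adjusted procedure stays at
or below nominal in null simulations. Fisher's exact test for 2×2 tables is
the package's own full enumeration of the conditional hypergeometric
distribution (two-sided p as the sum over tables no more probable than the
observed one, with the conventional $1 + 10^{-7}$ floating-point tie
guard); it matches an independent factorial-formula enumeration for every
table with total at most 40. Odds ratios use the Haldane–Anscombe 0.5
correction when a cell is zero (flagged in the output) and a log-scale Wald
interval. Relative expression uses the standard $\Delta\Delta C_t$ scheme
with the arithmetic mean reference $\Delta C_t$, so the reference group's
geometric-mean fold is exactly 1.

# The synthetic generator

`generate_site()` produces a full input bundle — two-channel spot table,
centerline trees, referents, ground truth — from a `site_config()`.
Geometry defaults: junctional-zone radius 900 µm, myometrial surface
1500 µm, outer muscle 1800 µm, which are plausible mid-gestation
dimensions; none of the downstream statistics depend on the absolute scale.
Arteries are helical centerlines (coil radius 60 µm, pitch 150 µm — a
minimal "loosely spiralled" model) seeded on the myometrial surface and
descending toward the dome apex where the ectoplacental cone sits; a
configured fraction terminate exactly on the junctional-zone surface
(placenta-connected). The coil amplitude tapers to zero at both ends so
each tree starts cleanly in the myometrium and ends exactly at its target
radius, making branch and connection counts exact by construction.

Trophoblasts follow a mixture that mirrors the phenotypes the pipeline is
meant to measure. A fraction `myometrial_fraction` (0 in controls, 0.20 in
the knockout preset) invades the muscle shell, and of those,
`artery_targeted_fraction` (0.75) are snapped to within the adjacency
radius of a myometrial artery segment. The remainder are decidual with
depth drawn from a Beta(2,2) scaled to $(0, d_{cap})$ — the cap, 0.95 in
mid-gestation presets, encodes "invasion nearly all the way through the
decidua" as a support bound rather than a mean — and azimuth from a von
Mises distribution (concentration 0 = isotropic control; the knockout
preset uses κ = 4 centred perpendicular to the midline, making its deep
invasion invisible to midline sections). A fraction `p_env` (0.75 control,
0.10 knockout) of decidual cells is snapped to within `r_snap` of a
centerline sample of a *designated* enveloped artery; designation (60% of
arteries in the control preset, drawn from the connected ones first) is
what lets per-artery envelopment be controlled and recovered — uniform
snapping across all arteries would envelop every artery. Snapping targets
exclude samples within 0.03 normalized depth of the region boundaries so
ground-truth labels and classifier output agree except for genuinely
boundary-straddling points (≥ 99% agreement is asserted).

Spot volumes are log-normal around 500 µm³ with a configurable contaminant
fraction below the 100 µm³ floor to exercise volume filtering, and an
optional mesometrial-contaminant fraction exercises the cutoff-plane
exclusion. Landmarks are placed systematically — boundary landmarks in
azimuthally antipodal pairs with golden-angle spread, luminal-epithelium
points as a symmetric ring — because that is what a careful annotator's
evenly spread landmarks look like; uniformly random cap sampling would tilt
the estimated dome axis by several degrees at realistic landmark counts, an
artefact of the sampling, not of the method. Landmark jitter (default 5 µm)
models placement error.

What the generator does **not** emulate: image segmentation itself (spot
positions are exact, not centroid estimates from voxels), anisotropic
point-spread along z, artery branching (each tree is a single helical
path; branch counting is nevertheless tested on hand-built branched trees),
tissue deformation between sites, and any biophysics of migration. Passing
tests therefore validate the geometry, statistics and bookkeeping of the
pipeline — not the segmentation upstream of it.

# Problem sizes used in the checks

The test suite and acceptance script size their simulations to run on a
single CPU in minutes while keeping every estimate in its well-behaved
regime: 3000 trophoblasts and 16 arteries per preset site (matching the
order of magnitude of real detections), 5000 points per channel for the
closed-form Gaussian overlap check, 600 points per channel × 200 bootstrap
replicates × 100 datasets for interval-coverage calibration, 20 seeds per
condition for the 2D/3D sampling-bias checks, and 200 null simulations for
the family-wise error check. The exhaustive Fisher enumeration covers all
~136,000 tables with total ≤ 40.

# Known limitations

* The spherical-cap frame is a convention; sites that are strongly
  ellipsoidal are better served by the spheroid option, and genuinely
  irregular boundaries would need a landmark-dense surface model the
  package does not implement.
* The mesometrial exclusion is a plane, not a segmentation of the
  mesometrial signal region.
* Point-to-sample distances bound point-to-curve distances only to half the
  resampling step (5 µm at defaults); radii much smaller than the step
  would need denser resampling.
* BC values from KDEs are biased downward at small per-channel counts
  (hundreds); comparisons across groups are safe when counts are
  comparable, but absolute values at low n should be read with the
  calibration section above in mind.
* Bootstrap resampling treats spots as exchangeable within a site; spatial
  dependence between neighbouring spots (e.g. one cell detected as two
  spots) is not modelled.
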