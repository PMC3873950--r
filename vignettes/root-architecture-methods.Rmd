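---
title: "Deep phenotyping of 3D coarse-root architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep phenotyping of 3D coarse-root architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootarch)
```

`rootarch` turns a 3D-digitized coarse root system of a container-grown
seedling into a full battery of architectural traits, and runs the
statistical layer that such phenotyping studies use. This vignette explains
the measurement model, the conventions and tunable parameters, what the
synthetic generator does and does not emulate, and the numerical choices
made where the underlying methods leave them open.

## The measurement model

A digitized root system is a rooted tree of *segments*. A segment is one
measured inter-node of a root axis: 3D endpoints in the container frame,
one basal diameter, and a count plus mean length of the unmeasured
"additional fine roots" (basal diameter below the 0.7 mm digitizing
threshold) borne by the segment. Axes are chains of segments; the order-1
axis is the stump plus taproot; laterals step the branching order up by
one.

The frame is fixed by the experiment: the origin at the collar, `x`
pointing north, which in tilted containers is also the upslope direction
(azimuth 0), `y` parallel to the upper container border, and `z`
perpendicular to the soil surface through the collar, positive upward, so
depths are negative. On a tilted container the frame tilts with it, which
is why `z` is directly "distance to the soil surface".

Diameters are digitized at segment boundaries, *just before* each branch
point but not directly after it. Two consequences follow. First, segment
volume is modelled as the frustum of its basal diameter and the next
segment's basal diameter (the distal segment of an axis is a cylinder);
a `volume_mode = "cylinder"` toggle exists because the solid model is a
convention, not a measurement. Second, in the fractal branching analysis
the post-branch cross-sectional area (CSA) of the continuing axis is taken
2 cm after the branch point by linear interpolation whenever the
continuing segment is longer than 2 cm; shorter segments use their distal
measurement point.

All interpolation along axes — coordinates and diameters alike — is linear
in curvilinear distance. No smoothing or spline fitting is applied to the
digitized polylines.

## Geometric traits

* **Axis length** adds the radius of the mother root at the attachment
  point, accounting for the primary growth buried inside the mother.
* **Mean diameter** treats the root as a cylinder:
  $\bar d = 2\sqrt{V/(\pi L)}$.
* **Proximal taper** is the % diameter decrease per cm over the first
  3.5 cm of the axis, from the interpolated diameter profile.
* **Taproot angle** is the angle to the soil surface of the line from the
  collar to the point where the order-1 root crosses the 70 mm deep-root
  limit; a vertical taproot scores −90°. Angles toward the soil surface
  are negative when descending, so a taproot angle of −71° means 19° off
  vertical.
* **Azimuth of an axis** is measured at the point 1 cm from its base
  (compass convention: 0 = +x = north/upslope, 90° = +y), about the
  bearing point on the order-1 root for the circular analysis.
* **RDD** (root directional deviation) is the absolute azimuth change
  between the point 10 mm from the root origin and the tip, folded to
  [0°, 180°]; **winding** is curvilinear length over base–tip distance
  (≥ 1, 1 = straight).
* Axes too short for a rule (azimuth < 1 cm, RDD < 10 mm, taper < 3.5 cm)
  fall back to the tip and set a quality flag rather than being dropped.

**Virtual segmentation.** Because digitized segments are long compared to
the root system, every segment is cut into 10 mm virtual segments for all
spatial distribution work. Slices are measured from the segment base; the
45 mm stump limit additionally cuts the straddling slice on the order-1
axis. Length and volume are conserved exactly (the frustum integral is
closed-form within a segment, where the diameter profile is linear), which
the test suite checks to 10⁻⁹ relative error across generated systems.

**Wall artifacts.** Roots that reach the container wall or bottom follow
it. Such axes are virtually extended in the direction the root was growing
before it attained the edge, keeping every segment length. Detection is
necessarily a heuristic; the rule used is: a vertex within 2 mm of a face
(`contact_tol`) followed by at least two segments (`min_follow`) that lie
*on* a face — endpoints within `follow_tol` = 0.1 mm and direction within
15° of the face plane (`face_angle_tol`). The tight `follow_tol`
distinguishes true wall-following from a free vertex that merely passes
near the wall, and checking "some face" rather than "the contact face"
keeps corner hits (wall-to-wall slides) in scope. All four thresholds are
arguments. An axis already starting on a face (a daughter born on a
wall-following segment) is left unchanged with a warning: its pre-contact
direction never existed.

## Compartments and circular sectors

Segments are classified into eight compartments: (1) stump, (2) taproot,
(3) zone of rapid taper (ZRT), (4) horizontal shallow roots beyond the
ZRT, (5) sinkers, (6) deep, (7) intermediate depth, (8) oblique roots.
The stump is the first 45 mm of curvilinear length of the order-1 root —
a standard *length*, not depth, so tilted and vertical taproots are
treated alike — and is excluded from total root volume, since it makes no
active contribution to anchorage. Laterals are classified by the depth of
their arborescence's initial branching point on the order-1 root (limits
−35 and −70 mm; boundaries assigned to the deeper class) crossed with
their own direction class (limits 30° and 60° to the soil surface;
boundaries to the steeper class). Sinkers are pooled into the taproot
compartment and oblique roots into the intermediate one, reflecting their
rarity in container seedlings; both the 8-class and pooled 6-class labels
are kept.

The ZRT/beyond split is spatial, on virtual segments, using the *relative
radial distance*: the horizontal distance from the end of the taproot
segment that bears the arborescence (not from the collar). The bounding
value is never stated in the classical analyses; `zrt_limit` defaults to
50 mm — roughly the taproot-proximal third of a 0.30 m container — and is
deliberately a prominent argument because every ZRT share depends on it.

Circular sectors are the three discontinuous slope-oriented bins: upslope
`us` = [315°, 45°), downslope `ds` = [135°, 225°), perpendicular `pp` =
the rest. Bins are half-open for determinism. Stump and taproot are the
centre of the circular analysis and are excluded from it; fine roots are
excluded too since their sector is not recorded. An even distribution
gives 25% per quadrant; *reinforcement* is `(share − 25)/25` in percent,
with the `pp` share halved first since it spans two quadrants.

## Topology and fractal branching

The link tree follows the classical topological analysis: an axis with m
branch points contributes m interior links and one exterior link; the path
length of an exterior link counts links from the collar inclusive. The
index

$$q_b = \frac{P_e - P_{e,\min}(n)}{P_{e,\max}(n) - P_{e,\min}(n)}$$

normalises the sum of exterior path lengths between the most balanced
(dichotomous) topology (0) and the herringbone topology (1) with the same
number of exterior links n. The extremes use closed forms
($P_{e,\max} = (n^2+3n-2)/2$; the balanced minimum from the two occupied
leaf depths), which the test suite verifies against exhaustive enumeration
of every binary topology with up to 7 tips. Multifurcations are resolved
to binary trees by serial splitting in position order; fine roots, when
included, attach as extra exterior links at their bearing segment's tip.
Scoped values (shallow / intermediate / deep) keep the order-1 chain as
backbone and retain only the arborescences whose origin falls in the
scope; this backbone convention is ours, since a compartment-restricted
tree needs a root.

The **mean branching order** (MBO) is used where q_b cannot be (an
arborescence can straddle sectors): the mean over lateral axes of
(topological order − 1), so a system bearing only second-order laterals
scores exactly 1, consistent with observed seedling values near 1.1–1.4.
The defining formula in the source material is an unrendered image; the
convention here is calibrated to that anchor and documented as a
convention, not an attribution. Fine roots count at their bearing axis'
order + 1 with multiplicity.

Fractal branching parameters per branch event: `p_branch` = CSA before /
Σ CSA after (tapering by branching; 1 under CSA conservation), `q` =
largest post-branch CSA / Σ CSA after (1/2 for an equal dichotomous
split), and `p_within` = % CSA decrease per cm between consecutive branch
points of an axis. `p_within` is computed between the pre-branch CSAs of
consecutive events, which is what the digitized diameters support; it
therefore includes the allocation drop of the intervening event, exactly
as a measurement on real data would. It is CSA-based for consistency with
`p_branch`; a diameter basis would halve the rates.

## The synthetic generator

No digitized seedlings are publicly deposited, so the generator is a
first-class module: it samples final architectures phenomenologically
(there is no growth simulation, no soil, no time) that match the digitized
situation — one near-vertical taproot with exponential within-axis taper,
laterals near-parallel to the soil surface with configurable azimuth law
(uniform, von Mises, or exactly stratified), CSA reallocation at branch
events driven by target `p_branch`/`q`, rare sinkers and oblique roots,
Poisson fine roots, and wall deflection inside the 0.30 × 0.30 × 0.11 m
container.

Defaults are the study conditions of a six-month glasshouse seedling:
collar diameter 9 mm, order-1 length 0.16 m (longer than the 0.11 m soil,
so taproots deflect along the container bottom, as real ones do), order-1
taper 6 %/cm, twelve measured laterals weighted 60/30/10 across
shallow/intermediate/deep origins, shallow laterals at −8° ± 5° to the
surface, stump `p_branch` 1.2 and `q` 0.78, taproot `p_branch` 1.4 and
`q` 0.75 (the stump allocates more gently than the taproot below it),
lateral `p_branch` 1.05 and `q` 0.67, fine roots at 0.04 per cm (≈ 60% of
the measured root number)
and tertiary branching at 0.05 per cm (MBO ≈ 1.3–1.5), tissue density
0.528 g cm⁻³ and a root mass fraction of 20% to derive dry weights, plus
10% lognormal plant-to-plant size jitter. The taproot is grown straight
(2° per-segment jitter applies to laterals only): digitized taproots are
essentially straight, and a deterministic taproot lets branch points be
placed at exact boundaries.

Two constructions are exact by design rather than stochastic:

* **Stratified azimuths** place n identical laterals at
  `180/n + k·360/n` degrees (22.5 + k·45 for n = 8), avoiding all sector
  boundaries; `config_stratified()` switches every noise source off, so
  quadrant shares are exactly 25% and reinforcement exactly 0. This mode
  exists specifically to make sector tests exact.
* **Herringbone weight** h: each higher-order branch joins the main chain
  with probability h, otherwise the shallowest leaf of the arborescence is
  split (breadth-first). h = 1 yields q_b = 1 arborescences; h = 0 reaches
  q_b = 0 exactly when the tip count is a power of two.

Hidden ground truth (true straight-growth tips, realized origin depths,
intended azimuths and angles, the generating configuration) is stored with
each system, enabling parameter-recovery tests: wall correction must land
within 1 mm of the true tip, measured `p_branch` must recover its target
on a non-degenerate configuration, a von Mises mean must be recovered by
the circular mean.

Two further touches keep the output measurement-faithful. A higher-order
branch whose allocated diameter falls below the 0.7 mm digitizing
threshold is recorded as an additional fine root on its bearing segment
rather than as a measured axis — which is exactly what a digitizer would
do, and why small plants often lack measured third-order roots. And when
a root contacts a face, the generator freezes direction jitter, so the
hidden truth is the *straight*-growth continuation — matching what the
wall-extension operation can reconstruct. What the generator does **not**
emulate: curvature responses near walls before contact, root mortality,
heterogeneous soil, nodules, and any correlation structure between traits
beyond what the shared skeleton induces. Tests passing on generated data
therefore validate the measurement pipeline, not biological realism.

## The statistical layer

**Trait ANOVA.** Each trait is fitted as
`trait ~ Slope + Flexing + Slope:Flexing + Block` (all factors two-level).
Residual normality is checked with the Shapiro test at α = 0.05; failing
traits are log-transformed (only when strictly positive), then
rank-transformed if still non-normal — a fixed none → log → rank ladder,
since the underlying prescription says only that variables were
transformed to normality. Significance uses sequential (Type I) sums of
squares in the stated model order, appropriate for the balanced cohorts
the generator produces; `ss_type = "II"` is available for unbalanced
cohorts like real experiments with unequal survival. Group means and %
variation versus the control are always reported on the untransformed
scale. Stars mark 5, 1, 0.1 and 0.01%.

**Sector mixed model.** Per treatment group, compartment and variable:
`value ~ sector + (1 | tree)`, REML, with Satterthwaite degrees of
freedom; the `pp` value is halved beforehand for volume/length/number
shares. Pairwise sector contrasts are unadjusted for multiplicity (raw
contrast p-values are the convention in these tables; a Holm option would
be a one-liner on the returned p columns) and summarised as a compact
letter display; letters are only split when the overall sector test is
significant at α = 0.05. Compartments present in half the trees or fewer
are reported NA — rare compartments (e.g. deep roots) cannot support the
model. Because shares sum to 100 within a tree, the tree random effect is
often estimated at the boundary (zero variance); this is expected and
harmless, the fixed-effect test being the object of interest.

**PCA** is computed on centred, unit-variance traits; each component is
oriented so its largest-magnitude loading is positive. The default
selection has 17 variables spanning size, allocation, branching,
compartment volume shares and circular distribution
(`default_pca_traits()`); it is configurable, and missing values follow an
explicit policy (`impute_mean` by default, or drop plants, or error).

## Problem sizes and determinism

Every stochastic routine takes a seed; the same configuration and seed
reproduce a system, cohort or pipeline run bit-for-bit. The test suite
runs at deliberate scales: exhaustive topology enumeration to 7 exterior
links, conservation checks over 100 generated systems, 1000 null cohorts
for the ANOVA type-I rate (checked against the 99% binomial interval),
200 simulations for the flexing-effect power and 100 for the
upslope-reinforcement power, each at the configured effect sizes (1.5 sd;
+50% reinforcement with sd 5 at n = 8). These sizes keep Monte-Carlo error
well below the margins being tested.

## Known limitations

* The MTG dialect is a documented subset (two scales, fixed feature set);
  the full multiscale grammar is out of scope and unsupported constructs
  are rejected explicitly rather than guessed at.
* The ZRT limit and the q_b scope backbone are conventions (above); both
  are parameters, and comparisons across studies should state them.
* Wall-contact detection thresholds trade false positives against misses;
  grazing approaches (within `follow_tol` of a wall at near-wall-parallel
  headings) are genuinely ambiguous.
* `p_within` conflates within-axis taper with the allocation drop at the
  intervening events (measurement-faithful, but worth remembering when
  comparing to anatomical taper).
* The generator's trait covariance is whatever the shared skeleton
  induces; it is not fitted to any real covariance structure.
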