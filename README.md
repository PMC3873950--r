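# rootarch

Deep phenotyping of 3D coarse-root architecture for container-grown
seedlings.

When a young tree's root system is excavated and digitized in 3D — every
segment's endpoints, basal diameter and fine-root load recorded in an MTG
(multitree graph) file — the raw polylines still have to be turned into
architecture. `rootarch` does that end to end, for researchers studying
how root systems respond to slopes, mechanical perturbation and container
geometry:

* **Parsing and validation** — a documented MTG dialect and a portable
  segment-table CSV, with structural validation (one collar, acyclicity,
  order steps, attachment of every base to its parent's tip) reported as
  data rather than errors.
* **Geometry** — axis lengths (adding the mother-root radius), cylinder
  mean diameters `2·sqrt(V/(πL))`, proximal taper over the first 3.5 cm,
  taproot angle at the 70 mm deep-root limit, azimuth at 1 cm, root
  directional deviation, winding, branching angles; 10 mm *virtual
  segments* that conserve length and volume exactly; and virtual extension
  of wall-deflected roots along their pre-contact direction.
* **Classification** — the eight architectural compartments (stump,
  taproot, zone of rapid taper, horizontal shallow beyond ZRT, sinkers,
  deep, intermediate, oblique; sinkers and obliques pooled), a standard
  45 mm stump length, and the three slope-oriented circular sectors
  (upslope 0°±45°, downslope 180°±45°, perpendicular) with reinforcement
  `(share − 25%)/25%`.
* **Topology and fractal branching** — the exterior-path-length index
  `q_b = (P_e − P_e,min)/(P_e,max − P_e,min)` (0 = wholly dichotomous,
  1 = wholly herringbone), mean branching order, and per-branch-event CSA
  scaling: `p_branch` (tapering by branching), `q` (largest daughter's
  share, 0.5 at an equal split) and `p_within` (%CSA/cm between branch
  points), with the 2 cm interpolation rule for the continuing axis.
* **A synthetic seedling generator** — container-grown architectures with
  controlled taproot geometry, azimuth law (uniform / von Mises / exactly
  stratified), herringbone↔dichotomous branching weight, wall deflection
  with hidden straight-growth ground truth; the cohort builder mirrors the
  2 × 2 (slope × flexing) + block design.
* **The statistical layer** — per-trait three-way ANOVA with a Shapiro-
  driven none→log→rank transform ladder, the sector mixed model
  `value ~ sector + (1 | tree)` with unadjusted contrasts and compact
  letter displays (perpendicular shares halved), and PCA of the plant ×
  trait table with broom-style `tidy()`/`glance()` and `autoplot()`.

## A worked example

```r
library(rootarch)

rs <- generate_root_system(generator_config(seed = 42, slope_deg = 45))
rs
#> <root_system> plant plant_1: 190 segments, 16 axes, max order 3
#>   slope 45 deg, not flexed, block b1; container 0.30 x 0.30 x 0.11 m

ph <- phenotype(rs)   # wall correction + full trait battery, one row
dplyr::select(ph, total_volume_cm3, stump_rv_incl_pct, qb_total_iafr,
              mbo_total_iafr, p_branch_stump, taproot_angle_deg)
#>   total_volume_cm3 stump_rv_incl_pct qb_total_iafr mbo_total_iafr p_branch_stump taproot_angle_deg
#> 1             2.28              24.7         0.234           1.59           1.22               -75
```

2.3 cm³ of coarse root outside the stump; the stump holds a quarter of
the whole volume; the branching pattern leans dichotomous (q_b 0.23) with
a mean branching order of 1.59; branch events on the stump taper CSA by a
factor 1.22; and the taproot descends at 75° to the soil surface. The
circular distribution of this plant's laterals:

```r
ss <- sector_shares(rs)
subset(ss, compartment == "all",
       select = c(sector, volume_share, volume_reinforcement))
#>   sector volume_share volume_reinforcement
#> 1     ds         26.1                  4.4
#> 2     pp         22.9                -54.1
#> 3     us         51.0                103.8
```

Half this plant's lateral volume happens to sit in the upslope quadrant —
a +104% upslope reinforcement over the uniform 25% expectation (the
perpendicular share is halved before comparing, since that sector spans
two quadrants). A whole cohort and its statistics:

```r
co <- generate_cohort(n_per_group = 8, seed = 1)
tt <- build_trait_table(co)               # 32 plants x ~90 traits
an <- anova_by_trait(tt)                  # slope/flexing/interaction/block
sm <- sector_mixed_model(sector_table(co))
pc <- pca_traits(tt)                      # 17 standard variables
autoplot(pc)
```

`run_pipeline()` wraps all of this (from MTG files or generator settings)
and writes segment, axis, branch-event, trait, sector, ANOVA, mixed-model
and PCA tables as CSV.

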