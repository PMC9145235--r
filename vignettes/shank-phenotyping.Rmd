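---
title: "Zone-based vascular-bundle phenotyping and downstream genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-based vascular-bundle phenotyping and downstream genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The shank — the short branch stem that connects a maize stalk to its ear —
carries every assimilate that ends up in the grain through its vascular
bundles. Micro-CT slices of shank internodes show those bundles as bright
discrete regions inside the stained tissue, denser and smaller near the
rind, sparser and larger toward the pith. Quantifying that anatomy across
an association panel means answering three questions per image: where is
the tissue, where are the bundles, and which functional zone — epidermis
(EZ), periphery (PZ) or inner (IZ) — does each bundle belong to. From
those answers a fixed registry of 36 traits is computed, and the traits
feed a standard quantitative-genetics chain: fold-variation summaries,
Spearman correlation and trait clustering, subgroup ANOVA with Duncan's
multiple range test, REML variance components with BLUP and broad-sense
heritability, and a multi-method genome-wide association scan whose hits
are intersected across methods before SNP-to-gene annotation.

`shankvb` implements that entire chain on synthetic data. No real CT
images or genotype panels ship with the package; instead a first-class
generator module produces cross-section images with exact ground truth,
phenotype panels with known variance components, and genotype matrices
with planted QTL. Every downstream stage is therefore testable against a
known answer.

## The imaging pipeline

**Segmentation.** The section is the largest 8-connected component above
an Otsu threshold, holes filled. Three well-separated intensity bands
(background, tissue, bundles) make a single global threshold sufficient;
for real scans a fixed threshold can be supplied instead.

**Bundle detection.** A second Otsu threshold, computed on the within-mask
histogram only, separates bundles from tissue. Candidate components must
pass three validity filters — an area window (default 0.005–0.5 mm²) and a
minimum solidity (area / convex area, default 0.5). Candidates that fail
are reported in a rejects table, never silently dropped and never split:
fused bundle pairs are rejected (by area or solidity) rather than
guessed apart.

**Zone partition.** EZ is the boundary band of depth 0.08 mm by default,
near the population-median epidermis thickness of shank sections; depth
is measured by Euclidean distance transform, so the definition works for
every section shape. The PZ/IZ boundary uses the radial density of bundle
centroid depths: the profile is smoothed with a fixed 0.25 mm kernel and
the boundary placed at the first substantial valley after the peripheral
peak. A candidate minimum counts as a valley only when the density
rebounds by at least 20% of the peak height; radial profiles that merely
decline after the peak — the typical picture when inner bundles thin out
with depth — have no valley, and the partition falls back to a fixed PZ
width of 1.0 mm. A `fixed_depth(d)` policy is also available and is what
the fallback uses internally. Labels partition the mask exactly by
construction; a centroid on a boundary pixel goes to the inner zone, and
a bundle centroid inside EZ is assigned to PZ because bundles are never
epidermal.

**Traits.** The registry holds 36 traits in five categories
(cross-section 7, epidermis 2, periphery 7, inner 7, vascular bundle 13).
Geometry per region: area from pixel counts; convex area from the hull of
the pixel-corner point set (so a single pixel has convex area one pixel);
circumcircle area from a minimal enclosing circle (Welzl's algorithm on
the hull vertices); axis lengths from the moment-equivalent ellipse with
the 1/12 per-pixel variance correction — a near-circular section then has
a length-width ratio just above 1, matching how such ratios behave in
practice. Zone thicknesses are measured along rays cast from the section
centroid: EZ and PZ thickness as the mean run length of the band, IZ
thickness as the mean distance from centroid to the PZ/IZ boundary.

Two trait names exist in the field without a published formula, and the
package fixes definitions for them: the separation ratio SRVB is the mean
nearest-neighbour centroid distance divided by the mean bundle equivalent
diameter, and the area ratio ARIVB is the mean bundle area in PZ divided
by the mean bundle area in IZ (dimensionless, below 1 whenever inner
bundles are larger, consistent with the published population range of
0.424–0.899). VB_LWR is implemented as its name says — mean long axis
over mean short axis, hence at least 1 — although published tables print
it on an inconsistent scale (median 0.004); the definition here is the
documented one, not a curve-fit to that scale.

### Numerical choices

* **Perimeter.** The 8-connected contour chain with raw weights
  (1, √2) overestimates smooth digitized outlines by about 5% — measured
  +4.1% to +5.1% on disks of radius 30–120 px — so the package uses the
  corner-corrected chain weights 0.948 (axial) and 1.340 (diagonal),
  which bring the disk bias to under 1.5%. The trade-off is standard:
  axis-aligned straight edges are underestimated by about 5%, acceptable
  for the round-ish regions measured here.
* **Connectivity.** Foreground is 8-connected (a 4-connected labelling
  plus a union-find merge over diagonal contacts), background
  4-connected.
* **Ties.** Boundary-pixel centroids go to the inner zone; centroid
  pixels are found by ceiling of the continuous coordinate. Both rules
  are deterministic.

## The synthetic-data generators

The section generator renders the five shank outline classes (round,
crescent, bell, horseshoe, irregular — the latter three by Boolean
carving of a secondary disk, a chord, or a wedge, and by low-order radial
harmonics) at 13.55 µm/pixel, the resolution of high-quality stem
micro-CT. Intensities are three bands (0 background, 120 tissue, 220
bundles) with additive Gaussian noise of sd 8: separable by a single
threshold yet not trivially noise-free, emulating iodine-stained CT
contrast without modelling physics. Default anatomy: a 7 mm outer
radius; 80 periphery bundles of equivalent radius 0.13 ± 0.015 mm placed
in a 1.0 mm annulus inside the 0.08 mm epidermis; 90 inner bundles of
0.17 ± 0.02 mm uniform in the remaining disk — peripheral bundles denser
and smaller, inner bundles sparser and larger, with mean areas in
proportion ARIVB ≈ 0.6. Placement is rejection sampling with a 0.45 mm
minimum centroid gap; radii are truncated at ±2.5 sd so the gap
guarantees non-overlap, and a 0.05 mm stand-off band keeps centroids off
the planted PZ/IZ boundary so planted zone labels stay well-defined
under rasterization. Infeasible packing requests fail with an error
naming the first unplaceable bundle. Identical seeds give bit-identical
rasters.

What the generator does **not** emulate: partial-volume blur, ring and
beam-hardening artefacts, intensity gradients across the slice, touching
bundles, and epidermal bundles. Perfect recall/precision on these scenes
therefore demonstrates correctness of the pipeline's logic, not expected
performance on real CT data.

The panel generator draws observations from
`y = mu + line + environment + line:environment + residual` with variances
(Vg, Vgl, Ve) and fixed-size environment draws (`env_sd`, default 0 —
there is no separate environment variance parameter, and a zero default
keeps the degenerate all-variances-zero panel exactly constant).
The truth object stores every drawn effect, and re-pooling them
reproduces the observations with zero residual. Default conditions are a
202-line, 2-environment, 3-replicate trial.

The genotype generator draws Hardy–Weinberg dosages at frequencies
uniform in the MAF range (default 0.05–0.5), redraws columns whose
realized MAF falls outside the range, applies missingness last, and
scales phenotype noise so planted QTL explain exactly the requested
share of variance in expectation.

## Quantitative genetics

Variance components are estimated by EM-REML on the mixed-model
equations, with environments fixed and line and line-by-environment
effects random — the usual parameterization for a two-location trial,
and the one whose components enter the entry-mean heritability
`H² = Vg / (Vg + Vgl/L + Ve/(L·R))`. The response is centred before the
quadratic forms so results are invariant to constant shifts at any data
scale. Initialization is the balanced-ANOVA method of moments, which on
balanced interior data *is* the REML solution, so EM typically converges
in one or two iterations (relative-change tolerance 1e-8, maximum 1000
iterations; non-convergence is flagged and warned, never silent).

Two boundary situations get special handling. When the ANOVA residual
mean square is numerically zero on balanced data, the ANOVA estimators
are returned directly (EM would need thousands of iterations to push Ve
to zero). When a component's REML estimate is exactly zero, EM
approaches the boundary only asymptotically — geometrically or, at the
boundary itself, harmonically — so a component is snapped to zero when
its Aitken-extrapolated limit is numerically zero, or when it has
decreased for 50 consecutive iterations and the extrapolated limit sits
well below the current value (an interior fixed point extrapolates to
roughly the current value instead). On panels where lme4 converges, the
EM estimates and the conditional-mode BLUPs agree with lme4 to four
decimals; lme4 serves only as an independent cross-check in the test
suite, never as the implementation.

Duncan's multiple range test uses studentized-range quantiles from R's
`qtukey` at protection level `1-(1-α)^(r-1)` for a range of `r` means,
the harmonic mean of group sizes in the standard error, and the
descending-means sweep for letters, so letter groups are always
contiguous; with two groups the decision provably coincides with the
pooled-variance t-test (`q = √2·t`), which the suite verifies
numerically.

## Association

Two scan methods exercise the multi-method contract: per-SNP simple
linear regression (Wald t), and the same regression with the top k = 3
genotype principal components as covariates. PCs approximate structure
correction; they are not a kinship mixed model, and the package makes no
claim of equivalence. Missing dosages are mean-imputed for testing only;
MAF and call rate are always computed on observed calls. Monomorphic
SNPs get p = 1 and a flag. The significance threshold is the
reciprocal-SNP-count rule `p ≤ 1/N` (a secondary fixed threshold such as
2e-4 can be passed explicitly); hits are intersected across methods
before annotation, which assigns a gene to a SNP when the position falls
within the 1-based inclusive gene interval, optionally widened by a
flank (default 0 — no window is asserted, the flank is a parameter).
Enrichment is an upper-tail hypergeometric test over a finite universe,
database-free.

One testing subtlety: 10,000 null tests that share a single permuted
response are positively correlated, so an empirical type-I rate from one
permutation fluctuates more than the binomial CI allows. Calibration
checks therefore average the rate over five independent permutations
before applying the binomial interval.

## Problem sizes used by the checks

The test suite measures: geometry against brute-force hull and
enclosing-circle oracles on 100 random blobs; phenotyping recovery on 50
full-size default sections (seeds 1–50); REML recovery on 200 simulated
panels at the default trial conditions; association calibration over
5 × 10,000 permuted SNP tests and power over 200 replicates of a planted
QTL explaining 20% of variance among 5,000 SNPs. The acceptance script
reports the same quantities at reduced replication (8 sections, 50
panels, 100 power replicates) — sizes chosen so a desk machine
reproduces the numbers in a few minutes.

## Known limitations

* Classical thresholding stands in for learned segmentation; real scans
  with stain gradients will need the fixed-threshold policy or external
  preprocessing.
* Fused bundles are rejected, not split, so heavily crowded sections
  will undercount.
* The density-valley boundary needs a genuine density contrast; sections
  without one silently use the fixed 1.0 mm PZ width (the partition
  object records which policy fired).
* H²'s L and R are the design's nominal values; unbalanced panels are
  fit through the general mixed-model equations but the heritability
  formula itself assumes balance.
* PC adjustment bounds, but does not eliminate, confounding by cryptic
  relatedness.
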