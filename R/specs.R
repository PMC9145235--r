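## Specification objects for the synthetic generators. Each constructor
## validates its invariants and returns a classed list so downstream code
## can dispatch / assert cheaply.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Cross-section shape specification
#'
#' Describes the outline of a synthetic shank cross-section. Five shape
#' classes are supported: `round`, `crescent`, `bell`, `horseshoe` and
#' `irregular`. Crescent/bell/horseshoe are built by carving a secondary
#' disk or wedge from the primary disk; `irregular` perturbs the round
#' outline with low-order radial harmonics.
#'
#' @param shape One of `"round"`, `"crescent"`, `"bell"`, `"horseshoe"`,
#'   `"irregular"`.
#' @param outer_radius Outer radius of the primary disk, mm.
#' @param resolution Physical pixel size, micrometres per pixel. The default
#'   13.55 matches high-resolution micro-CT slices of maize stems.
#' @param notch_depth Depth of the carved notch (crescent/horseshoe/bell),
#'   mm; must be smaller than `outer_radius`.
#' @param notch_angle Angular width of the carved wedge (horseshoe), radians.
#' @param eccentricity Relative offset of the carving disk centre
#'   (crescent/bell), dimensionless in [0, 2].
#' @param harmonics Amplitude of the radial harmonic perturbation
#'   (`irregular`), as a fraction of `outer_radius`.
#' @return A `section_shape_spec` object.
#' @export
section_shape_spec <- function(shape = c("round", "crescent", "bell",
                                         "horseshoe", "irregular"),
                               outer_radius = 7,
                               resolution = 13.55,
                               notch_depth = outer_radius / 3,
                               notch_angle = pi / 3,
                               eccentricity = 1.2,
                               harmonics = 0.08) {
  shape <- match.arg(shape)
  if (!is.numeric(outer_radius) || length(outer_radius) != 1L ||
      !is.finite(outer_radius) || outer_radius <= 0)
    stopf("outer_radius must be a single positive number (mm)")
  if (!is.numeric(resolution) || resolution <= 0)
    stopf("resolution must be positive (um/pixel)")
  if (notch_depth >= outer_radius)
    stopf("notch_depth (%.3f mm) must be smaller than outer_radius (%.3f mm)",
          notch_depth, outer_radius)
  structure(list(shape = shape, outer_radius = outer_radius,
                 resolution = resolution, notch_depth = notch_depth,
                 notch_angle = notch_angle, eccentricity = eccentricity,
                 harmonics = harmonics),
            class = "section_shape_spec")
}

#' Vascular-bundle layout specification
#'
#' Controls how many bundles are planted in the periphery (PZ) and inner
#' (IZ) zones and how large they are. Defaults emulate the anatomy of a
#' shank basal internode: peripheral bundles denser and smaller, inner
#' bundles sparser and larger.
#'
#' @param pz_count,iz_count Number of bundles planted in the periphery
#'   annulus and the inner disk.
#' @param pz_radius_mm,iz_radius_mm Length-2 vectors `c(mean, sd)` of the
#'   bundle equivalent radius in mm.
#' @param min_gap_mm Minimum centroid-to-centroid separation between any
#'   two bundles, mm.
#' @param pz_width_mm Width of the periphery placement annulus inside the
#'   epidermis, mm.
#' @param ez_mm Epidermis band depth, mm; bundles are planted deeper than
#'   this.
#' @param boundary_standoff_mm Half-width of the exclusion band around the
#'   planted PZ/IZ boundary, so no centroid straddles it.
#' @return A `bundle_spec` object.
#' @export
bundle_spec <- function(pz_count = 80, iz_count = 90,
                        pz_radius_mm = c(0.13, 0.015),
                        iz_radius_mm = c(0.17, 0.020),
                        min_gap_mm = 0.45,
                        pz_width_mm = 1.0,
                        ez_mm = 0.08,
                        boundary_standoff_mm = 0.05) {
  if (pz_count < 0 || iz_count < 0) stopf("bundle counts must be >= 0")
  if (pz_radius_mm[1] <= 0 || iz_radius_mm[1] <= 0)
    stopf("bundle radii must be positive")
  if (min_gap_mm < 0) stopf("min_gap_mm must be >= 0")
  structure(list(pz_count = as.integer(pz_count),
                 iz_count = as.integer(iz_count),
                 pz_radius_mm = pz_radius_mm, iz_radius_mm = iz_radius_mm,
                 min_gap_mm = min_gap_mm, pz_width_mm = pz_width_mm,
                 ez_mm = ez_mm, boundary_standoff_mm = boundary_standoff_mm),
            class = "bundle_spec")
}

#' Phenotype-panel simulation specification
#'
#' Parameters of the multi-environment trial simulator: observations follow
#' y = mu + line + environment + line:environment + residual, with the line,
#' interaction and residual effects drawn at variances `Vg`, `Vgl`, `Ve`.
#' Environment effects are fixed-size random draws with standard deviation
#' `env_sd` (default 0, i.e. no environment shift).
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param L Number of environments (>= 1).
#' @param R Replicates per line-by-environment cell (>= 1).
#' @param mu Grand mean, trait units.
#' @param Vg,Vgl,Ve Genotypic, line-by-environment and residual variances
#'   (trait units squared, >= 0).
#' @param env_sd Standard deviation of the per-environment effects.
#' @return A `panel_sim_spec` object.
#' @export
panel_sim_spec <- function(n_lines = 200, L = 2, R = 3, mu = 100,
                           Vg = 1, Vgl = 0.2, Ve = 0.5, env_sd = 0) {
  if (n_lines < 2) stopf("n_lines must be >= 2")
  if (L < 1 || R < 1) stopf("L and R must be >= 1")
  if (any(c(Vg, Vgl, Ve) < 0)) stopf("variance components must be >= 0")
  if (env_sd < 0) stopf("env_sd must be >= 0")
  structure(list(n_lines = as.integer(n_lines), L = as.integer(L),
                 R = as.integer(R), mu = mu, Vg = Vg, Vgl = Vgl, Ve = Ve,
                 env_sd = env_sd),
            class = "panel_sim_spec")
}

#' Genotype-matrix simulation specification
#'
#' @param n_lines Number of lines.
#' @param m_snps Number of SNPs.
#' @param maf_range Interval in (0, 0.5] from which per-SNP allele
#'   frequencies are drawn; realized minor-allele frequencies are enforced
#'   to fall in this interval before missingness.
#' @param missing_rate Fraction of entries set missing, in [0, 1).
#' @param qtl Data.frame with columns `snp` (1-based SNP index) and
#'   `effect` (additive effect per dosage unit), or NULL for none.
#' @param h2_marker Proportion of phenotypic variance explained by the
#'   planted QTL together, in [0, 1).
#' @param n_chrom Number of chromosomes SNPs are spread over.
#' @return A `geno_sim_spec` object.
#' @export
geno_sim_spec <- function(n_lines = 202, m_snps = 5000,
                          maf_range = c(0.05, 0.5), missing_rate = 0,
                          qtl = NULL, h2_marker = 0, n_chrom = 10) {
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("maf_range must be an interval within (0, 0.5]")
  if (h2_marker < 0 || h2_marker >= 1) stopf("h2_marker must be in [0, 1)")
  if (!is.null(qtl)) {
    if (!all(c("snp", "effect") %in% names(qtl)))
      stopf("qtl must have columns 'snp' and 'effect'")
    if (any(qtl$snp < 1 | qtl$snp > m_snps))
      stopf("qtl SNP index out of range 1..%d", m_snps)
  }
  structure(list(n_lines = as.integer(n_lines), m_snps = as.integer(m_snps),
                 maf_range = maf_range, missing_rate = missing_rate,
                 qtl = qtl, h2_marker = h2_marker,
                 n_chrom = as.integer(n_chrom)),
            class = "geno_sim_spec")
}
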