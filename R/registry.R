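#' Registry of the 36 zone-resolved shank traits
#'
#' Returns the full catalogue of traits computed by
#' [compute_trait_vector()]: abbreviation, category, unit and a short
#' description. The registry partitions into five categories —
#' cross-section (7), epidermis zone (2), periphery zone (7), inner zone
#' (7) and vascular bundle (13) — for a total of 36 traits.
#'
#' Units follow field convention: lengths in mm, areas in mm^2, densities
#' in bundles per mm^2; ratios and counts are dimensionless.
#'
#' @return A data.frame with columns `trait`, `category`, `unit`,
#'   `description`, one row per trait, in canonical order.
#' @export
#' @examples
#' reg <- trait_registry()
#' table(reg$category)
trait_registry <- function() {
  row <- function(trait, category, unit, description) {
    data.frame(trait = trait, category = category, unit = unit,
               description = description, stringsAsFactors = FALSE)
  }
  cs <- "cross_section"; ez <- "epidermis_zone"; pz <- "periphery_zone"
  iz <- "inner_zone"; vb <- "vascular_bundle"
  out <- rbind(
    row("SZ_SA",      cs, "mm",         "Short axis length of the slice zone"),
    row("SZ_P",       cs, "mm",         "Perimeter of the slice zone"),
    row("SZ_LWR",     cs, "-",          "Length-width ratio of the slice zone"),
    row("SZ_LA",      cs, "mm",         "Long axis length of the slice zone"),
    row("SZ_CCA",     cs, "mm^2",       "Circumcircle area of the slice zone"),
    row("SZ_CA",      cs, "mm^2",       "Convex area of the slice zone"),
    row("SZ_A",       cs, "mm^2",       "Area of the slice zone"),
    row("EZ_T",       ez, "mm",         "Thickness of the epidermis"),
    row("EZ_A",       ez, "mm^2",       "Area of the epidermis"),
    row("PZ_VB_N",    pz, "-",          "Number of vascular bundles in the periphery zone"),
    row("PZ_VB_D",    pz, "number/mm^2","Density of vascular bundles in the periphery zone"),
    row("PZ_VB_CAR",  pz, "-",          "Mean convex area ratio of periphery-zone bundles"),
    row("PZ_VB_CA",   pz, "mm^2",       "Total convex area of periphery-zone bundles"),
    row("PZ_VB_A",    pz, "mm^2",       "Total area of periphery-zone bundles"),
    row("PZ_T",       pz, "mm",         "Thickness of the periphery zone"),
    row("PZ_A",       pz, "mm^2",       "Area of the periphery zone"),
    row("IZ_VB_N",    iz, "-",          "Number of vascular bundles in the inner zone"),
    row("IZ_VB_D",    iz, "number/mm^2","Density of vascular bundles in the inner zone"),
    row("IZ_VB_CAR",  iz, "-",          "Mean convex area ratio of inner-zone bundles"),
    row("IZ_VB_CA",   iz, "mm^2",       "Total convex area of inner-zone bundles"),
    row("IZ_VB_A",    iz, "mm^2",       "Total area of inner-zone bundles"),
    row("IZ_T",       iz, "mm",         "Thickness of the inner zone"),
    row("IZ_A",       iz, "mm^2",       "Area of the inner zone"),
    row("VB_SAave",   vb, "mm",         "Mean short axis length of the vascular bundles"),
    row("VB_Pave",    vb, "mm",         "Mean perimeter of the vascular bundles"),
    row("VB_N",       vb, "-",          "Total number of vascular bundles"),
    row("VB_LWR",     vb, "-",          "Length-width ratio of the vascular bundles"),
    row("VB_LAave",   vb, "mm",         "Mean long axis length of the vascular bundles"),
    row("VB_D",       vb, "number/mm^2","Density of the vascular bundles"),
    row("VB_CCAave",  vb, "mm^2",       "Mean circumcircle area of the vascular bundles"),
    row("VB_CAR",     vb, "-",          "Mean convex area ratio of the vascular bundles"),
    row("VB_CAave",   vb, "mm^2",       "Mean convex area of the vascular bundles"),
    row("VB_Aave",    vb, "mm^2",       "Mean area of the vascular bundles"),
    row("VB_A",       vb, "mm^2",       "Total area of the vascular bundles"),
    row("SRVB",       vb, "-",          "Separation ratio of the vascular bundles"),
    row("ARIVB",      vb, "-",          "Area ratio of individual vascular bundles")
  )
  rownames(out) <- NULL
  out
}

#' Names of the 36 registered traits, in canonical order
#' @return Character vector of length 36.
#' @export
trait_names <- function() trait_registry()$trait
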