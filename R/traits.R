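#' Wood density from Archimedes displacement
#'
#' Oven-dry mass divided by water-saturated volume, where the volume is
#' obtained from the mass of water displaced by the soaked twig (water
#' density taken as 1.0 g cm^-3).
#'
#' @param dry_mass_g Oven-dry mass, g.
#' @param displaced_water_mass_g Mass of displaced water, g (= volume cm^3).
#' @return Density in g cm^-3.
#' @export
wood_density <- function(dry_mass_g, displaced_water_mass_g) {
  check_positive(dry_mass_g)
  check_positive(displaced_water_mass_g)
  dry_mass_g / displaced_water_mass_g
}

#' Ellipse area from two perpendicular diameters
#'
#' Used for pith area and sapwood cross-sectional area, both measured as
#' two perpendicular calliper diameters.
#'
#' @param d1,d2 Perpendicular diameters (same unit).
#' @return Area `pi * d1 * d2 / 4` in squared input units.
#' @export
ellipse_area <- function(d1, d2) {
  check_positive(d1)
  check_positive(d2)
  pi * d1 * d2 / 4
}

#' Composite tissue fractions
#'
#' Sums the elementary tissue fractions into the standard composites:
#' total parenchyma `TPF = APF + RPF`, total fibre `TFF = FLF + FWF`,
#' total vessel `TVF = VLF + VWF`, and the fibre-plus-vessel wall
#' fraction `WF = FWF + VWF`.
#'
#' @param fractions A `fraction_vector`, or a named numeric vector with
#'   elements `AXIAL_PARENCHYMA`, `RAY_PARENCHYMA`, `FIBRE_LUMEN`,
#'   `FIBRE_WALL`, `VESSEL_LUMEN`, `VESSEL_WALL`.
#' @return Named numeric vector `c(TPF, TFF, TVF, WF)`.
#' @export
composite_fractions <- function(fractions) {
  f <- if (inherits(fractions, "fraction_vector")) {
    fraction_of(fractions)
  } else fractions
  c(TPF = unname(f["AXIAL_PARENCHYMA"] + f["RAY_PARENCHYMA"]),
    TFF = unname(f["FIBRE_LUMEN"] + f["FIBRE_WALL"]),
    TVF = unname(f["VESSEL_LUMEN"] + f["VESSEL_WALL"]),
    WF = unname(f["FIBRE_WALL"] + f["VESSEL_WALL"]))
}

#' Specific leaf area
#'
#' Leaf area per unit dry mass, so that leaf mass per area is its
#' reciprocal (`LMA = 1 / SLA`).
#'
#' @param leaf_area_cm2 Projected leaf area, cm^2.
#' @param leaf_dry_mass_g Dry mass of the same leaves, g.
#' @return SLA in cm^2 g^-1.
#' @export
specific_leaf_area <- function(leaf_area_cm2, leaf_dry_mass_g) {
  check_positive(leaf_area_cm2)
  check_positive(leaf_dry_mass_g)
  leaf_area_cm2 / leaf_dry_mass_g
}

#' Leaf area to sapwood area ratio
#'
#' Total leaf area carried by a twig divided by its sapwood
#' cross-sectional area. Total leaf area is the area of the subsample used
#' for SLA plus the remaining leaf mass converted to area through SLA;
#' sapwood area is the ellipse of the two perpendicular wood diameters
#' (under bark, excluding pith).
#'
#' @param sla SLA in cm^2 g^-1.
#' @param sla_subset_area_cm2 Leaf area of the SLA subsample, cm^2.
#' @param remaining_leaf_mass_g Dry mass of the remaining leaves, g
#'   (0 allowed).
#' @param wood_diameters_mm Two perpendicular wood diameters, mm.
#' @return A named vector: `LASA` (cm^2 cm^-2), `total_leaf_area_cm2`,
#'   `sapwood_area_cm2`.
#' @export
leaf_area_sapwood_ratio <- function(sla, sla_subset_area_cm2,
                                    remaining_leaf_mass_g,
                                    wood_diameters_mm) {
  check_positive(sla)
  check_positive(sla_subset_area_cm2)
  if (remaining_leaf_mass_g < 0) {
    stop("`remaining_leaf_mass_g` must be >= 0", call. = FALSE)
  }
  stopifnot(length(wood_diameters_mm) == 2L)
  sa_cm2 <- ellipse_area(wood_diameters_mm[1] / 10, wood_diameters_mm[2] / 10)
  total <- sla_subset_area_cm2 + sla * remaining_leaf_mass_g
  c(LASA = unname(total / sa_cm2),
    total_leaf_area_cm2 = unname(total),
    sapwood_area_cm2 = unname(sa_cm2))
}

#' Modulus of elasticity from a three-point bending test
#'
#' Standard beam theory for a centrally loaded, simply supported beam:
#' `MOE = slope * span^3 / (48 I)` with the second moment of area of an
#' elliptical section `I = pi * a * b^3 / 64`, where `b` is the diameter
#' in the loading direction. The tested segment (including bark and pith)
#' should be at least 20 times longer than its diameter to keep shear
#' deflection negligible; shorter spans warn, or error in strict mode.
#'
#' @param bending_slope_N_per_mm Slope of the force-deflection line, N/mm.
#' @param span_mm Support span, mm.
#' @param diameters_mm Diameters `(a, b)` of the elliptical section, mm;
#'   `b` is measured in the loading direction. A single value is treated
#'   as a circular section.
#' @param strict If `TRUE`, violating the 20:1 span rule is an error.
#' @return MOE in MPa (N mm^-2).
#' @export
#' @examples
#' modulus_of_elasticity(10, 100, 5)  # ~6790 MPa for a 5 mm circular twig
modulus_of_elasticity <- function(bending_slope_N_per_mm, span_mm,
                                  diameters_mm, strict = FALSE) {
  check_positive(bending_slope_N_per_mm)
  check_positive(span_mm)
  check_positive(diameters_mm)
  if (length(diameters_mm) == 1L) diameters_mm <- rep(diameters_mm, 2L)
  if (span_mm < 20 * max(diameters_mm)) {
    msg <- sprintf(
      "span (%.1f mm) is under 20 times the diameter (%.1f mm); shear may bias MOE",
      span_mm, max(diameters_mm))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  I <- pi * diameters_mm[1] * diameters_mm[2]^3 / 64
  unname(bending_slope_N_per_mm * span_mm^3 / (48 * I))
}

#' Approximate cell-wall material density
#'
#' Wood density divided by the wall fraction of the cross-section
#' (fibre wall + vessel wall). This is an approximation: it attributes
#' all dry mass to the walls of fibres and vessels, ignoring parenchyma
#' wall material and cell contents, and is intended only as a
#' plausibility check against the ~1.5 g cm^-3 density of pure cell-wall
#' material.
#'
#' @param wood_density Wood density, g cm^-3.
#' @param wall_fraction Wall fraction (fibre wall + vessel wall), in (0, 1].
#' @return Approximate wall material density, g cm^-3.
#' @export
wall_material_density <- function(wood_density, wall_fraction) {
  check_positive(wood_density)
  if (any(wall_fraction <= 0) || any(wall_fraction > 1)) {
    stop("`wall_fraction` must be in (0, 1]", call. = FALSE)
  }
  wood_density / wall_fraction
}

#' Aggregate a replicate-level trait table to species means
#'
#' Arithmetic means per trait for each species-at-site; a species sampled
#' at two sites is kept as two separate entities. Missing replicate values
#' are dropped trait-wise; a trait missing for all replicates of a species
#' propagates as `NA`.
#'
#' @param table A trait table with columns `species`, `site`, `replicate`
#'   and numeric trait columns (see [generate_trait_table()]).
#' @return A tibble with one row per species-at-site.
#' @export
species_means <- function(table) {
  stopifnot(all(c("species", "site") %in% names(table)))
  num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                 "replicate")
  dplyr::summarise(
    dplyr::group_by(table, .data$species, .data$site),
    dplyr::across(dplyr::all_of(num), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' N-fold variation of a trait
#'
#' Ratio of the largest value to the smallest non-zero value. Zeros are
#' excluded from the denominator (a trait absent in some species would
#' otherwise have infinite fold variation).
#'
#' @param values Numeric vector with at least one positive value.
#' @return `max(values) / min(values[values > 0])`.
#' @export
#' @examples
#' nfold_variation(c(0.38, 0.5, 0.62))  # 1.63
nfold_variation <- function(values) {
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  if (!length(pos)) stop("all values are zero", call. = FALSE)
  max(values) / min(pos)
}

#' Trait summary table (range, mean, n-fold variation)
#'
#' Summarises each trait of a species-level table by its range, mean and
#' n-fold variation. For traits that are zero in some species (absent
#' tissues such as small conduits or mucilage canals), the reported low,
#' mean and n-fold use only the species where the tissue is present, and
#' the `n_nonzero` column records how many species that is.
#'
#' @param table Species-level trait table (see [species_means()]).
#' @param traits Trait columns to summarise; default all numeric columns.
#' @param digits Optional display rounding applied to low/high/average
#'   (`NULL` = none); n-fold is additionally rounded to 1 decimal.
#' @return A tibble with columns `trait`, `low`, `high`, `average`,
#'   `nfold`, `n`, `n_nonzero`, `zeros_excluded`.
#' @export
summarize_traits <- function(table, traits = NULL, digits = NULL) {
  if (nrow(table) == 0L) stop("empty trait table", call. = FALSE)
  if (is.null(traits)) {
    traits <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      "replicate")
  }
  rows <- lapply(traits, function(tr) {
    v <- table[[tr]]
    v <- v[!is.na(v)]
    pos <- v[v > 0]
    if (!length(pos)) {
      # a tissue absent from every species has no defined range or fold
      return(tibble::tibble(trait = tr, low = NA_real_, high = max(v),
                            average = NA_real_, nfold = NA_real_,
                            n = length(v), n_nonzero = 0L,
                            zeros_excluded = TRUE))
    }
    has_zero <- length(pos) < length(v)
    use <- if (has_zero) pos else v
    tibble::tibble(
      trait = tr,
      low = min(use), high = max(v), average = mean(use),
      nfold = nfold_variation(v),
      n = length(v), n_nonzero = length(pos),
      zeros_excluded = has_zero
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(digits)) {
    out$low <- round(out$low, digits)
    out$high <- round(out$high, digits)
    out$average <- round(out$average, digits)
  }
  out$nfold <- round(out$nfold, 1)
  out
}
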