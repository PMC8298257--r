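#' Material property table
#'
#' Poroelastic material cards for every constituent of the model: the
#' granulation tissue initially filling the callus growth region, cortical
#' bone, bone marrow, the fixator materials (PEEK body, titanium pins; used
#' only to derive the fixator spring stiffness), and the three tissues the
#' cells deposit (fibrous tissue, cartilage, bone). Young's modulus in MPa,
#' permeability in units of 1e-14 m^4/(N s), bulk moduli in MPa. The
#' `porosity` column feeds the poroelastic storage term; tissue-level
#' porosity is not separately reported for this model family, so a single
#' soft-tissue value is used by default and is configurable.
#'
#' @param porosity Fluid volume fraction used for all poroelastic phases.
#' @return A data frame with one row per material.
#' @export
default_material_table <- function(porosity = 0.8) {
  m <- data.frame(
    material = c("granulation", "cortex", "marrow", "fixator_peek",
                 "fixator_titanium", "fibrous", "cartilage", "bone"),
    young_modulus = c(0.2, 5000, 2, 3800, 110000, 2, 10, 5000),
    poisson_ratio = c(0.167, 0.3, 0.167, 0.3, 0.3, 0.167, 0.3, 0.3),
    permeability = c(1, 0.001, 1, NA, NA, 1, 0.5, 3.7),
    bulk_modulus_grain = c(2300, 13920, 2300, NA, NA, 2300, 3700, 13940),
    bulk_modulus_fluid = c(2300, 3200, 2300, NA, NA, 2300, 2300, 2300),
    porosity = c(porosity, porosity, porosity, NA, NA,
                 porosity, porosity, porosity)
  )
  rownames(m) <- m$material
  m
}

# Properties that participate in the rule-of-mixtures average.
HOMOG_PROPS <- c("young_modulus", "poisson_ratio", "permeability",
                 "bulk_modulus_grain", "bulk_modulus_fluid", "porosity")

#' Homogenize tissue fractions into per-element material cards
#'
#' Every scalar property of an element is the volume-fraction-weighted
#' arithmetic mean (rule of mixtures) of the properties of the tissues
#' present in it. Fractions must sum to one per element; granulation tissue
#' is the filler phase.
#'
#' @param fractions Numeric matrix (elements x tissues) with columns named
#'   `granulation`, `fibrous`, `cartilage`, `bone`.
#' @param cards Material table as from [default_material_table()].
#' @return Data frame of homogenized properties, one row per element.
#' @export
#' @examples
#' fr <- matrix(c(0.5, 0, 0, 0.5), 1,
#'              dimnames = list(NULL, c("granulation", "fibrous",
#'                                      "cartilage", "bone")))
#' homogenize_materials(fr)$young_modulus  # 0.5*0.2 + 0.5*5000
homogenize_materials <- function(fractions, cards = default_material_table()) {
  if (is.null(colnames(fractions)))
    stop("homogenize_materials: fractions must have tissue column names",
         call. = FALSE)
  unknown <- setdiff(colnames(fractions), cards$material)
  if (length(unknown))
    stop("homogenize_materials: unknown tissue label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rs <- rowSums(fractions)
  if (any(abs(rs - 1) > 1e-6))
    stop("homogenize_materials: fractions must sum to 1 per element",
         call. = FALSE)
  props <- as.matrix(cards[colnames(fractions), HOMOG_PROPS])
  out <- as.data.frame(fractions %*% props)
  names(out) <- HOMOG_PROPS
  out
}

#' Effective axial stiffness of the external fixator
#'
#' The fixator is reduced to a linear axial spring acting in parallel with
#' the bone/callus column. A unilateral external fixator loads the bone
#' through pin bending in series with the (much stiffer) axial body, so the
#' structural stiffness is far below the axial EA/L of the PEEK bar; the
#' default geometry yields a value of the order of 1e2 N/mm, typical for
#' rodent external fixators, and the result is an explicit calibration knob
#' of the mechanics stage.
#'
#' @param cards Material table (PEEK body and titanium pin moduli are read
#'   from it).
#' @param bar_section_mm2 Cross-section of the fixator body (mm^2).
#' @param bar_length_mm Free length of the body between pin clamps (mm).
#' @param pin_diameter_mm Pin diameter (mm).
#' @param pin_free_length_mm Free bending length of each pin (offset between
#'   bone surface and fixator body, mm).
#' @param n_pins Number of pins per bone fragment.
#' @return Effective axial stiffness (N/mm).
#' @export
fixator_stiffness <- function(cards = default_material_table(),
                              bar_section_mm2 = 9,
                              bar_length_mm = 20,
                              pin_diameter_mm = 1.0,
                              pin_free_length_mm = 6,
                              n_pins = 2) {
  e_bar <- cards["fixator_peek", "young_modulus"]
  e_pin <- cards["fixator_titanium", "young_modulus"]
  k_bar <- e_bar * bar_section_mm2 / bar_length_mm
  i_pin <- pi * pin_diameter_mm^4 / 64
  # cantilever tip stiffness per pin, pin group on each fragment in parallel
  k_pin_group <- n_pins * 3 * e_pin * i_pin / pin_free_length_mm^3
  # two pin groups (one per fragment) in series with the bar
  1 / (2 / k_pin_group + 1 / k_bar)
}
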