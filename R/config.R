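#' Domain configuration for the idealized femur-with-defect geometry
#'
#' Builds the geometric configuration of the simulation domain: an idealized
#' long bone (hollow cylinder with a medullary cavity), a transverse
#' osteotomy gap in the middle, and a callus growth region surrounding the
#' gap. All lengths are in millimetres except the cell-site spacing, which
#' follows the convention of being quoted in micrometres.
#'
#' The cortical and callus radii are model assumptions (the in vivo source
#' geometry is not published as numbers); they are deliberate defaults and
#' every one of them is configurable here.
#'
#' @param cortex_outer_radius Outer radius of the bone cortex (mm).
#' @param cortex_inner_radius Inner (endosteal) radius of the cortex (mm);
#'   everything inside is medullary cavity (marrow).
#' @param bone_segment_length Length of intact bone on each side of the gap (mm).
#' @param gap_width Width of the osteotomy gap (mm); the critical defect is 5 mm.
#' @param callus_outer_radius Outer radius of the callus growth region (mm).
#' @param callus_axial_overhang Axial extension of the callus growth region
#'   beyond each gap edge (mm).
#' @param marrow_margin Axial extension of the cell lattice beyond the callus
#'   span into the medullary cavity (mm); this is the reservoir from which
#'   marrow progenitors migrate toward the defect.
#' @param cell_site_spacing Lattice spacing between candidate cell positions
#'   (micrometres). The 60 um default makes one lattice hop per 2-h iteration
#'   equal to the 30 um/h progenitor migration rate.
#' @param fe_element_size_callus Hexahedral element edge length inside the
#'   callus bounding box (mm).
#' @param fe_element_size_outer Axial element size along the intact bone
#'   segments (mm).
#' @param bv_voxel_size Edge length of the cubic voxels used for the
#'   microCT-style bone-volume quantification (mm).
#' @param seed_fraction Fraction of marrow + periosteal cell sites initially
#'   occupied by mesenchymal stromal cells (MSCs).
#' @return An object of class `domain_config` (a validated list).
#' @export
#' @examples
#' cfg <- domain_config()
#' cfg$gap_width
domain_config <- function(cortex_outer_radius = 2.0,
                          cortex_inner_radius = 1.3,
                          bone_segment_length = 10.0,
                          gap_width = 5.0,
                          callus_outer_radius = 3.5,
                          callus_axial_overhang = 2.5,
                          marrow_margin = 2.0,
                          cell_site_spacing = 60,
                          fe_element_size_callus = 0.25,
                          fe_element_size_outer = 0.50,
                          bv_voxel_size = 0.04,
                          seed_fraction = 0.30) {
  cfg <- list(
    cortex_outer_radius = cortex_outer_radius,
    cortex_inner_radius = cortex_inner_radius,
    bone_segment_length = bone_segment_length,
    gap_width = gap_width,
    callus_outer_radius = callus_outer_radius,
    callus_axial_overhang = callus_axial_overhang,
    marrow_margin = marrow_margin,
    cell_site_spacing = cell_site_spacing,
    fe_element_size_callus = fe_element_size_callus,
    fe_element_size_outer = fe_element_size_outer,
    bv_voxel_size = bv_voxel_size,
    seed_fraction = seed_fraction
  )
  class(cfg) <- "domain_config"
  validate_domain_config(cfg)
  cfg
}

validate_domain_config <- function(cfg) {
  lens <- c("cortex_outer_radius", "cortex_inner_radius", "bone_segment_length",
            "gap_width", "callus_outer_radius", "callus_axial_overhang",
            "cell_site_spacing", "fe_element_size_callus",
            "fe_element_size_outer", "bv_voxel_size")
  for (f in lens) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("domain_config: '", f, "' must be a positive finite number",
           call. = FALSE)
  }
  if (cfg$marrow_margin < 0)
    stop("domain_config: 'marrow_margin' must be >= 0", call. = FALSE)
  if (cfg$cortex_inner_radius >= cfg$cortex_outer_radius)
    stop("domain_config: cortex inner radius must be smaller than the outer radius",
         call. = FALSE)
  if (cfg$callus_outer_radius < cfg$cortex_outer_radius)
    stop("domain_config: callus outer radius must not be smaller than the cortex outer radius",
         call. = FALSE)
  if (cfg$seed_fraction < 0 || cfg$seed_fraction > 1)
    stop("domain_config: seed_fraction must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.domain_config <- function(x, ...) {
  cat("<domain_config>\n")
  cat(sprintf("  cortex radius:  %.2f / %.2f mm (inner/outer)\n",
              x$cortex_inner_radius, x$cortex_outer_radius))
  cat(sprintf("  gap width:      %.2f mm, callus outer radius %.2f mm\n",
              x$gap_width, x$callus_outer_radius))
  cat(sprintf("  cell spacing:   %g um, FE element %g mm (callus)\n",
              x$cell_site_spacing, x$fe_element_size_callus))
  cat(sprintf("  BV voxel:       %g mm, seed fraction %g\n",
              x$bv_voxel_size, x$seed_fraction))
  invisible(x)
}

#' Scenario configuration for a healing simulation
#'
#' Assembles the full run configuration: which of the four treatment
#' scenarios to simulate, the cellular recruitment policy, the BMP-2 release
#' mode, the loading schedule and all numerical knobs.
#'
#' Scenarios mirror the four experimental groups: `control` (no external
#' stimulation, no exogenous BMP-2), `load` (weekly 500-um axial compression
#' episodes), `bmp2` (50 ug BMP-2 on a collagen sponge in the gap) and
#' `bmp2_load` (both).
#'
#' @param scenario One of `"control"`, `"load"`, `"bmp2"`, `"bmp2_load"`.
#' @param recruitment `"limited"` (MSC migration and proliferation stop after
#'   `recruitment_cutoff_day`) or `"continuous"`.
#' @param release `"sponge"` (biexponential carrier release) or `"fast"`
#'   (entire dose free in the gap at iteration 0); `"fast"` is only valid for
#'   BMP-2 scenarios.
#' @param duration_days Simulated time (days).
#' @param dt_hours Iteration length (hours).
#' @param bmp_dose_ug Exogenous BMP-2 dose (micrograms).
#' @param recruitment_cutoff_day Day after which limited recruitment zeroes
#'   MSC migration/proliferation.
#' @param stimulation_days Days on which the external 500-um stimulation
#'   episode replaces gait in the mechanics solve (crossbar removed).
#' @param stimulation_displacement_mm Amplitude of the stimulation episode (mm).
#' @param stimulation_rate_um_s Displacement ramp rate (um/s).
#' @param gait_force_n Axial compressive gait load (N); the habitual loading
#'   magnitude is a calibration knob, not a measured quantity.
#' @param gait_ramp_s Characteristic loading time of a gait episode (s), used
#'   as the consolidation interval of the poroelastic solve.
#' @param fixator_stiffness_n_mm Effective axial stiffness of the external
#'   fixator (N/mm); see [fixator_stiffness()].
#' @param output_days Days at which tissue/BV snapshots are recorded.
#' @param mech_backend `"fe"` (poroelastic finite elements) or `"surrogate"`
#'   (analytic interfragmentary-strain profile; same output contract, used
#'   for fast reduced-resolution studies).
#' @param apoptosis_stress_factor Multiplier on the apoptosis rate of
#'   differentiated cells sitting outside their favorable stimulus range.
#' @param materials Material table as from [default_material_table()], or
#'   `NULL` for the defaults; in a YAML configuration file individual
#'   properties can be overridden per material under a `materials:` block.
#' @param seed Integer RNG seed; a run is fully deterministic given the
#'   configuration and seed.
#' @param domain A [domain_config()] object.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("control", "load", "bmp2", "bmp2_load"),
                            recruitment = c("limited", "continuous"),
                            release = c("sponge", "fast"),
                            duration_days = 42,
                            dt_hours = 2,
                            bmp_dose_ug = 50,
                            recruitment_cutoff_day = 10,
                            stimulation_days = c(7, 14, 21, 28, 35),
                            stimulation_displacement_mm = 0.5,
                            stimulation_rate_um_s = 10,
                            gait_force_n = 7,
                            gait_ramp_s = 0.5,
                            fixator_stiffness_n_mm = 100,
                            output_days = c(14, 28, 42),
                            mech_backend = c("fe", "surrogate"),
                            apoptosis_stress_factor = 2,
                            materials = NULL,
                            seed = 1L,
                            domain = domain_config()) {
  scenario <- match.arg(scenario)
  recruitment <- match.arg(recruitment)
  release <- match.arg(release)
  mech_backend <- match.arg(mech_backend)
  stopifnot(inherits(domain, "domain_config"))
  if (duration_days <= 0 || dt_hours <= 0)
    stop("scenario_config: duration and time step must be positive", call. = FALSE)
  if (recruitment_cutoff_day <= 0)
    stop("scenario_config: recruitment cutoff day must be positive", call. = FALSE)
  has_bmp <- scenario %in% c("bmp2", "bmp2_load")
  if (has_bmp && bmp_dose_ug <= 0)
    stop("scenario_config: BMP-2 scenarios require a positive dose", call. = FALSE)
  if (release == "fast" && !has_bmp)
    stop("scenario_config: fast release is only valid for a BMP-2 scenario",
         call. = FALSE)
  if (!is.null(materials) &&
      !all(c("material", HOMOG_PROPS) %in% names(materials)))
    stop("scenario_config: materials must carry the standard property columns",
         call. = FALSE)
  cfg <- list(
    scenario = scenario,
    recruitment = recruitment,
    release = release,
    duration_days = duration_days,
    dt_hours = dt_hours,
    bmp_dose_ug = bmp_dose_ug,
    recruitment_cutoff_day = recruitment_cutoff_day,
    stimulation_days = stimulation_days,
    stimulation_displacement_mm = stimulation_displacement_mm,
    stimulation_rate_um_s = stimulation_rate_um_s,
    gait_force_n = gait_force_n,
    gait_ramp_s = gait_ramp_s,
    fixator_stiffness_n_mm = fixator_stiffness_n_mm,
    output_days = sort(unique(output_days)),
    mech_backend = mech_backend,
    apoptosis_stress_factor = apoptosis_stress_factor,
    materials = materials,
    seed = as.integer(seed),
    domain = domain
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  scenario:    %s (recruitment %s, release %s)\n",
              x$scenario, x$recruitment, x$release))
  cat(sprintf("  duration:    %g days at %g h per iteration, seed %d\n",
              x$duration_days, x$dt_hours, x$seed))
  cat(sprintf("  mechanics:   %s backend, gait %g N, fixator %g N/mm\n",
              x$mech_backend, x$gait_force_n, x$fixator_stiffness_n_mm))
  cat(sprintf("  outputs at:  day %s\n", paste(x$output_days, collapse = ", ")))
  invisible(x)
}

#' Reduced-resolution fixture configuration
#'
#' Produces a scenario configuration whose lattices are coarsened by
#' `1/scale` while the physical geometry (radii, gap width, callus extent)
#' is unchanged, so bone-volume outputs stay in the same units and range as
#' the full-resolution model. Each coarse lattice agent represents
#' `(spacing/60 um)^3` biological cells for tissue production and BMP-2
#' reaction counts, and migration hop probabilities are scaled so the
#' migration speed in um/h is preserved. Coarsened configurations default to
#' the analytic surrogate mechanics backend.
#'
#' @param scale Resolution factor in (0, 1]; `scale = 1` returns the default
#'   full-resolution configuration (FE backend).
#' @param ... Passed on to [scenario_config()] (e.g. `scenario`, `seed`,
#'   `duration_days`).
#' @return A `scenario_config` object.
#' @export
#' @examples
#' fx <- generate_fixture(0.25, scenario = "control", duration_days = 2)
generate_fixture <- function(scale = 0.25, ...) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("generate_fixture: scale must lie in (0, 1]", call. = FALSE)
  dom <- domain_config(
    cell_site_spacing = 60 / scale,
    fe_element_size_callus = 0.25 / scale,
    fe_element_size_outer = 0.50 / scale,
    bv_voxel_size = 0.04 / scale
  )
  backend <- if (scale < 1) "surrogate" else "fe"
  args <- list(...)
  if (is.null(args$mech_backend)) args$mech_backend <- backend
  args$domain <- dom
  do.call(scenario_config, args)
}

#' Read a scenario configuration from a YAML file
#'
#' The file may contain any subset of the arguments of [scenario_config()]
#' and, under the key `domain`, any subset of the arguments of
#' [domain_config()]; missing keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A `scenario_config` object.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dom_args <- raw$domain
  raw$domain <- NULL
  dom <- if (is.null(dom_args)) domain_config() else do.call(domain_config, dom_args)
  raw$domain <- dom
  if (!is.null(raw$materials)) {
    cards <- default_material_table()
    for (nm in names(raw$materials)) {
      if (!nm %in% cards$material)
        stop("read_scenario_config: unknown material '", nm, "'", call. = FALSE)
      for (prop in names(raw$materials[[nm]])) {
        if (!prop %in% HOMOG_PROPS)
          stop("read_scenario_config: unknown material property '", prop, "'",
               call. = FALSE)
        cards[nm, prop] <- raw$materials[[nm]][[prop]]
      }
    }
    raw$materials <- cards
  }
  do.call(scenario_config, raw)
}

#' Summarize the geometry of a configuration as JSON
#'
#' @param config A `domain_config`.
#' @param path Optional file to write to; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
geometry_summary_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "domain_config"))
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        pretty = TRUE)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
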