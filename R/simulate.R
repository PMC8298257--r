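#' Run a bone-defect healing scenario
#'
#' Drives the coupled iteration loop: carrier release, BMP-2
#' reaction/decay/diffusion, mechanics solve, MSC differentiation,
#' proliferation, chemotaxis-weighted migration, apoptosis, and tissue
#' production/degradation, in that fixed order, for `duration_days` at
#' `dt_hours` per iteration. Weekly external stimulation episodes (where the
#' scenario includes them) replace the gait load case, with the fixator
#' crossbar removed, on the first iteration of each stimulation day. The run
#' is fully deterministic for a given configuration and seed.
#'
#' @param config A [scenario_config()] (or [generate_fixture()]) object.
#' @param progress Print a short line at the end of every simulated day.
#' @return An object of class `healing_sim`: data frames `bv` (day, BV in
#'   mm^3, bridging flag), `census` (daily cell counts, total free BMP-2
#'   mass, spatial peak concentration, residual sponge mass), a list
#'   `snapshots` (tissue fractions, concentration field and BV report per
#'   output day), the `domain`, and the resolved `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_scenario(generate_fixture(0.2, scenario = "control",
#'                                      duration_days = 2,
#'                                      output_days = 2, seed = 1))
#' res$bv
#' }
run_scenario <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  domain <- build_domain(config$domain)
  cells <- seed_mscs(domain)
  rates0 <- default_rate_table()
  policy <- recruitment_policy(config$recruitment,
                               config$recruitment_cutoff_day)
  ranges <- differentiation_ranges()
  cards <- if (is.null(config$materials)) default_material_table()
           else config$materials
  ptab <- default_production_table()
  kin <- bmp_kinetics(dt_hours = config$dt_hours)
  grid <- bmp_grid(domain)

  has_bmp <- config$scenario %in% c("bmp2", "bmp2_load")
  has_stim <- config$scenario %in% c("load", "bmp2_load")
  gap_ids <- which(domain$agent_gap)
  sponge <- NULL
  if (has_bmp) {
    if (config$release == "fast") {
      grid <- fast_release_init(grid, config$bmp_dose_ug, gap_ids)
    } else {
      sponge <- sponge_state(config$bmp_dose_ug, gap_ids)
    }
  }

  fractions <- tissue_fractions(domain)
  mesh <- domain$mesh
  n_active <- length(mesh$active)
  n_agents <- prod(domain$agent_dims)

  # static material rows for non-tissue elements (cortex, marrow)
  mat <- as.data.frame(matrix(NA_real_, n_active, length(HOMOG_PROPS),
                              dimnames = list(NULL, HOMOG_PROPS)))
  for (reg in c(REGION_CORTEX, REGION_MARROW)) {
    rows <- which(mesh$active_region == reg)
    nm <- if (reg == REGION_CORTEX) "cortex" else "marrow"
    if (length(rows))
      mat[rows, ] <- cards[rep(nm, length(rows)), HOMOG_PROPS]
  }

  dth <- config$dt_hours
  iters_per_day <- max(1L, as.integer(round(24 / dth)))
  n_iter <- as.integer(round(config$duration_days * 24 / dth))
  stim_iters <- if (has_stim)
    as.integer(round((config$stimulation_days) * iters_per_day)) -
      iters_per_day + 1L else integer(0)
  out_iters <- as.integer(round(config$output_days * iters_per_day))

  gait <- load_case("gait", gait_force_n = config$gait_force_n,
                    gait_ramp_s = config$gait_ramp_s,
                    fixator_stiffness_n_mm = config$fixator_stiffness_n_mm)
  stim <- load_case("stimulation",
                    axial_displacement_um = config$stimulation_displacement_mm * 1000,
                    ramp_rate_um_s = config$stimulation_rate_um_s,
                    crossbar = FALSE,
                    fixator_stiffness_n_mm = config$fixator_stiffness_n_mm)
  solver <- if (config$mech_backend == "fe") solve_step else surrogate_step

  census_log <- vector("list", as.integer(ceiling(n_iter / iters_per_day)))
  snapshots <- list()
  bv_rows <- list()

  for (it in seq_len(n_iter)) {
    day0 <- (it - 1L) * dth / 24

    if (!is.null(sponge)) {
      rel <- sponge_release_step(sponge, grid, kin, t_min = day0 * 1440,
                                 dt_min = dth * 60)
      sponge <- rel$sponge
      grid <- rel$grid
    }

    msc_sites <- cells$occ == PHENO_MSC
    ob_sites <- cells$occ == PHENO_OSTEOBLAST
    n_msc <- tabulate(domain$agent_of_site[msc_sites], nbins = n_agents) *
      domain$n_rep
    n_ob <- tabulate(domain$agent_of_site[ob_sites], nbins = n_agents) *
      domain$n_rep
    grid <- reaction_step(grid, n_msc, n_ob, kin)
    grid <- decay_step(grid, kin)
    grid <- diffuse_step(grid, kin)

    mat[mesh$tissue, ] <- homogenize_materials(fractions, cards)
    lc <- if (it %in% stim_iters) stim else gait
    state <- solver(mesh, mat, lc)
    s_site <- state$S[domain$element_of_site]

    conc_agent <- as.vector(grid$conc)
    conc_site <- conc_agent[domain$agent_of_site]
    prolif_site <- dose_response(conc_site, "proliferation")
    chem_site <- dose_response(conc_site, "msc_chemotaxis")
    bone_site <- dose_response(conc_site, "bone_production")

    rates <- apply_recruitment_policy(rates0, day0, policy)
    cells <- differentiate(cells, domain, s_site, ranges, rates, dth)
    cells <- mature_osteoblasts(cells, domain, s_site, ranges, rates, dth)
    cells <- proliferate(cells, domain, s_site, prolif_site, rates, dth,
                         ranges)
    cells <- migrate(cells, domain, chem_site, rates, dth,
                     phenotypes = PHENO_MSC)
    cells <- migrate(cells, domain, rep(1, length(conc_site)), rates, dth,
                     phenotypes = PHENO_FIBROBLAST)
    cells <- apoptose(cells, domain, s_site, rates, dth,
                      config$apoptosis_stress_factor, ranges)

    fractions <- produce_tissue(cells, domain, fractions, ptab, bone_site,
                                dth)
    fractions <- degrade_tissue(cells, domain, fractions, ptab, dth)

    if (it %% iters_per_day == 0L) {
      day <- it %/% iters_per_day
      cen <- cell_census(cells)
      census_log[[day]] <- data.frame(
        day = day, msc = cen[["msc"]], fibroblast = cen[["fibroblast"]],
        chondrocyte = cen[["chondrocyte"]], osteoblast = cen[["osteoblast"]],
        osteoblast_mature = cen[["osteoblast_mature"]],
        bmp_total_ng = bmp_total_mass(grid),
        bmp_max_ng_cm3 = max(grid$conc),
        sponge_residual_ug = if (is.null(sponge)) 0 else sponge$residual_ug,
        delta_if_mm = state$delta_if
      )
      if (progress)
        message(sprintf(
          "day %3d | MSC %5d OB %5d | BMP max %9.3g ng/cm^3", day,
          cen[["msc"]], cen[["osteoblast"]], max(grid$conc)))
    }
    if (it %in% out_iters) {
      day <- it / iters_per_day
      bvr <- voxelize_bv(fractions, domain)
      bridged <- detect_bridging(bvr)
      bv_rows[[length(bv_rows) + 1L]] <-
        data.frame(day = day, bv_mm3 = bvr$bv_mm3, bridged = bridged)
      snapshots[[paste0("day", day)]] <-
        list(day = day, fractions = fractions, conc = grid$conc, bv = bvr,
             cells = cells)
    }
  }

  res <- list(
    config = config,
    domain = domain,
    bv = do.call(rbind, bv_rows),
    census = do.call(rbind, census_log),
    snapshots = snapshots
  )
  class(res) <- "healing_sim"
  res
}

#' @export
print.healing_sim <- function(x, ...) {
  cat("<healing_sim> scenario", x$config$scenario,
      sprintf("(%s recruitment, %s release, seed %d)\n",
              x$config$recruitment, x$config$release, x$config$seed))
  if (!is.null(x$bv)) {
    for (i in seq_len(nrow(x$bv)))
      cat(sprintf("  day %2d: BV = %7.3f mm^3, %s\n", x$bv$day[i],
                  x$bv$bv_mm3[i],
                  if (x$bv$bridged[i]) "bridged" else "not bridged"))
  }
  invisible(x)
}
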