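# Analytic surrogate mechanics backend. The interfragmentary column
# (gap + surrounding callus) is treated as axial layers in series, each
# layer being the parallel assembly of its elements (rule of mixtures);
# the fixator acts as a spring in parallel with the column. Compliant
# layers absorb proportionally more of the interfragmentary displacement,
# so local stiffening (bone formation) unloads its own layer exactly as in
# the series-spring picture. The octahedral shear strain follows from the
# uniaxial strain state and the fluid speed is taken proportional to the
# strain and the relative permeability, with a single calibration
# coefficient. Same output contract as the FE backend.

#' Analytic interfragmentary-strain surrogate for the mechanics stage
#'
#' Fast replacement for [solve_step()] built on a series/parallel spring
#' reduction of the callus column. Intended for reduced-resolution studies
#' and tests; it reproduces the load-sharing between fixator and callus,
#' the monotone unloading of the callus as it stiffens, and the strain
#' increase when the crossbar is removed, but no full 3D strain field.
#'
#' @param mesh FE mesh from `build_domain(...)$mesh`.
#' @param materials Per-active-element homogenized materials (see
#'   [solve_step()]).
#' @param load A [load_case()].
#' @param fluid_coefficient Fluid speed per unit axial strain at unit
#'   relative permeability (um/s); calibration constant of the surrogate.
#' @param support_attenuation Strain carried over into marrow/cortex
#'   elements adjacent to the callus, as a fraction of the local callus
#'   strain.
#' @return A `mechanical_state`, as from [solve_step()].
#' @export
surrogate_step <- function(mesh, materials, load = load_case(),
                           fluid_coefficient = 100,
                           support_attenuation = 0.1) {
  ne <- length(mesh$active)
  if (nrow(materials) != ne)
    stop("surrogate_step: materials must have one row per active element",
         call. = FALSE)
  zm <- mesh$midplane_z
  w2 <- mesh$gap_halfwidth
  cz <- mesh$centroid[mesh$active, 3]
  az <- abs(cz - zm)
  in_gap_span <- az <= w2 + 1e-9
  area <- mesh$hx * mesh$hy
  hz_el <- mesh$hz[mesh$active_ez]

  gap_layers <- sort(unique(mesh$active_ez[in_gap_span]))
  if (!length(gap_layers))
    stop("surrogate_step: no element layers intersect the gap", call. = FALSE)
  k_layer <- vapply(gap_layers, function(l) {
    sel <- in_gap_span & mesh$active_ez == l
    sum(materials$young_modulus[sel] * area) / mesh$hz[l]
  }, numeric(1))
  if (any(k_layer <= 0))
    stop("surrogate_step: zero-stiffness layer in the gap column", call. = FALSE)
  c_layer <- 1 / k_layer
  c_tot <- sum(c_layer)
  k_col <- 1 / c_tot

  if (load$kind == "stimulation") {
    delta <- load$axial_displacement_um / 1000
  } else {
    k_fix <- if (load$crossbar) load$fixator_stiffness_n_mm else 0
    delta <- load$gait_force_n / (k_fix + k_col)
  }

  # layer strains: compliant layers take more of the displacement
  eps_layer <- delta * (c_layer / c_tot) / mesh$hz[gap_layers]
  eps <- numeric(ne)
  for (i in seq_along(gap_layers))
    eps[in_gap_span & mesh$active_ez == gap_layers[i]] <- eps_layer[i]

  # attenuate into the callus overhang; supporting regions get a fraction
  over <- mesh$callus_overhang
  if (over > 0) {
    beyond <- az > w2 & az <= w2 + over
    edge_p <- eps_layer[1]; edge_d <- eps_layer[length(eps_layer)]
    w <- pmax(0, 1 - (az - w2) / over)
    edge <- ifelse(cz < zm, edge_p, edge_d)
    eps[beyond] <- edge[beyond] * w[beyond]
  }
  support <- mesh$active_region %in% c(REGION_MARROW, REGION_CORTEX)
  eps[support] <- eps[support] * support_attenuation

  eps <- -abs(eps)  # axial compression
  e <- cbind(e11 = numeric(ne), e22 = numeric(ne), e33 = eps,
             e12 = numeric(ne), e23 = numeric(ne), e13 = numeric(ne))
  gamma <- octahedral_shear(e)
  upsilon <- fluid_coefficient * abs(eps) * materials$permeability
  state <- list(e = e, gamma = gamma, upsilon = upsilon,
                S = prendergast_stimulus(gamma, upsilon),
                delta_if = delta, backend = "surrogate")
  class(state) <- "mechanical_state"
  state
}
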