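#' BMP-2 kinetic parameter set
#'
#' Parameters of the growth-factor dynamics: autocrine production and
#' cellular consumption (saturating Michaelis-Menten-type kinetics), free
#' and carrier-bound degradation half-lives, and Fickian diffusivity. The
#' kinetic gamma is stored as `gamma_b` to avoid colliding with the
#' octahedral shear strain symbol.
#'
#' @param alpha Production coefficient (ng cm^-3 cell^-1 day^-1).
#' @param gamma_b Production-inhibition coefficient (cm^3 ng^-1).
#' @param gamma0 Production-inhibition offset (dimensionless).
#' @param v_k Maximum consumption rate (ng cm^-3 day^-1 cell^-1).
#' @param k_m Consumption half-saturation concentration (ng cm^-3).
#' @param t_half_free_day Free BMP-2 half-life (day).
#' @param t_half_residual_day Carrier-bound (residual) half-life (day).
#' @param d_cm2_day Diffusivity (cm^2/day).
#' @param dt_hours Default iteration length (h).
#' @return An object of class `bmp_kinetics`.
#' @export
bmp_kinetics <- function(alpha = 2e-9, gamma_b = 15, gamma0 = 0.01,
                         v_k = 1.43e-7, k_m = 11.01,
                         t_half_free_day = 0.42, t_half_residual_day = 3.25,
                         d_cm2_day = 8.64e-2, dt_hours = 2) {
  k <- list(alpha = alpha, gamma_b = gamma_b, gamma0 = gamma0, v_k = v_k,
            k_m = k_m, t_half_free_day = t_half_free_day,
            t_half_residual_day = t_half_residual_day,
            d_cm2_day = d_cm2_day, dt_hours = dt_hours)
  if (any(unlist(k) <= 0))
    stop("bmp_kinetics: all parameters must be positive", call. = FALSE)
  class(k) <- "bmp_kinetics"
  k
}

#' BMP-2 concentration grid
#'
#' Coarse agent lattice carrying the BMP-2 concentration (ng/cm^3). Each
#' agent nests up to 125 (5 x 5 x 5) cell sites; the field lives on the
#' agents whose sites belong to the defect gap or the callus growth region
#' (the `active` mask), with zero-flux boundaries.
#'
#' @param domain A [build_domain()] lattice.
#' @return An object of class `bmp_grid` with fields `conc` (3D array),
#'   `active` (3D logical array), `pitch_cm` and `agent_volume_cm3`.
#' @export
bmp_grid <- function(domain) {
  stopifnot(inherits(domain, "region_lattice"))
  d <- domain$agent_dims
  g <- list(
    conc = array(0, dim = d),
    active = array(domain$agent_active, dim = d),
    dims = d,
    pitch_cm = domain$agent_pitch / 10,
    agent_volume_cm3 = domain$agent_volume_cm3
  )
  class(g) <- "bmp_grid"
  g
}

#' Total free BMP-2 mass on a grid
#'
#' @param grid A [bmp_grid()].
#' @return Mass in ng.
#' @export
bmp_total_mass <- function(grid) {
  sum(grid$conc[grid$active]) * grid$agent_volume_cm3
}

#' Cellular production/consumption step
#'
#' Per agent, the concentration changes by
#' \deqn{\Delta[BMP] = \left[\frac{\alpha}{\gamma_B [BMP] + \gamma_0}
#'   - \frac{V_K [BMP]}{K_M^A + [BMP]}\right] (n_{MSC} + n_{OB}) \Delta t,}
#' driven by the MSCs and osteoblasts the agent contains. Concentrations
#' are clamped at zero.
#'
#' @param grid A [bmp_grid()].
#' @param n_msc,n_ob Per-agent cell counts (biological cells; at coarse
#'   lattice resolutions each lattice agent contributes its representation
#'   factor).
#' @param kinetics A [bmp_kinetics()].
#' @param dt_days Step length (days); defaults to the kinetics iteration.
#' @return The updated grid.
#' @export
reaction_step <- function(grid, n_msc, n_ob, kinetics = bmp_kinetics(),
                          dt_days = kinetics$dt_hours / 24) {
  if (any(n_msc < 0) || any(n_ob < 0))
    stop("reaction_step: cell counts must be non-negative", call. = FALSE)
  b <- grid$conc
  n <- array(n_msc + n_ob, dim = grid$dims)
  prod <- kinetics$alpha / (kinetics$gamma_b * b + kinetics$gamma0)
  cons <- kinetics$v_k * b / (kinetics$k_m + b)
  upd <- pmax(b + (prod - cons) * n * dt_days, 0)
  grid$conc[grid$active] <- upd[grid$active]
  grid
}

#' First-order free BMP-2 decay step
#'
#' Multiplicative exponential survival update
#' `[BMP] <- [BMP] * exp(-ln(2) * dt / t_half)`, so twelve 2-hour steps
#' compose exactly into one 1-day step.
#'
#' @inheritParams reaction_step
#' @return The updated grid.
#' @export
decay_step <- function(grid, kinetics = bmp_kinetics(),
                       dt_days = kinetics$dt_hours / 24) {
  grid$conc <- grid$conc * exp(-log(2) * dt_days / kinetics$t_half_free_day)
  grid
}

#' Fickian diffusion step
#'
#' Explicit flux-form finite-volume update on the active agent domain with
#' zero-flux boundaries; pairwise antisymmetric face fluxes conserve total
#' mass to rounding. The explicit stability bound `D dt / h^2 <= 1/6` is
#' enforced by automatic sub-stepping.
#'
#' @inheritParams reaction_step
#' @param max_lambda Stability bound per sub-step.
#' @return The updated grid.
#' @export
diffuse_step <- function(grid, kinetics = bmp_kinetics(),
                         dt_days = kinetics$dt_hours / 24, max_lambda = 1 / 6) {
  h <- grid$pitch_cm
  lam_tot <- kinetics$d_cm2_day * dt_days / h^2
  nsub <- max(1L, as.integer(ceiling(lam_tot / max_lambda)))
  lam <- lam_tot / nsub
  if (lam > max_lambda + 1e-12)
    stop("diffuse_step: unstable diffusion step", call. = FALSE)
  a <- grid$conc
  d <- grid$dims
  lin <- array(seq_len(prod(d)), dim = d)
  faces <- list()
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    lo <- hi <- lapply(d, seq_len)
    lo[[ax]] <- 1:(d[ax] - 1L)
    hi[[ax]] <- 2:d[ax]
    ilo <- as.vector(do.call(`[`, c(list(lin), lo, list(drop = FALSE))))
    ihi <- as.vector(do.call(`[`, c(list(lin), hi, list(drop = FALSE))))
    keep <- grid$active[ilo] & grid$active[ihi]
    faces[[length(faces) + 1L]] <- list(lo = ilo[keep], hi = ihi[keep])
  }
  for (s in seq_len(nsub)) {
    for (fc in faces) {
      f <- lam * (a[fc$hi] - a[fc$lo])
      a[fc$lo] <- a[fc$lo] + f
      a[fc$hi] <- a[fc$hi] - f
    }
  }
  grid$conc <- a
  grid
}

#' BMP-2 dose-response fold-factors
#'
#' Non-monotonic fold-enhancement of cellular activities as a function of
#' the local BMP-2 concentration. Chemotaxis (MSC peak 3.5-fold, osteoblast
#' peak 2.2-fold, both at 1 ng/cm^3) and MSC proliferation (peak 2-fold at
#' 200 ng/cm^3) are log-concentration Gaussian bumps,
#' `1 + (peak - 1) exp(-log10(c/c_peak)^2 / (2 sigma^2))`; osteoblast bone
#' production saturates Hill-like toward a 3-fold asymptote,
#' `1 + 2 c / (c + K)`. Every curve equals 1 at zero concentration. The
#' published curves fix the peaks and asymptote but not the widths, so
#' `sigma` and `half_saturation` are explicit shape knobs.
#'
#' @param conc Concentration(s), ng/cm^3, `>= 0`.
#' @param curve Which response to evaluate.
#' @param sigma Width of the log-Gaussian curves (decades).
#' @param half_saturation Half-saturation concentration of the bone
#'   production curve (ng/cm^3).
#' @return Fold-factor(s) `>= 1`.
#' @export
#' @examples
#' dose_response(1, "msc_chemotaxis")    # 3.5
#' dose_response(0, "bone_production")   # 1
dose_response <- function(conc,
                          curve = c("msc_chemotaxis", "osteoblast_chemotaxis",
                                    "proliferation", "bone_production"),
                          sigma = 0.8, half_saturation = 10) {
  curve <- match.arg(curve)
  if (any(conc < 0))
    stop("dose_response: concentrations must be non-negative", call. = FALSE)
  if (curve == "bone_production")
    return(1 + 2 * conc / (conc + half_saturation))
  par <- switch(curve,
    msc_chemotaxis = c(peak = 3.5, c_peak = 1),
    osteoblast_chemotaxis = c(peak = 2.2, c_peak = 1),
    proliferation = c(peak = 2.0, c_peak = 200))
  out <- rep(1, length(conc))
  pos <- conc > 0
  lg <- log10(conc[pos] / par[["c_peak"]])
  out[pos] <- 1 + (par[["peak"]] - 1) * exp(-lg^2 / (2 * sigma^2))
  out
}
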