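#' Collagen sponge carrier state
#'
#' The carrier sponge fills the defect gap and releases its BMP-2 load
#' following a biexponential retention schedule (fast pool plus slow pool,
#' time in minutes). The printed pool coefficients sum to 90.1% of the
#' dose, which is read as an instantaneous 9.9% burst at implantation; the
#' burst is injected at the first iteration. Carrier-bound (residual) BMP-2
#' is biologically inert and degrades with its own, slower half-life.
#'
#' @param dose_ug Initial BMP-2 load (ug).
#' @param agent_ids Linear indices of the BMP agents covered by the sponge
#'   (the gap agents of the domain).
#' @param coefficients Pool sizes as percent of the dose.
#' @param rates_per_min Pool release rate constants (min^-1).
#' @param normalize Rescale the pool coefficients to sum to 100% (no burst);
#'   off by default.
#' @return An object of class `sponge_state` with `residual_ug` tracking the
#'   retained (still carrier-bound and undegraded) mass.
#' @export
sponge_state <- function(dose_ug = 50, agent_ids,
                         coefficients = c(68, 22.1),
                         rates_per_min = c(0.012, 0.00006),
                         normalize = FALSE) {
  if (dose_ug <= 0) stop("sponge_state: dose must be positive", call. = FALSE)
  if (!length(agent_ids))
    stop("sponge_state: no sponge agents supplied", call. = FALSE)
  if (normalize) coefficients <- coefficients * 100 / sum(coefficients)
  s <- list(m0 = dose_ug, residual_ug = dose_ug * sum(coefficients) / 100,
            released_ug = 0, burst_done = FALSE,
            coefficients = coefficients, rates_per_min = rates_per_min,
            agent_ids = as.integer(agent_ids))
  class(s) <- "sponge_state"
  s
}

# Retention fraction of the dose still scheduled inside the sponge at time
# t (minutes), before residual degradation.
sponge_retention <- function(sponge, t_min) {
  sum_terms <- outer(t_min, sponge$rates_per_min, function(t, r) exp(-r * t))
  as.vector(sum_terms %*% sponge$coefficients) / 100
}

#' One carrier release step
#'
#' Over `[t, t + dt]` the sponge releases the scheduled retention decrement
#' `m0 * (f(t) - f(t + dt))`, scaled by the residual-degradation survival at
#' the start of the step; at `t = 0` the instantaneous burst
#' `m0 * (1 - f(0))` is added. The released mass becomes free BMP-2,
#' distributed uniformly over the sponge-domain agents; the retained mass is
#' updated to `m0 * f(t + dt)` times its survival. Residual mass is strictly
#' decreasing and the total free mass ever injected is bounded by the dose.
#'
#' @param sponge A [sponge_state()].
#' @param grid A [bmp_grid()].
#' @param kinetics A [bmp_kinetics()] (residual half-life).
#' @param t_min Time at the start of the step (minutes).
#' @param dt_min Step length (minutes).
#' @return A list with the updated `sponge` and `grid`, plus `released_ug`.
#' @export
sponge_release_step <- function(sponge, grid, kinetics = bmp_kinetics(),
                                t_min, dt_min = kinetics$dt_hours * 60) {
  if (t_min < 0) stop("sponge_release_step: t must be >= 0", call. = FALSE)
  th_min <- kinetics$t_half_residual_day * 1440
  surv0 <- exp(-log(2) * t_min / th_min)
  surv1 <- exp(-log(2) * (t_min + dt_min) / th_min)
  f0 <- sponge_retention(sponge, t_min)
  f1 <- sponge_retention(sponge, t_min + dt_min)
  released <- sponge$m0 * (f0 - f1) * surv0
  if (!sponge$burst_done) {
    released <- released +
      sponge$m0 * max(0, 1 - sponge_retention(sponge, 0))
    sponge$burst_done <- TRUE
  }
  sponge$residual_ug <- sponge$m0 * f1 * surv1
  sponge$released_ug <- sponge$released_ug + released

  vol <- length(sponge$agent_ids) * grid$agent_volume_cm3
  grid$conc[sponge$agent_ids] <- grid$conc[sponge$agent_ids] +
    released * 1000 / vol  # ug -> ng over the sponge volume
  list(sponge = sponge, grid = grid, released_ug = released)
}

#' Instantaneous ("fast release") BMP-2 initialization
#'
#' The alternative delivery model: the whole dose is free inside the
#' osteotomy gap at iteration zero, as a homogeneous concentration over the
#' gap agents; no carrier state remains.
#'
#' @param grid A [bmp_grid()].
#' @param dose_ug Dose (ug).
#' @param agent_ids Linear indices of the gap agents.
#' @return The initialized grid.
#' @export
fast_release_init <- function(grid, dose_ug = 50, agent_ids) {
  if (!length(agent_ids))
    stop("fast_release_init: no gap agents supplied", call. = FALSE)
  vol <- length(agent_ids) * grid$agent_volume_cm3
  grid$conc[as.integer(agent_ids)] <- dose_ug * 1000 / vol
  grid
}
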