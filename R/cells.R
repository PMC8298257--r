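# Phenotype codes stored in the cell lattice occupancy vector.
PHENO_EMPTY <- 0L
PHENO_MSC <- 1L
PHENO_FIBROBLAST <- 2L
PHENO_CHONDROCYTE <- 3L
PHENO_OSTEOBLAST <- 4L

PHENO_NAMES <- c("msc", "fibroblast", "chondrocyte", "osteoblast")

# Native lattice pitch (um) at which the rate-table migration speeds
# correspond to one hop per 2-h iteration.
NATIVE_SPACING_UM <- 60

# Hop-attempt probability on a lattice of pitch `h` for a cell moving at
# `rate` um/h. At the native pitch this is rate*dt/h (one hop per iteration
# at 30 um/h). On coarsened lattices a 1/h scaling preserves the ballistic
# speed but inflates the random-walk diffusivity (D ~ p h^2), while a 1/h^2
# scaling preserves diffusivity but suppresses chemotactic drift; the
# geometric mean (p ~ h^-3/2) is used as the compromise, so coarse fixtures
# neither overshoot cell dispersal nor stall directed migration.
migration_hop_prob <- function(rate_um_h, dt_hours, spacing_um) {
  pmin(1, rate_um_h * dt_hours / spacing_um *
         sqrt(NATIVE_SPACING_UM / pmax(spacing_um, NATIVE_SPACING_UM)))
}

#' Cellular activity rate table
#'
#' Per-phenotype migration (um/h), proliferation, differentiation and
#' apoptosis rates (day^-1). Chondrocytes and osteoblasts do not migrate and
#' only MSCs differentiate; immature and mature osteoblasts share one row
#' (the maturity flag is reported but carries no distinct rates).
#'
#' @return Data frame with rows `msc`, `fibroblast`, `chondrocyte`,
#'   `osteoblast` (in phenotype-code order).
#' @export
default_rate_table <- function() {
  r <- data.frame(
    phenotype = PHENO_NAMES,
    migration_rate = c(30, 30, 0, 0),
    proliferation_rate = c(0.60, 0.55, 0.20, 0.30),
    differentiation_rate = c(0.30, 0, 0, 0),
    apoptosis_rate = c(0.05, 0.05, 0.10, 0.16)
  )
  rownames(r) <- PHENO_NAMES
  r
}

#' Cellular recruitment policy
#'
#' Untreated critical-sized defects arrest healing within days; the model
#' represents this as limited recruitment: MSC migration and proliferation
#' rates are set to zero after the cutoff day while differentiation and
#' apoptosis stay unaltered.
#'
#' @param mode `"limited"` or `"continuous"`.
#' @param cutoff_day Day after which MSC migration/proliferation stop
#'   (limited mode).
#' @return An object of class `recruitment_policy`.
#' @export
recruitment_policy <- function(mode = c("limited", "continuous"),
                               cutoff_day = 10) {
  mode <- match.arg(mode)
  if (cutoff_day <= 0)
    stop("recruitment_policy: cutoff_day must be positive", call. = FALSE)
  structure(list(mode = mode, cutoff_day = cutoff_day),
            class = "recruitment_policy")
}

#' Apply the recruitment policy to a rate table
#'
#' In limited mode, past the cutoff day the MSC migration and proliferation
#' rates become zero; all other entries (including MSC differentiation and
#' apoptosis) are unchanged. Continuous mode is the identity.
#'
#' @param rates Rate table from [default_rate_table()].
#' @param day Simulation day (>= 0).
#' @param policy A [recruitment_policy()].
#' @return The (possibly modified) rate table.
#' @export
apply_recruitment_policy <- function(rates, day, policy = recruitment_policy()) {
  if (day < 0) stop("apply_recruitment_policy: day must be >= 0", call. = FALSE)
  if (policy$mode == "limited" && day > policy$cutoff_day) {
    rates["msc", "migration_rate"] <- 0
    rates["msc", "proliferation_rate"] <- 0
  }
  rates
}

# Stochastic rate -> per-iteration probability (Poisson waiting time).
rate_to_prob <- function(rate_per_day, dt_days) 1 - exp(-rate_per_day * dt_days)

# Is the local stimulus favorable for a phenotype? MSCs and fibroblasts are
# unconstrained; chondrocytes favor the cartilage range, osteoblasts the
# (im)mature bone range.
favorable_stimulus <- function(pheno, s, ranges = differentiation_ranges()) {
  ok <- rep(TRUE, length(pheno))
  cho <- pheno == PHENO_CHONDROCYTE
  ob <- pheno == PHENO_OSTEOBLAST
  ok[cho] <- s[cho] > ranges$osteoblast & s[cho] <= ranges$chondrocyte
  ok[ob] <- s[ob] <= ranges$osteoblast
  ok
}

# Draw one destination per row of a weight matrix (rows x 6 candidates);
# returns 0 where all weights vanish.
sample_weighted_column <- function(w) {
  tot <- rowSums(w)
  choice <- integer(nrow(w))
  sel <- tot > 0
  if (any(sel)) {
    cs <- w[sel, , drop = FALSE]
    for (j in 2:ncol(cs)) cs[, j] <- cs[, j] + cs[, j - 1L]
    u <- stats::runif(sum(sel)) * tot[sel]
    choice[sel] <- 1L + rowSums(cs < u)
  }
  choice
}

# Resolve move conflicts: random priority order, first claim on a target
# site wins. Returns indices of the winning rows.
resolve_conflicts <- function(dest) {
  ord <- sample.int(length(dest))
  ord[!duplicated(dest[ord])]
}

#' Chemotaxis-weighted cell migration
#'
#' Each motile cell (MSC, fibroblast by default) attempts one hop per
#' iteration to one of its six face neighbors. The attempt probability is
#' `min(1, rate * dt / spacing)` so the migration speed in um/h is preserved
#' across lattice resolutions, and the destination is drawn with probability
#' proportional to the chemotaxis index at each candidate site; occupied or
#' out-of-domain candidates are excluded. Moves are synchronous against the
#' pre-step occupancy, with random-priority conflict resolution, so cell
#' count is conserved.
#'
#' @param cells A `cell_lattice`.
#' @param domain The `region_lattice`.
#' @param chem_index Chemotaxis index per site (>= 1 everywhere; 1 = no
#'   enhancement).
#' @param rates Rate table (possibly policy-adjusted).
#' @param dt_hours Iteration length (h).
#' @param phenotypes Phenotype codes this call moves (callers wanting
#'   phenotype-specific chemotaxis fields invoke it once per phenotype).
#' @return The updated `cell_lattice`.
#' @export
migrate <- function(cells, domain, chem_index, rates = default_rate_table(),
                    dt_hours = 2,
                    phenotypes = c(PHENO_MSC, PHENO_FIBROBLAST)) {
  if (any(chem_index < 1 - 1e-9))
    stop("migrate: chemotaxis index must be >= 1 everywhere", call. = FALSE)
  occ <- cells$occ
  movers <- which(occ %in% phenotypes)
  if (!length(movers)) return(cells)
  spacing_um <- domain$config$cell_site_spacing
  p_hop <- migration_hop_prob(rates$migration_rate[occ[movers]], dt_hours,
                              spacing_um)
  movers <- movers[stats::runif(length(movers)) < p_hop]
  if (!length(movers)) return(cells)

  nb <- domain$nb[movers, , drop = FALSE]
  nbz <- pmax(nb, 1L)
  open <- nb > 0L & occ[nbz] == PHENO_EMPTY & domain$cells_allowed[nbz]
  w <- matrix(chem_index[nbz], nrow(nb), 6L) * open
  choice <- sample_weighted_column(w)
  sel <- choice > 0L
  if (!any(sel)) return(cells)
  origin <- movers[sel]
  dest <- nb[cbind(which(sel), choice[sel])]
  win <- resolve_conflicts(dest)
  origin <- origin[win]; dest <- dest[win]
  cells$occ[dest] <- occ[origin]
  cells$mature[dest] <- cells$mature[origin]
  cells$occ[origin] <- PHENO_EMPTY
  cells$mature[origin] <- FALSE
  cells
}

#' Cell proliferation
#'
#' Each cell divides with probability `1 - exp(-r_eff * dt)`, where the
#' effective rate is the phenotype's base rate times the local BMP-2
#' proliferation factor (MSCs only), and only where the local mechanical
#' stimulus is favorable for the phenotype (MSCs and fibroblasts divide in
#' any stimulus). Mature osteoblasts are post-mitotic: the osteoblast
#' proliferation rate applies to immature osteoblasts, which drop out of
#' the cycling pool as they mature (see [mature_osteoblasts()]); without
#' this terminal arrest the osteoblast population would expand without
#' bound (0.30/day proliferation against 0.16/day apoptosis) and no healing
#' arrest could ever occur. Daughters occupy a uniformly chosen free
#' face-neighbor site; without a free neighbor the division is skipped.
#'
#' @param cells,domain,rates,dt_hours See [migrate()].
#' @param s_site Prendergast stimulus per cell site.
#' @param bmp_prolif_factor BMP-2 proliferation fold-factor per site (>= 1).
#' @param ranges [differentiation_ranges()] defining favorable windows.
#' @return The updated `cell_lattice`.
#' @export
proliferate <- function(cells, domain, s_site, bmp_prolif_factor = 1,
                        rates = default_rate_table(), dt_hours = 2,
                        ranges = differentiation_ranges()) {
  if (any(bmp_prolif_factor < 1 - 1e-9))
    stop("proliferate: BMP-2 proliferation factors must be >= 1", call. = FALSE)
  occ <- cells$occ
  idx <- which(occ != PHENO_EMPTY)
  if (!length(idx)) return(cells)
  if (length(bmp_prolif_factor) == 1L)
    bmp_prolif_factor <- rep(bmp_prolif_factor, length(occ))
  pheno <- occ[idx]
  rate <- rates$proliferation_rate[pheno]
  rate <- rate * ifelse(pheno == PHENO_MSC, bmp_prolif_factor[idx], 1)
  ok <- rate > 0 & favorable_stimulus(pheno, s_site[idx], ranges) &
    !(pheno == PHENO_OSTEOBLAST & cells$mature[idx])
  idx <- idx[ok]; rate <- rate[ok]
  if (!length(idx)) return(cells)
  div <- stats::runif(length(idx)) < rate_to_prob(rate, dt_hours / 24)
  idx <- idx[div]
  if (!length(idx)) return(cells)

  nb <- domain$nb[idx, , drop = FALSE]
  nbz <- pmax(nb, 1L)
  open <- (nb > 0L & occ[nbz] == PHENO_EMPTY & domain$cells_allowed[nbz]) * 1
  choice <- sample_weighted_column(open)
  sel <- choice > 0L
  if (!any(sel)) return(cells)
  parent <- idx[sel]
  dest <- nb[cbind(which(sel), choice[sel])]
  win <- resolve_conflicts(dest)
  parent <- parent[win]; dest <- dest[win]
  cells$occ[dest] <- occ[parent]
  cells$mature[dest] <- cells$mature[parent]
  cells
}

#' Mechano-regulated MSC differentiation
#'
#' Each MSC differentiates with probability `1 - exp(-rate * dt)`; the
#' target phenotype follows the stimulus ranges at its site (low stimulus:
#' osteoblast, carrying a maturity flag below the mature-osteoblast bound;
#' intermediate: chondrocyte; high: fibroblast).
#'
#' @param cells,domain,rates,dt_hours See [migrate()].
#' @param s_site Prendergast stimulus per cell site.
#' @param ranges [differentiation_ranges()].
#' @return The updated `cell_lattice`.
#' @export
differentiate <- function(cells, domain, s_site,
                          ranges = differentiation_ranges(),
                          rates = default_rate_table(), dt_hours = 2) {
  idx <- which(cells$occ == PHENO_MSC)
  if (!length(idx)) return(cells)
  p <- rate_to_prob(rates["msc", "differentiation_rate"], dt_hours / 24)
  idx <- idx[stats::runif(length(idx)) < p]
  if (!length(idx)) return(cells)
  fate <- fate_from_stimulus(s_site[idx], ranges)
  cells$occ[idx] <- fate$phenotype
  cells$mature[idx] <- fate$phenotype == PHENO_OSTEOBLAST & fate$mature
  cells
}

#' Apoptosis
#'
#' Each cell dies with probability `1 - exp(-rate * dt)`. Differentiated
#' cells (chondrocytes, osteoblasts) sitting outside their favorable
#' stimulus window have their apoptosis rate multiplied by `stress_factor`.
#'
#' @param cells,domain,rates,dt_hours See [migrate()].
#' @param s_site Prendergast stimulus per cell site.
#' @param stress_factor Apoptosis multiplier outside the favorable window.
#' @param ranges [differentiation_ranges()].
#' @return The updated `cell_lattice`.
#' @export
apoptose <- function(cells, domain, s_site, rates = default_rate_table(),
                     dt_hours = 2, stress_factor = 2,
                     ranges = differentiation_ranges()) {
  idx <- which(cells$occ != PHENO_EMPTY)
  if (!length(idx)) return(cells)
  pheno <- cells$occ[idx]
  rate <- rates$apoptosis_rate[pheno]
  stressed <- !favorable_stimulus(pheno, s_site[idx], ranges)
  rate[stressed] <- rate[stressed] * stress_factor
  die <- stats::runif(length(idx)) < rate_to_prob(rate, dt_hours / 24)
  idx <- idx[die]
  cells$occ[idx] <- PHENO_EMPTY
  cells$mature[idx] <- FALSE
  cells
}

#' Osteoblast maturation
#'
#' Immature osteoblasts sitting where the stimulus lies in the mature range
#' (`S <= 2.53`) mature with first-order kinetics (default: the same
#' 0.30/day rate that governs MSC differentiation). Mature osteoblasts are
#' terminally differentiated and post-mitotic, which bounds the osteoblast
#' population once progenitor recruitment ends and lets healing arrest
#' (non-union) emerge.
#'
#' @param cells,domain,rates,dt_hours See [migrate()].
#' @param s_site Prendergast stimulus per cell site.
#' @param ranges [differentiation_ranges()].
#' @param maturation_rate Maturation rate (day^-1); defaults to the MSC
#'   differentiation rate.
#' @return The updated `cell_lattice`.
#' @export
mature_osteoblasts <- function(cells, domain, s_site,
                               ranges = differentiation_ranges(),
                               rates = default_rate_table(), dt_hours = 2,
                               maturation_rate = rates["msc", "differentiation_rate"]) {
  idx <- which(cells$occ == PHENO_OSTEOBLAST & !cells$mature &
                 s_site <= ranges$osteoblast_mature)
  if (!length(idx)) return(cells)
  p <- rate_to_prob(maturation_rate, dt_hours / 24)
  idx <- idx[stats::runif(length(idx)) < p]
  cells$mature[idx] <- TRUE
  cells
}

#' Cell census by phenotype
#'
#' @param cells A `cell_lattice`.
#' @return Named integer vector: counts per phenotype plus the number of
#'   mature osteoblasts.
#' @export
cell_census <- function(cells) {
  tab <- tabulate(cells$occ, nbins = 4L)
  c(msc = tab[1], fibroblast = tab[2], chondrocyte = tab[3],
    osteoblast = tab[4], osteoblast_mature = sum(cells$mature))
}
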