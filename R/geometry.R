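# Region codes used across the package. The collagen sponge occupies the
# defect gap exactly, so it is tracked as a mask over BMP agents rather than
# a separate site label.
REGION_OUTSIDE <- 0L
REGION_CORTEX <- 1L
REGION_MARROW <- 2L
REGION_GAP <- 3L
REGION_CALLUS <- 4L
REGION_PERIOSTEUM <- 5L

REGION_NAMES <- c("outside", "cortex", "marrow", "gap", "callus_growth",
                  "periosteal_band")

#' Region label names
#'
#' @param code Integer region codes as stored in a [build_domain()] lattice.
#' @return Character vector of region names.
#' @export
region_name <- function(code) REGION_NAMES[code + 1L]

# Classify points into anatomical regions. `z` is the global axial
# coordinate (0 at the distal bone end); the gap is centered on the bone
# midplane. Returns integer region codes (without the periosteal band,
# which is a site-layer refinement of the callus label).
classify_region <- function(x, y, z, cfg) {
  eps <- 1e-9
  zm <- cfg$bone_segment_length + cfg$gap_width / 2
  w2 <- cfg$gap_width / 2
  az <- abs(z - zm)
  r <- sqrt(x^2 + y^2)
  rci <- cfg$cortex_inner_radius
  rco <- cfg$cortex_outer_radius
  rcal <- cfg$callus_outer_radius
  in_gap <- az <= w2 + eps
  in_cal <- az <= w2 + cfg$callus_axial_overhang + eps

  reg <- rep.int(REGION_OUTSIDE, length(r))
  # axial zone with cortex present (outside the gap span)
  cortex_zone <- !in_gap
  reg[cortex_zone & r < rci - eps] <- REGION_MARROW
  reg[cortex_zone & r >= rci - eps & r <= rco + eps] <- REGION_CORTEX
  reg[cortex_zone & in_cal & r > rco + eps & r <= rcal + eps] <- REGION_CALLUS
  # gap span: the defect itself plus the surrounding callus ring
  reg[in_gap & r <= rco + eps] <- REGION_GAP
  reg[in_gap & r > rco + eps & r <= rcal + eps] <- REGION_CALLUS
  reg
}

#' Build the simulation domain and its nested lattices
#'
#' Constructs the labeled 3D cell-site lattice (cortex, marrow, gap, callus
#' growth region, periosteal band), the coarse BMP-2 agent grid (5x5x5
#' cell-site nesting), the finite-element mesh, the bone-volume voxel grid
#' geometry, and all index maps between them.
#'
#' @param config A [domain_config()] object.
#' @return An object of class `region_lattice` with (among others) fields
#'   `region` (integer code per cell site), `nb` (site-by-6 face-neighbor
#'   index matrix, 0 = no neighbor), `agent_of_site`, `element_of_site`,
#'   `mesh` (FE mesh description) and `bv` (voxel grid geometry).
#' @export
#' @examples
#' dom <- build_domain(domain_config(cell_site_spacing = 600))
#' table(region_name(dom$region))
build_domain <- function(config) {
  validate_domain_config(config)
  h <- config$cell_site_spacing / 1000  # um -> mm
  rcal <- config$callus_outer_radius
  w2 <- config$gap_width / 2
  zm <- config$bone_segment_length + w2
  half_span <- w2 + config$callus_axial_overhang + config$marrow_margin

  nx <- max(1L, as.integer(round(2 * rcal / h)))
  ny <- nx
  nz <- max(1L, as.integer(round(2 * half_span / h)))
  x0 <- -nx * h / 2
  y0 <- -ny * h / 2
  z0 <- zm - nz * h / 2

  xs <- x0 + (seq_len(nx) - 0.5) * h
  ys <- y0 + (seq_len(ny) - 0.5) * h
  zs <- z0 + (seq_len(nz) - 0.5) * h
  n <- nx * ny * nz

  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  px <- xs[ix]; py <- ys[iy]; pz <- zs[iz]

  region <- classify_region(px, py, pz, config)
  # Periosteal band: outermost callus site layer hugging the cortical
  # surface (only where cortex exists, i.e. outside the gap span).
  r <- sqrt(px^2 + py^2)
  az <- abs(pz - zm)
  band <- region == REGION_CALLUS & az > w2 &
    r <= config$cortex_outer_radius + h + 1e-9
  region[band] <- REGION_PERIOSTEUM

  # 6-face neighbor table (order: -x, +x, -y, +y, -z, +z); 0 = outside grid.
  id <- seq_len(n)
  nb <- matrix(0L, n, 6L)
  nb[, 1L] <- ifelse(ix > 1L, id - 1L, 0L)
  nb[, 2L] <- ifelse(ix < nx, id + 1L, 0L)
  nb[, 3L] <- ifelse(iy > 1L, id - nx, 0L)
  nb[, 4L] <- ifelse(iy < ny, id + nx, 0L)
  nb[, 5L] <- ifelse(iz > 1L, id - nx * ny, 0L)
  nb[, 6L] <- ifelse(iz < nz, id + nx * ny, 0L)

  # BMP-2 agent grid: 5x5x5 blocks of cell sites (boundary blocks may hold
  # fewer sites, never more than 125).
  nax <- as.integer(ceiling(nx / 5)); nay <- as.integer(ceiling(ny / 5))
  naz <- as.integer(ceiling(nz / 5))
  ax <- (ix - 1L) %/% 5L; ay <- (iy - 1L) %/% 5L; az_i <- (iz - 1L) %/% 5L
  agent_of_site <- 1L + ax + nax * (ay + nay * az_i)
  n_agent <- nax * nay * naz
  agent_pitch <- 5 * h

  # Agent-center regions drive the diffusion domain and sponge placement.
  acx <- x0 + (rep.int(seq_len(nax), nay * naz) - 0.5) * agent_pitch
  acy <- y0 + (rep.int(rep(seq_len(nay), each = nax), naz) - 0.5) * agent_pitch
  acz <- z0 + (rep(seq_len(naz), each = nax * nay) - 0.5) * agent_pitch
  agent_region <- classify_region(acx, acy, acz, config)
  # An agent belongs to the BMP-2 domain if any of its sites is in the gap
  # or callus growth region (the growth-factor field is confined there).
  site_active <- region %in% c(REGION_GAP, REGION_CALLUS, REGION_PERIOSTEUM)
  agent_active <- tabulate(agent_of_site[site_active], nbins = n_agent) > 0L
  site_gap <- region == REGION_GAP
  agent_gap <- tabulate(agent_of_site[site_gap], nbins = n_agent) > 0L &
    abs(acz - zm) <= w2

  mesh <- build_fe_mesh(config)

  # Map every cell site to its FE element (full-grid index, then active id).
  ex <- pmin(pmax(findInterval(px, mesh$xn, all.inside = TRUE), 1L), mesh$nex)
  ey <- pmin(pmax(findInterval(py, mesh$yn, all.inside = TRUE), 1L), mesh$ney)
  ez <- pmin(pmax(findInterval(pz, mesh$zn, all.inside = TRUE), 1L), mesh$nez)
  egrid <- ex + mesh$nex * ((ey - 1L) + mesh$ney * (ez - 1L))

  # Elements whose centroid fell outside the callus cylinder can still hold
  # boundary cell sites; promote them using the majority site region so the
  # site -> element map is total over the domain.
  inside <- region != REGION_OUTSIDE
  need <- unique(egrid[inside][mesh$region[egrid[inside]] == REGION_OUTSIDE])
  if (length(need)) {
    for (e in need) {
      sr <- region[inside & egrid == e]
      sr[sr == REGION_PERIOSTEUM] <- REGION_CALLUS
      tab <- tabulate(sr, nbins = 5L)
      mesh$region[e] <- which.max(tab)
    }
    mesh <- finalize_fe_mesh(mesh)
  }
  element_of_site <- mesh$active_id[egrid]
  element_of_site[element_of_site == 0L] <- NA_integer_  # outside-domain sites

  dom <- list(
    config = config,
    spacing = h,
    dims = c(nx, ny, nz),
    origin = c(x0, y0, z0),
    xs = xs, ys = ys, zs = zs,
    midplane_z = zm,
    region = region,
    nb = nb,
    cells_allowed = region %in% c(REGION_MARROW, REGION_GAP, REGION_CALLUS,
                                  REGION_PERIOSTEUM),
    site_volume_mm3 = h^3,
    n_rep = (config$cell_site_spacing / 60)^3,
    agent_dims = c(nax, nay, naz),
    agent_of_site = agent_of_site,
    agent_pitch = agent_pitch,
    agent_volume_cm3 = (agent_pitch / 10)^3,
    agent_active = agent_active,
    agent_gap = agent_gap,
    mesh = mesh,
    element_of_site = element_of_site,
    bv = list(
      voxel = config$bv_voxel_size,
      xlim = c(x0, x0 + nx * h), ylim = c(y0, y0 + ny * h),
      zlim = c(zm - (w2 + config$callus_axial_overhang),
               zm + (w2 + config$callus_axial_overhang))
    )
  )
  class(dom) <- "region_lattice"
  dom
}

#' @export
print.region_lattice <- function(x, ...) {
  cat("<region_lattice>\n")
  cat(sprintf("  cell sites:  %d x %d x %d (spacing %.3f mm)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  tab <- table(factor(region_name(x$region), levels = REGION_NAMES))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("    %-16s %d\n", nm, tab[[nm]]))
  cat(sprintf("  BMP agents:  %d x %d x %d (pitch %.3f mm, %d in domain)\n",
              x$agent_dims[1], x$agent_dims[2], x$agent_dims[3],
              x$agent_pitch, sum(x$agent_active)))
  cat(sprintf("  FE elements: %d active (%d tissue)\n",
              length(x$mesh$active), length(x$mesh$tissue)))
  invisible(x)
}

#' Seed the initial mesenchymal stromal cell population
#'
#' Places `round(fraction * N)` MSCs uniformly at random (without
#' replacement) over the cell sites available in the marrow and periosteal
#' band; the defect gap and callus growth region start cell-free. Uses R's
#' global random number stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param domain A [build_domain()] lattice.
#' @param fraction Occupancy fraction in \[0, 1\].
#' @return An object of class `cell_lattice`: `occ` (integer phenotype code
#'   per site: 0 empty, 1 MSC, 2 fibroblast, 3 chondrocyte, 4 osteoblast)
#'   and `mature` (logical osteoblast maturity flag per site).
#' @export
seed_mscs <- function(domain, fraction = domain$config$seed_fraction) {
  stopifnot(inherits(domain, "region_lattice"))
  if (fraction < 0 || fraction > 1)
    stop("seed_mscs: fraction must lie in [0, 1]", call. = FALSE)
  avail <- which(domain$region %in% c(REGION_MARROW, REGION_PERIOSTEUM))
  n_seed <- round(fraction * length(avail))
  occ <- integer(length(domain$region))
  if (n_seed > 0) occ[sample(avail, n_seed)] <- PHENO_MSC
  cells <- list(occ = occ, mature = logical(length(occ)))
  class(cells) <- "cell_lattice"
  cells
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat("<cell_lattice>\n")
  cen <- cell_census(x)
  cat(sprintf("  MSC %d | fibroblast %d | chondrocyte %d | osteoblast %d (%d mature)\n",
              cen[["msc"]], cen[["fibroblast"]], cen[["chondrocyte"]],
              cen[["osteoblast"]], cen[["osteoblast_mature"]]))
  invisible(x)
}

#' Map cell sites to their BMP agent, FE element and BV voxel
#'
#' The nesting maps are total over the domain: every in-domain cell site
#' belongs to exactly one BMP-2 agent (at most 125 sites per agent) and one
#' finite element; sites outside the bone-volume reporting box have voxel id
#' `NA`.
#'
#' @param domain A [build_domain()] lattice.
#' @param site Integer site indices.
#' @return A data frame with columns `site`, `bmp_agent`, `fe_element`,
#'   `bv_voxel`.
#' @export
map_indices <- function(domain, site) {
  stopifnot(inherits(domain, "region_lattice"))
  site <- as.integer(site)
  n <- prod(domain$dims)
  if (any(site < 1L | site > n))
    stop("map_indices: site index out of range", call. = FALSE)
  if (any(domain$region[site] == REGION_OUTSIDE))
    stop("map_indices: site lies outside the domain", call. = FALSE)
  co <- site_coords(domain, site)
  b <- domain$bv
  vox <- b$voxel
  vi <- floor((co[, 1] - b$xlim[1]) / vox)
  vj <- floor((co[, 2] - b$ylim[1]) / vox)
  vk <- floor((co[, 3] - b$zlim[1]) / vox)
  nvx <- round(diff(b$xlim) / vox); nvy <- round(diff(b$ylim) / vox)
  nvz <- round(diff(b$zlim) / vox)
  ok <- vi >= 0 & vi < nvx & vj >= 0 & vj < nvy & vk >= 0 & vk < nvz
  bv_voxel <- ifelse(ok, 1 + vi + nvx * (vj + nvy * vk), NA_integer_)
  data.frame(
    site = site,
    bmp_agent = domain$agent_of_site[site],
    fe_element = domain$element_of_site[site],
    bv_voxel = as.integer(bv_voxel)
  )
}

# Cartesian coordinates (mm) of site centers.
site_coords <- function(domain, site = seq_len(prod(domain$dims))) {
  d <- domain$dims
  s <- site - 1L
  ix <- s %% d[1]; rem <- s %/% d[1]
  iy <- rem %% d[2]; iz <- rem %/% d[2]
  cbind(domain$xs[ix + 1L], domain$ys[iy + 1L], domain$zs[iz + 1L])
}

# Integer site index from integer grid coordinates (used by tests).
site_index <- function(domain, ix, iy, iz) {
  d <- domain$dims
  ix + d[1] * ((iy - 1L) + d[2] * (iz - 1L))
}
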