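# Finite-element stage: quasi-static small-strain linear poroelasticity
# (u-p two-field, trilinear hexahedra, equal-order interpolation) with a
# single backward-difference consolidation step over the load ramp. The
# element grid is a tensor-product hex mesh: uniform x/y spacing at the
# callus element size, fine axial spacing across the callus span and coarse
# axial spacing along the intact bone segments. Elements whose centroid
# falls outside the bone/callus cylinder are void and carry no DOFs.

build_fe_mesh <- function(config) {
  hc <- config$fe_element_size_callus
  ho <- config$fe_element_size_outer
  rcal <- config$callus_outer_radius
  w2 <- config$gap_width / 2
  zm <- config$bone_segment_length + w2
  lz <- 2 * config$bone_segment_length + config$gap_width
  fine_half <- w2 + config$callus_axial_overhang + config$marrow_margin

  nex <- max(1L, as.integer(round(2 * rcal / hc)))
  ney <- nex
  hx <- 2 * rcal / nex
  xn <- seq(-rcal, rcal, length.out = nex + 1L)
  yn <- xn

  z_lo <- max(0, zm - fine_half)
  z_hi <- min(lz, zm + fine_half)
  n_fine <- max(1L, as.integer(round((z_hi - z_lo) / hc)))
  zn_fine <- seq(z_lo, z_hi, length.out = n_fine + 1L)
  zn <- zn_fine
  if (z_lo > 1e-9) {
    n_lo <- max(1L, as.integer(round(z_lo / ho)))
    zn <- c(seq(0, z_lo, length.out = n_lo + 1L)[-(n_lo + 1L)], zn)
  }
  if (z_hi < lz - 1e-9) {
    n_hi <- max(1L, as.integer(round((lz - z_hi) / ho)))
    zn <- c(zn, seq(z_hi, lz, length.out = n_hi + 1L)[-1L])
  }
  nez <- length(zn) - 1L
  hz <- diff(zn)

  ecx <- (xn[-1L] + xn[-(nex + 1L)]) / 2
  ecy <- (yn[-1L] + yn[-(ney + 1L)]) / 2
  ecz <- (zn[-1L] + zn[-(nez + 1L)]) / 2
  cx <- rep.int(ecx, ney * nez)
  cy <- rep.int(rep(ecy, each = nex), nez)
  cz <- rep(ecz, each = nex * ney)
  region <- classify_region(cx, cy, cz, config)

  mesh <- list(
    nex = nex, ney = ney, nez = nez,
    xn = xn, yn = yn, zn = zn,
    hx = hx, hy = hx, hz = hz,
    centroid = cbind(cx, cy, cz),
    ez_of_element = rep(seq_len(nez), each = nex * ney),
    region = region,
    midplane_z = zm,
    gap_halfwidth = w2,
    callus_overhang = config$callus_axial_overhang
  )
  finalize_fe_mesh(mesh)
}

finalize_fe_mesh <- function(mesh) {
  active <- which(mesh$region != REGION_OUTSIDE)
  active_id <- integer(mesh$nex * mesh$ney * mesh$nez)
  active_id[active] <- seq_along(active)
  mesh$active <- active
  mesh$active_id <- active_id
  areg <- mesh$region[active]
  mesh$active_region <- areg
  mesh$tissue <- which(areg %in% c(REGION_GAP, REGION_CALLUS))
  ez <- mesh$ez_of_element[active]
  mesh$active_ez <- ez
  mesh$volume <- mesh$hx * mesh$hy * mesh$hz[ez]  # mm^3 per active element
  mesh
}

# 8-node trilinear hexahedron reference matrices for a box hx x hy x hz.
# Local DOF order: (u1x,u1y,u1z, ..., u8x,u8y,u8z) then (p1..p8).
# Returns the lambda and mu parts of the stiffness, the divergence coupling
# Q, the unit-permeability conductivity H, the pressure mass Mp, and the
# centroid strain/gradient operators.
hex_matrices <- function(hx, hy, hz) {
  xi_n <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  et_n <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  ze_n <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  g <- 1 / sqrt(3)
  gp <- expand.grid(xi = c(-g, g), et = c(-g, g), ze = c(-g, g))
  wjac <- hx * hy * hz / 8  # |J| (constant), unit Gauss weights

  shape <- function(xi, et, ze) {
    n <- (1 + xi * xi_n) * (1 + et * et_n) * (1 + ze * ze_n) / 8
    dx <- xi_n * (1 + et * et_n) * (1 + ze * ze_n) / 8 * (2 / hx)
    dy <- (1 + xi * xi_n) * et_n * (1 + ze * ze_n) / 8 * (2 / hy)
    dz <- (1 + xi * xi_n) * (1 + et * et_n) * ze_n / 8 * (2 / hz)
    list(n = n, dx = dx, dy = dy, dz = dz)
  }
  bmat <- function(s) {
    b <- matrix(0, 6, 24)
    ixs <- 3 * (0:7)
    b[1, ixs + 1] <- s$dx
    b[2, ixs + 2] <- s$dy
    b[3, ixs + 3] <- s$dz
    b[4, ixs + 1] <- s$dy; b[4, ixs + 2] <- s$dx
    b[5, ixs + 2] <- s$dz; b[5, ixs + 3] <- s$dy
    b[6, ixs + 1] <- s$dz; b[6, ixs + 3] <- s$dx
    b
  }

  ka <- matrix(0, 24, 24); kb <- matrix(0, 24, 24)
  q <- matrix(0, 24, 8); h <- matrix(0, 8, 8); mp <- matrix(0, 8, 8)
  d0 <- diag(c(2, 2, 2, 1, 1, 1))
  for (i in seq_len(nrow(gp))) {
    s <- shape(gp$xi[i], gp$et[i], gp$ze[i])
    b <- bmat(s)
    divr <- b[1, ] + b[2, ] + b[3, ]  # divergence row (1 x 24)
    ka <- ka + wjac * tcrossprod(divr)
    kb <- kb + wjac * t(b) %*% d0 %*% b
    q <- q + wjac * tcrossprod(divr, s$n)
    gradp <- rbind(s$dx, s$dy, s$dz)
    h <- h + wjac * crossprod(gradp)
    mp <- mp + wjac * tcrossprod(s$n)
  }
  s0 <- shape(0, 0, 0)
  list(ka = ka, kb = kb, q = q, h = h, mp = mp,
       b0 = bmat(s0), g0 = rbind(s0$dx, s0$dy, s0$dz))
}

# Connectivity (8 global node ids, VTK ordering) for active elements.
fe_connectivity <- function(mesh) {
  nnx <- mesh$nex + 1L; nny <- mesh$ney + 1L
  e <- mesh$active - 1L
  ex <- e %% mesh$nex
  rem <- e %/% mesh$nex
  ey <- rem %% mesh$ney
  ez <- rem %/% mesh$ney
  nid <- function(i, j, k) 1L + i + nnx * (j + nny * k)
  cbind(nid(ex, ey, ez), nid(ex + 1L, ey, ez),
        nid(ex + 1L, ey + 1L, ez), nid(ex, ey + 1L, ez),
        nid(ex, ey, ez + 1L), nid(ex + 1L, ey, ez + 1L),
        nid(ex + 1L, ey + 1L, ez + 1L), nid(ex, ey + 1L, ez + 1L))
}

#' Mechanical load case
#'
#' Describes one mechanics evaluation: either habitual `gait` loading (axial
#' compressive force at the proximal bone end, external fixator crossbar in
#' place) or an external `stimulation` episode (500-um axial compression
#' ramp applied with the crossbar removed).
#'
#' @param kind `"gait"` or `"stimulation"`.
#' @param axial_displacement_um Stimulation displacement amplitude (um).
#' @param ramp_rate_um_s Stimulation displacement rate (um/s); together with
#'   the amplitude it sets the consolidation interval of the poroelastic step.
#' @param gait_force_n Axial gait force (N, compression).
#' @param gait_ramp_s Characteristic gait loading time (s).
#' @param crossbar Is the fixator crossbar mounted? Stimulation requires it
#'   removed.
#' @param fixator_stiffness_n_mm Axial fixator spring stiffness (N/mm).
#' @param constraint Displacement constraint at the distal end: `"clamped"`
#'   (all components fixed) or `"roller"` (axial only, with minimal lateral
#'   pinning; used for patch tests).
#' @return An object of class `load_case`.
#' @export
load_case <- function(kind = c("gait", "stimulation"),
                      axial_displacement_um = 500,
                      ramp_rate_um_s = 10,
                      gait_force_n = 7,
                      gait_ramp_s = 0.5,
                      crossbar = (match.arg(kind) == "gait"),
                      fixator_stiffness_n_mm = 100,
                      constraint = c("clamped", "roller")) {
  kind <- match.arg(kind)
  constraint <- match.arg(constraint)
  if (kind == "stimulation" && crossbar)
    stop("load_case: the stimulation episode requires the crossbar removed",
         call. = FALSE)
  structure(list(kind = kind,
                 axial_displacement_um = axial_displacement_um,
                 ramp_rate_um_s = ramp_rate_um_s,
                 gait_force_n = gait_force_n,
                 gait_ramp_s = gait_ramp_s,
                 crossbar = crossbar,
                 fixator_stiffness_n_mm = fixator_stiffness_n_mm,
                 constraint = constraint),
            class = "load_case")
}

# Permeability card units (1e-14 m^4/(N s)) to mm^4/(N s).
PERM_TO_MM <- 1e-2

#' Solve one quasi-static poroelastic step
#'
#' Assembles and solves the coupled displacement-pressure system for the
#' current homogenized materials and load case, then evaluates the
#' element-centroid strain tensor, Darcy fluid speed, octahedral shear
#' strain and Prendergast stimulus.
#'
#' @param mesh FE mesh, as found in `build_domain(...)$mesh`.
#' @param materials Data frame with one row per active element and columns
#'   `young_modulus`, `poisson_ratio`, `permeability`, `bulk_modulus_grain`,
#'   `bulk_modulus_fluid`, `porosity` (see [homogenize_materials()]).
#' @param load A [load_case()].
#' @return An object of class `mechanical_state`: matrix `e` (active
#'   elements x 6 strain components `e11,e22,e33,e12,e23,e13`, tensor
#'   shears), vectors `gamma`, `upsilon` (um/s), `S`, and the interfragmentary
#'   displacement `delta_if` (mm).
#' @export
solve_step <- function(mesh, materials, load = load_case()) {
  ne <- length(mesh$active)
  if (nrow(materials) != ne)
    stop("solve_step: materials must have one row per active element",
         call. = FALSE)
  if (any(!is.finite(materials$young_modulus)) ||
      any(materials$young_modulus <= 0))
    stop("solve_step: non-positive Young's modulus", call. = FALSE)

  conn <- fe_connectivity(mesh)
  used_nodes <- sort(unique(as.vector(conn)))
  node_id <- integer((mesh$nex + 1L) * (mesh$ney + 1L) * (mesh$nez + 1L))
  node_id[used_nodes] <- seq_along(used_nodes)
  nn <- length(used_nodes)
  connl <- matrix(node_id[conn], ne, 8L)

  nnx <- mesh$nex + 1L; nny <- mesh$ney + 1L
  g <- used_nodes - 1L
  node_xyz <- cbind(mesh$xn[g %% nnx + 1L],
                    mesh$yn[(g %/% nnx) %% nny + 1L],
                    mesh$zn[g %/% (nnx * nny) + 1L])

  e_mod <- materials$young_modulus
  nu <- materials$poisson_ratio
  mu <- e_mod / (2 * (1 + nu))
  lam <- e_mod * nu / ((1 + nu) * (1 - 2 * nu))
  kperm <- materials$permeability * PERM_TO_MM
  inv_m <- materials$porosity / materials$bulk_modulus_fluid +
    (1 - materials$porosity) / materials$bulk_modulus_grain

  tau <- if (load$kind == "stimulation") {
    (load$axial_displacement_um / load$ramp_rate_um_s)
  } else load$gait_ramp_s

  udof <- function(nodes, comp) 3L * (nodes - 1L) + comp
  pdof_off <- 3L * nn
  ndof <- 4L * nn

  hz_key <- round(mesh$hz[mesh$active_ez], 12)
  groups <- split(seq_len(ne), hz_key)
  ti <- tj <- tx <- vector("list", 3L * length(groups))
  slot <- 0L
  refs <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    hzg <- mesh$hz[mesh$active_ez[idx[1L]]]
    ref <- hex_matrices(mesh$hx, mesh$hy, hzg)
    refs[[gname]] <- ref
    cg <- connl[idx, , drop = FALSE]
    dmat <- matrix(0L, length(idx), 24L)
    for (a in 1:8) dmat[, (3 * a - 2):(3 * a)] <-
      cbind(udof(cg[, a], 1L), udof(cg[, a], 2L), udof(cg[, a], 3L))
    pmat <- pdof_off + cg

    rp24 <- rep(1:24, times = 24); cp24 <- rep(1:24, each = 24)
    vals <- tcrossprod(as.vector(ref$ka), lam[idx]) +
      tcrossprod(as.vector(ref$kb), mu[idx])
    slot <- slot + 1L
    ti[[slot]] <- as.vector(t(dmat[, rp24, drop = FALSE]))
    tj[[slot]] <- as.vector(t(dmat[, cp24, drop = FALSE]))
    tx[[slot]] <- as.vector(vals)

    # coupling blocks: -Q (u,p) and -Q^T (p,u)  [symmetric indefinite form]
    rq <- rep(1:24, times = 8); cq <- rep(1:8, each = 24)
    qv <- as.vector(tcrossprod(as.vector(ref$q), rep.int(1, length(idx))))
    iu <- as.vector(t(dmat[, rq, drop = FALSE]))
    jp <- as.vector(t(pmat[, cq, drop = FALSE]))
    slot <- slot + 1L
    ti[[slot]] <- c(iu, jp)
    tj[[slot]] <- c(jp, iu)
    tx[[slot]] <- c(-qv, -qv)

    # pressure block: -(Sc + tau * H)
    rp8 <- rep(1:8, times = 8); cp8 <- rep(1:8, each = 8)
    pv <- tcrossprod(as.vector(ref$mp), inv_m[idx]) +
      tcrossprod(as.vector(ref$h), tau * kperm[idx])
    slot <- slot + 1L
    ti[[slot]] <- as.vector(t(pmat[, rp8, drop = FALSE]))
    tj[[slot]] <- as.vector(t(pmat[, cp8, drop = FALSE]))
    tx[[slot]] <- as.vector(-pv)
  }

  zmin <- min(node_xyz[, 3]); zmax <- max(node_xyz[, 3])
  tol <- 1e-9
  bottom <- which(abs(node_xyz[, 3] - zmin) < tol)
  top <- which(abs(node_xyz[, 3] - zmax) < tol)

  b <- numeric(ndof)
  fixed <- integer(0)
  ufix <- numeric(0)

  if (load$constraint == "clamped") {
    fixed <- c(fixed, udof(rep(bottom, each = 3L), rep(1:3, length(bottom))))
    ufix <- c(ufix, numeric(3L * length(bottom)))
  } else {
    fixed <- c(fixed, udof(bottom, 3L))
    ufix <- c(ufix, numeric(length(bottom)))
    pin <- bottom[which.min(node_xyz[bottom, 1]^2 + node_xyz[bottom, 2]^2)]
    pin2 <- bottom[which.max(node_xyz[bottom, 1])]
    fixed <- c(fixed, udof(pin, 1L), udof(pin, 2L), udof(pin2, 2L))
    ufix <- c(ufix, 0, 0, 0)
  }

  if (load$kind == "stimulation") {
    dz <- -load$axial_displacement_um / 1000  # um -> mm, compression
    fixed <- c(fixed, udof(top, 3L))
    ufix <- c(ufix, rep(dz, length(top)))
  } else {
    b[udof(top, 3L)] <- -load$gait_force_n / length(top)
    if (load$crossbar && load$fixator_stiffness_n_mm > 0) {
      kspr <- load$fixator_stiffness_n_mm / length(top)
      slot <- slot + 1L
      ti[[slot]] <- udof(top, 3L); tj[[slot]] <- udof(top, 3L)
      tx[[slot]] <- rep(kspr, length(top))
    }
  }

  amat <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                               x = unlist(tx), dims = c(ndof, ndof))
  keep <- !duplicated(fixed)
  fixed <- fixed[keep]; ufix <- ufix[keep]
  free <- setdiff(seq_len(ndof), fixed)
  rhs <- b[free] - as.vector(amat[free, fixed, drop = FALSE] %*% ufix)
  sol <- tryCatch(
    Matrix::solve(amat[free, free], rhs),
    error = function(e) stop("solve_step: singular or ill-conditioned system (",
                             conditionMessage(e), ")", call. = FALSE))
  x <- numeric(ndof)
  x[fixed] <- ufix
  x[free] <- as.vector(sol)

  strain <- matrix(0, ne, 6L)
  gradp <- matrix(0, ne, 3L)
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    ref <- refs[[gname]]
    cg <- connl[idx, , drop = FALSE]
    ue <- matrix(0, length(idx), 24L)
    for (a in 1:8) ue[, (3 * a - 2):(3 * a)] <-
      cbind(x[udof(cg[, a], 1L)], x[udof(cg[, a], 2L)], x[udof(cg[, a], 3L)])
    pe <- matrix(x[pdof_off + cg], length(idx), 8L)
    strain[idx, ] <- ue %*% t(ref$b0)
    gradp[idx, ] <- pe %*% t(ref$g0)
  }
  # engineering -> tensor shears
  strain[, 4:6] <- strain[, 4:6] / 2
  colnames(strain) <- c("e11", "e22", "e33", "e12", "e23", "e13")
  vmag <- kperm * sqrt(rowSums(gradp^2))  # mm/s
  upsilon <- vmag * 1000                  # um/s
  gamma <- octahedral_shear(strain)

  top_uz <- mean(x[udof(top, 3L)])
  state <- list(e = strain, gamma = gamma, upsilon = upsilon,
                S = prendergast_stimulus(gamma, upsilon),
                delta_if = abs(top_uz), backend = "fe")
  class(state) <- "mechanical_state"
  state
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat("<mechanical_state> (", x$backend, " backend)\n", sep = "")
  cat(sprintf("  elements: %d | gamma max %.4g | fluid speed max %.4g um/s\n",
              length(x$gamma), max(x$gamma), max(x$upsilon)))
  cat(sprintf("  stimulus S: median %.3g, max %.3g | interfragmentary %.4g mm\n",
              stats::median(x$S), max(x$S), x$delta_if))
  invisible(x)
}

# Convenience mesh builder for verification problems: a rectangular block of
# nx x ny x nz uniform hex elements with edge h (mm), all one region.
fe_block_mesh <- function(nx = 2L, ny = 2L, nz = 2L, h = 1) {
  mesh <- list(
    nex = as.integer(nx), ney = as.integer(ny), nez = as.integer(nz),
    xn = seq(0, nx * h, by = h), yn = seq(0, ny * h, by = h),
    zn = seq(0, nz * h, by = h),
    hx = h, hy = h, hz = rep(h, nz),
    centroid = NULL,
    ez_of_element = rep(seq_len(nz), each = nx * ny),
    region = rep.int(REGION_GAP, nx * ny * nz),
    midplane_z = nz * h / 2, gap_halfwidth = nz * h / 2, callus_overhang = 0
  )
  cx <- rep.int((seq_len(nx) - 0.5) * h, ny * nz)
  cy <- rep.int(rep((seq_len(ny) - 0.5) * h, each = nx), nz)
  cz <- rep((seq_len(nz) - 0.5) * h, each = nx * ny)
  mesh$centroid <- cbind(cx, cy, cz)
  finalize_fe_mesh(mesh)
}

# Uniform material table for a block mesh.
uniform_materials <- function(mesh, card = default_material_table()["granulation", ]) {
  ne <- length(mesh$active)
  out <- card[rep(1, ne), HOMOG_PROPS]
  rownames(out) <- NULL
  out
}
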