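#' Tissue production and degradation rate table
#'
#' Matrix volume produced/resorbed per cell per hour (um^3/cell/h) for the
#' three cell-made tissues. Granulation tissue is the filler phase and has
#' no rates of its own.
#'
#' @return Data frame with rows `fibrous`, `cartilage`, `bone`.
#' @export
default_production_table <- function() {
  p <- data.frame(
    tissue = c("fibrous", "cartilage", "bone"),
    production_rate = c(5000, 5000, 3000),
    degradation_rate = c(5000, 5000, 3000)
  )
  rownames(p) <- p$tissue
  p
}

TISSUE_COLS <- c("granulation", "fibrous", "cartilage", "bone")
# producing phenotype -> tissue column (MSCs produce nothing)
TISSUE_OF_PHENO <- c(NA, "fibrous", "cartilage", "bone")

#' Initialize per-element tissue volume fractions
#'
#' Every tissue element (defect gap and callus growth region) starts as
#' 100% granulation tissue. Fractions live on the simplex: each row is
#' non-negative and sums to one.
#'
#' @param domain A [build_domain()] lattice.
#' @return A `tissue_fractions` object: matrix (tissue elements x 4) with
#'   attributes `element` (active element ids) and `volume_um3`.
#' @export
tissue_fractions <- function(domain) {
  mesh <- domain$mesh
  ne <- length(mesh$tissue)
  fr <- matrix(0, ne, 4L, dimnames = list(NULL, TISSUE_COLS))
  fr[, "granulation"] <- 1
  attr(fr, "element") <- mesh$tissue
  attr(fr, "volume_um3") <- mesh$volume[mesh$tissue] * 1e9  # mm^3 -> um^3
  class(fr) <- c("tissue_fractions", class(fr))
  fr
}

# Row index into the fractions matrix for each active element (NA outside
# the tissue region).
tissue_row_of_element <- function(domain, fractions) {
  row <- rep(NA_integer_, length(domain$mesh$active))
  row[attr(fractions, "element")] <- seq_len(nrow(fractions))
  row
}

#' Cell-driven tissue production
#'
#' Each differentiated cell deposits its phenotype's matrix into the element
#' it occupies: fibroblasts fibrous tissue, chondrocytes cartilage,
#' osteoblasts bone (scaled by the local BMP-2 bone-production factor). The
#' deposited volume (`rate * dt * representation factor`) is converted to a
#' fraction of the element volume and taken from the granulation filler;
#' fractions stay on the simplex.
#'
#' @param cells A `cell_lattice`.
#' @param domain The `region_lattice`.
#' @param fractions A [tissue_fractions()] matrix.
#' @param table Production/degradation table.
#' @param bone_factor_site BMP-2 bone-production fold-factor per cell site
#'   (>= 1; applies to osteoblasts only).
#' @param dt_hours Iteration length (h).
#' @return Updated `tissue_fractions`.
#' @export
produce_tissue <- function(cells, domain, fractions,
                           table = default_production_table(),
                           bone_factor_site = 1, dt_hours = 2) {
  if (any(bone_factor_site < 1 - 1e-9))
    stop("produce_tissue: bone production factors must be >= 1", call. = FALSE)
  if (length(bone_factor_site) == 1L)
    bone_factor_site <- rep(bone_factor_site, length(cells$occ))
  trow <- tissue_row_of_element(domain, fractions)
  idx <- which(cells$occ %in% c(PHENO_FIBROBLAST, PHENO_CHONDROCYTE,
                                PHENO_OSTEOBLAST))
  row <- trow[domain$element_of_site[idx]]
  keep <- !is.na(row)
  idx <- idx[keep]; row <- row[keep]
  if (!length(idx)) return(fractions)

  pheno <- cells$occ[idx]
  vol <- table[TISSUE_OF_PHENO[pheno], "production_rate"] * dt_hours *
    domain$n_rep
  vol[pheno == PHENO_OSTEOBLAST] <- vol[pheno == PHENO_OSTEOBLAST] *
    bone_factor_site[idx[pheno == PHENO_OSTEOBLAST]]

  add <- matrix(0, nrow(fractions), 3L,
                dimnames = list(NULL, c("fibrous", "cartilage", "bone")))
  for (p in c(PHENO_FIBROBLAST, PHENO_CHONDROCYTE, PHENO_OSTEOBLAST)) {
    sel <- pheno == p
    if (!any(sel)) next
    agg <- rowsum(vol[sel], row[sel])
    add[as.integer(rownames(agg)), TISSUE_OF_PHENO[p]] <-
      add[as.integer(rownames(agg)), TISSUE_OF_PHENO[p]] + agg[, 1]
  }
  dfrac <- add / attr(fractions, "volume_um3")
  tot <- rowSums(dfrac)
  scale <- ifelse(tot > 0, pmin(1, fractions[, "granulation"] / tot), 0)
  dfrac <- dfrac * scale
  fractions[, c("fibrous", "cartilage", "bone")] <-
    fractions[, c("fibrous", "cartilage", "bone")] + dfrac
  fractions[, "granulation"] <- pmax(0, fractions[, "granulation"] -
                                          rowSums(dfrac))
  fractions
}

#' Cell-driven tissue degradation
#'
#' Differentiated cells resorb mismatched matrix: in each element, a tissue
#' loses `degradation rate x number of resident differentiated cells of
#' other producing phenotypes x dt`, returned to the granulation filler.
#' MSCs resorb nothing and acellular elements are inert.
#'
#' @inheritParams produce_tissue
#' @return Updated `tissue_fractions`.
#' @export
degrade_tissue <- function(cells, domain, fractions,
                           table = default_production_table(), dt_hours = 2) {
  trow <- tissue_row_of_element(domain, fractions)
  idx <- which(cells$occ %in% c(PHENO_FIBROBLAST, PHENO_CHONDROCYTE,
                                PHENO_OSTEOBLAST))
  row <- trow[domain$element_of_site[idx]]
  keep <- !is.na(row)
  idx <- idx[keep]; row <- row[keep]
  if (!length(idx)) return(fractions)
  pheno <- cells$occ[idx]

  counts <- matrix(0, nrow(fractions), 3L,
                   dimnames = list(NULL, c("fibrous", "cartilage", "bone")))
  for (p in c(PHENO_FIBROBLAST, PHENO_CHONDROCYTE, PHENO_OSTEOBLAST)) {
    sel <- pheno == p
    if (!any(sel)) next
    agg <- rowsum(rep(1, sum(sel)), row[sel])
    counts[as.integer(rownames(agg)), TISSUE_OF_PHENO[p]] <- agg[, 1]
  }
  n_diff <- rowSums(counts)
  removed <- matrix(0, nrow(fractions), 3L)
  colnames(removed) <- c("fibrous", "cartilage", "bone")
  for (tname in c("fibrous", "cartilage", "bone")) {
    mism <- n_diff - counts[, tname]  # cells of the other producing phenotypes
    loss <- table[tname, "degradation_rate"] * mism * dt_hours *
      domain$n_rep / attr(fractions, "volume_um3")
    removed[, tname] <- pmin(fractions[, tname], loss)
  }
  fractions[, c("fibrous", "cartilage", "bone")] <-
    fractions[, c("fibrous", "cartilage", "bone")] - removed
  fractions[, "granulation"] <- fractions[, "granulation"] + rowSums(removed)
  fractions
}

#' MicroCT-style bone-volume voxelization
#'
#' The callus bounding box is divided into small cubic voxels; a voxel is
#' "bone" iff the bone volume fraction, trilinearly interpolated from the
#' element-center values to the voxel center, exceeds one half, and the
#' voxel lies in the defect gap or callus growth region (the bone cortices
#' are excluded from the quantification). The mineralized volume BV is the
#' bone-voxel count times the voxel volume.
#'
#' @param fractions A [tissue_fractions()] matrix.
#' @param domain The `region_lattice`.
#' @param voxel_mm Voxel edge length (mm); defaults to the domain
#'   configuration.
#' @return A `bv_report`: logical `bone` array, `bv_mm3`, `n_bone`,
#'   `voxel_mm`, plus the voxel-center axes and cortex mask used by
#'   [detect_bridging()].
#' @export
voxelize_bv <- function(fractions, domain,
                        voxel_mm = domain$config$bv_voxel_size) {
  mesh <- domain$mesh
  b <- domain$bv
  nvx <- max(1L, as.integer(round(diff(b$xlim) / voxel_mm)))
  nvy <- max(1L, as.integer(round(diff(b$ylim) / voxel_mm)))
  nvz <- max(1L, as.integer(round(diff(b$zlim) / voxel_mm)))
  vx <- b$xlim[1] + (seq_len(nvx) - 0.5) * voxel_mm
  vy <- b$ylim[1] + (seq_len(nvy) - 0.5) * voxel_mm
  vz <- b$zlim[1] + (seq_len(nvz) - 0.5) * voxel_mm

  # element-center bone-fraction array over the full element grid
  arr <- numeric(mesh$nex * mesh$ney * mesh$nez)
  arr[mesh$active[attr(fractions, "element")]] <- fractions[, "bone"]
  dim(arr) <- c(mesh$nex, mesh$ney, mesh$nez)

  ecx <- (mesh$xn[-1L] + mesh$xn[-length(mesh$xn)]) / 2
  ecy <- (mesh$yn[-1L] + mesh$yn[-length(mesh$yn)]) / 2
  ecz <- (mesh$zn[-1L] + mesh$zn[-length(mesh$zn)]) / 2
  axw <- function(v, centers) {
    i0 <- pmin(pmax(findInterval(v, centers), 1L), length(centers) - 1L)
    if (length(centers) == 1L) return(list(i0 = rep(1L, length(v)),
                                           t = numeric(length(v))))
    t <- (v - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    list(i0 = i0, t = pmin(pmax(t, 0), 1))
  }
  wx <- axw(vx, ecx); wy <- axw(vy, ecy); wz <- axw(vz, ecz)
  val <- array(0, dim = c(nvx, nvy, nvz))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(wx$i0 + dx, length(ecx))
    iy <- pmin(wy$i0 + dy, length(ecy))
    iz <- pmin(wz$i0 + dz, length(ecz))
    term <- arr[ix, iy, iz, drop = FALSE]
    dim(term) <- c(nvx, nvy, nvz)
    term <- term * (if (dx) wx$t else 1 - wx$t)
    term <- sweep(term, 2, if (dy) wy$t else 1 - wy$t, `*`)
    term <- sweep(term, 3, if (dz) wz$t else 1 - wz$t, `*`)
    val <- val + term
  }

  px <- rep.int(vx, nvy * nvz)
  py <- rep.int(rep(vy, each = nvx), nvz)
  pz <- rep(vz, each = nvx * nvy)
  vreg <- classify_region(px, py, pz, domain$config)
  countable <- array(vreg %in% c(REGION_GAP, REGION_CALLUS),
                     dim = c(nvx, nvy, nvz))
  cortex <- array(vreg == REGION_CORTEX, dim = c(nvx, nvy, nvz))

  bone <- val > 0.5 & countable
  out <- list(bone = bone, n_bone = sum(bone),
              bv_mm3 = sum(bone) * voxel_mm^3,
              voxel_mm = voxel_mm, vx = vx, vy = vy, vz = vz,
              cortex = cortex,
              midplane_z = domain$midplane_z,
              gap_halfwidth = domain$config$gap_width / 2)
  class(out) <- "bv_report"
  out
}

#' @export
print.bv_report <- function(x, ...) {
  cat(sprintf("<bv_report> %d bone voxels of %g mm -> BV = %.4g mm^3\n",
              x$n_bone, x$voxel_mm, x$bv_mm3))
  invisible(x)
}

# 6-neighborhood binary dilation of a 3D logical array.
dilate6 <- function(a) {
  d <- dim(a)
  out <- a
  if (d[1] > 1) {
    out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  }
  if (d[2] > 1) {
    out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  }
  if (d[3] > 1) {
    out[, , -1] <- out[, , -1] | a[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  }
  out
}

#' Bony bridging detection
#'
#' The defect is bridged when a 6-connected path of bone voxels connects
#' the proximal and distal cortical bone ends across the gap. The detector
#' flood-fills the bone-voxel set from the voxels adjacent to the proximal
#' cortex and reports whether the fill reaches the neighborhood of the
#' distal cortex.
#'
#' @param report A [voxelize_bv()] report.
#' @return Logical.
#' @export
detect_bridging <- function(report) {
  stopifnot(inherits(report, "bv_report"))
  bone <- report$bone
  if (!any(bone)) return(FALSE)
  zc <- report$midplane_z
  prox <- report$cortex &
    array(rep(report$vz < zc, each = length(report$vx) * length(report$vy)),
          dim = dim(bone))
  dist <- report$cortex & !prox
  if (!any(prox) || !any(dist)) return(FALSE)
  reach <- bone & dilate6(prox)
  if (!any(reach)) return(FALSE)
  repeat {
    grown <- dilate6(reach) & bone
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  any(dilate6(reach) & dist)
}
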