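#' Write a 3D scalar field as a legacy ASCII VTK file
#'
#' Emits a `STRUCTURED_POINTS` dataset (VTK legacy format, readable by
#' ParaView and friends) for a regular 3D array such as a BMP-2
#' concentration field or a Boolean bone-voxel grid.
#'
#' @param a 3D numeric or logical array.
#' @param path Output file path.
#' @param spacing Grid spacing (mm), scalar or length-3.
#' @param origin Grid origin (mm), length-3.
#' @param name Name of the scalar field.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(a, path, spacing = 1, origin = c(0, 0, 0),
                            name = "field") {
  stopifnot(length(dim(a)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(a)
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing[1], spacing[2], spacing[3]),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(as.numeric(a), format = "g"), con)
  invisible(path)
}

#' Export a cell snapshot as CSV
#'
#' One row per cell: site index, lattice coordinates (mm), phenotype name
#' and osteoblast maturity.
#'
#' @param cells A `cell_lattice`.
#' @param domain The `region_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(cells, domain, path) {
  idx <- which(cells$occ != PHENO_EMPTY)
  co <- site_coords(domain, idx)
  df <- data.frame(site = idx, x = co[, 1], y = co[, 2], z = co[, 3],
                   phenotype = PHENO_NAMES[cells$occ[idx]],
                   mature = cells$mature[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export simulation outputs
#'
#' Writes the BV time series and daily census as CSV, a JSON run manifest
#' with the fully resolved configuration and seed, per-output-day cell
#' snapshots (CSV), and BMP-2 / bone-voxel fields as legacy VTK files.
#'
#' @param result A [run_scenario()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
export_simulation <- function(result, outdir) {
  stopifnot(inherits(result, "healing_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$bv, file.path(outdir, "bv.csv"), row.names = FALSE)
  utils::write.csv(result$census, file.path(outdir, "census.csv"),
                   row.names = FALSE)
  cfg <- result$config
  cfg$domain <- unclass(cfg$domain)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dom <- result$domain
  for (snap in result$snapshots) {
    tag <- sprintf("day%02d", snap$day)
    write_cell_csv(snap$cells, dom, file.path(outdir, paste0("cells_", tag, ".csv")))
    write_vtk_image(snap$conc, file.path(outdir, paste0("bmp2_", tag, ".vtk")),
                    spacing = dom$agent_pitch, origin = dom$origin,
                    name = "bmp2_ng_cm3")
    write_vtk_image(snap$bv$bone * 1,
                    file.path(outdir, paste0("bone_", tag, ".vtk")),
                    spacing = snap$bv$voxel_mm,
                    origin = c(dom$bv$xlim[1], dom$bv$ylim[1], dom$bv$zlim[1]),
                    name = "bone")
  }
  invisible(outdir)
}
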