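# A domain plus one cell of the given phenotype placed mid-gap.
one_cell_setup <- function(pheno = callusim:::PHENO_OSTEOBLAST) {
  dom <- small_domain(spacing_um = 500)
  site <- which(dom$region == callusim:::REGION_GAP)[200]
  cells <- list(occ = integer(prod(dom$dims)),
                mature = logical(prod(dom$dims)))
  class(cells) <- "cell_lattice"
  cells$occ[site] <- pheno
  list(dom = dom, cells = cells, site = site)
}

test_that("one osteoblast deposits rate * dt of bone, taken from granulation", {
  su <- one_cell_setup()
  fr <- tissue_fractions(su$dom)
  out <- produce_tissue(su$cells, su$dom, fr, dt_hours = 2)
  row <- callusim:::tissue_row_of_element(su$dom, fr)[
    su$dom$element_of_site[su$site]]
  added_um3 <- unname(out[row, "bone"] * attr(fr, "volume_um3")[row])
  expect_equal(added_um3, 3000 * 2 * su$dom$n_rep)  # 6000 um^3 per cell
  expect_equal(unname(out[row, "granulation"]), unname(1 - out[row, "bone"]))
  expect_equal(rowSums(out), rep(1, nrow(out)))
  # a threefold BMP-2 factor triples the increment
  out3 <- produce_tissue(su$cells, su$dom, fr, bone_factor_site = 3,
                         dt_hours = 2)
  expect_equal(out3[row, "bone"], 3 * out[row, "bone"])
  # no cells, no change
  empty <- su$cells; empty$occ[] <- 0L
  expect_equal(produce_tissue(empty, su$dom, fr), fr, ignore_attr = TRUE)
})

test_that("a mismatched chondrocyte removes fibrous matrix at the table rate", {
  su <- one_cell_setup(callusim:::PHENO_CHONDROCYTE)
  fr <- tissue_fractions(su$dom)
  row <- callusim:::tissue_row_of_element(su$dom, fr)[
    su$dom$element_of_site[su$site]]
  fr[row, "fibrous"] <- 0.5; fr[row, "granulation"] <- 0.5
  out <- degrade_tissue(su$cells, su$dom, fr, dt_hours = 2)
  removed_um3 <- unname((0.5 - out[row, "fibrous"]) * attr(fr, "volume_um3")[row])
  expect_equal(removed_um3, 5000 * 2 * su$dom$n_rep)  # 10000 um^3 per cell
  expect_equal(rowSums(out), rep(1, nrow(out)))
  # acellular elements are inert and matched tissue is spared
  expect_equal(sum(out[-row, ] != fr[-row, ]), 0)
  expect_equal(unname(out[row, "cartilage"]), 0)
})

test_that("production and degradation at matched rates cancel", {
  su <- one_cell_setup(callusim:::PHENO_CHONDROCYTE)
  # one chondrocyte and one fibroblast in the same element: the fibroblast
  # deposits 5000*dt of fibrous matrix, the chondrocyte removes 5000*dt
  nbs <- su$dom$nb[su$site, ]
  same_el <- nbs[su$dom$element_of_site[nbs] ==
                   su$dom$element_of_site[su$site]][1]
  skip_if(is.na(same_el))
  su$cells$occ[same_el] <- callusim:::PHENO_FIBROBLAST
  fr <- tissue_fractions(su$dom)
  row <- callusim:::tissue_row_of_element(su$dom, fr)[
    su$dom$element_of_site[su$site]]
  fr[row, "fibrous"] <- 0.3; fr[row, "granulation"] <- 0.7
  out <- produce_tissue(su$cells, su$dom, fr, dt_hours = 2)
  out <- degrade_tissue(su$cells, su$dom, out, dt_hours = 2)
  expect_equal(unname(out[row, "fibrous"]), 0.3, tolerance = 1e-12)
})

test_that("fractions stay on the simplex under aggressive production", {
  dom <- small_domain(spacing_um = 500)
  set.seed(21)
  cells <- list(occ = integer(prod(dom$dims)),
                mature = logical(prod(dom$dims)))
  class(cells) <- "cell_lattice"
  allowed <- which(dom$cells_allowed)
  cells$occ[allowed] <- sample(2:4, length(allowed), replace = TRUE)
  fr <- tissue_fractions(dom)
  for (i in 1:30) {
    fr <- produce_tissue(cells, dom, fr, bone_factor_site = 3, dt_hours = 24)
    fr <- degrade_tissue(cells, dom, fr, dt_hours = 24)
    expect_true(all(fr >= -1e-12 & fr <= 1 + 1e-12))
    expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-9)
  }
})

test_that("voxelization thresholds at one half and excludes the cortices", {
  dom <- small_domain(spacing_um = 500)
  fr <- tissue_fractions(dom)
  # all-granulation callus: BV = 0
  expect_equal(voxelize_bv(fr, dom)$bv_mm3, 0)
  # uniform 60% bone: every countable voxel is bone and BV is the voxel count
  fr[, "bone"] <- 0.6; fr[, "granulation"] <- 0.4
  rep6 <- voxelize_bv(fr, dom)
  expect_gt(rep6$n_bone, 0)
  expect_equal(rep6$bv_mm3, rep6$n_bone * dom$config$bv_voxel_size^3)
  # no voxel inside the cortex is counted
  expect_equal(sum(rep6$bone & rep6$cortex), 0)
  # uniform 40%: below threshold everywhere
  fr[, "bone"] <- 0.4; fr[, "granulation"] <- 0.6
  expect_equal(voxelize_bv(fr, dom)$n_bone, 0)
  # BV is invariant under relabeling of the non-bone tissues
  fr[, "bone"] <- 0.6
  fr[, "granulation"] <- 0; fr[, "fibrous"] <- 0.4
  expect_equal(voxelize_bv(fr, dom)$n_bone, rep6$n_bone)
})

test_that("BV uses the 0.04-mm voxel volume at native resolution", {
  # 1000 bone voxels of 6.4e-5 mm^3 give 0.064 mm^3
  expect_equal(1000 * 0.04^3, 0.064)
  dom <- small_domain(spacing_um = 500)
  fr <- tissue_fractions(dom)
  fr[, "bone"] <- 1; fr[, "granulation"] <- 0
  rep1 <- voxelize_bv(fr, dom, voxel_mm = 0.5)
  expect_equal(rep1$bv_mm3, rep1$n_bone * 0.5^3)
})

test_that("bridging requires a 6-connected bone path between the cortical ends", {
  dom <- small_domain(spacing_um = 500)
  fr <- tissue_fractions(dom)
  # all granulation: no bridge
  expect_false(detect_bridging(voxelize_bv(fr, dom)))
  # a solid bone callus bridges
  fr[, "bone"] <- 1; fr[, "granulation"] <- 0
  expect_true(detect_bridging(voxelize_bv(fr, dom)))
  # bone on both ends with a cleared central band does not bridge
  mesh <- dom$mesh
  cz <- mesh$centroid[mesh$active, 3][mesh$tissue]
  central <- abs(cz - dom$midplane_z) < 1.0
  fr[central, "bone"] <- 0
  fr[central, "granulation"] <- 1
  expect_false(detect_bridging(voxelize_bv(fr, dom)))
})
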