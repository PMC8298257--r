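test_that("octahedral shear strain matches closed forms", {
  expect_equal(octahedral_shear(rep(0, 6)), 0)
  expect_equal(octahedral_shear(c(0.03, 0, 0, 0, 0, 0)),
               2 * sqrt(2) / 3 * 0.03)
  # pure tensor shear e12 = s: gamma = (2/3) sqrt(6) |s|
  s <- 0.01
  expect_equal(octahedral_shear(c(0, 0, 0, s, 0, 0)), (2 / 3) * sqrt(6) * s)
  # rotation invariance: gamma of a rotated tensor is unchanged
  set.seed(1)
  e <- matrix(rnorm(9), 3); e <- (e + t(e)) / 200
  th <- 0.7
  q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  er <- q %*% e %*% t(q)
  as6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[2, 3], m[1, 3])
  expect_equal(octahedral_shear(as6(e)), octahedral_shear(as6(er)),
               tolerance = 1e-12)
  # the unsquared-shear variant truncates negative radicands at zero
  expect_equal(octahedral_shear(c(0, 0, 0, -0.1, 0, 0), strict = TRUE), 0)
})

test_that("Prendergast stimulus is the stated linear combination", {
  expect_equal(prendergast_stimulus(0.0375, 3), 2)
  expect_equal(prendergast_stimulus(0, 0), 0)
  expect_equal(prendergast_stimulus(0.075, 6), 4)
  g <- seq(0, 0.2, by = 0.04)
  expect_true(all(diff(prendergast_stimulus(g, 1)) > 0))
  expect_true(all(diff(prendergast_stimulus(0.01, g * 50)) > 0))
  expect_error(prendergast_stimulus(-0.1, 0), "non-negative")
})

test_that("differentiation ranges partition the stimulus axis as printed", {
  r <- differentiation_ranges()
  f <- callusim:::fate_from_stimulus
  expect_equal(f(2.0, r)$phenotype, callusim:::PHENO_OSTEOBLAST)
  expect_true(f(2.0, r)$mature)
  expect_equal(f(2.8, r)$phenotype, callusim:::PHENO_OSTEOBLAST)
  expect_false(f(2.8, r)$mature)
  expect_equal(f(4.0, r)$phenotype, callusim:::PHENO_CHONDROCYTE)
  expect_equal(f(6.0, r)$phenotype, callusim:::PHENO_FIBROBLAST)
  # boundaries are inclusive upper bounds
  expect_true(f(2.53, r)$mature)
  expect_equal(f(3.00, r)$phenotype, callusim:::PHENO_OSTEOBLAST)
  expect_equal(f(5.00, r)$phenotype, callusim:::PHENO_CHONDROCYTE)
  # exhaustive and mutually exclusive over a dense grid
  s <- seq(0, 12, by = 0.01)
  ph <- f(s, r)$phenotype
  expect_true(all(ph %in% c(callusim:::PHENO_OSTEOBLAST,
                            callusim:::PHENO_CHONDROCYTE,
                            callusim:::PHENO_FIBROBLAST)))
})

test_that("homogenization is the volume-weighted arithmetic rule of mixtures", {
  cards <- default_material_table()
  fr <- matrix(0, 3, 4, dimnames = list(NULL, c("granulation", "fibrous",
                                                "cartilage", "bone")))
  fr[1, "granulation"] <- 1
  fr[2, c("bone", "cartilage")] <- 0.5
  fr[3, "cartilage"] <- 1
  h <- homogenize_materials(fr, cards)
  expect_equal(h$young_modulus[1], 0.2)
  expect_equal(h$poisson_ratio[1], 0.167)
  expect_equal(h$young_modulus[2], 2505)  # (5000 + 10) / 2 by hand
  expect_equal(unlist(h[3, ]), unlist(cards["cartilage", callusim:::HOMOG_PROPS]),
               ignore_attr = TRUE)
  # stiffness is monotone non-decreasing in the bone fraction
  fb <- seq(0, 1, by = 0.1)
  fr2 <- cbind(granulation = 1 - fb, fibrous = 0, cartilage = 0, bone = fb)
  expect_true(all(diff(homogenize_materials(fr2, cards)$young_modulus) >= 0))
  expect_error(homogenize_materials(matrix(1, 1, 1,
                                           dimnames = list(NULL, "enamel"))),
               "unknown tissue")
  fr[1, 1] <- 0.9
  expect_error(homogenize_materials(fr, cards), "sum to 1")
})

test_that("FE patch test: affine end displacement gives the uniform strain field", {
  mesh <- callusim:::fe_block_mesh(3, 3, 3, 1)
  mat <- callusim:::uniform_materials(mesh)
  lc <- load_case("stimulation", axial_displacement_um = 30,
                  ramp_rate_um_s = 10, crossbar = FALSE,
                  constraint = "roller")
  st <- solve_step(mesh, mat, lc)
  expect_equal(st$e[, 3], rep(-0.01, nrow(st$e)), tolerance = 1e-8)
  expect_lt(max(abs(st$e[, 4:6])), 1e-10)
  expect_lt(diff(range(st$e[, 1])), 1e-10)  # uniform lateral strain
  expect_lt(max(st$upsilon), 1e-10)          # no flow under uniform pressure
})

test_that("FE solution is linear and softer calli strain more (spring oracle)", {
  mesh <- callusim:::fe_block_mesh(2, 2, 4, 1)
  cards <- default_material_table()
  soft <- callusim:::uniform_materials(mesh, cards["granulation", ])
  stiff <- callusim:::uniform_materials(mesh, cards["bone", ])
  lc <- load_case("gait", gait_force_n = 5, crossbar = FALSE,
                  constraint = "clamped")
  st_soft <- solve_step(mesh, soft, lc)
  st_stiff <- solve_step(mesh, stiff, lc)
  # two-spring series picture: vastly stiffer material, vastly smaller motion
  expect_gt(st_soft$delta_if / st_stiff$delta_if, 1e3)
  # doubling all stiffness-like moduli (with permeability halved so the
  # consolidation operator scales consistently) halves displacements
  twice <- soft
  twice$young_modulus <- twice$young_modulus * 2
  twice$bulk_modulus_grain <- twice$bulk_modulus_grain * 2
  twice$bulk_modulus_fluid <- twice$bulk_modulus_fluid * 2
  twice$permeability <- twice$permeability / 2
  st2 <- solve_step(mesh, twice, lc)
  expect_equal(st_soft$delta_if / st2$delta_if, 2, tolerance = 1e-6)
  # interfragmentary strain magnitude strictly smaller for all-bone callus
  expect_lt(max(st_stiff$gamma), max(st_soft$gamma))
})

test_that("fluid speed vanishes at zero permeability", {
  mesh <- callusim:::fe_block_mesh(2, 2, 2, 1)
  mat <- callusim:::uniform_materials(mesh)
  mat$permeability <- 0
  lc <- load_case("gait", gait_force_n = 5, crossbar = FALSE)
  st <- solve_step(mesh, mat, lc)
  expect_equal(max(st$upsilon), 0)
})

test_that("FE field is axisymmetric for an axisymmetric geometry and load", {
  dom <- small_domain()
  mesh <- dom$mesh
  fr <- tissue_fractions(dom)
  mat <- as.data.frame(matrix(NA_real_, length(mesh$active),
                              length(callusim:::HOMOG_PROPS),
                              dimnames = list(NULL, callusim:::HOMOG_PROPS)))
  cards <- default_material_table()
  mat[mesh$active_region == callusim:::REGION_CORTEX, ] <-
    cards[rep("cortex", sum(mesh$active_region == callusim:::REGION_CORTEX)),
          callusim:::HOMOG_PROPS]
  mat[mesh$active_region == callusim:::REGION_MARROW, ] <-
    cards[rep("marrow", sum(mesh$active_region == callusim:::REGION_MARROW)),
          callusim:::HOMOG_PROPS]
  mat[mesh$tissue, ] <- homogenize_materials(fr, cards)
  st <- solve_step(mesh, mat, load_case("gait"))
  # rotate element centroids by 90 degrees about the bone axis and compare S
  ce <- mesh$centroid[mesh$active, ]
  rot <- cbind(-ce[, 2], ce[, 1], ce[, 3])
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  idx <- match(key(rot), key(ce))
  ok <- !is.na(idx)
  expect_gt(mean(ok), 0.99)
  expect_equal(st$S[idx[ok]], st$S[ok], tolerance = 1e-6)
})

test_that("surrogate backend honors the load-sharing contract", {
  dom <- small_domain()
  mesh <- dom$mesh
  fr <- tissue_fractions(dom)
  cards <- default_material_table()
  mat <- as.data.frame(matrix(NA_real_, length(mesh$active),
                              length(callusim:::HOMOG_PROPS),
                              dimnames = list(NULL, callusim:::HOMOG_PROPS)))
  for (reg in c(callusim:::REGION_CORTEX, callusim:::REGION_MARROW)) {
    rows <- which(mesh$active_region == reg)
    nm <- if (reg == callusim:::REGION_CORTEX) "cortex" else "marrow"
    mat[rows, ] <- cards[rep(nm, length(rows)), callusim:::HOMOG_PROPS]
  }
  mat[mesh$tissue, ] <- homogenize_materials(fr, cards)
  with_bar <- surrogate_step(mesh, mat, load_case("gait", crossbar = TRUE))
  no_bar <- surrogate_step(mesh, mat, load_case("gait", crossbar = FALSE))
  # crossbar removal strictly increases interfragmentary displacement
  expect_gt(no_bar$delta_if, with_bar$delta_if)
  # stimulation episode is displacement-controlled at 500 um
  stim <- surrogate_step(mesh, mat, load_case("stimulation"))
  expect_equal(stim$delta_if, 0.5)
  # stiffening the callus reduces gait-phase strain (monotonicity)
  fr_bone <- fr; fr_bone[, "bone"] <- 1; fr_bone[, "granulation"] <- 0
  mat2 <- mat; mat2[mesh$tissue, ] <- homogenize_materials(fr_bone, cards)
  hard <- surrogate_step(mesh, mat2, load_case("gait"))
  expect_lt(hard$delta_if, with_bar$delta_if)
  expect_lt(max(hard$gamma), max(with_bar$gamma))
})

test_that("stimulation load case requires the crossbar removed", {
  expect_error(load_case("stimulation", crossbar = TRUE), "crossbar")
  expect_false(load_case("stimulation")$crossbar)
})
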