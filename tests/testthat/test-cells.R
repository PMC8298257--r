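test_that("migration in a uniform chemotaxis field is isotropic", {
  dom <- small_domain(spacing_um = 500)
  sites <- isolated_cells(dom)
  set.seed(11)
  counts <- direction_counts(dom, sites, rep(1, prod(dom$dims)), 120)
  expect_gt(sum(counts), 5e3)
  p <- stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.01)
})

test_that("a 3.5-weighted direction is chosen at the exact multinomial rate", {
  dom <- small_domain(spacing_um = 500)
  sites <- isolated_cells(dom)
  chem <- rep(1, prod(dom$dims))
  chem[dom$nb[sites, 6L]] <- 3.5  # +z candidates weighted 3.5
  set.seed(23)
  counts <- direction_counts(dom, sites, chem, 220)
  n <- sum(counts)
  expect_gt(n, 1e4)
  p0 <- c(rep(1 / 8.5, 5), 3.5 / 8.5)
  expect_gt(stats::chisq.test(counts, p = p0)$p.value, 0.01)
  se <- sqrt(p0[6] * (1 - p0[6]) / n)
  expect_lt(abs(counts[6] / n - 3.5 / 8.5), 4 * se)
})

test_that("a fully blocked cell stays put and counts are conserved", {
  dom <- small_domain(spacing_um = 500)
  s <- isolated_cells(dom)[1]
  cells <- empty_lattice(dom)
  cells$occ[s] <- callusim:::PHENO_MSC
  cells$occ[dom$nb[s, ]] <- callusim:::PHENO_OSTEOBLAST  # immobile wall
  set.seed(5)
  out <- migrate(cells, dom, rep(1, prod(dom$dims)), dt_hours = 60)
  expect_equal(out$occ[s], callusim:::PHENO_MSC)
  expect_identical(sum(out$occ > 0), sum(cells$occ > 0))
})

test_that("division probability follows the Poisson waiting-time conversion", {
  expect_equal(callusim:::rate_to_prob(0.60, 2 / 24), 1 - exp(-0.05))
  expect_equal(callusim:::rate_to_prob(0.16, 2 / 24), 1 - exp(-0.16 / 12))
  dom <- small_domain(spacing_um = 500)
  sites <- isolated_cells(dom)
  set.seed(31)
  n_div <- 0; n_tot <- 0
  for (r in 1:100) {
    cells <- empty_lattice(dom)
    cells$occ[sites] <- callusim:::PHENO_MSC
    out <- proliferate(cells, dom, s_site = rep(1, prod(dom$dims)),
                       bmp_prolif_factor = 1)
    n_div <- n_div + sum(out$occ > 0) - length(sites)
    n_tot <- n_tot + length(sites)
  }
  p_exp <- 1 - exp(-0.05)
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(n_div / n_tot - p_exp), 4 * se)
})

test_that("differentiation follows the stimulus ranges at the cell's site", {
  dom <- small_domain(spacing_um = 500)
  sites <- isolated_cells(dom)
  s_site <- rep(0, prod(dom$dims))
  s_site[sites[1]] <- 2.0; s_site[sites[2]] <- 4.0; s_site[sites[3]] <- 6.0
  cells <- empty_lattice(dom)
  cells$occ[sites[1:3]] <- callusim:::PHENO_MSC
  set.seed(2)
  out <- differentiate(cells, dom, s_site, dt_hours = 24 * 60)
  expect_equal(out$occ[sites[1]], callusim:::PHENO_OSTEOBLAST)
  expect_true(out$mature[sites[1]])
  expect_equal(out$occ[sites[2]], callusim:::PHENO_CHONDROCYTE)
  expect_equal(out$occ[sites[3]], callusim:::PHENO_FIBROBLAST)
})

test_that("apoptosis gives exponential population decay at the table rate", {
  dom <- small_domain(spacing_um = 500)
  cells <- empty_lattice(dom)
  cells$occ[dom$cells_allowed] <- callusim:::PHENO_OSTEOBLAST
  cells$mature[dom$cells_allowed] <- TRUE
  n0 <- sum(cells$occ > 0)
  s_site <- rep(1, prod(dom$dims))  # favorable for osteoblasts
  set.seed(13)
  for (i in 1:12) cells <- apoptose(cells, dom, s_site)  # one simulated day
  expect_equal(sum(cells$occ > 0) / n0, exp(-0.16), tolerance = 0.05)
  # unfavorable stimulus doubles the rate
  set.seed(13)
  cells2 <- empty_lattice(dom)
  cells2$occ[dom$cells_allowed] <- callusim:::PHENO_OSTEOBLAST
  for (i in 1:12) cells2 <- apoptose(cells2, dom, rep(6, prod(dom$dims)))
  expect_equal(sum(cells2$occ > 0) / n0, exp(-0.32), tolerance = 0.05)
  # zero rates are a fixed point
  rates0 <- default_rate_table()
  rates0$apoptosis_rate <- 0
  before <- cells
  expect_identical(apoptose(before, dom, s_site, rates0), before)
})

test_that("limited recruitment zeroes MSC migration/proliferation after day 10", {
  r <- default_rate_table()
  lim <- recruitment_policy("limited", 10)
  r11 <- apply_recruitment_policy(r, 11, lim)
  expect_equal(r11["msc", "migration_rate"], 0)
  expect_equal(r11["msc", "proliferation_rate"], 0)
  expect_equal(r11["msc", "differentiation_rate"], 0.30)
  expect_equal(r11["msc", "apoptosis_rate"], 0.05)
  expect_equal(r11["fibroblast", "migration_rate"], 30)
  expect_identical(apply_recruitment_policy(r, 9, lim), r)
  cont <- recruitment_policy("continuous")
  expect_identical(apply_recruitment_policy(r, 1000, cont), r)
})

test_that("with all stochastic rates zero the lattice is a fixed point", {
  dom <- small_domain(spacing_um = 500)
  set.seed(3)
  cells <- seed_mscs(dom, 0.3)
  r0 <- default_rate_table()
  r0[, c("migration_rate", "proliferation_rate", "differentiation_rate",
         "apoptosis_rate")] <- 0
  s_site <- rep(1, prod(dom$dims))
  out <- cells
  out <- differentiate(out, dom, s_site, rates = r0)
  out <- proliferate(out, dom, s_site, 1, rates = r0)
  out <- migrate(out, dom, rep(1, length(s_site)), rates = r0)
  out <- apoptose(out, dom, s_site, rates = r0)
  expect_identical(out, cells)
})

test_that("occupancy stays at most one per site through a busy update", {
  dom <- small_domain(spacing_um = 500)
  set.seed(9)
  cells <- seed_mscs(dom, 0.3)
  s_site <- rep(1, prod(dom$dims))
  for (i in 1:8) {
    cells <- proliferate(cells, dom, s_site, 1)
    cells <- migrate(cells, dom, rep(1.5, prod(dom$dims)), dt_hours = 30)
    expect_true(all(cells$occ %in% 0:4))
    expect_true(all(cells$occ[!dom$cells_allowed] == 0))
  }
})

test_that("mature osteoblasts are post-mitotic, immature ones divide and mature", {
  dom <- small_domain(spacing_um = 500)
  sites <- isolated_cells(dom)
  cells <- empty_lattice(dom)
  cells$occ[sites] <- callusim:::PHENO_OSTEOBLAST
  cells$mature[sites] <- TRUE
  s_site <- rep(1, prod(dom$dims))
  set.seed(4)
  out <- proliferate(cells, dom, s_site, 1, dt_hours = 24 * 30)
  expect_equal(sum(out$occ > 0), length(sites))  # no divisions
  cells$mature[] <- FALSE
  out2 <- proliferate(cells, dom, s_site, 1, dt_hours = 24 * 30)
  expect_gt(sum(out2$occ > 0), length(sites))
  out3 <- mature_osteoblasts(cells, dom, s_site, dt_hours = 24 * 365)
  expect_true(all(out3$mature[sites]))
})
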