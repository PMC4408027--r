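test_that("wood density is dry mass over displaced volume", {
  expect_equal(wood_density(0.53, 1.00), 0.53)
  expect_equal(wood_density(2.5, 2.5), 1.0)
  expect_equal(wood_density(0.38, 1.00), 0.38)
  expect_error(wood_density(-1, 1), "positive")
})

test_that("ellipse area is pi d1 d2 / 4 and symmetric", {
  expect_equal(ellipse_area(2, 2), pi)
  expect_equal(ellipse_area(2, 4), 2 * pi)
  expect_equal(ellipse_area(3.1, 7.7), ellipse_area(7.7, 3.1))
  expect_error(ellipse_area(0, 1), "positive")
})

test_that("composite fractions add their components", {
  f <- c(AXIAL_PARENCHYMA = 0.14, RAY_PARENCHYMA = 0.21,
         FIBRE_LUMEN = 0.13, FIBRE_WALL = 0.32,
         VESSEL_LUMEN = 0.13, VESSEL_WALL = 0.04)
  comp <- composite_fractions(f)
  expect_equal(unname(comp["TPF"]), 0.35)
  expect_equal(unname(comp["TFF"]), 0.45)
  expect_equal(unname(comp["TVF"]), 0.17)
  expect_equal(unname(comp["WF"]), 0.36)
  zero <- composite_fractions(stats::setNames(rep(0, 6), names(f)))
  expect_true(all(zero == 0))
})

test_that("SLA is area per mass with LMA its reciprocal", {
  expect_equal(specific_leaf_area(100, 1), 100)
  expect_equal(specific_leaf_area(200, 1), 2 * specific_leaf_area(100, 1))
  sla <- specific_leaf_area(137, 2.2)
  expect_equal((1 / sla) * sla, 1)
})

test_that("leaf area to sapwood area ratio follows the worked example", {
  out <- leaf_area_sapwood_ratio(sla = 100, sla_subset_area_cm2 = 200,
                                 remaining_leaf_mass_g = 3,
                                 wood_diameters_mm = c(5, 5))
  expect_equal(unname(out["total_leaf_area_cm2"]), 500)
  expect_equal(unname(out["sapwood_area_cm2"]), pi * 0.5 * 0.5 / 4)
  expect_equal(unname(out["LASA"]), 500 / (pi * 0.25 / 4), tolerance = 1e-6)
  # no remaining leaves: LA/SA reduces to subset area over sapwood area
  out0 <- leaf_area_sapwood_ratio(100, 200, 0, c(5, 5))
  expect_equal(unname(out0["LASA"]), 200 / unname(out0["sapwood_area_cm2"]))
  # doubling all leaf quantities doubles LA/SA at fixed sapwood
  out2 <- leaf_area_sapwood_ratio(100, 400, 6, c(5, 5))
  expect_equal(unname(out2["LASA"]), 2 * unname(out["LASA"]))
})

test_that("bending stiffness follows beam theory on an elliptical section", {
  moe <- suppressWarnings(modulus_of_elasticity(10, 100, 5))
  I <- pi * 5^4 / 64
  expect_equal(moe, 10 * 100^3 / (48 * I))
  expect_equal(suppressWarnings(modulus_of_elasticity(20, 100, 5)), 2 * moe)
  # the 20:1 span rule warns, or errors in strict mode
  expect_warning(modulus_of_elasticity(10, 99, 5), "20 times")
  expect_error(modulus_of_elasticity(10, 99, 5, strict = TRUE), "20 times")
  expect_silent(modulus_of_elasticity(10, 120, 5))
  # realistic twig inputs land inside the observed stiffness envelope
  expect_gt(suppressWarnings(modulus_of_elasticity(8, 110, 5.5)), 1555)
  expect_lt(suppressWarnings(modulus_of_elasticity(8, 110, 5.5)), 11778)
})

test_that("approximate wall material density is density over wall fraction", {
  expect_equal(wall_material_density(0.53, 0.36), 0.53 / 0.36)
  expect_equal(wall_material_density(0.5, 1), 0.5)
  expect_gt(wall_material_density(0.5, 0.3), wall_material_density(0.5, 0.4))
  expect_error(wall_material_density(0.5, 0), "0, 1")
})

test_that("species means aggregate replicates arithmetically", {
  tab <- tibble::tibble(
    species = rep(c("a", "b"), c(3, 1)),
    site = "x", replicate = c(1:3, 1),
    WD = c(0.1, 0.2, 0.3, 0.5), TPF = c(0.3, NA, 0.5, 0.2)
  )
  sm <- species_means(tab)
  expect_equal(sm$WD, c(0.2, 0.5))
  expect_equal(sm$TPF, c(0.4, 0.2))  # NA dropped trait-wise
  # species at two sites stay separate entities
  tab2 <- tibble::tibble(species = "a", site = c("x", "y"),
                         replicate = 1L, WD = c(1, 2))
  expect_equal(nrow(species_means(tab2)), 2L)
})

test_that("n-fold variation excludes zeros from the denominator", {
  expect_equal(round(nfold_variation(c(0.38, 0.5, 0.62)), 1), 1.6)
  expect_equal(nfold_variation(c(0, 0.01, 0.64)), 64)
  expect_equal(nfold_variation(rep(2.5, 5)), 1)
  expect_error(nfold_variation(c(0, 0)), "zero")
})

test_that("trait summaries report range, mean and fold with the zero rule", {
  tab <- tibble::tibble(species = letters[1:5], site = "x",
                        WD = c(0.4, 0.45, 0.5, 0.55, 0.6),
                        CF = c(0, 0, 0.01, 0.02, 0.05))
  s <- summarize_traits(tab, traits = c("WD", "CF"))
  wd <- s[s$trait == "WD", ]
  expect_equal(wd$low, 0.4)
  expect_equal(wd$high, 0.6)
  expect_equal(wd$average, 0.5)
  expect_equal(wd$nfold, 1.5)
  expect_false(wd$zeros_excluded)
  cf <- s[s$trait == "CF", ]
  expect_equal(cf$low, 0.01)       # smallest nonzero
  expect_equal(cf$average, mean(c(0.01, 0.02, 0.05)))
  expect_equal(cf$nfold, 5)
  expect_equal(cf$n_nonzero, 3L)
  expect_error(summarize_traits(tab[0, ]), "empty")
})
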