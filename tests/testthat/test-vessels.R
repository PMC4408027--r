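test_that("disjoint discs are extracted with near-analytic areas", {
  centers <- rbind(c(50, 50), c(130, 60), c(80, 150))
  radii <- c(10, 14, 18)
  sec <- disc_section(centers, radii, n = 200L, scale_um_per_px = 1)
  recs <- extract_vessels(sec)
  expect_equal(nrow(recs), 3L)
  got <- sort(recs$area_mm2)
  want <- sort(pi * (radii / 1000)^2)
  expect_true(all(abs(got - want) / want < 0.05))  # rasterization error
  # circle identity: disc of radius 10 px at 1 um/px
  d <- recs$eq_diameter_mm[which.min(recs$area_mm2)]
  expect_equal(d, 0.020, tolerance = 0.05)
  expect_true(all(recs$feret_mm >= recs$eq_diameter_mm - 1e-9))
})

test_that("sections without vessel pixels yield an empty record table", {
  recs <- extract_vessels(uniform_section("FIBRE_WALL"))
  expect_equal(nrow(recs), 0L)
})

test_that("component labeling agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  sec <- generate_section(small_section_spec(seed = 21L, size = 300L))
  mask <- sec$labels == match("VESSEL_LUMEN", tissue_labels())
  mine <- twigwood:::label_components(mask)
  theirs <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(mine$n, max(theirs))
})

test_that("rasterized disc area converges to pi r^2 with resolution", {
  err <- vapply(c(8, 32), function(r) {
    sec <- disc_section(rbind(c(2 * r + 2, 2 * r + 2)), r, n = 4L * r + 4L)
    abs(extract_vessels(sec)$n_px - pi * r^2) / (pi * r^2)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("the 15-um partition is strict and exhaustive", {
  recs <- tibble::tibble(
    id = 1:4, area_mm2 = 1e-4, eq_diameter_mm = 0.01,
    feret_mm = c(10, 14.9, 15, 30) / 1000,
    centroid_x = 0, centroid_y = 0, n_px = 1L, label = "VESSEL_LUMEN"
  )
  parts <- partition_conduits15(recs)
  expect_equal(parts$conduits$feret_mm * 1000, c(10, 14.9))
  expect_equal(parts$vessels$feret_mm * 1000, c(15, 30))
  expect_equal(nrow(parts$vessels) + nrow(parts$conduits), nrow(recs))

  empty <- partition_conduits15(recs[0, ])
  expect_equal(nrow(empty$vessels), 0L)
  expect_equal(nrow(empty$conduits), 0L)
})

test_that("generated small conduits are recovered by the partition", {
  sec <- generate_section(small_section_spec(seed = 22L, size = 300L))
  truth <- sum(twigwood:::label_components(
    sec$labels == match("CONDUIT15", tissue_labels()))$n)
  recs <- extract_vessels(sec, labels = c("VESSEL_LUMEN", "CONDUIT15"))
  parts <- partition_conduits15(recs)
  # conduit diameters are generated strictly below 15 um, vessels above
  expect_equal(nrow(parts$conduits), truth)
  expect_true(all(parts$vessels$label == "VESSEL_LUMEN"))
})

test_that("hydraulic diameter matches hand-computed and bounds the mean", {
  expect_equal(hydraulic_diameter(c(10, 20)), 3300000 / 170000)
  expect_equal(hydraulic_diameter(rep(7.3, 5)), 7.3)
  expect_error(hydraulic_diameter(numeric(0)), "non-empty")
  expect_error(hydraulic_diameter(c(10, -1)), "positive")
  # power-mean ordering, property-style over random diameter lists
  set.seed(31)
  for (i in 1:200) {
    d <- stats::rlnorm(sample(2:40, 1), meanlog = 3, sdlog = 0.5)
    expect_gte(hydraulic_diameter(d), mean(d) - 1e-12)
  }
})

test_that("vessel statistics satisfy their algebraic identities", {
  recs <- tibble::tibble(area_mm2 = rep(6e-4, 10),
                         eq_diameter_mm = 2 * sqrt(6e-4 / pi))
  vs <- vessel_stats(recs, vlf = 0.12)
  expect_equal(vs$N, 200)
  expect_equal(vs$S, 3e-6)
  expect_equal(vs$N * vs$A, vs$VLF)
  expect_equal(vs$S, vs$A^2 / vs$VLF)

  # n = 1 closed form
  one <- tibble::tibble(area_mm2 = 2e-3, eq_diameter_mm = 2 * sqrt(2e-3 / pi))
  v1 <- vessel_stats(one, vlf = 0.1)
  expect_equal(v1$A, 2e-3)
  expect_equal(v1$N, 0.1 / 2e-3)
  expect_equal(v1$S, (2e-3)^2 / 0.1)
  expect_equal(v1$Dh, 2 * sqrt(2e-3 / pi))

  expect_error(vessel_stats(recs[0, ], 0.1), "no vessel records")
  expect_error(vessel_stats(recs, 0), "fraction")
})
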