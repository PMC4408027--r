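test_that("the point lattice has the expected geometry", {
  sec <- uniform_section(n = 300L)
  pts <- overlay_grid(sec, grid_spec(spacing_px = 30L))
  expect_equal(nrow(pts), 100L)  # 10 x 10 lattice
  expect_setequal(unique(pts$x), seq(1L, 300L, 30L))
  # offsets shift the lattice
  pts2 <- overlay_grid(sec, grid_spec(spacing_px = 30L, offset_px = c(5L, 7L)))
  expect_setequal(unique(pts2$x), seq(6L, 300L, 30L))
  expect_setequal(unique(pts2$y), seq(8L, 300L, 30L))
})

test_that("points outside the sector mask are excluded", {
  n <- 100L
  m <- matrix("FIBRE_WALL", n, n)
  mask <- matrix(TRUE, n, n); mask[, (n %/% 2 + 1):n] <- FALSE
  sec <- labeled_section(m, 1, mask = mask)
  pts <- overlay_grid(sec, grid_spec(spacing_px = 10L))
  expect_true(all(pts$x <= n %/% 2))
  expect_error(overlay_grid(uniform_section(n = 20L),
                            grid_spec(spacing_px = 50L)),
               "spacing exceeds")
})

test_that("point counts tally labels and conserve the total", {
  sec <- split_section(n = 100L)
  pts <- overlay_grid(sec, grid_spec(spacing_px = 10L))
  counts <- count_points(sec, pts)
  expect_equal(attr(counts, "total"), nrow(pts))
  expect_equal(counts$count[counts$label == "FIBRE_WALL"],
               counts$count[counts$label == "RAY_PARENCHYMA"])
  expect_error(count_points(sec, tibble::tibble(x = 0L, y = 5L)),
               "bounds")
})

test_that("fractions follow counts with binomial standard errors", {
  counts <- tibble::tibble(label = wood_labels(), count = 0L)
  counts$count[counts$label == "FIBRE_WALL"] <- 150L
  counts$count[counts$label == "FIBRE_LUMEN"] <- 50L
  counts$count[counts$label == "RAY_PARENCHYMA"] <- 100L
  attr(counts, "total") <- 300L
  class(counts) <- c("point_counts", class(counts))
  fv <- fractions_from_counts(counts)
  f <- fraction_of(fv)
  expect_equal(unname(f[c("FIBRE_WALL", "FIBRE_LUMEN", "RAY_PARENCHYMA")]),
               c(0.5, 50 / 300, 100 / 300))
  expect_equal(sum(fv$fraction), 1)
  expect_equal(fv$se[fv$label == "FIBRE_WALL"], sqrt(0.5 * 0.5 / 300))

  # the 300-point minimum is enforced in strict mode, warned otherwise
  attr(counts, "total") <- 299L
  counts$count[counts$label == "FIBRE_WALL"] <- 149L
  expect_error(fractions_from_counts(counts), "minimum of 300")
  expect_warning(fractions_from_counts(counts, strict = FALSE), "minimum")
})

test_that("grid estimates agree with the pixel-exact oracle within 3 SE", {
  sec <- generate_section(small_section_spec(seed = 9L, size = 400L))
  truth <- fraction_of(realized_fractions(sec))
  est <- estimate_fractions(sec, spacing_px = 10L)  # 1600 points
  f <- fraction_of(est)
  se <- stats::setNames(est$se, est$label)[names(f)]
  expect_true(all(abs(f - truth) <= 3 * pmax(se, 1e-6) + 1e-9))
})

test_that("estimation error shrinks as the grid gets denser", {
  sec <- generate_section(small_section_spec(seed = 10L, size = 400L))
  truth <- fraction_of(realized_fractions(sec))
  err_at <- function(spacing) {
    offs <- expand.grid(dx = c(0L, 7L, 13L) %% spacing,
                        dy = c(0L, 5L, 11L) %% spacing)
    mean(vapply(seq_len(nrow(offs)), function(i) {
      pts <- overlay_grid(sec, grid_spec(spacing, c(offs$dx[i], offs$dy[i])))
      f <- fraction_of(suppressWarnings(
        fractions_from_counts(count_points(sec, pts), strict = FALSE)))
      max(abs(f - truth))
    }, numeric(1)))
  }
  errs <- c(err_at(40L), err_at(20L), err_at(8L))
  expect_lt(errs[3], errs[1])  # ~1/sqrt(n) consistency, coarse vs fine
})
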