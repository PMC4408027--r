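test_that("the trait table spec validates its invariants", {
  expect_error(trait_table_spec(replicate_cv = 1.2), "0, 1")
  bad <- default_trait_marginals()
  bad$low[1] <- bad$high[1]
  expect_error(trait_table_spec(marginals = bad), "low >= high")
  R <- default_latent_correlation()
  R[1, 2] <- R[2, 1] <- 0.999
  R[1, 3] <- R[3, 1] <- 0.999
  R[2, 3] <- R[3, 2] <- -0.999
  expect_error(trait_table_spec(latent_correlation = R), "nearPD")
  Rasym <- default_latent_correlation()
  Rasym[1, 2] <- 0.5
  expect_error(trait_table_spec(latent_correlation = Rasym), "symmetric")
})

test_that("generated tables have the documented shape and bounds", {
  tab <- generate_trait_table(trait_table_spec(rng_seed = 3L))
  expect_equal(nrow(tab), 69L * 3L)
  expect_true(all(trait_columns() %in% names(tab)))
  sv <- attr(tab, "species_values")
  mg <- default_trait_marginals()
  for (tr in c("TPF", "TFF", "VLF", "A", "Dh", "PA", "WD", "H", "MH",
               "MOE", "LASA")) {
    i <- match(tr, mg$trait)
    # fractions are renormalized after closure, so allow the closure ratio
    slack <- if (tr %in% c("TPF", "TFF", "VLF")) 1.12 else 1 + 1e-9
    expect_gte(min(sv[[tr]]), mg$low[i] / slack)
    expect_lte(max(sv[[tr]]), mg$high[i] * slack)
  }
})

test_that("composite identities and closure hold on every record", {
  tab <- generate_trait_table(trait_table_spec(rng_seed = 5L))
  expect_equal(tab$TPF, tab$APF + tab$RPF, tolerance = 1e-12)
  expect_equal(tab$TFF, tab$FLF + tab$FWF, tolerance = 1e-12)
  expect_equal(tab$TVF, tab$VLF + tab$VWF, tolerance = 1e-12)
  expect_equal(tab$WF, tab$FWF + tab$VWF, tolerance = 1e-12)
  csum <- tab$APF + tab$RPF + tab$FLF + tab$FWF + tab$VLF + tab$VWF +
    tab$CF + tab$MCF
  expect_true(all(abs(csum - 1) < 1e-9))
  # vessel identities
  expect_equal(tab$N, tab$VLF / tab$A, tolerance = 1e-12)
  expect_equal(tab$S, tab$A / tab$N, tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  a <- generate_trait_table(trait_table_spec(rng_seed = 11L))
  b <- generate_trait_table(trait_table_spec(rng_seed = 11L))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_trait_table(trait_table_spec(rng_seed = 12L))
  expect_false(identical(a$TPF, c2$TPF))
})

test_that("presence structure matches the design: conduits and canals", {
  sv <- attr(generate_trait_table(trait_table_spec(rng_seed = 2L)),
             "species_values")
  expect_equal(sum(sv$CF > 0), 26L)
  expect_equal(sum(sv$MCF > 0), 3L)
  expect_true(all(sv$site[sv$MCF > 0] == "rainforest"))
  bysite <- table(sv$site[sv$CF > 0])
  expect_equal(as.integer(bysite[c("rainforest", "woodland", "temperate")]),
               c(2L, 10L, 14L))
})

test_that("the copula recovers a strong latent correlation at large n", {
  spec <- trait_table_spec(n_species = 1000L, n_replicates = 1L,
                           replicate_cv = 0, rng_seed = 17L)
  sv <- attr(generate_trait_table(spec), "species_values")
  expect_equal(stats::cor(sv$TFF, sv$TPF), -0.86, tolerance = 0.05 / 0.86)
})

test_that("an identity latent correlation yields near-null dependence", {
  spec <- trait_table_spec(n_species = 200L, n_replicates = 1L,
                           replicate_cv = 0,
                           latent_correlation = diag(16L) |>
                             (\(m) {
                               dimnames(m) <- list(
                                 twigwood:::latent_driver_names(),
                                 twigwood:::latent_driver_names())
                               m
                             })(),
                           rng_seed = 19L)
  sv <- attr(generate_trait_table(spec), "species_values")
  # the unclosed physical traits are mutually independent under the null;
  # familywise bound at ~1% over the 28 pairs: 3.5 / sqrt(n)
  open_traits <- c("A", "Dh", "PA", "WD", "H", "MH", "MOE", "LASA")
  rs <- stats::cor(as.matrix(sv[, open_traits]))
  off <- rs[upper.tri(rs)]
  expect_lt(max(abs(off)), 3.5 / sqrt(200))
  expect_lt(mean(abs(off)), 0.1)
})

test_that("replicate noise has the requested scale", {
  tab <- generate_trait_table(trait_table_spec(rng_seed = 23L,
                                               replicate_cv = 0.1))
  cvs <- dplyr::summarise(dplyr::group_by(tab, species),
                          cv = stats::sd(WD) / mean(WD))$cv
  expect_equal(mean(cvs), 0.1, tolerance = 0.35)
  zero <- generate_trait_table(trait_table_spec(rng_seed = 23L,
                                                replicate_cv = 0))
  expect_equal(stats::sd(zero$WD[zero$species == zero$species[1]]), 0)
})
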