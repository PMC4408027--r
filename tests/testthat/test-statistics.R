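test_that("the normality gate keeps its nominal error rates", {
  set.seed(101)
  hits_normal <- vapply(1:200, function(i) {
    shapiro_normal(stats::rnorm(69))$is_normal
  }, logical(1))
  expect_gte(mean(hits_normal), 0.90)  # type-I error ~5%
  expect_lte(mean(hits_normal), 0.99)

  hits_exp <- vapply(1:200, function(i) {
    shapiro_normal(stats::rexp(69))$is_normal
  }, logical(1))
  expect_lt(mean(hits_exp), 0.05)  # power against strong skew > 95%

  expect_error(shapiro_normal(rep(1, 10)), "constant")
  expect_error(shapiro_normal(c(1, 2)), "at least 3")
})

test_that("correlate_pair picks the method from the normality flags", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5, 6.1, 7.9)
  y <- 2 * x + 1
  ct <- correlate_pair(x, y, TRUE, TRUE)
  expect_equal(ct$method, "pearson")
  expect_equal(ct$estimate, 1)
  ct2 <- correlate_pair(x, y, TRUE, FALSE)
  expect_equal(ct2$method, "spearman")
  # rank invariance of Spearman under monotone transforms
  set.seed(5)
  a <- stats::rnorm(40); b <- a + stats::rnorm(40)
  expect_equal(correlate_pair(a, b, FALSE, FALSE)$estimate,
               correlate_pair(a, exp(b), FALSE, FALSE)$estimate)
  expect_error(correlate_pair(1:5, 1:4), "mismatch")
  expect_error(correlate_pair(1:5, rep(1, 5), TRUE, TRUE), "variance")
})

test_that("significance bands follow the 0.05 / 0.01 / 0.001 legend", {
  expect_equal(as.character(twigwood:::significance_band(
    c(0.2, 0.04, 0.009, 0.0009))), c("ns", "*", "**", "***"))
})

test_that("correlation matrices are symmetric, gated, and consistent", {
  tab <- species_means(generate_trait_table(trait_table_spec(rng_seed = 8L)))
  corr <- suppressWarnings(
    correlation_matrix(tab, traits = c("TPF", "TFF", "WD", "MOE", "PA")))
  expect_equal(corr$headline, t(corr$headline))
  expect_equal(unname(diag(corr$headline)), rep(1, 5))
  # each headline entry equals the matching base matrix entry
  for (i in 1:4) for (j in (i + 1):5) {
    base <- if (corr$method[i, j] == "pearson") corr$pearson else corr$spearman
    expect_identical(corr$headline[i, j], base[i, j])
  }
  # the gate depends only on the two traits' normality flags
  norm <- corr$normality
  for (i in 1:4) for (j in (i + 1):5) {
    want <- if (norm$is_normal[i] && norm$is_normal[j]) "pearson" else "spearman"
    expect_equal(corr$method[i, j], want)
  }
  # zero-variance traits are dropped with a warning
  tab$K <- 1
  expect_warning(correlation_matrix(tab, traits = c("TPF", "TFF", "K")),
                 "zero-variance")
})

test_that("pearson and spearman agree on linear tie-free data", {
  tab <- tibble::tibble(x = 1:30 + 0.1, y = 3 * (1:30) - 2)
  corr <- correlation_matrix(tab, traits = c("x", "y"))
  expect_equal(corr$pearson[1, 2], corr$spearman[1, 2], tolerance = 1e-9)
})

test_that("no multiple-testing correction is applied to pair p values", {
  tab <- species_means(generate_trait_table(trait_table_spec(rng_seed = 4L)))
  corr <- suppressWarnings(
    correlation_matrix(tab, traits = c("TPF", "TFF", "WD")))
  raw <- correlate_pair(tab$TPF, tab$WD,
                        corr$normality$is_normal[1],
                        corr$normality$is_normal[3])
  expect_equal(correlation_of(corr, "TPF", "WD")$p, raw$p)
})

test_that("pairwise-complete observations are used and n reported", {
  tab <- tibble::tibble(a = c(1, 2, 3, 4, NA, 6, 5, 8),
                        b = c(2, 1, 4, 3, 5, NA, 7, 9),
                        c = c(1, 2, 3, 4, 5, 6, 7, 8))
  corr <- correlation_matrix(tab)
  expect_equal(corr$n["a", "b"], 6)
  expect_equal(corr$n["a", "c"], 7)
})
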