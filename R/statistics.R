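#' Shapiro-Wilk normality screen for a trait
#'
#' Runs the Shapiro-Wilk test and flags the trait as normal when the test
#' does not reject at level `alpha` (`p > alpha`). An optional log10
#' transform can be applied first, mirroring the common practice of
#' re-checking right-skewed traits on the log scale.
#'
#' @param values Numeric vector, `n >= 3`, not all equal.
#' @param alpha Significance level of the gate (default 0.05).
#' @param log10_transform Test `log10(values)` instead (requires positive
#'   values).
#' @return A one-row tibble: `W`, `p`, `is_normal`, `n`.
#' @export
shapiro_normal <- function(values, alpha = 0.05, log10_transform = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    stop("need at least 3 non-missing values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("values are constant; normality test undefined", call. = FALSE)
  }
  if (log10_transform) {
    check_positive(values, "values (log10 transform)")
    values <- log10(values)
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(W = unname(sw$statistic), p = sw$p.value,
                 is_normal = sw$p.value > alpha, n = length(values))
}

#' Normality screen across the traits of a table
#'
#' @param table Species-level trait table.
#' @param traits Trait columns to screen; default all numeric.
#' @param alpha Gate level.
#' @return Tibble with one row per trait: `trait`, `W`, `p`, `is_normal`,
#'   `n`.
#' @export
normality_screen <- function(table, traits = NULL, alpha = 0.05) {
  if (is.null(traits)) {
    traits <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      "replicate")
  }
  out <- lapply(traits, function(tr) {
    res <- tryCatch(shapiro_normal(table[[tr]], alpha = alpha),
                    error = function(e) {
                      tibble::tibble(W = NA_real_, p = NA_real_,
                                     is_normal = FALSE,
                                     n = sum(!is.na(table[[tr]])))
                    })
    dplyr::bind_cols(tibble::tibble(trait = tr), res)
  })
  dplyr::bind_rows(out)
}

significance_band <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"))
}

#' Correlate a pair of traits with a normality-gated test choice
#'
#' Pearson's r when both traits are flagged normally distributed,
#' Spearman's rank rho otherwise (average ranks for ties, asymptotic
#' p values). Two-sided p values; significance bands `*` (p < 0.05),
#' `**` (p < 0.01), `***` (p < 0.001).
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @param normal_x,normal_y Logical normality flags of the two traits.
#' @return One-row tibble: `method`, `estimate`, `p`, `n`, `band`.
#' @export
correlate_pair <- function(x, y, normal_x = TRUE, normal_y = TRUE) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  method <- if (isTRUE(normal_x) && isTRUE(normal_y)) "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)
  )
  tibble::tibble(method = method, estimate = unname(ct$estimate),
                 p = ct$p.value, n = length(x),
                 band = as.character(significance_band(ct$p.value)))
}

#' Pairwise trait correlation matrices with a normality gate
#'
#' Computes the full Pearson and Spearman matrices over the requested
#' traits (pairwise-complete observations), screens each trait with
#' Shapiro-Wilk, and assembles the headline matrix in which each pair
#' carries Pearson's r if both traits are normal and Spearman's rho
#' otherwise. Traits with zero variance are dropped with a warning. No
#' multiple-testing correction is applied; with this many pairs,
#' individual significance flags should be read loosely.
#'
#' @param table Species-level trait table.
#' @param traits Trait columns; default all numeric columns.
#' @param alpha Gate level for the normality screen.
#' @return An object of class `trait_correlations`: list with `traits`,
#'   `normality` (tibble), matrices `pearson`, `spearman`, `headline`,
#'   `p_pearson`, `p_spearman`, `p_headline`, `method` (character matrix),
#'   `n` (pairwise n), and `pairs` (long-form tibble).
#' @export
correlation_matrix <- function(table, traits = NULL, alpha = 0.05) {
  if (is.null(traits)) {
    traits <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      "replicate")
  }
  if (nrow(table) < 3L) stop("need at least 3 species", call. = FALSE)
  if (length(traits) < 2L) stop("need at least 2 traits", call. = FALSE)
  const <- vapply(traits, function(tr) {
    v <- table[[tr]]
    stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))
  }, logical(1))
  if (any(const)) {
    warning("dropping zero-variance trait(s): ",
            paste(traits[const], collapse = ", "), call. = FALSE)
    traits <- traits[!const]
  }
  k <- length(traits)
  norm <- normality_screen(table, traits, alpha = alpha)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(traits, traits))
  rp <- mk(); rs <- mk(); pp <- mk(); ps <- mk(); nn <- mk()
  method <- matrix(NA_character_, k, k, dimnames = list(traits, traits))
  diag(rp) <- diag(rs) <- 1
  pairs <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- table[[traits[i]]]; y <- table[[traits[j]]]
      ok <- !is.na(x) & !is.na(y)
      ctp <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "pearson"))
      cts <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                              method = "spearman",
                                              exact = FALSE))
      rp[i, j] <- rp[j, i] <- unname(ctp$estimate)
      pp[i, j] <- pp[j, i] <- ctp$p.value
      rs[i, j] <- rs[j, i] <- unname(cts$estimate)
      ps[i, j] <- ps[j, i] <- cts$p.value
      nn[i, j] <- nn[j, i] <- sum(ok)
      both_norm <- norm$is_normal[i] && norm$is_normal[j]
      method[i, j] <- method[j, i] <- if (both_norm) "pearson" else "spearman"
      est <- if (both_norm) rp[i, j] else rs[i, j]
      pv <- if (both_norm) pp[i, j] else ps[i, j]
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        trait_x = traits[i], trait_y = traits[j],
        method = method[i, j], estimate = est, p = pv, n = sum(ok),
        band = as.character(significance_band(pv))
      )
    }
  }
  headline <- ifelse(method == "pearson", rp, rs)
  diag(headline) <- 1
  p_headline <- ifelse(method == "pearson", pp, ps)
  structure(
    list(traits = traits, normality = norm,
         pearson = rp, spearman = rs, headline = headline,
         p_pearson = pp, p_spearman = ps, p_headline = p_headline,
         method = method, n = nn, pairs = dplyr::bind_rows(pairs),
         alpha = alpha),
    class = "trait_correlations"
  )
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("<trait_correlations> ", length(x$traits), " traits, ",
      nrow(x$pairs), " pairs (", sum(x$normality$is_normal),
      " traits gated normal at alpha = ", x$alpha, ")\n", sep = "")
  print(round(x$headline, 2))
  invisible(x)
}

#' Extract one pairwise correlation from a correlation object
#'
#' @param corr A `trait_correlations` object.
#' @param trait_x,trait_y Trait names.
#' @param method `"headline"` (the gated choice), `"pearson"` or
#'   `"spearman"`.
#' @return One-row tibble with `method`, `estimate`, `p`, `n`.
#' @export
correlation_of <- function(corr, trait_x, trait_y,
                           method = c("headline", "pearson", "spearman")) {
  stopifnot(inherits(corr, "trait_correlations"))
  method <- match.arg(method)
  m <- switch(method, headline = corr$headline, pearson = corr$pearson,
              spearman = corr$spearman)
  p <- switch(method, headline = corr$p_headline, pearson = corr$p_pearson,
              spearman = corr$p_spearman)
  used <- if (method == "headline") corr$method[trait_x, trait_y] else method
  tibble::tibble(method = used, estimate = m[trait_x, trait_y],
                 p = p[trait_x, trait_y], n = corr$n[trait_x, trait_y])
}

#' Long-form export of a correlation matrix
#'
#' @param corr A `trait_correlations` object.
#' @return The long-form pair tibble (`trait_x`, `trait_y`, `method`,
#'   `estimate`, `p`, `n`, `band`).
#' @export
correlation_pairs <- function(corr) {
  stopifnot(inherits(corr, "trait_correlations"))
  corr$pairs
}
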