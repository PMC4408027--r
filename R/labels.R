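#' Tissue labels used in labeled wood cross-sections
#'
#' The label vocabulary for per-pixel classified twig cross-sections.
#' Eight labels describe wood tissue inside the analysed sector; `PITH`
#' and `OUTSIDE` mark pixels that never enter fraction denominators
#' (the analysed region is the wood between pith and bark).
#'
#' `CONDUIT15` is the pooled category for conduits whose maximum lumen
#' diameter is below 15 micrometres (small vessels or tracheids); its wall
#' and lumen are not separated.
#'
#' @return Character vector of the ten label names, in canonical order.
#'   The position of a label in this vector is its integer code in a
#'   label map.
#' @export
#' @examples
#' tissue_labels()
tissue_labels <- function() {
  c("VESSEL_LUMEN", "VESSEL_WALL", "AXIAL_PARENCHYMA", "RAY_PARENCHYMA",
    "FIBRE_LUMEN", "FIBRE_WALL", "CONDUIT15", "MUCILAGE_CANAL",
    "PITH", "OUTSIDE")
}

#' @rdname tissue_labels
#' @export
wood_labels <- function() {
  setdiff(tissue_labels(), c("PITH", "OUTSIDE"))
}

label_code <- function(label) {
  code <- match(label, tissue_labels())
  if (anyNA(code)) {
    stop("unknown tissue label(s): ",
         paste(label[is.na(code)], collapse = ", "), call. = FALSE)
  }
  code
}

#' Construct a labeled wood cross-section
#'
#' Bundles a per-pixel label map with its physical scale and the mask of
#' the analysed sector. This is the measurement substrate for the
#' stereology and vessel-morphometry functions.
#'
#' @param labels Integer matrix of label codes (see [tissue_labels()]), or a
#'   character matrix of label names.
#' @param scale_um_per_px Physical side length of one pixel, micrometres.
#' @param mask Logical matrix of the analysed sector, same shape as
#'   `labels`. Defaults to every pixel whose label is not `PITH`/`OUTSIDE`.
#' @return An object of class `labeled_section`: a list with elements
#'   `labels` (integer matrix), `scale_um_per_px`, and `mask`.
#' @export
labeled_section <- function(labels, scale_um_per_px, mask = NULL) {
  if (is.character(labels)) {
    dm <- dim(labels)
    labels <- matrix(label_code(labels), nrow = dm[1], ncol = dm[2])
  }
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop("`labels` must be an integer or character matrix", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 1L | labels > length(tissue_labels()))) {
    stop("label codes out of range 1..", length(tissue_labels()), call. = FALSE)
  }
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0) {
    stop("`scale_um_per_px` must be a single positive number", call. = FALSE)
  }
  out_code <- label_code(c("PITH", "OUTSIDE"))
  if (is.null(mask)) {
    mask <- !(labels %in% out_code)
    dim(mask) <- dim(labels)
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(labels))) {
    stop("`mask` must be a logical matrix with the shape of `labels`",
         call. = FALSE)
  }
  bad <- mask & (labels == label_code("OUTSIDE"))
  if (any(bad)) {
    stop("every in-sector pixel must carry a non-OUTSIDE label (",
         sum(bad), " violations)", call. = FALSE)
  }
  structure(
    list(labels = labels, scale_um_per_px = scale_um_per_px, mask = mask),
    class = "labeled_section"
  )
}

#' @export
print.labeled_section <- function(x, ...) {
  dm <- dim(x$labels)
  cat(sprintf(
    "<labeled_section> %d x %d px at %.4g um/px (%.3g mm^2 in sector)\n",
    dm[1], dm[2], x$scale_um_per_px,
    sum(x$mask) * (x$scale_um_per_px / 1000)^2
  ))
  rf <- realized_fractions(x)
  nz <- rf$fraction > 0
  cat(paste(sprintf("  %-16s %.4f", rf$label[nz], rf$fraction[nz]),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Pixel-exact tissue area fractions of a labeled section
#'
#' Counts in-sector pixels per tissue label and divides by the total
#' in-sector pixel count. This is the exact quantity that grid-point
#' stereology estimates, so it serves as the oracle for the estimator.
#'
#' @param section A [labeled_section()].
#' @return A `fraction_vector` tibble with columns `label`, `fraction`,
#'   `se` (zero here: the value is exact) and attribute `n` (pixels).
#' @export
realized_fractions <- function(section) {
  stopifnot(inherits(section, "labeled_section"))
  in_sector <- section$mask
  labs <- section$labels[in_sector]
  keep <- !(labs %in% label_code(c("PITH", "OUTSIDE")))
  labs <- labs[keep]
  n <- length(labs)
  if (n == 0L) stop("sector mask selects no wood pixels", call. = FALSE)
  counts <- tabulate(labs, nbins = length(tissue_labels()))
  wl <- wood_labels()
  counts <- counts[label_code(wl)]
  fraction_vector(stats::setNames(counts / n, wl), n = n,
                  se = stats::setNames(rep(0, length(wl)), wl),
                  source = "pixel")
}

fraction_vector <- function(fractions, n, se = NULL, source = "grid") {
  wl <- wood_labels()
  f <- stats::setNames(rep(0, length(wl)), wl)
  f[names(fractions)] <- fractions
  if (is.null(se)) se <- sqrt(f * (1 - f) / n)
  s <- stats::setNames(rep(0, length(wl)), wl)
  s[names(se)] <- se
  out <- tibble::tibble(label = wl, fraction = unname(f), se = unname(s))
  attr(out, "n") <- as.integer(n)
  attr(out, "source") <- source
  class(out) <- c("fraction_vector", class(out))
  out
}

#' Extract named fractions from a fraction vector
#'
#' @param fv A `fraction_vector` as returned by [realized_fractions()] or
#'   [fractions_from_counts()].
#' @param labels Labels to extract; default all wood labels.
#' @return Named numeric vector of fractions.
#' @export
fraction_of <- function(fv, labels = wood_labels()) {
  stopifnot(inherits(fv, "fraction_vector"))
  stats::setNames(fv$fraction[match(labels, fv$label)], labels)
}
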