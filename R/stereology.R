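#' Specification of a systematic point grid
#'
#' A square lattice of sampling points used to estimate tissue area
#' fractions by point counting. The default spacing of 300 px matches the
#' classical protocol for twig sections digitized at 0.281 um/px, where
#' 300 px corresponds to 84.3 um between points.
#'
#' @param spacing_px Lattice spacing in pixels (horizontal and vertical).
#' @param offset_px Integer `(dx, dy)` offset of the first point, each in
#'   `[0, spacing_px)`.
#' @param randomize_offset If `TRUE`, draw the offset uniformly at random
#'   (used for unbiasedness checks); requires `rng_seed`.
#' @param rng_seed Seed for the random offset.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(spacing_px = 300L, offset_px = c(0L, 0L),
                      randomize_offset = FALSE, rng_seed = NULL) {
  spacing_px <- as.integer(spacing_px)
  if (spacing_px < 1L) stop("`spacing_px` must be >= 1", call. = FALSE)
  offset_px <- as.integer(offset_px)
  stopifnot(length(offset_px) == 2L)
  if (any(offset_px < 0L) || any(offset_px >= spacing_px)) {
    stop("offsets must lie in [0, spacing)", call. = FALSE)
  }
  structure(list(spacing_px = spacing_px, offset_px = offset_px,
                 randomize_offset = isTRUE(randomize_offset),
                 rng_seed = rng_seed),
            class = "grid_spec")
}

#' Overlay a systematic point grid on a labeled section
#'
#' Returns the lattice points `(offset + i * spacing, offset + j * spacing)`
#' that fall on in-sector pixels. Points are taken at pixel centres; a
#' point carries the label of the pixel it lands on.
#'
#' @param section A [labeled_section()].
#' @param grid A [grid_spec()].
#' @return A tibble with integer columns `x`, `y` (1-based pixel
#'   coordinates) of the in-sector grid points, with the realized offset
#'   stored in attribute `"offset_px"`.
#' @export
overlay_grid <- function(section, grid = grid_spec()) {
  stopifnot(inherits(section, "labeled_section"), inherits(grid, "grid_spec"))
  H <- nrow(section$labels); W <- ncol(section$labels)
  if (grid$spacing_px > max(W, H)) {
    stop("grid spacing exceeds the image extent", call. = FALSE)
  }
  off <- grid$offset_px
  if (grid$randomize_offset) {
    off <- with_seed(grid$rng_seed,
                     as.integer(floor(stats::runif(2, 0, grid$spacing_px))))
  }
  xs <- seq.int(1L + off[1], W, by = grid$spacing_px)
  ys <- seq.int(1L + off[2], H, by = grid$spacing_px)
  pts <- expand.grid(y = ys, x = xs, KEEP.OUT.ATTRS = FALSE)
  keep <- section$mask[cbind(pts$y, pts$x)]
  pts <- pts[keep, c("x", "y")]
  if (nrow(pts) == 0L) {
    stop("no grid points fall inside the sector; decrease `spacing_px`",
         call. = FALSE)
  }
  out <- tibble::as_tibble(pts)
  attr(out, "offset_px") <- off
  out
}

#' Tally grid points by the tissue they fall on
#'
#' @param section A [labeled_section()].
#' @param points A tibble of points as returned by [overlay_grid()].
#' @return A `point_counts` object: tibble with columns `label`, `count`
#'   and attribute `total` (number of in-sector points). Points landing on
#'   `PITH` or `OUTSIDE` pixels are excluded from the total.
#' @export
count_points <- function(section, points) {
  stopifnot(inherits(section, "labeled_section"))
  H <- nrow(section$labels); W <- ncol(section$labels)
  if (any(points$x < 1L | points$x > W | points$y < 1L | points$y > H)) {
    stop("points outside image bounds", call. = FALSE)
  }
  labs <- section$labels[cbind(points$y, points$x)]
  labs <- labs[!(labs %in% label_code(c("PITH", "OUTSIDE")))]
  counts <- tabulate(labs, nbins = length(tissue_labels()))
  wl <- wood_labels()
  out <- tibble::tibble(label = wl, count = counts[label_code(wl)])
  attr(out, "total") <- sum(out$count)
  class(out) <- c("point_counts", class(out))
  out
}

#' Estimate tissue fractions from point counts
#'
#' The stereological estimate: fraction of a tissue = number of grid
#' points falling on it divided by the total number of analysed points,
#' with a binomial standard error `sqrt(p (1 - p) / n)` attached. The
#' protocol this implements requires at least 300 analysed points per
#' sample; fewer points raise an error in strict mode and a warning
#' otherwise.
#'
#' @param counts A `point_counts` object from [count_points()].
#' @param min_points Minimum number of analysed points (default 300).
#' @param strict If `TRUE` (default), fewer than `min_points` points is an
#'   error; if `FALSE`, a warning.
#' @return A `fraction_vector` tibble (label, fraction, se) with attribute
#'   `n` = total points.
#' @export
fractions_from_counts <- function(counts, min_points = 300L, strict = TRUE) {
  stopifnot(inherits(counts, "point_counts"))
  total <- attr(counts, "total")
  if (total == 0L) stop("no analysed points", call. = FALSE)
  if (total < min_points) {
    msg <- sprintf(
      "only %d analysed points; the protocol requires a minimum of %d",
      total, min_points)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  p <- stats::setNames(counts$count / total, counts$label)
  fraction_vector(p, n = total, source = "grid")
}

#' One-call stereological measurement of a section
#'
#' Convenience wrapper: overlay a grid, tally points, estimate fractions.
#' If `spacing_px` is `NULL`, a spacing is chosen so that roughly
#' `target_points` points fall in the sector.
#'
#' @inheritParams fractions_from_counts
#' @param section A [labeled_section()].
#' @param spacing_px Grid spacing; `NULL` to auto-select.
#' @param target_points Aimed-for point count when auto-selecting.
#' @param ... Passed to [grid_spec()].
#' @return A `fraction_vector`.
#' @export
estimate_fractions <- function(section, spacing_px = NULL,
                               target_points = 400L, min_points = 300L,
                               strict = TRUE, ...) {
  if (is.null(spacing_px)) {
    spacing_px <- max(1L, floor(sqrt(sum(section$mask) / target_points)))
  }
  pts <- overlay_grid(section, grid_spec(spacing_px = spacing_px, ...))
  fractions_from_counts(count_points(section, pts),
                        min_points = min_points, strict = strict)
}
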