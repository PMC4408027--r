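#' Extract conduit lumens from a labeled section
#'
#' Finds 4-connected components of conduit-lumen pixels and measures each:
#' lumen area (mm^2), circle-equivalent diameter (mm), maximum Feret
#' diameter (mm) and centroid. Components whose centroid falls outside the
#' sector mask are dropped (border-touching components are kept if and
#' only if their centroid is inside).
#'
#' @param section A [labeled_section()].
#' @param labels Which tissue labels to treat as conduit lumen; by default
#'   only `VESSEL_LUMEN`. Add `"CONDUIT15"` to also extract the pooled
#'   small-conduit category.
#' @return A tibble with one row per conduit: `id`, `area_mm2`,
#'   `eq_diameter_mm`, `feret_mm`, `centroid_x`, `centroid_y`, `n_px`,
#'   `label`.
#' @export
extract_vessels <- function(section, labels = "VESSEL_LUMEN") {
  stopifnot(inherits(section, "labeled_section"))
  sc_mm <- section$scale_um_per_px / 1000
  out <- list()
  for (lb in labels) {
    mask <- section$labels == label_code(lb)
    comp <- label_components(mask)
    if (comp$n == 0L) next
    idx <- which(mask)
    cid <- comp$labels[idx]
    row <- ((idx - 1L) %% nrow(mask)) + 1L
    col <- ((idx - 1L) %/% nrow(mask)) + 1L
    npx <- tabulate(cid, nbins = comp$n)
    cx <- tapply(col, cid, mean)
    cy <- tapply(row, cid, mean)
    inside <- section$mask[cbind(pmin(pmax(round(cy), 1L), nrow(mask)),
                                 pmin(pmax(round(cx), 1L), ncol(mask)))]
    feret <- vapply(seq_len(comp$n), function(k) {
      sel <- cid == k
      max_feret_px(col[sel], row[sel])
    }, numeric(1))
    rec <- tibble::tibble(
      area_mm2 = npx * sc_mm^2,
      eq_diameter_mm = 2 * sqrt(npx * sc_mm^2 / pi),
      feret_mm = feret * sc_mm,
      centroid_x = as.numeric(cx),
      centroid_y = as.numeric(cy),
      n_px = npx,
      label = lb
    )[inside, ]
    out[[lb]] <- rec
  }
  if (!length(out)) {
    return(tibble::tibble(id = integer(0), area_mm2 = numeric(0),
                          eq_diameter_mm = numeric(0), feret_mm = numeric(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          n_px = integer(0), label = character(0)))
  }
  res <- dplyr::bind_rows(out)
  dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(res))), res)
}

# 4-connected component labeling by column-run merging with union-find.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  runs_start <- vector("list", W); runs_end <- vector("list", W)
  runs_id <- vector("list", W)
  n_runs <- 0L
  for (j in seq_len(W)) {
    colv <- mask[, j]
    if (!any(colv)) next
    r <- rle(colv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    runs_start[[j]] <- starts[keep]
    runs_end[[j]] <- ends[keep]
    ids <- n_runs + seq_len(sum(keep))
    runs_id[[j]] <- ids
    n_runs <- n_runs + length(ids)
  }
  if (n_runs == 0L) {
    return(list(labels = matrix(0L, H, W), n = 0L))
  }
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  prev <- NULL
  for (j in seq_len(W)) {
    cur <- if (is.null(runs_id[[j]])) NULL else j
    if (!is.null(cur) && !is.null(prev)) {
      a_s <- runs_start[[prev]]; a_e <- runs_end[[prev]]; a_i <- runs_id[[prev]]
      b_s <- runs_start[[j]]; b_e <- runs_end[[j]]; b_i <- runs_id[[j]]
      for (bi in seq_along(b_s)) {
        ov <- which(a_s <= b_e[bi] & a_e >= b_s[bi])
        for (ai in ov) union(a_i[ai], b_i[bi])
      }
    }
    if (!is.null(cur)) prev <- j
    if (is.null(runs_id[[j]])) prev <- NULL
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  labels <- matrix(0L, H, W)
  for (j in seq_len(W)) {
    ids <- runs_id[[j]]
    if (is.null(ids)) next
    for (k in seq_along(ids)) {
      labels[runs_start[[j]][k]:runs_end[[j]][k], j] <- relab[ids[k]]
    }
  }
  list(labels = labels, n = max(relab))
}

# Maximum Feret diameter of a pixel set, in pixel units. Computed on the
# convex hull of pixel centres plus one pixel width to account for the
# finite pixel extent (a disc of n pixels across then measures n, not n-1).
max_feret_px <- function(x, y) {
  if (length(x) == 1L) return(1)
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1L) return(1)
  hull <- if (nrow(pts) > 2L) pts[grDevices::chull(pts), , drop = FALSE] else pts
  d2 <- stats::dist(hull)
  max(d2) + 1
}

#' Split conduit records at the 15-micrometre rule
#'
#' Conduits whose maximum lumen (Feret) diameter is strictly below the
#' threshold are classed as small conduits; the remainder are vessels
#' proper, used for the vessel statistics A, N, S and the hydraulically
#' weighted diameter.
#'
#' @param records A tibble from [extract_vessels()].
#' @param threshold_um Diameter threshold in micrometres (default 15).
#' @return A list with elements `vessels` and `conduits` (disjoint,
#'   union = input).
#' @export
partition_conduits15 <- function(records, threshold_um = 15) {
  check_positive(threshold_um)
  small <- records$feret_mm * 1000 < threshold_um
  list(vessels = records[!small, , drop = FALSE],
       conduits = records[small, , drop = FALSE])
}

#' Hydraulically weighted conduit diameter
#'
#' `D_H = sum(d^5) / sum(d^4)`: the diameter weighting each conduit by its
#' contribution to hydraulic conductance. Always at least the arithmetic
#' mean diameter, with equality only when all diameters are equal.
#'
#' @param diameters Positive numeric vector of conduit diameters (any
#'   single length unit; the result is in the same unit).
#' @return The hydraulically weighted diameter.
#' @export
#' @examples
#' hydraulic_diameter(c(10, 20))  # 19.4118, pulled toward the wide conduit
hydraulic_diameter <- function(diameters) {
  if (length(diameters) == 0L) {
    stop("`diameters` must be non-empty", call. = FALSE)
  }
  check_positive(diameters, "diameters")
  sum(diameters^5) / sum(diameters^4)
}

#' Vessel statistics of a cross-section
#'
#' Computes the summary statistics of the vessel population: `A`, the
#' arithmetic mean vessel lumen area (mm^2); `N`, the vessel number per
#' area, defined as the vessel lumen fraction of the cross-section divided
#' by `A` (mm^-2); `S = A / N` (mm^4), the vessel area-to-number ratio
#' (large when few large vessels dominate); and `D_H`, the hydraulically
#' weighted diameter over circle-equivalent lumen diameters (mm). The
#' identities `N * A = VLF` and `S = A^2 / VLF` hold exactly.
#'
#' @param records Vessel records from [extract_vessels()] (after
#'   [partition_conduits15()] if small conduits are present).
#' @param vlf Vessel lumen fraction of the cross-section, typically the
#'   grid-based stereological estimate.
#' @return A one-row tibble with columns `A`, `N`, `S`, `Dh`, `VLF`,
#'   `n_vessels`.
#' @export
vessel_stats <- function(records, vlf) {
  if (nrow(records) == 0L) {
    stop("no vessel records; cannot compute vessel statistics", call. = FALSE)
  }
  if (!is.numeric(vlf) || length(vlf) != 1L || vlf <= 0 || vlf > 1) {
    stop("`vlf` must be a single fraction in (0, 1]", call. = FALSE)
  }
  A <- mean(records$area_mm2)
  N <- vlf / A
  tibble::tibble(
    A = A, N = N, S = A / N,
    Dh = hydraulic_diameter(records$eq_diameter_mm),
    VLF = vlf, n_vessels = nrow(records)
  )
}

#' Full vessel morphometry of a labeled section
#'
#' Extracts conduits, applies the 15-um partition, estimates the vessel
#' lumen fraction (from the supplied fraction vector, or pixel-exact if
#' none given) and returns the vessel statistics.
#'
#' @param section A [labeled_section()].
#' @param fractions Optional `fraction_vector` supplying the vessel lumen
#'   fraction (e.g. a grid estimate); defaults to pixel-exact fractions.
#' @param threshold_um 15-um partition threshold.
#' @return A one-row tibble as [vessel_stats()], plus `n_conduits15`.
#' @export
measure_vessels <- function(section, fractions = NULL, threshold_um = 15) {
  recs <- extract_vessels(section, labels = c("VESSEL_LUMEN", "CONDUIT15"))
  parts <- partition_conduits15(recs, threshold_um = threshold_um)
  if (is.null(fractions)) fractions <- realized_fractions(section)
  vlf <- unname(fraction_of(fractions, "VESSEL_LUMEN"))
  stats <- vessel_stats(parts$vessels, vlf = vlf)
  stats$n_conduits15 <- nrow(parts$conduits)
  stats
}
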