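#' Specification for a synthetic labeled wood cross-section
#'
#' Describes the mosaic geometry of a twig-wood sector: target area
#' fractions per tissue, conduit size distributions, ray geometry and the
#' fibre tessellation. [generate_section()] realizes the specification as a
#' pixel label map whose in-sector fractions land within +/- 0.02 of each
#' target, with pixel-exact ground truth available from
#' [realized_fractions()].
#'
#' Defaults follow the across-species average composition of the study
#' system this package models: fibre wall 0.32, fibre lumen 0.13, axial
#' parenchyma 0.14, rays 0.21, vessel lumen 0.13, vessel wall 0.04,
#' small conduits 0.02, mucilage canals 0.01.
#'
#' @param target_fractions Named numeric vector over (a subset of) the
#'   in-sector labels of [wood_labels()]; must sum to 1 within 1e-9.
#' @param image_size_px Integer `(width, height)` of the section in pixels.
#' @param scale_um_per_px Micrometres per pixel.
#' @param vessel_diameter_um `(mean, sd)` of the lognormal vessel lumen
#'   diameter distribution, truncated to at least 15 um (vessels proper).
#' @param conduit_diameter_um `(mean, sd)` of the lognormal diameter of
#'   small conduits, truncated below 15 um.
#' @param mucilage_diameter_um Diameter of mucilage canals, um.
#' @param ray_width_um Width of a ray band, um.
#' @param fibre_cell_diameter_um Across-flats diameter of a fibre cell
#'   (hexagon pitch), um.
#' @param parenchyma_patch_diameter_um Diameter of an axial-parenchyma
#'   patch, um.
#' @param rng_seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `section_spec` (a validated list).
#' @export
section_spec <- function(target_fractions = c(
                           FIBRE_WALL = 0.32, FIBRE_LUMEN = 0.13,
                           AXIAL_PARENCHYMA = 0.14, RAY_PARENCHYMA = 0.21,
                           VESSEL_LUMEN = 0.13, VESSEL_WALL = 0.04,
                           CONDUIT15 = 0.02, MUCILAGE_CANAL = 0.01),
                         image_size_px = c(800L, 800L),
                         scale_um_per_px = 1,
                         vessel_diameter_um = c(mean = 40, sd = 8),
                         conduit_diameter_um = c(mean = 10, sd = 1.5),
                         mucilage_diameter_um = 60,
                         ray_width_um = 30,
                         fibre_cell_diameter_um = 20,
                         parenchyma_patch_diameter_um = 30,
                         rng_seed = 1L) {
  if (is.null(names(target_fractions)) ||
      !all(names(target_fractions) %in% wood_labels())) {
    stop("`target_fractions` must be named with in-sector tissue labels",
         call. = FALSE)
  }
  if (any(target_fractions < 0)) {
    stop("target fractions must be non-negative", call. = FALSE)
  }
  if (abs(sum(target_fractions) - 1) > 1e-9) {
    stop("target fractions must sum to 1 (got ",
         format(sum(target_fractions), digits = 12), ")", call. = FALSE)
  }
  tf <- stats::setNames(rep(0, length(wood_labels())), wood_labels())
  tf[names(target_fractions)] <- target_fractions
  image_size_px <- as.integer(image_size_px)
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 16L))
  check_positive(scale_um_per_px)
  check_positive(vessel_diameter_um)
  check_positive(conduit_diameter_um)
  check_positive(ray_width_um)
  check_positive(fibre_cell_diameter_um)
  check_positive(parenchyma_patch_diameter_um)
  check_positive(mucilage_diameter_um)
  # image must hold a reasonable number of fibre cells for the tessellation
  n_fibres <- prod(image_size_px) * (scale_um_per_px / fibre_cell_diameter_um)^2
  if (tf["FIBRE_WALL"] + tf["FIBRE_LUMEN"] > 0 && n_fibres < 50) {
    stop("image too small: holds fewer than 50 fibre cells", call. = FALSE)
  }
  structure(
    list(target_fractions = tf,
         image_size_px = image_size_px,
         scale_um_per_px = scale_um_per_px,
         vessel_diameter_um = vessel_diameter_um,
         conduit_diameter_um = conduit_diameter_um,
         mucilage_diameter_um = mucilage_diameter_um,
         ray_width_um = ray_width_um,
         fibre_cell_diameter_um = fibre_cell_diameter_um,
         parenchyma_patch_diameter_um = parenchyma_patch_diameter_um,
         rng_seed = as.integer(rng_seed)),
    class = "section_spec"
  )
}

# paint a filled disc into `lab` (by reference semantics: returns indices).
# Returns linear indices of pixels inside the disc, clipped to the image.
disc_indices <- function(cx, cy, r, W, H) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  inside <- outer(dy2, dx2, `+`) <= r^2
  idx <- which(inside)
  if (!length(idx)) return(integer(0))
  row <- ((idx - 1L) %% length(ys)) + y0
  col <- ((idx - 1L) %/% length(ys)) + x0
  (col - 1L) * H + row
}

#' Generate a synthetic labeled wood cross-section
#'
#' Realizes a [section_spec()] as a tissue mosaic: rays as straight bands
#' crossing the section at randomized oblique angles (the Cartesian
#' analogue of the radial ray fan of a wedge-shaped sector), vessels as
#' non-overlapping discs with a wall annulus (placed by dart throwing),
#' small conduits and mucilage canals as discs, axial parenchyma as
#' clipped circular patches, and fibres as a hexagonal tessellation of the
#' remaining area whose lumen share is set pixel-exactly from the
#' requested wall:lumen split.
#'
#' Generation is deterministic given the spec (including `rng_seed`), and
#' the realized in-sector fraction of every tissue lands within +/- 0.02 of
#' its target; targets that cannot be realized (e.g. a vessel fraction
#' beyond the disc-packing limit) raise an error naming the violated
#' fraction.
#'
#' @param spec A [section_spec()].
#' @return A [labeled_section()] with the generating `spec` attached as
#'   attribute `"spec"`.
#' @export
#' @examples
#' sec <- generate_section(section_spec(image_size_px = c(300, 300)))
#' realized_fractions(sec)
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(spec$rng_seed, generate_section_impl(spec))
}

generate_section_impl <- function(spec) {
  W <- spec$image_size_px[1]; H <- spec$image_size_px[2]
  total <- as.numeric(W) * H
  sc <- spec$scale_um_per_px
  tf <- spec$target_fractions
  tol_px <- 0.02 * total

  # upfront packing feasibility: darts jam well below ~0.55 coverage
  free_frac <- 1 - tf["RAY_PARENCHYMA"]
  disc_frac <- tf["VESSEL_LUMEN"] + tf["VESSEL_WALL"] + tf["CONDUIT15"] +
    tf["MUCILAGE_CANAL"]
  if (disc_frac > 0.45 * free_frac) {
    worst <- c("VESSEL_LUMEN", "CONDUIT15", "MUCILAGE_CANAL")
    worst <- worst[which.max(tf[worst])]
    stop("infeasible target fractions: ", worst, " (total disc coverage ",
         signif(disc_frac, 3), " exceeds the packing limit for free area ",
         signif(free_frac, 3), ")", call. = FALSE)
  }

  lab <- matrix(0L, nrow = H, ncol = W)

  ## 1. rays: straight bands crossing the section at randomized oblique
  ## angles, emulating the fan of radial rays seen in a wedge-shaped
  ## sector (and avoiding any alignment with rectangular sampling grids);
  ## painted row by row, pixel-exact in total
  ray_target <- round(tf["RAY_PARENCHYMA"] * total)
  if (ray_target >= H) {
    ray_code <- label_code("RAY_PARENCHYMA")
    w_px <- max(1L, round(spec$ray_width_um / sc))
    n_bands <- max(1L, round(ray_target / (w_px * H)))
    pitch <- W / n_bands
    # plan extra bands beyond the layout: slope drift and band overlap can
    # leave the planned set short, especially on small images
    n_plan <- n_bands * 4L + 4L
    centers <- c((sample(n_bands) - 0.5) * pitch +
                   stats::runif(n_bands, -pitch / 3, pitch / 3),
                 stats::runif(n_plan - n_bands, 1, W))
    slopes <- stats::runif(n_plan, 0.15, 0.45) *
      sample(c(-1, 1), n_plan, replace = TRUE)
    painted <- 0
    rows <- seq_len(H)
    for (b in seq_len(n_plan)) {
      if (painted >= ray_target) break
      # band centre drifts across columns with row: x = c + s * (y - H/2)
      cx <- centers[b] + slopes[b] * (rows - H / 2)
      x0 <- pmax(1L, pmin(W, round(cx - w_px / 2)))
      x1 <- pmax(1L, pmin(W, round(cx + w_px / 2 - 1)))
      for (y in rows) {
        if (x1[y] < x0[y]) next
        xs <- x0[y]:x1[y]
        new <- xs[lab[y, xs] == 0L]
        if (!length(new)) next
        take <- min(length(new), ray_target - painted)
        lab[y, new[seq_len(take)]] <- ray_code
        painted <- painted + take
        if (painted >= ray_target) break
      }
    }
  }

  ## 2..4. disc tissues: vessels (+wall), conduits, mucilage canals
  wall_ratio <- if (tf["VESSEL_LUMEN"] > 0) {
    tf["VESSEL_WALL"] / tf["VESSEL_LUMEN"]
  } else 0

  throw_discs <- function(lab, target_px, label, diam_sampler, wall = 0,
                          what = label, min_diam_um = NULL) {
    if (target_px < 1) return(lab)
    code <- label_code(label)
    wall_code <- label_code("VESSEL_WALL")
    min_est <- if (is.null(min_diam_um)) 0 else pi * (min_diam_um / (2 * sc))^2
    painted <- 0
    fails <- 0L
    while (painted < target_px - 1) {
      # discs are indivisible: once the deficit is below half the smallest
      # disc the sampler can offer, stopping is closer than continuing
      if (target_px - painted <= min_est / 2) break
      d_um <- diam_sampler()
      r <- d_um / (2 * sc)
      w_px <- if (wall > 0) r * (sqrt(1 + wall) - 1) else 0
      r_out <- r + w_px
      if (2 * r_out + 2 > min(W, H)) { fails <- fails + 1L; next }
      cx <- stats::runif(1, r_out + 1, W - r_out)
      cy <- stats::runif(1, r_out + 1, H - r_out)
      # the footprint plus a one-pixel margin must be unclaimed, which
      # keeps discs disjoint from rays, canals and each other
      guard <- disc_indices(cx, cy, r_out + 1, W, H)
      if (any(lab[guard] != 0L)) {
        fails <- fails + 1L
        if (fails > 20000L) {
          if (target_px - painted <= 0.02 * total) break
          stop("infeasible target fractions: could not place enough ",
               what, " discs (reached ", signif(painted / total, 3),
               " of target ", signif(target_px / total, 3), ")",
               call. = FALSE)
        }
        next
      }
      # an oversized draw that would overshoot past the target counts as
      # a failed attempt; a smaller diameter may still fit
      est <- pi * r^2
      if (painted + est - target_px > target_px - painted) {
        fails <- fails + 1L
        if (fails > 5000L) break  # deficit already below one typical disc
        next
      }
      fails <- 0L
      if (w_px > 0) {
        lab[disc_indices(cx, cy, r_out, W, H)] <- wall_code
      }
      core <- disc_indices(cx, cy, r, W, H)
      lab[core] <- code
      painted <- painted + length(core)
    }
    lab
  }

  # largest discs first: canals, then vessels, then the small conduits
  lab <- throw_discs(lab, round(tf["MUCILAGE_CANAL"] * total), "MUCILAGE_CANAL",
                     function() spec$mucilage_diameter_um,
                     min_diam_um = spec$mucilage_diameter_um)
  vd <- spec$vessel_diameter_um
  lab <- throw_discs(lab, round(tf["VESSEL_LUMEN"] * total), "VESSEL_LUMEN",
                     function() rtrunc_lnorm(1, vd[1], vd[2], lo = 16, hi = 120),
                     wall = wall_ratio, min_diam_um = 16)
  cd <- spec$conduit_diameter_um
  lab <- throw_discs(lab, round(tf["CONDUIT15"] * total), "CONDUIT15",
                     function() rtrunc_lnorm(1, cd[1], cd[2], lo = 5, hi = 14),
                     min_diam_um = 5)

  ## 5. axial parenchyma: clipped circular patches into unassigned space
  ap_target <- round(tf["AXIAL_PARENCHYMA"] * total)
  if (ap_target >= 1) {
    code <- label_code("AXIAL_PARENCHYMA")
    r_ap <- spec$parenchyma_patch_diameter_um / (2 * sc)
    painted <- 0
    fails <- 0L
    while (painted < ap_target - 1) {
      cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
      idx <- disc_indices(cx, cy, r_ap, W, H)
      idx <- idx[lab[idx] == 0L]
      if (!length(idx)) {
        fails <- fails + 1L
        if (fails > 20000L) {
          stop("infeasible target fractions: AXIAL_PARENCHYMA (no ",
               "unassigned space left at ", signif(painted / total, 3), ")",
               call. = FALSE)
        }
        next
      }
      fails <- 0L
      if (painted + length(idx) > ap_target + r_ap^2) {
        idx <- idx[seq_len(max(1L, ap_target - painted))]
      }
      lab[idx] <- code
      painted <- painted + length(idx)
    }
  }

  ## 6. fibres: hexagonal tessellation of the remainder, wall:lumen tuned
  rem <- which(lab == 0L)
  fib_target <- tf["FIBRE_WALL"] + tf["FIBRE_LUMEN"]
  if (length(rem)) {
    if (fib_target <= 0 && length(rem) > tol_px) {
      stop("infeasible target fractions: ", signif(length(rem) / total, 3),
           " of the section is left unassigned but the fibre target is 0",
           call. = FALSE)
    }
    row <- ((rem - 1L) %% H) + 1L
    col <- ((rem - 1L) %/% H) + 1L
    hx <- hex_distance(col, row, pitch = spec$fibre_cell_diameter_um / sc)
    lumen_share <- if (fib_target > 0) tf["FIBRE_LUMEN"] / fib_target else 0
    lumen_target <- round(lumen_share * length(rem))
    # h <= t  => lumen; pick threshold as the empirical quantile: exact
    t_cut <- if (lumen_target <= 0) -1 else {
      sort(hx, partial = lumen_target)[lumen_target]
    }
    is_lumen <- hx <= t_cut
    lab[rem[is_lumen]] <- label_code("FIBRE_LUMEN")
    lab[rem[!is_lumen]] <- label_code("FIBRE_WALL")
  }

  sec <- labeled_section(lab, scale_um_per_px = sc)
  attr(sec, "spec") <- spec

  realized <- fraction_of(realized_fractions(sec))
  err <- abs(realized - tf)
  if (any(err > 0.02 + 1e-12)) {
    worst <- names(which.max(err))
    stop("generation failed to realize target fraction for ", worst,
         " (target ", signif(tf[worst], 3), ", realized ",
         signif(realized[worst], 3), ")", call. = FALSE)
  }
  sec
}

# Normalized hexagonal distance of pixels (x, y) to their nearest hexagon
# centre, for a pointy-top hex lattice with centre spacing `pitch` px.
# 0 at a centre, 1 on the cell boundary; a pixel with value <= t lies in
# the concentric hexagon shrunk by factor t (the fibre lumen).
hex_distance <- function(x, y, pitch) {
  s <- pitch / sqrt(3)  # hexagon circumradius
  # axial coordinates of the nearest hex centre (cube rounding)
  q <- (sqrt(3) / 3 * x - 1 / 3 * y) / s
  r <- (2 / 3 * y) / s
  xq <- round(q); xr <- round(r); xs <- round(-q - r)
  dq <- abs(xq - q); dr <- abs(xr - r); ds <- abs(xs - (-q - r))
  fix_q <- dq > dr & dq > ds
  xq[fix_q] <- -xr[fix_q] - xs[fix_q]
  fix_r <- !fix_q & dr > ds
  xr[fix_r] <- -xq[fix_r] - xs[fix_r]
  cx <- s * sqrt(3) * (xq + xr / 2)
  cy <- s * 3 / 2 * xr
  px <- x - cx; py <- y - cy
  # hexagon support function: max projection on the three edge normals,
  # scaled by the apothem (pitch / 2)
  a <- pitch / 2
  h1 <- abs(px)
  h2 <- abs(px * 0.5 + py * sqrt(3) / 2)
  h3 <- abs(px * 0.5 - py * sqrt(3) / 2)
  pmax(h1, h2, h3) / a
}
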