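# Shared fixtures: all synthetic, built in code at test time.

# a small, quick-to-generate section with all eight tissues
small_section_spec <- function(seed = 42L, size = 400L) {
  section_spec(image_size_px = c(size, size), rng_seed = seed)
}

# a uniform single-tissue section built directly (no generator involved)
uniform_section <- function(label = "FIBRE_WALL", n = 60L,
                            scale_um_per_px = 1) {
  labeled_section(matrix(label, n, n), scale_um_per_px = scale_um_per_px)
}

# left half one tissue, right half another, even width
split_section <- function(left = "FIBRE_WALL", right = "RAY_PARENCHYMA",
                          n = 100L) {
  m <- matrix(right, n, n)
  m[, seq_len(n %/% 2)] <- left
  labeled_section(m, scale_um_per_px = 1)
}

# paint discs of a label onto a background section; returns the section
disc_section <- function(centers, radii, label = "VESSEL_LUMEN",
                         n = 200L, background = "FIBRE_WALL",
                         scale_um_per_px = 1) {
  m <- matrix(label_code_t(background), n, n)
  for (k in seq_along(radii)) {
    cx <- centers[k, 1]; cy <- centers[k, 2]; r <- radii[k]
    xs <- pmax(1, floor(cx - r)):pmin(n, ceiling(cx + r))
    ys <- pmax(1, floor(cy - r)):pmin(n, ceiling(cy + r))
    for (x in xs) {
      inside <- (x - cx)^2 + (ys - cy)^2 <= r^2
      m[ys[inside], x] <- label_code_t(label)
    }
  }
  labeled_section(m, scale_um_per_px = scale_um_per_px)
}

label_code_t <- function(label) match(label, tissue_labels())
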