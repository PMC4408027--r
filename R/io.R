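#' Write / read a labeled section as an indexed PNG with a JSON sidecar
#'
#' The label map is stored as an 8-bit grayscale PNG whose pixel value is
#' the palette index; the JSON sidecar (`<path>.json`) records the
#' palette (index to tissue label), the physical scale, and optionally a
#' generation seed. If the sector mask differs from the default
#' (non-`OUTSIDE` pixels), it is written alongside as `<path>_mask.png`.
#' The round trip is lossless on labels, scale and mask.
#'
#' @param section A [labeled_section()].
#' @param path Path of the PNG to write (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(section, path) {
  stopifnot(inherits(section, "labeled_section"))
  png::writePNG(section$labels / 255, target = path)
  spec <- attr(section, "spec")
  default_mask <- !(section$labels %in%
                      label_code(c("PITH", "OUTSIDE")))
  dim(default_mask) <- dim(section$labels)
  has_mask_file <- !identical(section$mask, default_mask)
  sidecar <- list(
    palette = as.list(stats::setNames(tissue_labels(),
                                      seq_along(tissue_labels()))),
    scale_um_per_px = section$scale_um_per_px
  )
  if (has_mask_file) {
    sidecar$mask_file <- paste0(sub("\\.png$", "", path), "_mask.png")
  }
  if (!is.null(spec)) sidecar$rng_seed <- spec$rng_seed
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (has_mask_file) {
    png::writePNG(section$mask * 1, target = sidecar$mask_file)
  }
  invisible(path)
}

#' @rdname write_label_map
#' @param strict_palette If `TRUE` (default), a pixel index with no
#'   palette entry is an error naming the index.
#' @export
read_label_map <- function(path, strict_palette = TRUE) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  sidecar <- jsonlite::read_json(sidecar_path)
  if (is.null(sidecar$scale_um_per_px)) {
    stop("sidecar lacks `scale_um_per_px`", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  idx <- round(img * 255)
  pal <- sidecar$palette
  known <- as.integer(names(pal))
  seen <- sort(unique(as.integer(idx)))
  unknown <- setdiff(seen, known)
  if (length(unknown) && strict_palette) {
    stop("palette index with no label mapping: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # map file indices through the palette onto canonical label codes
  lut <- rep(NA_integer_, max(seen) + 1L)
  lut[known + 1L] <- label_code(unlist(pal))
  labels <- matrix(lut[as.integer(idx) + 1L], nrow = nrow(idx))
  if (anyNA(labels)) {
    labels[is.na(labels)] <- label_code("OUTSIDE")
  }
  mask <- NULL
  if (is.character(sidecar$mask_file) && file.exists(sidecar$mask_file)) {
    m <- png::readPNG(sidecar$mask_file)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    mask <- m > 0.5
  }
  sec <- labeled_section(labels, sidecar$scale_um_per_px, mask = mask)
  sec
}

#' Write / read a trait table as CSV
#'
#' One row per (species, site, replicate); trait columns keep the
#' standard abbreviations (see [trait_columns()]).
#'
#' @param table Trait table tibble.
#' @param path CSV path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_trait_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Ingest an external species trait dataset
#'
#' Reads a deposited trait dataset (CSV, or XLSX when the `readxl`
#' package is available) and renames its columns to the standard trait
#' abbreviations through an explicit user-editable mapping, since the
#' headers of deposited files vary.
#'
#' @param path CSV or XLSX file.
#' @param mapping Named character vector `c(standard_name = file_column)`;
#'   columns not in the mapping are kept under their original names.
#' @param sheet Sheet index or name for XLSX input.
#' @return A tibble with standardized trait columns.
#' @export
read_trait_dataset <- function(path, mapping = NULL, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the `readxl` package", call. = FALSE)
    }
    tibble::as_tibble(readxl::read_excel(path, sheet = sheet))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(mapping)) {
    missing_cols <- setdiff(unname(mapping), names(tab))
    if (length(missing_cols)) {
      stop("mapped column(s) not found in file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    idx <- match(unname(mapping), names(tab))
    names(tab)[idx] <- names(mapping)
  }
  tab
}

#' Serialize a fraction vector or point counts to CSV
#'
#' @param x A `fraction_vector` or `point_counts` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fractions <- function(x, path) {
  df <- tibble::as_tibble(x)
  if (!is.null(attr(x, "n"))) df$n <- attr(x, "n")
  readr::write_csv(df, path)
  invisible(path)
}
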