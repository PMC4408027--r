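#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles the tunable thresholds and specifications of a full run:
#' synthetic-section and trait-table specs, the stereology grid, the
#' conduit partition threshold, the minimum point count, the normality
#' gate level and the output directory.
#'
#' @param section_spec A [section_spec()] for the demonstration sections.
#' @param trait_spec A [trait_table_spec()] for the species table.
#' @param n_sections Number of synthetic sections measured in the
#'   `measure` stage.
#' @param grid_spacing_px Grid spacing for section measurement; `NULL`
#'   auto-selects to land near `target_points` points.
#' @param target_points Aimed-for analysed point count per section.
#' @param min_points Minimum analysed points (strict stereology rule).
#' @param conduit_threshold_um 15-um conduit partition threshold.
#' @param alpha Normality-gate and significance level.
#' @param out_dir Output directory for CSVs and figures, or `NULL` to
#'   skip writing.
#' @param rng_seed Master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(section_spec = twigwood::section_spec(),
                            trait_spec = trait_table_spec(),
                            n_sections = 2L,
                            grid_spacing_px = NULL,
                            target_points = 400L,
                            min_points = 300L,
                            conduit_threshold_um = 15,
                            alpha = 0.05,
                            out_dir = NULL,
                            rng_seed = 1L) {
  check_positive(conduit_threshold_um)
  check_positive(target_points)
  check_positive(min_points)
  stopifnot(alpha > 0, alpha < 1)
  structure(
    list(section_spec = section_spec, trait_spec = trait_spec,
         n_sections = as.integer(n_sections),
         grid_spacing_px = grid_spacing_px,
         target_points = as.integer(target_points),
         min_points = as.integer(min_points),
         conduit_threshold_um = conduit_threshold_um,
         alpha = alpha, out_dir = out_dir, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> measure -> derive -> aggregate -> correlate ->
#' summarize on synthetic inputs (or on a supplied trait table): generates
#' and stereologically measures demonstration sections with vessel
#' morphometrics, generates the species trait table, aggregates replicates
#' to species means, computes the trait summary (range / mean / n-fold)
#' and the normality-gated correlation matrices, and optionally writes
#' CSVs and figures. All randomness derives from the config seed, so
#' reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @param trait_table Optional externally supplied replicate-level trait
#'   table; when given, the trait-simulation stage is skipped.
#' @return A list of class `pipeline_report`: `section_measurements`
#'   (per-section fraction estimates and vessel stats), `trait_table`,
#'   `species_table`, `summary`, `correlations`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), trait_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate + measure demonstration sections
  section_measurements <- stage("measure", {
    out <- list()
    for (i in seq_len(config$n_sections)) {
      sspec <- config$section_spec
      sspec$rng_seed <- config$rng_seed + i
      sec <- generate_section(sspec)
      est <- estimate_fractions(sec, spacing_px = config$grid_spacing_px,
                                target_points = config$target_points,
                                min_points = config$min_points)
      vs <- measure_vessels(sec, fractions = est,
                            threshold_um = config$conduit_threshold_um)
      truth <- realized_fractions(sec)
      f <- fraction_of(est)
      out[[i]] <- dplyr::bind_cols(
        tibble::tibble(section = i, n_points = attr(est, "n")),
        tibble::as_tibble(as.list(f)),
        vs,
        tibble::tibble(
          max_abs_error = max(abs(f - fraction_of(truth))))
      )
    }
    dplyr::bind_rows(out)
  })

  ## simulate traits
  if (is.null(trait_table)) {
    trait_table <- stage("simulate-traits", {
      tspec <- config$trait_spec
      tspec$rng_seed <- config$rng_seed
      generate_trait_table(tspec)
    })
  }

  ## derive + aggregate
  species_table <- stage("aggregate", species_means(trait_table))

  ## summarize + correlate
  summary_tab <- stage("summarize",
                       summarize_traits(species_table,
                                        traits = intersect(trait_columns(),
                                                           names(species_table))))
  corr_traits <- setdiff(intersect(trait_columns(), names(species_table)),
                         "MCF")  # canal fraction excluded from correlations
  correlations <- stage("correlate",
                        suppressWarnings(
                          correlation_matrix(species_table,
                                             traits = corr_traits,
                                             alpha = config$alpha)))

  report <- structure(
    list(section_measurements = section_measurements,
         trait_table = trait_table, species_table = species_table,
         summary = summary_tab, correlations = correlations,
         config = config),
    class = "pipeline_report"
  )

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(f) file.path(config$out_dir, f)
      readr::write_csv(section_measurements, p("section_measurements.csv"))
      readr::write_csv(trait_table, p("trait_table.csv"))
      readr::write_csv(species_table, p("species_table.csv"))
      readr::write_csv(summary_tab, p("trait_summary.csv"))
      readr::write_csv(correlations$pairs, p("correlations_long.csv"))
      utils::write.csv(round(correlations$headline, 3),
                       p("correlation_matrix.csv"))
      ggplot2::ggsave(p("tissue_fractions.png"),
                      plot_tissue_fractions(species_table),
                      width = 9, height = 6, dpi = 150)
      ggplot2::ggsave(p("fibre_vs_parenchyma.png"),
                      plot_trait_pair(species_table, "TFF", "TPF",
                                      correlations),
                      width = 5, height = 4, dpi = 150)
    })
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  sections measured :", nrow(x$section_measurements), "\n")
  cat("  species-at-sites  :", nrow(x$species_table), "\n")
  cat("  traits summarised :", nrow(x$summary), "\n")
  tfp <- correlation_of(x$correlations, "TFF", "TPF")
  cat(sprintf("  TFF~TPF           : %s %.2f (p = %.2g)\n",
              tfp$method, tfp$estimate, tfp$p))
  invisible(x)
}

#' Stacked tissue-fraction bar chart across species
#'
#' One stacked bar per species (ordered by decreasing total parenchyma
#' fraction) showing the composition of the wood cross-section.
#'
#' @param species_table Species-level trait table.
#' @return A ggplot object.
#' @export
plot_tissue_fractions <- function(species_table) {
  comp <- c("APF", "RPF", "FLF", "FWF", "VLF", "VWF", "CF", "MCF")
  df <- species_table[, c("species", comp)]
  df$species <- stats::reorder(df$species, -(df$APF + df$RPF))
  long <- tidyr::pivot_longer(df, dplyr::all_of(comp),
                              names_to = "tissue", values_to = "fraction")
  long$tissue <- factor(long$tissue, levels = rev(comp))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$species, y = .data$fraction,
                               fill = .data$tissue)) +
    ggplot2::geom_col(width = 1, colour = NA) +
    ggplot2::scale_fill_brewer(palette = "Spectral") +
    ggplot2::labs(x = NULL, y = "fraction of wood cross-section") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Scatter plot of a trait pair with its gated correlation
#'
#' @param species_table Species-level trait table.
#' @param trait_x,trait_y Trait column names.
#' @param correlations Optional `trait_correlations` to annotate the
#'   coefficient in the subtitle.
#' @return A ggplot object.
#' @export
plot_trait_pair <- function(species_table, trait_x, trait_y,
                            correlations = NULL) {
  sub <- NULL
  if (!is.null(correlations)) {
    cc <- correlation_of(correlations, trait_x, trait_y)
    sym <- if (cc$method == "pearson") "r" else "rho"
    sub <- sprintf("%s = %.2f (%s, p = %.2g, n = %d)",
                   sym, cc$estimate, cc$method, cc$p, cc$n)
  }
  aes_site <- if ("site" %in% names(species_table)) {
    ggplot2::aes(x = .data[[trait_x]], y = .data[[trait_y]],
                 colour = .data$site)
  } else {
    ggplot2::aes(x = .data[[trait_x]], y = .data[[trait_y]])
  }
  ggplot2::ggplot(species_table, aes_site) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(subtitle = sub) +
    ggplot2::theme_minimal()
}
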