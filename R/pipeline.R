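#' Run the full simulation-to-report pipeline
#'
#' Orchestrates every stage on synthetic data: generates a SNP panel and
#' peak table, computes normalized dosage ratios, calls copy states and the
#' truncation breakpoint, estimates transgene escape by shared-allele
#' deconvolution, simulates and classifies FISH scoring experiments, and
#' runs the spatial-association comparison. All tables (and a JSON
#' provenance sidecar with the full configuration) are written under
#' `out_dir`; outputs are deterministic for a fixed configuration seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param region_start,region_end,n_snps SNP panel parameters; defaults
#'   span the endogenous escapee locus used throughout the package
#'   examples.
#' @param thresholds Copy-state thresholds ([copy_state_thresholds()]).
#' @param reference_snp Id of the non-transgenic control SNP used for
#'   X-loss correction (the panel generator appends it).
#' @param alpha Rejection level for FISH hypothesis classification.
#' @param area_threshold Nuclear-area cutoff in square micrometres.
#' @param display_fraction Fraction of closest observations kept in
#'   cumulative-frequency plots.
#' @param write_plots Write PNG figures alongside the tables.
#' @return A named list with every intermediate and final result
#'   (`panel`, `peaks`, `ratios`, `calls`, `breakpoint`, `escape`,
#'   `fish`, `spatial`), invisibly.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = NULL,
                         region_start = 148557326,
                         region_end = 148807402,
                         n_snps = 18,
                         thresholds = copy_state_thresholds(),
                         reference_snp = "ref_snp",
                         alpha = 0.001,
                         area_threshold = 175,
                         display_fraction = 0.7,
                         write_plots = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_xci_table(df, file.path(out_dir, name))
    df
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sim_config(config, file.path(out_dir, "config.json"))
  }

  ## -- simulate -------------------------------------------------------
  panel <- simulate_snp_panel(region_start, region_end, n_snps,
                              seed = config$seed,
                              reference_snp_id = reference_snp)
  peaks <- simulate_peak_table(panel, config)
  if (!is.null(out_dir)) {
    write_markers(panel, file.path(out_dir, "markers.tsv"))
    write_peaks(peaks, file.path(out_dir, "peaks.tsv"))
  }
  message(sprintf("[simulate] %d SNPs, %d peak measurements",
                  nrow(panel), nrow(peaks)))

  ## -- ratios ---------------------------------------------------------
  agg <- aggregate_replicates(peak_ratios(peaks))
  tg <- agg %>% filter(.data$sample_id == "transgenic")
  ref <- agg %>% filter(.data$sample_id == "nontransgenic")
  normalized <- normalize_to_nontransgenic(tg, ref) %>%
    correct_x_loss(reference_snp = reference_snp)
  ratios <- emit(normalized, "ratios.tsv")
  message(sprintf("[ratios] %d normalized SNP ratios", nrow(ratios)))

  ## -- map-transgene --------------------------------------------------
  dna <- ratios %>%
    filter(.data$template == "DNA", .data$snp_id != reference_snp) %>%
    inner_join(panel %>% select("snp_id", "pos"), by = "snp_id") %>%
    arrange(.data$pos)
  calls <- emit(call_copy_state(dna, thresholds), "copy_state_calls.tsv")
  pattern <- validate_pattern(calls)
  breakpoint <- if (pattern == "simple_truncation" &&
                    any(calls$state == "absent") &&
                    any(calls$state %in% c("single_copy", "multi_copy"))) {
    infer_breakpoint(calls)
  } else {
    NULL
  }
  if (!is.null(breakpoint)) {
    if (!is.null(out_dir)) {
      write_breakpoint_bed(breakpoint, file.path(out_dir, "breakpoint.bed"))
      emit(tidy(breakpoint), "breakpoint.tsv")
    }
    message(sprintf("[map-transgene] %s; breakpoint midpoint %s (width %s bp)",
                    pattern, format(breakpoint$midpoint, big.mark = ","),
                    format(breakpoint$width, big.mark = ",")))
  } else {
    message(sprintf("[map-transgene] %s; no breakpoint interval", pattern))
  }
  if (write_plots && !is.null(out_dir)) {
    ggplot2::ggsave(file.path(out_dir, "ratio_track.png"),
                    plot_ratio_track(calls, breakpoint),
                    width = 7, height = 4, dpi = 150)
  }

  ## -- escape ---------------------------------------------------------
  tg_snps <- panel$snp_id[panel$pos <= config$breakpoint_pos &
                            panel$panel_role == "transgene_region"]
  escape <- if (length(tg_snps) > 0L && config$copy_number > 0L) {
    emit(estimate_tg_escape(peaks, snp_ids = tg_snps), "escape.tsv")
  } else {
    NULL
  }
  if (!is.null(escape)) {
    message(sprintf("[escape] mean e = %.3f over %d SNP(s)",
                    mean(escape$e), nrow(escape)))
  }

  ## -- fish-classify --------------------------------------------------
  cells <- simulate_fish_cells(config, "inactivated_gene")
  if (!is.null(out_dir)) {
    write_cells(cells %>% select(dplyr::all_of(xci_schemas$cells)),
                file.path(out_dir, "cells.tsv"))
  }
  hyps <- list(
    expected_category_probs("distal_escape", config$skewing_p,
                            config$detection_eff, config$fp_rate),
    expected_category_probs("distal_inactivated", config$skewing_p,
                            config$detection_eff, config$fp_rate)
  )
  fish <- classify_xci_status(cells, hyps, alpha = alpha,
                              mc_seed = config$seed)
  emit(tidy(fish), "fish_classification.tsv")
  message(sprintf("[fish-classify] %d scored nuclei; best hypothesis: %s",
                  sum(cells$included), fish$best))

  ## -- spatial --------------------------------------------------------
  sim_ee <- simulate_nuclei(config, "escape_escape", "inactive")
  sim_ei <- simulate_nuclei(config, "escape_inactivated", "inactive")
  pairs <- bind_rows(sim_ee$pairs, sim_ei$pairs)
  if (!is.null(out_dir)) {
    write_geometry(bind_rows(sim_ee$geometry, sim_ei$geometry),
                   file.path(out_dir, "geometry.tsv"))
    write_coordinates(bind_rows(sim_ee$coordinates, sim_ei$coordinates),
                      file.path(out_dir, "coordinates.tsv"))
    emit(pairs, "probe_pairs.tsv")
  }
  kept <- filter_by_area(pairs, area_threshold)
  kept_ee <- kept$pairs %>% filter(.data$pair_class == "escape_escape")
  kept_ei <- kept$pairs %>% filter(.data$pair_class == "escape_inactivated")
  ks <- ks_two_sample(kept_ee$norm_distance, kept_ei$norm_distance)
  emit(tidy(ks) %>% mutate(retention = kept$retention), "spatial_ks.tsv")
  message(sprintf(
    "[spatial] area filter retained %.1f%%; KS D = %.3f, p = %.3g",
    100 * kept$retention, ks$statistic, ks$p.value))
  if (write_plots && !is.null(out_dir)) {
    ggplot2::ggsave(
      file.path(out_dir, "cumulative_frequency.png"),
      plot_cumulative_frequency(kept$pairs,
                                display_fraction = display_fraction),
      width = 6, height = 4, dpi = 150
    )
  }

  invisible(list(
    config = config, panel = panel, peaks = peaks, ratios = ratios,
    calls = calls, pattern = pattern, breakpoint = breakpoint,
    escape = escape, cells = cells, fish = fish, pairs = pairs,
    area_retention = kept$retention, ks = ks
  ))
}
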