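test_that("SNP panels are ordered, informative and deterministic", {
  p <- simulate_snp_panel(1, 1000, 2, seed = 5, reference_snp_id = NULL)
  expect_equal(nrow(p), 2L)
  expect_true(all(p$pos >= 1 & p$pos <= 1000))
  expect_true(all(diff(p$pos) > 0))
  expect_true(all(p$allele_129 != p$allele_cast))

  # a full-size panel across the endogenous escapee locus
  big <- simulate_snp_panel(148557326, 148807402, 18, seed = 2,
                            reference_snp_id = NULL)
  expect_equal(nrow(big), 18L)
  expect_true(all(diff(big$pos) > 0))
  expect_true(all(big$pos >= 148557326 & big$pos <= 148807402))

  expect_identical(simulate_snp_panel(1, 1000, 5, seed = 9),
                   simulate_snp_panel(1, 1000, 5, seed = 9))

  expect_error(simulate_snp_panel(10, 10, 2, seed = 1),
               class = "xciescape_config_error")
  expect_error(simulate_snp_panel(1, 4, 10, seed = 1),
               class = "xciescape_config_error")
})

test_that("noise-free peak tables reproduce allele-mass ratios exactly", {
  cfg <- noisefree_config()
  panel <- small_panel()
  peaks <- simulate_peak_table(panel, cfg)
  r <- aggregate_replicates(peak_ratios(peaks))

  dna <- dplyr::filter(r, sample_id == "transgenic", template == "DNA")
  inside <- panel$snp_id[panel$pos <= cfg$breakpoint_pos &
                           panel$panel_role == "transgene_region"]
  outside <- setdiff(panel$snp_id, inside)
  expect_true(length(inside) > 0 && length(outside) > 0)
  expect_equal(dna$ratio[dna$snp_id %in% inside],
               rep(2, length(inside)))
  expect_equal(dna$ratio[dna$snp_id %in% outside],
               rep(1, length(outside)))

  # no transgene: ratio exactly 1 everywhere
  cfg0 <- noisefree_config(copy_number = 0L)
  r0 <- aggregate_replicates(peak_ratios(simulate_peak_table(panel, cfg0)))
  expect_equal(dplyr::filter(r0, sample_id == "transgenic",
                             template == "DNA")$ratio,
               rep(1, nrow(panel)))
})

test_that("multi-copy, dye-bias and X-loss effects enter the DNA masses", {
  panel <- small_panel()
  cfg2 <- noisefree_config(copy_number = 2L, dye_bias = 1.2,
                           x_loss_frac = 0.1)
  r <- aggregate_replicates(peak_ratios(simulate_peak_table(panel, cfg2)))
  dna_tg <- dplyr::filter(r, sample_id == "transgenic", template == "DNA")
  inside <- panel$snp_id[panel$pos <= cfg2$breakpoint_pos &
                           panel$panel_role == "transgene_region"]
  # raw ratio = (1 + c) * dye / (1 - x_loss)
  expect_equal(dna_tg$ratio[dna_tg$snp_id %in% inside],
               rep(3 * 1.2 / 0.9, length(inside)))
  # non-transgenic reference carries the dye bias only
  dna_ref <- dplyr::filter(r, sample_id == "nontransgenic",
                           template == "DNA")
  expect_equal(dna_ref$ratio, rep(1.2, nrow(panel)))
})

test_that("lognormal peak noise is unbiased to ~1% at CV 0.05", {
  panel <- simulate_snp_panel(1, 100, 2, seed = 3, reference_snp_id = NULL)
  cfg <- sim_config(seed = 1, noise_cv = 0.05, dye_bias = 1,
                    x_loss_frac = 0, copy_number = 1L, breakpoint_pos = 200,
                    n_replicates = 1000L)
  peaks <- simulate_peak_table(panel, cfg)
  ratios <- peak_ratios(peaks) |>
    dplyr::filter(sample_id == "transgenic", template == "DNA")
  expect_equal(mean(ratios$ratio), 2, tolerance = 0.01)
  # determinism: identical config gives byte-identical tables
  expect_identical(peaks, simulate_peak_table(panel, cfg))
})

test_that("FISH cell generation follows skewing and detection efficiency", {
  # large-n frequency of inactive-X foci converges to skewing_p * detection
  cfg <- sim_config(seed = 21, skewing_p = 0.25, detection_eff = 1,
                    n_cells = 4000L)
  cells <- simulate_fish_cells(cfg, "inactivated_gene")
  frac <- mean(cells$category[cells$included] == "xi_expression")
  expect_equal(frac, 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / 4000) / 0.25)

  # thinned detection: frequency tracks p * delta
  cfg8 <- sim_config(seed = 22, skewing_p = 0.25, detection_eff = 0.8,
                     n_cells = 4000L)
  cells8 <- simulate_fish_cells(cfg8, "inactivated_gene")
  frac8 <- mean(cells8$category[cells8$included] == "xi_expression")
  expect_equal(frac8, 0.2, tolerance = 0.15)

  # detection_eff = 0: no inactive-X focus anywhere
  cfg0 <- sim_config(seed = 23, detection_eff = 0, n_cells = 200L)
  cells0 <- simulate_fish_cells(cfg0, "inactivated_gene")
  expect_false(any(cells0$category == "xi_expression", na.rm = TRUE))

  # reproducible and inside the binomial 99% envelope at n = 100
  cfg100 <- sim_config(seed = 31, skewing_p = 0.25, n_cells = 100L)
  a <- simulate_fish_cells(cfg100, "inactivated_gene")
  b <- simulate_fish_cells(cfg100, "inactivated_gene")
  expect_identical(a, b)
  k <- sum(a$category[a$included] == "xi_expression")
  env <- stats::qbinom(c(0.005, 0.995), 100, 0.25)
  expect_gte(k, env[1]); expect_lte(k, env[2])

  expect_error(simulate_fish_cells(cfg100, "no_such_assay"))
})

test_that("escape-gene assay produces the three-category scheme", {
  cfg <- sim_config(seed = 41, skewing_p = 0.25, detection_eff = 0.8,
                    n_cells = 2000L)
  cells <- simulate_fish_cells(cfg, "escape_gene")
  tab <- prop.table(table(factor(cells$category[cells$included],
                                 levels = fish_categories("escape_gene"))))
  expect_equal(unname(tab["xi_two_foci"]), 0.25 * 0.8, tolerance = 0.15)
  expect_equal(unname(tab["xa_tg_expressed"]), 0.75, tolerance = 0.05)
  expect_equal(unname(tab["tg_silenced"]), 0.25 * 0.2, tolerance = 0.3)
  # under the inactivated hypothesis the two-Xi-foci pattern disappears
  silent <- simulate_fish_cells(cfg, "escape_gene",
                                hypothesis = "transgene_inactivated")
  expect_false(any(silent$category == "xi_two_foci", na.rm = TRUE))
})

test_that("nucleus simulation honours the configured distance model", {
  # degenerate distribution: every measured pair distance equals the mean
  cfg <- sim_config(seed = 5, n_cells = 40L, dist_params = list(
    escape_escape = list(active = 1, inactive = 0.32, shape = Inf),
    escape_inactivated = list(active = 1, inactive = 0.9, shape = 4)
  ))
  sim <- simulate_nuclei(cfg, "escape_escape", "inactive")
  expect_equal(sim$pairs$distance, rep(0.32, 40), tolerance = 1e-12)

  # law of large numbers: empirical means within 2% at n = 10,000
  cfg_big <- sim_config(seed = 6, n_cells = 10000L)
  for (cls in c("escape_escape", "escape_inactivated")) {
    sim_b <- simulate_nuclei(cfg_big, cls, "inactive")
    expect_equal(mean(sim_b$pairs$distance),
                 cfg_big$dist_params[[cls]]$inactive, tolerance = 0.02)
    geom_mean <- mean(nuclear_areas(sim_b$geometry)$mean_area)
    area_expected <- exp(cfg_big$area_params$meanlog +
                           cfg_big$area_params$sdlog^2 / 2)
    expect_equal(geom_mean, area_expected, tolerance = 0.02)
  }

  # measured distance reproduces the generated separation by construction
  expect_equal(sim$pairs$norm_distance,
               sim$pairs$distance / sim$pairs$mean_area)
})
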