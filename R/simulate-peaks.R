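#' Simulate a primer-extension peak-height table
#'
#' Forward model of the quantitative primer-extension (qSNaPshot) assay on a
#' hybrid diploid carrying a truncated BAC transgene on the 129 haplotype.
#' For each SNP the expected DNA allele masses are CAST = 1 and
#' 129-haplotype = 1 + c for SNPs at or before the truncation breakpoint
#' (c = `copy_number`), 1 beyond it. RNA masses follow the expression model
#' of a clonal line carrying the transgene on the inactive CAST X: the
#' endogenous 129 allele is fully active (mass 1), the endogenous CAST
#' allele expresses at `escape_e`, and each transgene copy expresses at
#' `tg_escape_e`. A cell fraction `x_loss_frac` that has lost the CAST X
#' scales the CAST mass by `1 - x_loss_frac` in the clonal line. Peak
#' heights are mass times `dye_bias` (129 allele only) times multiplicative
#' lognormal noise with coefficient of variation `noise_cv` (unit mean).
#'
#' Two samples are emitted per template: the transgenic clonal line
#' (`"transgenic"`) and the non-transgenic parental ES line
#' (`"nontransgenic"`, no transgene, no X loss, biallelic RNA), which
#' downstream normalization uses to cancel dye bias.
#'
#' @param panel SNP panel tibble from [simulate_snp_panel()].
#' @param config A [sim_config()] object.
#' @return A tibble with columns `snp_id`, `sample_id`, `template`
#'   (`"DNA"`/`"RNA"`), `replicate`, `height_129`, `height_cast`.
#' @examples
#' panel <- simulate_snp_panel(1e6, 2e6, 6, seed = 1)
#' cfg <- sim_config(seed = 1, noise_cv = 0, breakpoint_pos = 1.5e6)
#' simulate_peak_table(panel, cfg)
#' @export
simulate_peak_table <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(panel, c("snp_id", "pos", "panel_role"), "SNP panel")

  in_tg <- panel$pos <= config$breakpoint_pos &
    panel$panel_role == "transgene_region"
  c_n <- config$copy_number
  keep_cast <- 1 - config$x_loss_frac

  masses <- bind_rows(
    tibble(snp_id = panel$snp_id, sample_id = "transgenic", template = "DNA",
           mass_129 = 1 + c_n * in_tg, mass_cast = keep_cast),
    tibble(snp_id = panel$snp_id, sample_id = "transgenic", template = "RNA",
           mass_129 = 1 + c_n * config$tg_escape_e * in_tg,
           mass_cast = config$escape_e * keep_cast),
    tibble(snp_id = panel$snp_id, sample_id = "nontransgenic", template = "DNA",
           mass_129 = 1, mass_cast = 1),
    tibble(snp_id = panel$snp_id, sample_id = "nontransgenic", template = "RNA",
           mass_129 = 1, mass_cast = 1)
  )

  out <- tidyr::expand_grid(masses, replicate = seq_len(config$n_replicates))

  set.seed(derive_seed(config$seed, 1L))
  n <- nrow(out)
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log1p(config$noise_cv^2))
    noise_129 <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    noise_cast <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise_129 <- noise_cast <- rep(1, n)
  }

  out %>%
    mutate(
      height_129 = .data$mass_129 * config$dye_bias * noise_129,
      height_cast = .data$mass_cast * noise_cast
    ) %>%
    select("snp_id", "sample_id", "template", "replicate",
           "height_129", "height_cast")
}
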