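#' Inactive-X escape level by direct allelic comparison
#'
#' When the active-X and inactive-X alleles are distinguishable, the escape
#' level e is simply the inactive/active allelic expression ratio divided by
#' the matching DNA ratio (to correct allelic dosage). In a clonal line with
#' the CAST X inactive, the measured (129+BAC)/CAST ratios are
#' active/inactive, so they are inverted first.
#'
#' @param rna,dna Aggregated allele-ratio tibbles for the same SNP(s) and
#'   sample (templates `"RNA"` and `"DNA"`).
#' @param inactive_allele Which allele sits on the inactive X: `"cast"`
#'   (invert the 129/CAST ratios) or `"129"` (use them as-is).
#' @param gene Gene label recorded on the estimate.
#' @param floor Detection floor passed to [apply_detection_floor()]; `NULL`
#'   skips censoring.
#' @return An escape-estimate tibble (see [apply_detection_floor()] for the
#'   censoring fields): columns `gene`, `snp_id`, `sample_id`, `e`,
#'   `e_bounded`, `method`, `censored`, `inconsistent`.
#' @examples
#' rna <- tibble::tibble(snp_id = "s", sample_id = "clone", template = "RNA",
#'                       ratio = 1 / 0.30, sd = 0, n_replicates = 3)
#' dna <- tibble::tibble(snp_id = "s", sample_id = "clone", template = "DNA",
#'                       ratio = 1, sd = 0, n_replicates = 3)
#' direct_escape_fraction(rna, dna)$e  # 0.30
#' @export
direct_escape_fraction <- function(rna, dna, inactive_allele = c("cast", "129"),
                                   gene = NA_character_, floor = 0.01) {
  inactive_allele <- match.arg(inactive_allele)
  ex <- expression_ratio(rna, dna)
  # expression_ratio is (RNA 129/CAST)/(DNA 129/CAST); with the CAST allele
  # inactive this is active/inactive and must be inverted to give e
  e <- if (inactive_allele == "cast") 1 / ex$expression_ratio
       else ex$expression_ratio
  est <- tibble(
    gene = gene,
    snp_id = ex$snp_id,
    sample_id = ex$sample_id,
    e = e,
    e_bounded = pmin(pmax(e, 0), 1),
    method = "direct",
    censored = FALSE,
    inconsistent = e > 1
  )
  if (!is.null(floor)) est <- apply_detection_floor(est, floor) else est
}

#' Shared-allele deconvolution of transgene escape level
#'
#' When the transgene allele is indistinguishable from the endogenous
#' active-X allele (both domestic-strain), the inactive-X escape level
#' cannot be read off directly. Under the assumption that both inactive-X
#' copies -- the endogenous CAST allele and the transgene -- escape at the
#' same fraction e of active-X expression, the DNA-normalized DOM/CAST
#' expression ratio R of a single-copy line satisfies
#' \deqn{R = \frac{(1 + e)/e}{2} = \frac{1 + e}{2e},}
#' since RNA masses are 1 (active 129) + e (inactive transgene) over e
#' (inactive CAST), and DNA dosage is 2:1. Inverting gives the closed form
#' \deqn{e = \frac{1}{2R - 1},}
#' strictly decreasing in R on (1/2, Inf). R at or below 1/2 is inconsistent
#' with the model (it would imply infinite or negative escape) and raises an
#' error; R below 1 implies e above 1 and is flagged (`inconsistent`), with
#' `e_bounded` clamped to 1 while `e` keeps the raw estimate so that
#' averages over replicate experiments stay unbiased.
#'
#' @param R Numeric vector of DNA-normalized DOM/CAST expression ratios
#'   (e.g. `expression_ratio()$expression_ratio` after the double DNA
#'   normalization), each > 0.5.
#' @param gene Gene label recorded on the estimate.
#' @param floor Detection floor (see [apply_detection_floor()]); `NULL`
#'   skips censoring.
#' @return Escape-estimate tibble with `method = "shared_allele_deconvolution"`.
#' @examples
#' deconvolve_shared_allele(1.9706)$e  # ~0.34
#' deconvolve_shared_allele(1)$e       # 1: full escape
#' @export
deconvolve_shared_allele <- function(R, gene = NA_character_, floor = 0.01) {
  if (any(!is.finite(R))) stop_data("R must be finite")
  if (any(R <= 0.5)) {
    stop_data(paste0("R = %s is at or below 0.5: inconsistent with the ",
                     "shared-allele model (implied e undefined or negative)"),
              paste(signif(R[R <= 0.5], 4), collapse = ", "))
  }
  e <- 1 / (2 * R - 1)
  est <- tibble(
    gene = gene,
    snp_id = NA_character_,
    sample_id = NA_character_,
    e = e,
    e_bounded = pmin(e, 1),
    method = "shared_allele_deconvolution",
    censored = FALSE,
    inconsistent = e > 1
  )
  if (!is.null(floor)) apply_detection_floor(est, floor) else est
}

#' Censor escape estimates at the assay detection floor
#'
#' Allelic expression at or below roughly 1% of the active-X level is
#' indistinguishable from background in the primer-extension assay, so
#' estimates at or below the floor are reported as upper bounds ("at or
#' below the floor") rather than point values. The boundary is inclusive.
#'
#' @param estimates Escape-estimate tibble with an `e` column.
#' @param floor Detection floor as a fraction of active-X expression, in
#'   (0, 1); default 0.01.
#' @return The input with `censored` set where `e <= floor`, and
#'   `e_bounded` raised to the floor for censored rows (the reportable
#'   upper bound).
#' @examples
#' est <- deconvolve_shared_allele(c(1.9706, 60), floor = NULL)
#' apply_detection_floor(est)[, c("e", "e_bounded", "censored")]
#' @export
apply_detection_floor <- function(estimates, floor = 0.01) {
  check_number(floor, "floor", min = .Machine$double.xmin, max = 1 - 1e-12)
  check_columns(estimates, "e", "escape-estimate table")
  eb <- if ("e_bounded" %in% names(estimates)) estimates$e_bounded
        else pmin(pmax(estimates$e, 0), 1)
  estimates %>%
    mutate(
      censored = .data$e <= floor,
      e_bounded = ifelse(.data$censored, floor, eb)
    )
}

#' Full transgene escape estimation from a peak table
#'
#' Convenience chain implementing the double DNA normalization used for a
#' transgenic clonal line whose transgene allele is shared with the active
#' X: the clonal-line RNA ratio is divided by non-transgenic-line DNA (to
#' cancel dye incorporation differences) and then by the clonal-line
#' DNA/non-transgenic DNA ratio (to cancel copy number and any partial X
#' loss), giving R; [deconvolve_shared_allele()] then returns e.
#'
#' @param peaks Peak table containing samples `"transgenic"` and
#'   `"nontransgenic"` with both templates (the layout produced by
#'   [simulate_peak_table()]).
#' @param snp_ids SNPs (inside the transgene) to estimate from; defaults to
#'   all SNPs present in all four (sample, template) combinations.
#' @param gene,floor Passed through to [deconvolve_shared_allele()].
#' @return Escape-estimate tibble, one row per SNP, with the intermediate
#'   `R` recorded.
#' @export
estimate_tg_escape <- function(peaks, snp_ids = NULL, gene = NA_character_,
                               floor = 0.01) {
  agg <- aggregate_replicates(peak_ratios(peaks))
  pick <- function(sample, template) {
    agg %>% filter(.data$sample_id == .env$sample,
                   .data$template == .env$template)
  }
  rna_tg <- pick("transgenic", "RNA")
  dna_tg <- pick("transgenic", "DNA")
  dna_ref <- pick("nontransgenic", "DNA")
  if (nrow(rna_tg) == 0L || nrow(dna_tg) == 0L || nrow(dna_ref) == 0L) {
    stop_data(paste0("peak table must contain 'transgenic' RNA and DNA and ",
                     "'nontransgenic' DNA measurements"))
  }
  if (!is.null(snp_ids)) {
    rna_tg <- rna_tg %>% filter(.data$snp_id %in% snp_ids)
  }

  # two sequential divisions by the non-transgenic DNA reference
  r1 <- normalize_to_nontransgenic(rna_tg, dna_ref, by = "snp_id")  # dye
  dna_norm <- normalize_to_nontransgenic(dna_tg, dna_ref)  # dosage + X loss
  joined <- inner_join(
    r1 %>% select("snp_id", rna_norm = "ratio"),
    dna_norm %>% select("snp_id", dna_norm = "ratio"),
    by = "snp_id"
  )
  R <- joined$rna_norm / joined$dna_norm
  est <- deconvolve_shared_allele(R, gene = gene, floor = floor)
  est$snp_id <- joined$snp_id
  est$R <- R
  est
}
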