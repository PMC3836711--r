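#' Raw (129+BAC)/CAST allele ratio from peak heights
#'
#' The fundamental dosage read-out of the primer-extension assay: the
#' 129-allele peak height (which pools the endogenous 129 allele and any BAC
#' transgene copies, since both derive from domestic strains) divided by the
#' CAST-allele peak height. A ratio of 1 means no transgene; 2 means one
#' additional copy. The ratio is scale-invariant in the raw fluorescence
#' units.
#'
#' @param height_129,height_cast Non-negative peak heights (vectorized).
#' @return Numeric ratio(s).
#' @examples
#' raw_ratio(200, 100)
#' @export
raw_ratio <- function(height_129, height_cast) {
  if (any(!is.finite(height_129)) || any(!is.finite(height_cast)) ||
      any(height_129 < 0) || any(height_cast < 0)) {
    stop_data("peak heights must be finite and non-negative")
  }
  if (any(height_cast == 0)) {
    stop_data(paste0("CAST peak height of zero at %d measurement(s): ",
                     "allele dropout, ratio undefined"),
              sum(height_cast == 0))
  }
  height_129 / height_cast
}

#' Add per-measurement allele ratios to a peak table
#'
#' @param peaks Tibble with columns `snp_id`, `sample_id`, `template`,
#'   `replicate`, `height_129`, `height_cast`.
#' @return The input with a `ratio` column appended.
#' @export
peak_ratios <- function(peaks) {
  check_columns(peaks, c("snp_id", "sample_id", "template", "replicate",
                         "height_129", "height_cast"), "peak table")
  peaks %>% mutate(ratio = raw_ratio(.data$height_129, .data$height_cast))
}

#' Aggregate technical replicates into per-SNP allele ratios
#'
#' Averages replicate-level ratios (not heights) per SNP, sample, and
#' template, reporting the sample standard deviation over technical
#' replicates (0 when a single replicate is available).
#'
#' @param ratios Tibble with `snp_id`, `sample_id`, `template`, `ratio`
#'   (one row per replicate), e.g. from [peak_ratios()].
#' @return Tibble with one row per (`snp_id`, `sample_id`, `template`):
#'   `ratio` (mean), `sd`, `n_replicates`.
#' @examples
#' tb <- tibble::tibble(snp_id = "s", sample_id = "a", template = "DNA",
#'                      replicate = 1:3, ratio = c(1.9, 2.0, 2.1))
#' aggregate_replicates(tb)
#' @export
aggregate_replicates <- function(ratios) {
  check_columns(ratios, c("snp_id", "sample_id", "template", "ratio"),
                "replicate ratio table")
  if (nrow(ratios) == 0L) stop_data("no replicate measurements to aggregate")
  ratios %>%
    group_by(.data$snp_id, .data$sample_id, .data$template) %>%
    summarise(
      sd = dplyr::coalesce(stats::sd(.data$ratio), 0),  # single replicate: 0
      n_replicates = dplyr::n(),
      ratio = mean(.data$ratio),
      .groups = "drop"
    ) %>%
    select("snp_id", "sample_id", "template", "ratio", "sd", "n_replicates")
}

#' Normalize allele ratios against a non-transgenic line
#'
#' Dividing each SNP's ratio in the transgenic line by the same SNP's ratio
#' in the non-transgenic parental line cancels SNP-specific dye-incorporation
#' and PCR biases, which affect both lines identically.
#'
#' @param sample_ratios,reference_ratios Aggregated ratio tibbles (see
#'   [aggregate_replicates()]); matched by `snp_id` and `template`.
#' @param by Join key; drop `"template"` to normalize RNA ratios against a
#'   DNA reference (dye bias is template-independent).
#' @return `sample_ratios` with `ratio` replaced by the normalized value,
#'   `sd` rescaled accordingly, and a `reference_ratio` column recording the
#'   divisor.
#' @examples
#' s <- tibble::tibble(snp_id = "s", sample_id = "tg", template = "DNA",
#'                     ratio = 2.4, sd = 0.1, n_replicates = 3)
#' r <- tibble::tibble(snp_id = "s", sample_id = "ref", template = "DNA",
#'                     ratio = 1.2, sd = 0.05, n_replicates = 3)
#' normalize_to_nontransgenic(s, r)$ratio  # 2.0
#' @export
normalize_to_nontransgenic <- function(sample_ratios, reference_ratios,
                                       by = c("snp_id", "template")) {
  check_columns(sample_ratios, c(by, "ratio"), "sample ratio table")
  check_columns(reference_ratios, c(by, "ratio"), "reference ratio table")
  ref <- reference_ratios %>%
    select(dplyr::all_of(by), reference_ratio = "ratio")
  joined <- inner_join(sample_ratios, ref, by = by)
  if (nrow(joined) < nrow(sample_ratios)) {
    missing <- setdiff(sample_ratios$snp_id, reference_ratios$snp_id)
    stop_data("no reference ratio for SNP(s): %s",
              paste(unique(missing), collapse = ", "))
  }
  if (any(joined$reference_ratio <= 0)) {
    stop_data("reference ratios must be positive")
  }
  joined %>%
    mutate(
      ratio = .data$ratio / .data$reference_ratio,
      sd = if ("sd" %in% names(joined)) .data$sd / .data$reference_ratio else NULL
    )
}

#' Correct allele ratios for partial X loss in a clonal line
#'
#' A non-transgenic control SNP in the same line should show a normalized
#' ratio of exactly 1.0; observed deviations are attributed to a change in
#' CAST-X dosage shared by every SNP in the line (loss of an X in a cell
#' subpopulation). The correction divides each ratio by the control SNP's
#' deviation factor.
#'
#' @param ratios Normalized ratio tibble containing the reference SNP.
#' @param reference_snp `snp_id` of the non-transgenic control SNP.
#' @param template Template whose reference deviation is used (`"DNA"`).
#' @return `ratios` with each `ratio` (and `sd`) divided by the per-sample
#'   reference deviation, plus an `x_loss_factor` column.
#' @examples
#' tb <- tibble::tibble(
#'   snp_id = c("s1", "ref"), sample_id = "tg", template = "DNA",
#'   ratio = c(2.2, 1.1), sd = 0, n_replicates = 3
#' )
#' correct_x_loss(tb, "ref")$ratio  # 2.0 at s1
#' @export
correct_x_loss <- function(ratios, reference_snp, template = "DNA") {
  check_columns(ratios, c("snp_id", "sample_id", "template", "ratio"),
                "ratio table")
  ref <- ratios %>%
    filter(.data$snp_id == .env$reference_snp,
           .data$template == .env$template)
  if (nrow(ref) == 0L) {
    stop_data("reference SNP '%s' (%s) not found in ratio table",
              reference_snp, template)
  }
  if (any(ref$ratio <= 0)) {
    stop_data("reference SNP deviation factor must be positive")
  }
  factors <- ref %>% select("sample_id", x_loss_factor = "ratio")
  out <- inner_join(ratios, factors, by = "sample_id")
  if (nrow(out) < nrow(ratios)) {
    stop_data("some samples lack a reference SNP measurement")
  }
  out %>%
    mutate(
      ratio = .data$ratio / .data$x_loss_factor,
      sd = if ("sd" %in% names(out)) .data$sd / .data$x_loss_factor else NULL
    )
}

#' DNA-normalized allelic expression ratio
#'
#' Divides an RNA allele ratio by the matching DNA allele ratio so that
#' allelic expression is expressed relative to allelic dosage: a value of 1
#' means expression mirrors copy number, values below 1 mean the
#' 129-haplotype alleles are under-expressed relative to their dosage.
#'
#' @param rna,dna Aggregated ratio tibbles for the same SNPs and sample,
#'   with `template` `"RNA"` and `"DNA"` respectively.
#' @return Tibble with `snp_id`, `sample_id`, `expression_ratio`, plus the
#'   contributing `rna_ratio` and `dna_ratio`.
#' @examples
#' rna <- tibble::tibble(snp_id = "s", sample_id = "a", template = "RNA",
#'                       ratio = 2, sd = 0, n_replicates = 3)
#' dna <- tibble::tibble(snp_id = "s", sample_id = "a", template = "DNA",
#'                       ratio = 2, sd = 0, n_replicates = 3)
#' expression_ratio(rna, dna)$expression_ratio  # 1
#' @export
expression_ratio <- function(rna, dna) {
  check_columns(rna, c("snp_id", "sample_id", "template", "ratio"),
                "RNA ratio table")
  check_columns(dna, c("snp_id", "sample_id", "template", "ratio"),
                "DNA ratio table")
  if (any(rna$template != "RNA")) {
    stop_data("`rna` must contain RNA-template rows only")
  }
  if (any(dna$template != "DNA")) {
    stop_data("`dna` must contain DNA-template rows only")
  }
  if (any(dna$ratio <= 0)) stop_data("DNA ratios must be positive")
  joined <- inner_join(
    rna %>% select("snp_id", "sample_id", rna_ratio = "ratio"),
    dna %>% select("snp_id", "sample_id", dna_ratio = "ratio"),
    by = c("snp_id", "sample_id")
  )
  if (nrow(joined) == 0L) {
    stop_data("RNA and DNA tables share no (snp_id, sample_id) pairs")
  }
  joined %>%
    mutate(expression_ratio = .data$rna_ratio / .data$dna_ratio)
}

#' Flag degenerate allele ratios
#'
#' Ratios of exactly zero (129 dropout) or non-finite value are flagged
#' rather than dropped, so downstream steps can decide how to treat them.
#'
#' @param ratios Tibble with a `ratio` column.
#' @return The input with a logical `degenerate` column.
#' @export
flag_degenerate_ratios <- function(ratios) {
  check_columns(ratios, "ratio", "ratio table")
  ratios %>%
    mutate(degenerate = !is.finite(.data$ratio) | .data$ratio == 0)
}
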