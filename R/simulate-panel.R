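#' Simulate an ordered SNP marker panel
#'
#' Draws `n_snps` distinct 1-based positions uniformly inside a genomic
#' region and assigns each marker a pair of distinguishable strain alleles
#' (129 vs CAST). Stands in for the informative-SNP discovery step that, on
#' real data, comes from a strain SNP database.
#'
#' @param region_start,region_end 1-based inclusive bounds of the region (bp).
#' @param n_snps Number of markers (>= 2).
#' @param seed Integer seed; the same seed reproduces the same panel.
#' @param chrom Chromosome name recorded on every marker.
#' @param reference_snp_id Optional id for one extra marker appended outside
#'   the panel's region role: a non-transgenic reference SNP (role
#'   `"reference"`) used for X-loss correction. `NULL` omits it.
#'
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `allele_129`,
#'   `allele_cast`, `panel_role`, sorted by strictly increasing `pos`.
#' @examples
#' simulate_snp_panel(148557326, 148807402, n_snps = 18, seed = 1)
#' @export
simulate_snp_panel <- function(region_start, region_end, n_snps, seed = 1L,
                               chrom = "chrX", reference_snp_id = "ref_snp") {
  check_number(region_start, "region_start", min = 1)
  check_number(region_end, "region_end", min = 1)
  if (region_end <= region_start) {
    stop_config("`region_end` (%s) must exceed `region_start` (%s)",
                region_end, region_start)
  }
  check_number(n_snps, "n_snps", min = 2)
  width <- region_end - region_start + 1
  if (n_snps > width) {
    stop_config("cannot place %d distinct SNPs in a %d bp region", n_snps, width)
  }

  set.seed(derive_seed(seed))
  pos <- sort(sample.int(width, size = n_snps)) + region_start - 1
  bases <- c("A", "C", "G", "T")
  allele_129 <- sample(bases, n_snps, replace = TRUE)
  # CAST allele drawn from the three remaining bases so the pair is informative
  allele_cast <- vapply(allele_129,
                        function(b) sample(setdiff(bases, b), 1L), character(1))

  panel <- tibble(
    snp_id = sprintf("snp%02d", seq_len(n_snps)),
    chrom = chrom,
    pos = as.numeric(pos),
    allele_129 = allele_129,
    allele_cast = unname(allele_cast),
    panel_role = "transgene_region"
  )
  if (!is.null(reference_snp_id)) {
    ref <- tibble(
      snp_id = reference_snp_id, chrom = chrom,
      pos = region_end + 1e6,
      allele_129 = "A", allele_cast = "G",
      panel_role = "reference"
    )
    panel <- bind_rows(panel, ref)
  }
  panel
}
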