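# Shared fixtures: small, fast configurations used across test files.

quiet <- function(expr) suppressMessages(expr)

# noise-free single-copy configuration with a breakpoint mid-region;
# dots override the noise-free defaults
noisefree_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, noise_cv = 0, dye_bias = 1, x_loss_frac = 0,
         copy_number = 1L, breakpoint_pos = 1500),
    list(...)
  )
  do.call(sim_config, args)
}

small_panel <- function(seed = 1L, n_snps = 6, ...) {
  simulate_snp_panel(1, 3000, n_snps = n_snps, seed = seed, ...)
}

# one aggregated-ratio row, as produced by aggregate_replicates()
ratio_row <- function(snp_id = "s", sample_id = "a", template = "DNA",
                      ratio = 1, sd = 0, n_replicates = 3L) {
  tibble::tibble(snp_id = snp_id, sample_id = sample_id, template = template,
                 ratio = ratio, sd = sd, n_replicates = n_replicates)
}

# normalized + X-loss-corrected DNA dosage ratios for a transgenic line,
# the standard front half of the mapping pipeline
dna_dosage_ratios <- function(peaks, reference_snp = "ref_snp") {
  agg <- aggregate_replicates(peak_ratios(peaks))
  tg <- dplyr::filter(agg, sample_id == "transgenic")
  ref <- dplyr::filter(agg, sample_id == "nontransgenic")
  normalize_to_nontransgenic(tg, ref) |>
    correct_x_loss(reference_snp = reference_snp) |>
    dplyr::filter(template == "DNA")
}

# brute-force contiguity oracle: a pattern is a simple truncation iff some
# prefix split puts all present calls before all absent calls
brute_force_pattern <- function(states) {
  s <- states[states != "ambiguous"]
  present <- s %in% c("single_copy", "multi_copy")
  n <- length(present)
  for (k in 0:n) {
    prefix_ok <- k == 0 || all(present[seq_len(k)])
    suffix_ok <- k == n || all(!present[seq.int(k + 1L, n)])
    if (prefix_ok && suffix_ok) return("simple_truncation")
  }
  "complex_rearrangement"
}

# brute-force KS statistic: max ECDF gap over every pooled evaluation point
brute_force_ks_d <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(q) abs(mean(x <= q) - mean(y <= q)), numeric(1)))
}
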