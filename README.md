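# xciescape

Quantitative analysis of X-chromosome inactivation (XCI) escape and
X-linked BAC transgene content in hybrid (129 × CAST) female mouse cells,
with a fully parameterized forward simulator so every stage runs and is
tested on synthetic data.

Most X-linked genes are silenced on one X in female cells, but some
*escape* XCI and stay expressed from the inactive X (Xi), often at a
fraction of the active-X (Xa) level. Dissecting the boundary between an
escape domain and its silenced neighbours uses a set of allele-specific
measurements that this package implements end to end:

* **Dosage ratios** — quantitative primer-extension peak heights at strain
  SNPs give a `(129+BAC)/CAST` allele ratio: 1 where no transgene covers
  the SNP, 2 under a single-copy transgene on the 129 haplotype
  (`raw_ratio()`, `aggregate_replicates()`,
  `normalize_to_nontransgenic()`, `correct_x_loss()`).
* **Breakpoint mapping** — ordered copy-state calls
  (`call_copy_state()`) localize a transgene truncation to the interval
  between the last present and first absent SNP, with midpoint summary and
  BED export (`infer_breakpoint()`, `validate_pattern()`,
  `write_breakpoint_bed()`).
* **Escape levels** — Xi expression as a fraction *e* of Xa expression,
  either directly from distinguishable alleles
  (`direct_escape_fraction()`) or, when the transgene allele is
  indistinguishable from the active 129 allele, by shared-allele
  deconvolution under the equal-escape assumption

  R = (1 + e) / (2e)  ⇒  e = 1 / (2R − 1),

  where R is the DNA-normalized DOM/CAST expression ratio
  (`deconvolve_shared_allele()`, `estimate_tg_escape()`), with a ~1%
  detection floor (`apply_detection_floor()`).
* **RNA FISH expectations** — XCI skewing (the transgenic CAST X is
  inactive in ~25% of cells) converts competing XCI hypotheses into
  expected scoring-category proportions; observed nucleus counts are
  classified by chi-square goodness of fit
  (`expected_category_probs()`, `chi_square_gof()`,
  `classify_xci_status()`).
* **3D association** — inter-probe distances normalized by mean nuclear
  area, cumulative frequency curves, and two-sample Kolmogorov–Smirnov
  comparison of locus-pair classes (`probe_distances()`,
  `filter_by_area()`, `cumulative_frequency()`, `ks_two_sample()`).

Everything is tidyverse-shaped: tables in and out are tibbles, fitted
objects support `tidy()`/`glance()`, and `plot_*()`/`autoplot()` return
ggplots. `vignettes/xci-escape-methods.Rmd` derives the models and
documents every tunable parameter.

## Worked example

`run_pipeline()` simulates a transgenic line under the default study
conditions (single-copy transgene truncated inside an 18-SNP panel, 25%
skewing, escape level 0.34, 5% peak noise, triplicates) and runs every
stage:

```r
library(xciescape)
res <- run_pipeline(sim_config(seed = 11), out_dir = "xci_out")
#> [simulate] 19 SNPs, 228 peak measurements
#> [ratios] 38 normalized SNP ratios
#> [map-transgene] simple_truncation; breakpoint midpoint 148,695,561 (width 12,203 bp)
#> [escape] mean e = 0.342 over 11 SNP(s)
#> [fish-classify] 100 scored nuclei; best hypothesis: distal_escape
#> [spatial] area filter retained 94.5%; KS D = 0.396, p = 7.54e-07

tidy(res$breakpoint)
#> # A tibble: 1 × 5
#>   last_present_pos first_absent_pos  midpoint width pattern
#>              <dbl>            <dbl>     <dbl> <dbl> <chr>
#> 1        148689460        148701663 148695561 12203 simple_truncation
```

Reading the output: the dosage track drops from ratio ≈ 2 to ≈ 1 between
positions 148,689,460 and 148,701,663, so the transgene's 3′ end is placed
at the interval midpoint. The escape estimate recovers the simulated
e = 0.34 (the transgene expresses from the inactive X at 34% of the
active-X level). The FISH classifier retains the generating hypothesis
(integration-site transcripts escape when the transgenic X is inactive),
and the KS test detects that escapee–escapee probe pairs sit closer on the
inactive X than escapee–inactivated pairs. All tables, a BED interval, a
JSON provenance sidecar, and the two standard figures are written to
`xci_out/`.

A thin command-line wrapper with per-stage subcommands ships at
`inst/scripts/xci-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "xci-pipeline.R", package = "xciescape"))')" all --seed 3 --out xci_out
```

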