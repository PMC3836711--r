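---
title: "Models and methods behind xciescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xciescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciescape)
```

## The system being modelled

In female mammals one X chromosome is transcriptionally silenced
(X-chromosome inactivation, XCI), but a minority of genes *escape* and
remain expressed from the inactive X (Xi), often at a fraction of the
active-X (Xa) level. xciescape implements the quantitative analyses used to
study escape at an XCI boundary in hybrid (129 × CAST) female mouse ES
cells carrying an X-linked BAC transgene derived from an escapee locus:

1. **Dosage quantification** — primer-extension peak heights at strain SNPs
   give a (129+BAC)/CAST allele ratio. A SNP covered by a single-copy
   transgene on the 129 haplotype has two domestic-allele copies against one
   CAST copy, hence an expected ratio of 2; uncovered SNPs give 1.
2. **Breakpoint mapping** — a truncated transgene turns the ordered panel
   of per-SNP copy states into a present-prefix/absent-suffix pattern; the
   breakpoint is localized to the interval between the last present and
   first absent SNP.
3. **Escape quantification** — Xi expression as a fraction *e* of Xa
   expression, from allele-resolved RNA/DNA ratios, with a deconvolution
   for the case where the transgene allele is indistinguishable from the
   active 129 allele.
4. **RNA FISH expectations** — strain background skews XCI so the
   transgenic CAST X is inactive in ~25% of cells; this skewing probability
   converts competing XCI hypotheses into expected scoring-category
   proportions, compared to observed counts by chi-square.
5. **Spatial association** — 3D inter-probe distances on the Xi,
   normalized by mean nuclear cross-sectional area, summarized as
   cumulative frequency curves and compared between locus-pair classes with
   a two-sample Kolmogorov–Smirnov (KS) test.

A fully parameterized forward simulator (`sim_config()` plus the
`simulate_*()` generators) produces every input table, so the entire
pipeline is exercised and tested without sequencer or microscopy data.

## Dosage model and ratio normalization

For SNP *i* with position $x_i$, transgene copy number $c$ and truncation
coordinate $b$, the expected DNA allele masses are

$$m^{129}_i = 1 + c\,\mathbf{1}[x_i \le b], \qquad m^{CAST}_i = 1 - \ell,$$

where $\ell$ is the fraction of cells that have lost the CAST X. Peak
heights are masses scaled by a 129-specific dye factor and multiplicative
lognormal noise with unit mean and coefficient of variation `noise_cv`
(lognormal because fluorescence peak heights are strictly positive with
roughly scale-free noise). Three corrections recover the dosage ratio
exactly in the noise-free regime, in any order:

* replicate aggregation averages *ratios*, not heights, and reports the
  technical SD (`aggregate_replicates()`);
* division by the same SNP's ratio in the non-transgenic parental line
  cancels dye/PCR bias (`normalize_to_nontransgenic()`);
* division by the deviation of a non-transgenic control SNP from 1.0
  cancels the shared CAST-dosage change caused by X loss
  (`correct_x_loss()`). Attributing the whole control-SNP deviation to
  CAST-dosage change is the most parsimonious model consistent with X loss
  in a cell subpopulation; it uses a single factor per line.

## Copy-state thresholds and breakpoint convention

Noise-free expectations are 1 / 2 / 3+ for absent / single-copy /
multi-copy SNPs. Default thresholds sit at the midpoints (`t_low` 1.4,
`t_high` 2.5) with a ±0.1 guard band inside which the call is `ambiguous`
rather than forced; all three are exposed in `copy_state_thresholds()`.
Ambiguous calls never bound a breakpoint interval — they can only widen it,
a deliberately conservative localization. The reported midpoint uses an
integer floor because genomic coordinates are base pairs. A panel whose
present calls do not form a contiguous prefix is classified
`complex_rearrangement` (`validate_pattern()`) and no interval is reported.

## Shared-allele deconvolution

For a clonal line with the transgene on the inactive CAST X, the transgene
and the endogenous active-X allele are both domestic-strain and cannot be
distinguished. Assume both Xi copies (endogenous CAST allele and transgene)
escape at the same fraction $e$. With single-copy dosage (DOM:CAST = 2:1),
the DNA-normalized DOM/CAST expression ratio is

$$R = \frac{(1 + e)/e}{2} = \frac{1+e}{2e} \quad\Longrightarrow\quad
  e = \frac{1}{2R - 1}.$$

The estimator is strictly decreasing on $R \in (0.5, \infty)$; $R \le 0.5$
is inconsistent with the model and raises an error. $R < 1$ implies
$e > 1$: the row is flagged `inconsistent` and `e_bounded` is clamped to 1,
but the raw estimate is kept in `e`. Clamping the point estimate itself
would bias the mean of replicate experiments downward near full escape
(half of the sampling distribution of $\hat e$ sits above 1 when the true
$e$ is 1), so averages are taken over the raw values and the bound is a
reporting convenience.

The double DNA normalization used for the transgene locus is implemented as
two sequential divisions (`estimate_tg_escape()`): RNA by non-transgenic
DNA (dye), then by the clonal-line/non-transgenic DNA ratio (copy number
and X loss); both nuisance factors cancel exactly in the noise-free
algebra.

An escape level at or below the assay sensitivity — about 1% of active-X
expression — cannot be distinguished from zero; `apply_detection_floor()`
therefore censors estimates with $e \le$ `floor` (inclusive boundary, since
"at the floor" is already indistinguishable) and reports the floor as an
upper bound in `e_bounded`.

## FISH scoring expectations

Each nucleus independently inactivates the transgenic CAST X with the
skewing probability $p$ (default 0.25). For the escape-gene assay the three
scoring categories and their probabilities under the escape hypothesis are
$p\delta$ (two Xi foci), $1-p$ (transgene expressed from Xa) and
$p(1-\delta)$ (absent transgenic-X signal, conservatively scored as
silencing), with $\delta$ the focus detection efficiency. Under the
inactivated hypothesis the two-Xi-foci pattern can only arise from spurious
foci. Detection efficiency is applied to inactive-X foci; nascent active-X
transgene signals are scored as robust, which is what makes the
conservative "absent signal means silencing" rule well-defined. Neither
$\delta$ nor a false-positive rate has a reported value in this system, so
both are configuration parameters defaulting to 1 and 0.

Scoring criteria mirror practice: an escapee assay requires at least one Xa
and one Xi endogenous signal; an X-inactivated-gene assay requires a robust
Xa signal. Category probabilities are conditional on inclusion, and nuclei
are generated until the configured number meets criteria (default 100, the
usual minimum scored per experiment; smaller counts are supported).

`chi_square_gof()` uses the Pearson statistic with degrees of freedom equal
to non-empty categories minus one. Two validity guards: expected counts
below 5 switch to a seeded Monte-Carlo multinomial p-value (10,000 draws by
default), and a category expected to be empty but observed occupied makes
the statistic infinite — the hypothesis is contradicted outright and the
result is flagged with p = 0 rather than passed through the asymptotic
formula. `classify_xci_status()` reports the single hypothesis not rejected
at `alpha` (default 0.001), or `indeterminate` when none or several
survive, as happens at very small n.

## Spatial association

Probe separations are Euclidean 3D distances; nuclear size is the mean of
per-Z-section polygon areas. Normalized distance divides micrometres by
square micrometres — dimensionally odd but the established convention for
this normalization, and the KS comparison is rank-based, so any shared
monotone rescaling (including no normalization at all) leaves D unchanged;
`probe_distances()` carries both raw and normalized columns so either can
be analyzed. Analysis is restricted to nuclei with mean area strictly below
175 µm² (the generator's area distribution is quantile-matched so ~95% of
nuclei pass, mirroring the filter's design goal of overlapping
distributions across lines). Cumulative frequency curves can be truncated
to the closest 60–80% of observations for display (default fraction 0.7,
the middle of that range); truncation is cosmetic and statistics are always
computed on full samples.

The KS statistic is evaluated at every pooled data point, which handles
ties exactly. P-values use the asymptotic Kolmogorov series, switching to
the exact conditional distribution when the combined sample size is at most
30 and there are no ties; at the 100–150 nuclei per class typical here the
asymptotic form is appropriate.

## The generator: what it emulates and what it does not

`sim_config()` defaults encode the study conditions: skewing 0.25, partial
escape $e = 0.34$ for both the endogenous escapee and the transgene,
single-copy transgene, 5% peak-height CV, technical triplicates, 100
scored nuclei, and gamma-distributed Xi inter-probe distances with means
0.6 µm (escapee–escapee) versus 0.9 µm (escapee–inactivated), within the
range of representative measured separations (0.32–1.33 µm) and separated
by 50% so that class differences are detectable at realistic sample sizes.
Distances use a gamma with shape 4 (positive support, moderate skew; no
distributional form is reported, and an infinite shape degenerates to a
point mass for calibration checks). Nuclear areas are lognormal with the
95th percentile at 175 µm².

The generator works at the level of *scored signals and coordinates*: it
does not synthesize images, model probe hybridization efficiency
differences between loci, chromatin-scale correlation between adjacent
SNPs' noise, or biological replicate variance beyond the technical CV.
Passing tests therefore demonstrate that the estimators invert the stated
forward models under realistic noise — not that real microscopy or
sequencer artefacts are handled. Each generator seeds R's single RNG
stream once per call (deterministically derived from the configuration
seed and a per-generator offset), which gives bit-identical outputs for
equal configurations without per-nucleus stream splitting.

## Numerical and testing choices

* Ratios of exactly zero or infinity are flagged, never silently dropped.
* The lognormal noise uses `meanlog = -sdlog^2/2` so heights are unbiased;
  the ratio of two such noises carries a small convexity bias
  (< 1% at CV 0.05), which the recovery tests bound explicitly.
* Test problem sizes: parameter-recovery properties use 200–500 seeded
  simulations per claim (500 for breakpoint and deconvolution recovery,
  1,000 for FISH power/type-I, 500 for KS power at 100–150 nuclei per
  class), large enough that the asserted rates have Monte-Carlo error well
  below the margins being tested while keeping the suite fast.
* A 100-nucleus FISH experiment is a single binomial draw; its agreement
  with a published percentage is asserted distributionally across seeds
  (the fraction of runs inside the binomial 2 SD envelope), because a
  one-draw assertion fails by chance at the envelope's nominal rate even
  under the correct model.

## Limitations

* The X-loss correction assumes the entire control-SNP deviation reflects
  CAST-dosage change; mosaic loss of the 129 X would be misattributed.
* The shared-allele deconvolution is only as good as its equal-escape
  assumption; if the transgene escaped at a different level than the
  endogenous CAST allele, $e$ would be an effective average constrained by
  the measured ratio.
* Copy-state thresholds assume near-integer dosage; heavily mosaic lines
  would need line-specific thresholds.
* The chi-square classification treats nuclei as independent; field- or
  slide-level clustering is not modelled.
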