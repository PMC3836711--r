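#' Simulation configuration for the forward model
#'
#' Collects every parameter of the synthetic-data generator into a single
#' validated object. The defaults describe the hybrid (129 x CAST) female ES
#' cell system the package models: strain-driven XCI skewing puts the
#' transgenic CAST X on the inactive side in about a quarter of cells, the
#' endogenous escapee and its transgenic copy each express from the inactive
#' X at roughly a third of the active-X level, and a small cell fraction has
#' lost one X.
#'
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   bit-identical outputs from every generator.
#' @param skewing_p Probability that the transgenic (CAST) X is the inactive
#'   X in a given cell (XCI skewing).
#' @param escape_e Inactive-X expression of the endogenous escapee as a
#'   fraction of its active-X expression, in (0, 1].
#' @param tg_escape_e Same fraction for the transgenic copy.
#' @param copy_number Non-negative integer number of BAC transgene copies on
#'   the 129 haplotype.
#' @param breakpoint_pos 1-based genomic coordinate (bp) of the transgene's
#'   3' truncation; SNPs at or before this position are covered by the
#'   transgene.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   peak-height noise (>= 0; 0 switches noise off).
#' @param dye_bias Multiplicative factor applied to the 129-allele peak
#'   height, emulating dye-incorporation differences between the two
#'   extension products.
#' @param x_loss_frac Fraction of cells in the clonal line that have lost the
#'   CAST X; scales the CAST allele mass in bulk measurements.
#' @param detection_eff Probability that a true nascent-transcript focus is
#'   detected in RNA FISH.
#' @param fp_rate Probability of a spurious inactive-X focus in a cell whose
#'   inactive-X allele is silent (no value is reported for this in the
#'   source system; default 0).
#' @param n_cells Nuclei per FISH experiment that must meet scoring criteria.
#' @param n_replicates Technical replicates per peak measurement.
#' @param area_params List with `meanlog` and `sdlog` of the lognormal
#'   nuclear-area distribution (micrometres squared). The defaults place the
#'   95th percentile at 175 so that the standard area filter retains ~95% of
#'   nuclei.
#' @param dist_params Named list of per-class 3D inter-probe distance
#'   parameters. Each of `escape_escape` / `escape_inactivated` holds a list
#'   with `active` and `inactive` mean distances (micrometres) and a shared
#'   gamma `shape`. Defaults echo representative measured separations: two
#'   escapees sit closer on the inactive X (mean 0.6) than an
#'   escapee-inactivated pair (mean 0.9), while active-X distances are
#'   larger and class-independent.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, noise_cv = 0)
#' cfg$skewing_p
#' @export
sim_config <- function(seed = 1L,
                       skewing_p = 0.25,
                       escape_e = 0.34,
                       tg_escape_e = 0.34,
                       copy_number = 1L,
                       breakpoint_pos = 148700000,
                       noise_cv = 0.05,
                       dye_bias = 1,
                       x_loss_frac = 0,
                       detection_eff = 1,
                       fp_rate = 0,
                       n_cells = 100L,
                       n_replicates = 3L,
                       area_params = list(meanlog = 4.7531, sdlog = 0.25),
                       dist_params = list(
                         escape_escape = list(active = 1.2, inactive = 0.60, shape = 4),
                         escape_inactivated = list(active = 1.3, inactive = 0.90, shape = 4)
                       )) {
  check_prob(skewing_p, "skewing_p")
  check_prob(escape_e, "escape_e")
  check_prob(tg_escape_e, "tg_escape_e")
  check_prob(x_loss_frac, "x_loss_frac")
  check_prob(detection_eff, "detection_eff")
  check_prob(fp_rate, "fp_rate")
  check_number(copy_number, "copy_number", min = 0)
  if (copy_number != round(copy_number)) {
    stop_config("`copy_number` must be a non-negative integer")
  }
  check_number(breakpoint_pos, "breakpoint_pos", min = 1)
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(dye_bias, "dye_bias", min = .Machine$double.eps)
  check_number(n_cells, "n_cells", min = 1)
  check_number(n_replicates, "n_replicates", min = 1)
  check_number(area_params$meanlog, "area_params$meanlog")
  check_number(area_params$sdlog, "area_params$sdlog", min = 0)
  for (cls in c("escape_escape", "escape_inactivated")) {
    p <- dist_params[[cls]]
    if (is.null(p)) stop_config("`dist_params` must define class '%s'", cls)
    check_number(p$active, paste0("dist_params$", cls, "$active"),
                 min = .Machine$double.eps)
    check_number(p$inactive, paste0("dist_params$", cls, "$inactive"),
                 min = .Machine$double.eps)
    check_number(p$shape, paste0("dist_params$", cls, "$shape"),
                 min = .Machine$double.eps)
  }
  if (dist_params$escape_escape$inactive >=
      dist_params$escape_inactivated$inactive) {
    stop_config(paste0(
      "inactive-X mean distance for escape_escape must be below the ",
      "escape_inactivated mean (the escape-association signal)"))
  }

  structure(
    list(
      seed = as.integer(seed),
      skewing_p = skewing_p,
      escape_e = escape_e,
      tg_escape_e = tg_escape_e,
      copy_number = as.integer(copy_number),
      breakpoint_pos = as.numeric(breakpoint_pos),
      noise_cv = noise_cv,
      dye_bias = dye_bias,
      x_loss_frac = x_loss_frac,
      detection_eff = detection_eff,
      fp_rate = fp_rate,
      n_cells = as.integer(n_cells),
      n_replicates = as.integer(n_replicates),
      area_params = area_params,
      dist_params = dist_params
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | skewing_p %.3g | escape_e %.3g | tg_escape_e %.3g\n",
              x$seed, x$skewing_p, x$escape_e, x$tg_escape_e))
  cat(sprintf("  copy_number %d | breakpoint_pos %s | noise_cv %.3g | dye_bias %.3g\n",
              x$copy_number, format(x$breakpoint_pos, big.mark = ","),
              x$noise_cv, x$dye_bias))
  cat(sprintf("  x_loss_frac %.3g | detection_eff %.3g | fp_rate %.3g\n",
              x$x_loss_frac, x$detection_eff, x$fp_rate))
  cat(sprintf("  n_cells %d | n_replicates %d\n", x$n_cells, x$n_replicates))
  invisible(x)
}

#' Serialize a simulation configuration to JSON
#'
#' Written next to every generated table as a provenance sidecar so a run can
#' be reproduced from its outputs alone.
#'
#' @param config A [sim_config()] object.
#' @param path File path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a simulation configuration sidecar
#'
#' @param path Path written by [write_sim_config()].
#' @return A validated [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$area_params <- as.list(x$area_params)
  x$dist_params <- lapply(x$dist_params, as.list)
  do.call(sim_config, x)
}
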