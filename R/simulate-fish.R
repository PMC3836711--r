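#' Simulate scored RNA FISH cell populations
#'
#' Forward model behind the nascent-transcript scoring experiments. Each
#' nucleus first draws which X is inactive: the transgenic CAST X with
#' probability `skewing_p` (XCI skewing), otherwise the 129 X. Expression
#' states then follow the requested hypothesis, every true focus is detected
#' independently with probability `detection_eff`, and spurious inactive-X
#' foci appear at `fp_rate` in cells whose inactive-X allele is silent.
#' Scoring criteria are applied with [apply_scoring_criteria()]; nuclei are
#' generated until `config$n_cells` meet criteria (or a safety cap is hit),
#' mirroring the practice of scoring a fixed number of criterion-passing
#' nuclei.
#'
#' Two assay designs are supported:
#' * `"escape_gene"`: an escapee with three loci (endogenous on both Xs plus
#'   the transgenic copy). Under `transgene_escapes` the transgene expresses
#'   wherever it sits; under `transgene_inactivated` it is silent on the
#'   inactive X. Active-X transgene expression is robustly visible, so
#'   detection thinning only affects inactive-X foci.
#' * `"inactivated_gene"`: a normally X-inactivated transcript near the
#'   integration site. Under `distal_escape` it expresses from the inactive
#'   X exactly when the transgenic CAST X is the inactive one; under
#'   `distal_inactivated` it never does.
#'
#' @param config A [sim_config()] object (`skewing_p`, `detection_eff`,
#'   `fp_rate`, `n_cells`, `seed`).
#' @param assay `"escape_gene"` or `"inactivated_gene"`.
#' @param hypothesis Generating hypothesis; defaults to the escape-side
#'   hypothesis of the assay (`"transgene_escapes"` / `"distal_escape"`).
#' @param line_id Label recorded on every cell.
#' @return A scored cell tibble from [apply_scoring_criteria()]: columns
#'   `nucleus_id`, `line_id`, `assay`, `category`, `included`,
#'   `exclusion_reason`.
#' @examples
#' cfg <- sim_config(seed = 7, skewing_p = 0.25, n_cells = 100)
#' cells <- simulate_fish_cells(cfg, "inactivated_gene")
#' table(cells$category[cells$included])
#' @export
simulate_fish_cells <- function(config, assay,
                                hypothesis = NULL, line_id = "simline") {
  stopifnot(inherits(config, "sim_config"))
  assay <- match.arg(assay, c("escape_gene", "inactivated_gene"))
  default_hyp <- switch(assay,
    escape_gene = "transgene_escapes",
    inactivated_gene = "distal_escape"
  )
  allowed <- switch(assay,
    escape_gene = c("transgene_escapes", "transgene_inactivated"),
    inactivated_gene = c("distal_escape", "distal_inactivated")
  )
  hypothesis <- hypothesis %||% default_hyp
  hypothesis <- match.arg(hypothesis, allowed)

  p <- config$skewing_p
  d <- config$detection_eff
  fp <- config$fp_rate
  target <- config$n_cells

  # probability that a random nucleus passes the assay's scoring criterion
  p_incl <- switch(assay, escape_gene = d * d, inactivated_gene = d)

  set.seed(derive_seed(config$seed, 2L))
  draw_batch <- function(n, id_offset) {
    tg_on_xi <- stats::runif(n) < p
    if (assay == "escape_gene") {
      xa_focus <- stats::runif(n) < d     # endogenous active-X focus
      xi_focus <- stats::runif(n) < d     # endogenous inactive-X focus
      tg_expresses_on_xi <- hypothesis == "transgene_escapes"
      tg_focus <- ifelse(
        tg_on_xi,
        if (tg_expresses_on_xi) stats::runif(n) < d else stats::runif(n) < fp,
        TRUE  # transgene on the active X: robust nascent signal
      )
    } else {
      xa_focus <- stats::runif(n) < d     # robust active-X signal of the gene
      xi_expressed <- hypothesis == "distal_escape" & tg_on_xi
      xi_focus <- ifelse(xi_expressed, stats::runif(n) < d,
                         stats::runif(n) < fp)
      tg_focus <- FALSE
    }
    tibble(
      nucleus_id = sprintf("cell%05d", id_offset + seq_len(n)),
      line_id = line_id, assay = assay,
      tg_on_xi = tg_on_xi, xa_focus = xa_focus,
      xi_focus = xi_focus, tg_focus = tg_focus
    )
  }

  if (p_incl <= 0) {
    signals <- draw_batch(target, 0L)
  } else {
    batch_n <- ceiling(target / p_incl * 1.5) + 50L
    signals <- draw_batch(batch_n, 0L)
    tries <- 0L
    while (sum(apply_scoring_criteria(signals, assay)$included) < target &&
           tries < 40L) {
      signals <- bind_rows(signals, draw_batch(batch_n, nrow(signals)))
      tries <- tries + 1L
    }
    # stop at the nucleus where the target count of criterion-passing cells
    # is reached, as a scorer at the microscope would
    incl_cum <- cumsum(apply_scoring_criteria(signals, assay)$included)
    cut <- which(incl_cum >= target)
    if (length(cut) > 0L) signals <- signals[seq_len(cut[1L]), ]
  }

  apply_scoring_criteria(signals, assay)
}

#' Apply assay-specific FISH scoring criteria
#'
#' Implements the inclusion rules used when scoring nascent-transcript
#' hybridization patterns, then assigns each included nucleus a category.
#' For an escapee assay a nucleus must show at least one active-X and one
#' inactive-X signal of the endogenous locus; for a normally X-inactivated
#' gene a robust active-X signal suffices. A nucleus whose transgenic-X
#' transcript signal is absent is conservatively scored as silencing the
#' transgene (`"tg_silenced"`), whichever X carries it.
#'
#' @param signals Per-nucleus signal tibble with columns `nucleus_id`,
#'   `line_id`, `assay`, `tg_on_xi`, `xa_focus`, `xi_focus`, `tg_focus`
#'   (logical focus indicators).
#' @param assay `"escape_gene"` (categories `xi_two_foci`,
#'   `xa_tg_expressed`, `tg_silenced`) or `"inactivated_gene"` (categories
#'   `xi_expression`, `xa_only`).
#' @return A tibble of per-nucleus scores: `nucleus_id`, `line_id`, `assay`,
#'   `category` (`NA` for excluded nuclei), `included`, `exclusion_reason`.
#' @examples
#' sig <- tibble::tibble(
#'   nucleus_id = c("c1", "c2"), line_id = "l", assay = "escape_gene",
#'   tg_on_xi = c(TRUE, FALSE), xa_focus = c(TRUE, TRUE),
#'   xi_focus = c(TRUE, FALSE), tg_focus = c(TRUE, TRUE)
#' )
#' apply_scoring_criteria(sig, "escape_gene")
#' @export
apply_scoring_criteria <- function(signals, assay) {
  assay <- match.arg(assay, c("escape_gene", "inactivated_gene"))
  check_columns(signals,
                c("nucleus_id", "tg_on_xi", "xa_focus", "xi_focus", "tg_focus"),
                "FISH signal table")

  if (assay == "escape_gene") {
    included <- signals$xa_focus & signals$xi_focus
    reason <- dplyr::case_when(
      included ~ NA_character_,
      !signals$xa_focus & !signals$xi_focus ~ "no endogenous Xa or Xi signal",
      !signals$xa_focus ~ "no endogenous Xa signal",
      TRUE ~ "no endogenous Xi signal"
    )
    category <- dplyr::case_when(
      !included ~ NA_character_,
      !signals$tg_focus ~ "tg_silenced",
      signals$tg_on_xi ~ "xi_two_foci",
      TRUE ~ "xa_tg_expressed"
    )
  } else {
    included <- signals$xa_focus
    reason <- ifelse(included, NA_character_, "no robust Xa signal")
    category <- dplyr::case_when(
      !included ~ NA_character_,
      signals$xi_focus ~ "xi_expression",
      TRUE ~ "xa_only"
    )
  }

  tibble(
    nucleus_id = signals$nucleus_id,
    line_id = signals$line_id %||% NA_character_,
    assay = assay,
    category = category,
    included = included,
    exclusion_reason = reason
  )
}

#' Names of the scoring categories of an assay
#' @param assay `"escape_gene"` or `"inactivated_gene"`.
#' @return Character vector of category labels in canonical order.
#' @export
fish_categories <- function(assay) {
  switch(match.arg(assay, c("escape_gene", "inactivated_gene")),
    escape_gene = c("xi_two_foci", "xa_tg_expressed", "tg_silenced"),
    inactivated_gene = c("xi_expression", "xa_only")
  )
}
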