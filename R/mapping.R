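#' Default copy-state thresholds
#'
#' Noise-free expectations for the normalized (129+BAC)/CAST ratio are 1
#' (no transgene), 2 (single copy), 3+ (multi copy). Thresholds sit at the
#' midpoints between these expectations, with a guard band on either side
#' within which a call is deemed ambiguous rather than forced.
#'
#' @param t_low Boundary between `absent` and `single_copy`.
#' @param t_high Boundary between `single_copy` and `multi_copy`.
#' @param guard Half-width of the ambiguity band around each boundary.
#' @return A named list of thresholds.
#' @export
copy_state_thresholds <- function(t_low = 1.4, t_high = 2.5, guard = 0.1) {
  check_number(t_low, "t_low", min = .Machine$double.eps)
  check_number(t_high, "t_high", min = t_low)
  check_number(guard, "guard", min = 0)
  if (t_low + guard >= t_high - guard) {
    stop_config("guard bands around t_low and t_high overlap")
  }
  list(t_low = t_low, t_high = t_high, guard = guard)
}

#' Call per-SNP transgene copy state from normalized dosage ratios
#'
#' @param ratios Tibble with `snp_id` and `ratio` columns (normalized,
#'   X-loss-corrected DNA ratios); a `pos` column is carried through if
#'   present.
#' @param thresholds A [copy_state_thresholds()] list.
#' @return The input with `state` (`absent`, `single_copy`, `multi_copy`, or
#'   `ambiguous`) and `ratio_used` columns.
#' @examples
#' tb <- tibble::tibble(snp_id = c("a", "b", "c"), pos = c(1, 2, 3),
#'                      ratio = c(1.0, 2.0, 3.1))
#' call_copy_state(tb)$state
#' @export
call_copy_state <- function(ratios, thresholds = copy_state_thresholds()) {
  check_columns(ratios, c("snp_id", "ratio"), "ratio table")
  if (any(!is.finite(ratios$ratio)) || any(ratios$ratio <= 0)) {
    stop_data("copy-state calling requires positive finite ratios")
  }
  t1 <- thresholds$t_low; t2 <- thresholds$t_high; g <- thresholds$guard
  ratios %>%
    mutate(
      ratio_used = .data$ratio,
      state = dplyr::case_when(
        abs(.data$ratio - t1) <= g | abs(.data$ratio - t2) <= g ~ "ambiguous",
        .data$ratio < t1 ~ "absent",
        .data$ratio < t2 ~ "single_copy",
        TRUE ~ "multi_copy"
      )
    )
}

#' Locate a transgene truncation breakpoint from ordered copy-state calls
#'
#' For a simply truncated transgene the present-state SNPs (single- or
#' multi-copy) form a contiguous run followed by absent-state SNPs. The
#' breakpoint interval is bounded by the last present SNP and the first
#' absent SNP after it; its midpoint (integer floor, since coordinates are
#' base pairs) is the conventional summary position for the transgene 3'
#' end. Ambiguous calls never bound the interval -- they only widen it.
#'
#' @param calls Position-sorted tibble from [call_copy_state()] with `pos`
#'   and `state` columns.
#' @return An object of class `breakpoint_interval`: fields
#'   `last_present_pos`, `first_absent_pos`, `midpoint`, `width`, `pattern`.
#'   Supports [tidy()] and `print()`.
#' @examples
#' calls <- tibble::tibble(
#'   snp_id = letters[1:4], pos = c(100, 500, 1400, 2000),
#'   state = c("single_copy", "single_copy", "absent", "absent")
#' )
#' infer_breakpoint(calls)
#' @export
infer_breakpoint <- function(calls) {
  check_columns(calls, c("pos", "state"), "copy-state calls")
  if (is.unsorted(calls$pos, strictly = FALSE)) {
    stop_data("calls must be sorted by position")
  }
  informative <- calls %>% filter(.data$state != "ambiguous")
  present <- informative$state %in% c("single_copy", "multi_copy")
  absent <- informative$state == "absent"
  if (!any(present)) stop_data("no breakpoint: no present-state SNP in panel")
  if (!any(absent)) stop_data("no breakpoint: no absent-state SNP in panel")

  pattern <- validate_pattern(calls)
  if (pattern != "simple_truncation") {
    stop_data(paste0("present/absent pattern is not a simple truncation; ",
                     "see validate_pattern()"))
  }

  last_present <- max(informative$pos[present])
  first_absent <- min(informative$pos[absent & informative$pos > last_present])
  structure(
    list(
      last_present_pos = last_present,
      first_absent_pos = first_absent,
      midpoint = floor((last_present + first_absent) / 2),
      width = first_absent - last_present,
      pattern = pattern
    ),
    class = "breakpoint_interval"
  )
}

#' @export
print.breakpoint_interval <- function(x, ...) {
  cat("Transgene breakpoint interval\n")
  cat(sprintf("  last present SNP: %s\n  first absent SNP: %s\n",
              format(x$last_present_pos, big.mark = ","),
              format(x$first_absent_pos, big.mark = ",")))
  cat(sprintf("  midpoint: %s   width: %s bp\n",
              format(x$midpoint, big.mark = ","),
              format(x$width, big.mark = ",")))
  invisible(x)
}

#' @rdname infer_breakpoint
#' @param x A `breakpoint_interval`.
#' @param ... Unused.
#' @method tidy breakpoint_interval
#' @export
tidy.breakpoint_interval <- function(x, ...) {
  tibble(
    last_present_pos = x$last_present_pos,
    first_absent_pos = x$first_absent_pos,
    midpoint = x$midpoint,
    width = x$width,
    pattern = x$pattern
  )
}

#' Classify the present/absent pattern of a panel
#'
#' A simply truncated transgene shows present-state calls as one contiguous
#' prefix of the position-sorted panel (ambiguous calls ignored); any other
#' arrangement indicates a more complex vector rearrangement on insertion.
#'
#' @param calls Position-sorted tibble with `pos` and `state` columns.
#' @return `"simple_truncation"` or `"complex_rearrangement"`.
#' @examples
#' tb <- tibble::tibble(pos = 1:4,
#'                      state = c("single_copy", "absent", "single_copy", "absent"))
#' validate_pattern(tb)
#' @export
validate_pattern <- function(calls) {
  check_columns(calls, c("pos", "state"), "copy-state calls")
  if (nrow(calls) == 0L) stop_data("empty call set")
  if (is.unsorted(calls$pos, strictly = FALSE)) {
    stop_data("calls must be sorted by position")
  }
  s <- calls$state[calls$state != "ambiguous"]
  present <- s %in% c("single_copy", "multi_copy")
  if (!any(present) || all(present)) return("simple_truncation")
  # contiguous prefix: no present call after the first absent call
  if (max(which(present)) < min(which(!present))) {
    "simple_truncation"
  } else {
    "complex_rearrangement"
  }
}

#' Export a breakpoint interval as a BED record
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the record spans `last_present_pos - 1` to `first_absent_pos`.
#'
#' @param bp A `breakpoint_interval`.
#' @param path Output file path.
#' @param chrom Chromosome name.
#' @param name Feature name written in column 4.
#' @return `path`, invisibly.
#' @export
write_breakpoint_bed <- function(bp, path, chrom = "chrX",
                                 name = "transgene_breakpoint") {
  stopifnot(inherits(bp, "breakpoint_interval"))
  rec <- tibble(
    chrom = chrom,
    start = format(bp$last_present_pos - 1, scientific = FALSE, trim = TRUE),
    end = format(bp$first_absent_pos, scientific = FALSE, trim = TRUE),
    name = name
  )
  readr::write_tsv(rec, path, col_names = FALSE)
  invisible(path)
}
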