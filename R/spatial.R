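#' Euclidean 3D distance between probe signals
#'
#' @param coord_a,coord_b Numeric length-3 vectors `(x, y, z)` or n-by-3
#'   matrices of coordinates in micrometres.
#' @return Distance(s) in micrometres.
#' @examples
#' distance_3d(c(0, 0, 0), c(0.32, 0, 0))
#' distance_3d(c(1, 2, 2), c(0, 0, 0))
#' @export
distance_3d <- function(coord_a, coord_b) {
  a <- rbind(coord_a); b <- rbind(coord_b)
  if (ncol(a) != 3L || ncol(b) != 3L || !all(dim(a) == dim(b))) {
    stop_data("coordinates must be (x, y, z) triplets of matching shape")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop_data("coordinates must be finite")
  }
  d <- sqrt(rowSums((a - b)^2))
  if (is.vector(coord_a) && length(coord_a) == 3L) d[[1L]] else d
}

#' Mean nuclear cross-sectional area
#'
#' Averages polygon areas demarcating the nucleus across all in-focus Z
#' sections, the per-nucleus size measure used to normalize probe distances.
#'
#' @param z_areas Numeric vector of per-section polygon areas (micrometres
#'   squared), all positive.
#' @return The arithmetic mean area.
#' @examples
#' nuclear_area(c(90, 100, 110))
#' @export
nuclear_area <- function(z_areas) {
  if (length(z_areas) == 0L) stop_data("no Z-section areas supplied")
  if (!is.numeric(z_areas) || any(!is.finite(z_areas)) || any(z_areas <= 0)) {
    stop_data("Z-section areas must be positive finite numbers")
  }
  mean(z_areas)
}

#' Per-nucleus mean areas from a long-form geometry table
#'
#' @param geometry Tibble with columns `nucleus_id`, `z_index`,
#'   `polygon_area`.
#' @return Tibble with `nucleus_id` and `mean_area`.
#' @export
nuclear_areas <- function(geometry) {
  check_columns(geometry, c("nucleus_id", "polygon_area"), "geometry table")
  if (any(!is.finite(geometry$polygon_area)) || any(geometry$polygon_area <= 0)) {
    stop_data("Z-section areas must be positive finite numbers")
  }
  geometry %>%
    group_by(.data$nucleus_id) %>%
    summarise(mean_area = mean(.data$polygon_area), .groups = "drop")
}

#' Build a probe-pair distance table
#'
#' Joins two probes' 3D coordinates per nucleus, computes their Euclidean
#' separation, and normalizes it by the nucleus's mean cross-sectional area
#' (units micrometres per micrometre squared). Area normalization corrects
#' for differences in nuclear size and morphology between cells.
#'
#' @param coordinates Tibble with columns `nucleus_id`, `locus`, `x`, `y`,
#'   `z`.
#' @param geometry Long-form geometry table (see [nuclear_areas()]).
#' @param locus_a,locus_b Locus labels to pair, as they appear in
#'   `coordinates$locus`.
#' @return Tibble with `nucleus_id`, `locus_a`, `locus_b`, `distance` (um),
#'   `mean_area` (um^2), `norm_distance` (um/um^2).
#' @export
probe_distances <- function(coordinates, geometry, locus_a, locus_b) {
  check_columns(coordinates, c("nucleus_id", "locus", "x", "y", "z"),
                "coordinates table")
  a <- coordinates %>% filter(.data$locus == locus_a)
  b <- coordinates %>% filter(.data$locus == locus_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop_data("locus '%s' or '%s' not found in coordinates",
              locus_a, locus_b)
  }
  joined <- inner_join(a, b, by = "nucleus_id", suffix = c("_a", "_b"))
  areas <- nuclear_areas(geometry)
  joined %>%
    mutate(distance = distance_3d(
      cbind(.data$x_a, .data$y_a, .data$z_a),
      cbind(.data$x_b, .data$y_b, .data$z_b)
    )) %>%
    inner_join(areas, by = "nucleus_id") %>%
    transmute(
      nucleus_id = .data$nucleus_id,
      locus_a = locus_a, locus_b = locus_b,
      coord_ax = .data$x_a, coord_ay = .data$y_a, coord_az = .data$z_a,
      coord_bx = .data$x_b, coord_by = .data$y_b, coord_bz = .data$z_b,
      distance = .data$distance,
      mean_area = .data$mean_area,
      norm_distance = .data$distance / .data$mean_area
    )
}

#' Restrict analysis to nuclei below an area threshold
#'
#' Large, flat, or aberrant nuclei distort normalized distances; analysis is
#' limited to cells whose mean nuclear area falls strictly below a threshold
#' chosen so that the retained distributions overlap across cell lines
#' (default 175 um^2, retaining about 95% of nuclei under the default
#' area model).
#'
#' @param pairs Probe-pair tibble containing a `mean_area` column (as
#'   produced by [probe_distances()]).
#' @param threshold Area cutoff in micrometres squared (> 0).
#' @return A list with `pairs` (the retained subset) and `retention` (the
#'   fraction of input nuclei kept).
#' @examples
#' pairs <- tibble::tibble(nucleus_id = c("a", "b"), mean_area = c(100, 200),
#'                         norm_distance = c(0.01, 0.02))
#' filter_by_area(pairs)$retention
#' @export
filter_by_area <- function(pairs, threshold = 175) {
  check_number(threshold, "threshold", min = .Machine$double.eps)
  check_columns(pairs, "mean_area", "probe-pair table")
  keep <- pairs$mean_area < threshold
  list(pairs = pairs[keep, , drop = FALSE],
       retention = if (nrow(pairs) == 0L) NA_real_ else mean(keep))
}

#' Empirical cumulative frequency curve of normalized distances
#'
#' Returns the right-continuous empirical cumulative proportion of nuclei in
#' which the two loci are closer than each observed distance. An optional
#' display truncation keeps only the closest fraction of observations for
#' plotting; statistics must always be computed on the full sample, so
#' truncation here is cosmetic and flagged on the result.
#'
#' @param norm_distances Non-empty numeric vector (any distance unit).
#' @param display_fraction Optional fraction in (0, 1]; the returned curve
#'   stops at that order statistic.
#' @return Tibble with `distance` (sorted) and `cum_prop`; attribute
#'   `display_fraction` records any truncation.
#' @examples
#' cumulative_frequency(c(1, 2, 3))
#' @export
cumulative_frequency <- function(norm_distances, display_fraction = NULL) {
  if (length(norm_distances) == 0L) stop_data("empty distance sample")
  if (any(!is.finite(norm_distances))) stop_data("distances must be finite")
  n <- length(norm_distances)
  curve <- tibble(
    distance = sort(norm_distances),
    cum_prop = seq_len(n) / n
  )
  if (!is.null(display_fraction)) {
    check_number(display_fraction, "display_fraction",
                 min = .Machine$double.eps, max = 1)
    keep <- seq_len(ceiling(display_fraction * n))
    curve <- curve[keep, , drop = FALSE]
  }
  attr(curve, "display_fraction") <- display_fraction %||% 1
  curve
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' Computes the KS statistic D as the supremum absolute difference between
#' the two empirical cumulative curves, evaluated at every pooled data point
#' (which handles ties exactly). The p-value is the asymptotic Kolmogorov
#' series by default, or the exact conditional distribution for small
#' samples (combined n below `exact_max`, no ties). Because D compares
#' ranks, dividing both samples by any shared positive constant -- such as a
#' common area normalization -- never changes it.
#'
#' @param sample_x,sample_y Non-empty numeric vectors (e.g. normalized
#'   distances of two locus-pair classes).
#' @param exact `TRUE`/`FALSE` to force the exact or asymptotic p-value;
#'   `NULL` (default) chooses exact when the combined sample size is at most
#'   `exact_max` and there are no ties.
#' @param exact_max Combined-size cutoff for the automatic exact rule.
#' @return An object of class `xci_ks` with fields `statistic` (D),
#'   `p.value`, `n_x`, `n_y`, `method`; supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic  # disjoint supports: D = 1
#' @export
ks_two_sample <- function(sample_x, sample_y, exact = NULL, exact_max = 30L) {
  if (length(sample_x) == 0L || length(sample_y) == 0L) {
    stop_data("both samples must be non-empty")
  }
  if (any(!is.finite(sample_x)) || any(!is.finite(sample_y))) {
    stop_data("samples must be finite")
  }
  m <- length(sample_x); n <- length(sample_y)

  pooled <- sort(unique(c(sample_x, sample_y)))
  fx <- vapply(pooled, function(q) mean(sample_x <= q), numeric(1))
  fy <- vapply(pooled, function(q) mean(sample_y <= q), numeric(1))
  d <- max(abs(fx - fy))

  ties <- anyDuplicated(c(sample_x, sample_y)) > 0L
  if (is.null(exact)) exact <- (m + n) <= exact_max && !ties
  if (exact && ties) {
    warning("ties present; falling back to the asymptotic p-value")
    exact <- FALSE
  }

  if (exact) {
    p <- 1 - stats::psmirnov(d, sizes = c(m, n), two.sided = TRUE)
    method <- "exact"
  } else {
    lambda <- sqrt(m * n / (m + n)) * d
    k <- seq_len(100)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    method <- "asymptotic"
  }
  p <- min(1, max(0, p))

  structure(
    list(statistic = d, p.value = p, n_x = m, n_y = n, method = method,
         sample_x = sample_x, sample_y = sample_y),
    class = "xci_ks"
  )
}

#' @export
print.xci_ks <- function(x, ...) {
  cat("Two-sample Kolmogorov-Smirnov comparison\n")
  cat(sprintf("  D = %.4f, p = %.4g (%s), n = %d vs %d\n",
              x$statistic, x$p.value, x$method, x$n_x, x$n_y))
  invisible(x)
}

#' @rdname ks_two_sample
#' @param x An `xci_ks` object.
#' @param ... Unused.
#' @method tidy xci_ks
#' @export
tidy.xci_ks <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n_x = x$n_x, n_y = x$n_y, method = x$method)
}

#' @rdname ks_two_sample
#' @method glance xci_ks
#' @export
glance.xci_ks <- function(x, ...) tidy(x)
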