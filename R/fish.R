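#' Expected FISH category probabilities under an XCI hypothesis
#'
#' Converts an XCI hypothesis plus the cell line's XCI skewing into expected
#' proportions of the scoring categories. With skewing probability p (the
#' transgenic CAST X is the inactive X) and focus detection efficiency
#' delta:
#'
#' * `transgene_escapes`: two inactive-X foci in p*delta of nuclei, the
#'   transgene expressed from the active X in 1-p, and a conservatively
#'   "silenced" score (absent transgenic-X signal) in p*(1-delta);
#' * `transgene_inactivated`: the two-inactive-X-foci pattern only arises
#'   from spurious foci (rate `fp_rate`), so p*fp, with 1-p on the active X
#'   and p*(1-fp) silenced;
#' * `distal_escape`: an integration-site transcript shows an inactive-X
#'   focus when the transgenic X is inactive and the focus is detected
#'   (p*delta), plus false positives elsewhere;
#' * `distal_inactivated`: inactive-X foci at the false-positive rate only.
#'
#' Probabilities are conditional on a nucleus meeting the assay's scoring
#' criterion, and always sum to 1.
#'
#' @param hypothesis One of `"transgene_escapes"`, `"transgene_inactivated"`,
#'   `"distal_escape"`, `"distal_inactivated"`.
#' @param skewing_p XCI skewing probability p in `[0, 1]`.
#' @param detection_eff Focus detection efficiency delta in `[0, 1]`.
#' @param fp_rate Spurious-focus probability in `[0, 1]`.
#' @param n Planned number of scored nuclei (recorded, used by
#'   [chi_square_gof()] when only proportions are given).
#' @return An object of class `scoring_expectation`: `hypothesis`, `probs`
#'   (named, summing to 1), `n`.
#' @examples
#' expected_category_probs("transgene_escapes", 0.25, 1)$probs
#' # 0.25, 0.75, 0
#' @export
expected_category_probs <- function(hypothesis, skewing_p, detection_eff = 1,
                                    fp_rate = 0, n = 100L) {
  hypothesis <- match.arg(hypothesis,
                          c("transgene_escapes", "transgene_inactivated",
                            "distal_escape", "distal_inactivated"))
  check_prob(skewing_p, "skewing_p")
  check_prob(detection_eff, "detection_eff")
  check_prob(fp_rate, "fp_rate")
  p <- skewing_p; d <- detection_eff; fp <- fp_rate

  probs <- switch(hypothesis,
    transgene_escapes = c(
      xi_two_foci = p * d,
      xa_tg_expressed = 1 - p,
      tg_silenced = p * (1 - d)
    ),
    transgene_inactivated = c(
      xi_two_foci = p * fp,
      xa_tg_expressed = 1 - p,
      tg_silenced = p * (1 - fp)
    ),
    distal_escape = c(
      xi_expression = p * d + (1 - p) * fp,
      xa_only = 1 - (p * d + (1 - p) * fp)
    ),
    distal_inactivated = c(
      xi_expression = fp,
      xa_only = 1 - fp
    )
  )
  stopifnot(all(probs >= -1e-12), abs(sum(probs) - 1) < 1e-12)
  structure(
    list(hypothesis = hypothesis, probs = pmax(probs, 0), n = as.integer(n)),
    class = "scoring_expectation"
  )
}

#' @export
print.scoring_expectation <- function(x, ...) {
  cat(sprintf("<scoring_expectation: %s, n = %d>\n", x$hypothesis, x$n))
  print(round(x$probs, 4))
  invisible(x)
}

#' Chi-square goodness of fit of observed FISH counts to an expectation
#'
#' Pearson chi-square test of observed category counts against the expected
#' proportions of a [expected_category_probs()] hypothesis, with degrees of
#' freedom equal to the number of non-empty expected categories minus one.
#' Two validity guards apply:
#' * a category expected to be empty but observed non-empty makes the
#'   statistic infinite; the result is flagged `degenerate` with p-value 0
#'   (the hypothesis is contradicted outright). Categories empty under both
#'   are dropped.
#' * if any expected count falls below 5 the asymptotic chi-square
#'   approximation is unreliable and a seeded Monte-Carlo multinomial
#'   p-value is substituted.
#'
#' @param observed Named integer vector of category counts (names must
#'   match the expectation's categories) or a scored cell tibble from
#'   [apply_scoring_criteria()] (included nuclei are tabulated).
#' @param expectation A `scoring_expectation`.
#' @param n_mc Number of Monte-Carlo draws for the small-count fallback.
#' @param mc_seed Seed for the Monte-Carlo draw.
#' @return An object of class `xci_gof`: `statistic`, `df`, `p.value`,
#'   `method` (`"asymptotic"`, `"monte_carlo"` or
#'   `"degenerate_expectation"`), `degenerate` flag, `observed`, `expected`.
#' @examples
#' exp_esc <- expected_category_probs("transgene_escapes", 0.25, 1)
#' chi_square_gof(c(xi_two_foci = 22, xa_tg_expressed = 78, tg_silenced = 0),
#'                exp_esc)
#' @export
chi_square_gof <- function(observed, expectation, n_mc = 10000L,
                           mc_seed = 1L) {
  stopifnot(inherits(expectation, "scoring_expectation"))
  observed <- as_category_counts(observed, names(expectation$probs))
  n <- sum(observed)
  if (n == 0L) stop_data("no scored nuclei: observed counts sum to zero")
  probs <- expectation$probs[names(observed)]
  expected <- probs * n

  # categories empty under both observation and expectation carry no
  # information and are dropped before computing df
  drop <- expected == 0 & observed == 0
  observed <- observed[!drop]; expected <- expected[!drop]
  probs <- probs[!drop]

  if (any(expected == 0 & observed > 0)) {
    return(structure(
      list(statistic = Inf, df = NA_integer_, p.value = 0,
           method = "degenerate_expectation", degenerate = TRUE,
           observed = observed, expected = expected),
      class = "xci_gof"
    ))
  }

  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L

  if (any(expected < 5)) {
    set.seed(derive_seed(mc_seed))
    sims <- stats::rmultinom(n_mc, size = n, prob = probs)
    sim_stats <- colSums((sims - expected)^2 / expected)
    p <- (1 + sum(sim_stats >= statistic - 1e-12)) / (n_mc + 1)
    method <- "monte_carlo"
  } else {
    p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
    method <- "asymptotic"
  }

  structure(
    list(statistic = statistic, df = df, p.value = p, method = method,
         degenerate = FALSE, observed = observed, expected = expected),
    class = "xci_gof"
  )
}

as_category_counts <- function(observed, categories) {
  if (is.data.frame(observed)) {
    check_columns(observed, c("category", "included"), "scored cell table")
    tab <- table(factor(observed$category[observed$included],
                        levels = categories))
    observed <- stats::setNames(as.integer(tab), names(tab))
  }
  if (is.null(names(observed))) {
    if (length(observed) != length(categories)) {
      stop_data("unnamed counts must match the %d expectation categories",
                length(categories))
    }
    names(observed) <- categories
  }
  missing <- setdiff(categories, names(observed))
  observed <- c(observed, stats::setNames(integer(length(missing)), missing))
  extra <- setdiff(names(observed), categories)
  if (length(extra) > 0L) {
    stop_data("observed categories not in expectation: %s",
              paste(extra, collapse = ", "))
  }
  observed[categories]
}

#' @export
print.xci_gof <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X2 = %s, df = %s, p = %.4g (%s)\n",
              format(x$statistic, digits = 4), x$df, x$p.value, x$method))
  invisible(x)
}

#' @rdname chi_square_gof
#' @param x An `xci_gof` object.
#' @param ... Unused.
#' @method tidy xci_gof
#' @export
tidy.xci_gof <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method, degenerate = x$degenerate)
}

#' Classify XCI status by testing competing hypotheses
#'
#' Tests the observed category counts against each candidate hypothesis with
#' [chi_square_gof()] and reports the hypothesis that is *not* rejected at
#' `alpha` when exactly one survives. When none or several survive the
#' verdict is `"indeterminate"` (typical at very small n, where power
#' collapses).
#'
#' @param observed Named counts or a scored cell tibble (see
#'   [chi_square_gof()]).
#' @param hypotheses A list of `scoring_expectation` objects (at least two).
#' @param alpha Rejection level (default 0.001).
#' @param ... Passed to [chi_square_gof()].
#' @return An object of class `xci_classification`: `best` (hypothesis name
#'   or `"indeterminate"`), `alpha`, and `tests`, a tibble of per-hypothesis
#'   results. Supports [tidy()] and [glance()].
#' @examples
#' hyps <- list(
#'   expected_category_probs("transgene_escapes", 0.25, 1),
#'   expected_category_probs("transgene_inactivated", 0.25, 1)
#' )
#' obs <- c(xi_two_foci = 24, xa_tg_expressed = 76, tg_silenced = 0)
#' classify_xci_status(obs, hyps)
#' @export
classify_xci_status <- function(observed, hypotheses, alpha = 0.001, ...) {
  if (length(hypotheses) < 2L) {
    stop_config("at least two hypotheses are required")
  }
  check_number(alpha, "alpha", min = .Machine$double.xmin, max = 1)
  tests <- purrr::map_dfr(hypotheses, function(h) {
    fit <- chi_square_gof(observed, h, ...)
    tidy(fit) %>% mutate(hypothesis = h$hypothesis, .before = 1)
  })
  tests <- tests %>% mutate(rejected = .data$p.value < alpha)
  survivors <- tests$hypothesis[!tests$rejected]
  best <- if (length(survivors) == 1L) survivors else "indeterminate"
  structure(
    list(best = best, alpha = alpha, tests = tests),
    class = "xci_classification"
  )
}

#' @export
print.xci_classification <- function(x, ...) {
  cat(sprintf("XCI status classification (alpha = %g): %s\n", x$alpha, x$best))
  print(as.data.frame(x$tests[, c("hypothesis", "statistic", "p.value",
                                  "method", "rejected")]))
  invisible(x)
}

#' @rdname classify_xci_status
#' @param x An `xci_classification` object.
#' @method tidy xci_classification
#' @export
tidy.xci_classification <- function(x, ...) x$tests

#' @rdname classify_xci_status
#' @method glance xci_classification
#' @export
glance.xci_classification <- function(x, ...) {
  tibble(best = x$best, alpha = x$alpha,
         n_hypotheses = nrow(x$tests), n_rejected = sum(x$tests$rejected))
}
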