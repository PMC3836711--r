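#' @importFrom rlang .data .env abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# error helpers: config errors vs data errors carry distinct classes so the
# command-line wrapper can map them to distinct exit codes
stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "xciescape_config_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "xciescape_data_error")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config("`%s` must be a single probability in [0, 1], got %s",
                name, deparse(substitute(x)))
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_config("`%s` must be a single number in [%s, %s]", name, min, max)
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_data("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# seed every generator from one user-visible integer; keep derived seeds
# within 32-bit range
derive_seed <- function(seed, offset = 0L) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% .Machine$integer.max
}
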