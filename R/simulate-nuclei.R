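#' Simulate nuclear geometries and 3D probe coordinate pairs
#'
#' Forward model of the 3D DNA FISH association experiment. Each nucleus
#' draws a mean cross-sectional area from the lognormal in
#' `config$area_params` and a set of per-Z-section polygon areas jittered
#' around it. The true inter-probe separation is drawn from a gamma
#' distribution whose mean depends on the locus-pair class and chromosome
#' (`config$dist_params`); an infinite `shape` collapses the distribution to
#' its mean (degenerate case, useful for calibration). Probe A is placed
#' uniformly inside the nucleus bounding box and probe B at the drawn
#' separation in a uniformly random 3D direction, so measured Euclidean
#' distances reproduce the configured distribution exactly.
#'
#' @param config A [sim_config()] object.
#' @param pair_class `"escape_escape"` (both loci escape XCI) or
#'   `"escape_inactivated"` (one escapee, one X-inactivated locus).
#' @param chromosome `"active"` or `"inactive"` X.
#' @param n_nuclei Number of nuclei; defaults to `config$n_cells`.
#' @param n_z Number of in-focus Z sections per nucleus.
#' @return A list of three tibbles:
#'   * `geometry`: `nucleus_id`, `z_index`, `polygon_area` (long form);
#'   * `coordinates`: `nucleus_id`, `locus`, `x`, `y`, `z` (micrometres);
#'   * `pairs`: the measured [probe_distances()] table (`distance`,
#'     `mean_area`, `norm_distance`, with `pair_class` and `chromosome`).
#' @examples
#' cfg <- sim_config(seed = 3, n_cells = 50)
#' sim <- simulate_nuclei(cfg, "escape_escape", "inactive")
#' head(sim$pairs)
#' @export
simulate_nuclei <- function(config, pair_class, chromosome,
                            n_nuclei = config$n_cells, n_z = 8L) {
  stopifnot(inherits(config, "sim_config"))
  pair_class <- match.arg(pair_class, c("escape_escape", "escape_inactivated"))
  chromosome <- match.arg(chromosome, c("active", "inactive"))
  check_number(n_nuclei, "n_nuclei", min = 1)
  check_number(n_z, "n_z", min = 1)

  par <- config$dist_params[[pair_class]]
  mean_d <- par[[chromosome]]
  shape <- par$shape
  if (mean_d <= 0) stop_config("distance distribution mean must be positive")

  set.seed(derive_seed(config$seed, 3L +
                         2L * (pair_class == "escape_inactivated") +
                         (chromosome == "inactive")))
  n <- as.integer(n_nuclei)
  ids <- sprintf("nuc%05d", seq_len(n))

  target_area <- stats::rlnorm(n, meanlog = config$area_params$meanlog,
                               sdlog = config$area_params$sdlog)
  geometry <- tidyr::expand_grid(nucleus_id = ids, z_index = seq_len(n_z)) %>%
    mutate(polygon_area = rep(target_area, each = n_z) *
             stats::runif(n * n_z, 0.85, 1.15))

  if (is.finite(shape)) {
    true_d <- stats::rgamma(n, shape = shape, rate = shape / mean_d)
  } else {
    true_d <- rep(mean_d, n)
  }

  # probe A uniform in a nominal imaging volume; B at the drawn separation
  # along an isotropic random direction
  ax <- stats::runif(n, 0, 12); ay <- stats::runif(n, 0, 12)
  az <- stats::runif(n, 0, 3)
  dir <- matrix(stats::rnorm(3L * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))

  loci <- switch(pair_class,
    escape_escape = c("escapee_a", "escapee_b"),
    escape_inactivated = c("escapee_a", "inactivated_b")
  )
  coordinates <- bind_rows(
    tibble(nucleus_id = ids, locus = loci[1L], x = ax, y = ay, z = az),
    tibble(nucleus_id = ids, locus = loci[2L],
           x = ax + true_d * dir[, 1L],
           y = ay + true_d * dir[, 2L],
           z = az + true_d * dir[, 3L])
  ) %>% arrange(.data$nucleus_id, .data$locus)

  pairs <- probe_distances(coordinates, geometry,
                           locus_a = loci[1L], locus_b = loci[2L]) %>%
    mutate(pair_class = pair_class, chromosome = chromosome)

  list(geometry = geometry, coordinates = coordinates, pairs = pairs)
}
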