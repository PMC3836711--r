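test_that("3D distances are Euclidean and rigid-motion invariant", {
  expect_equal(distance_3d(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(distance_3d(c(0, 0, 0), c(0.32, 0, 0)), 0.32)
  expect_equal(distance_3d(c(1, 2, 2), c(0, 0, 0)), 3)
  expect_error(distance_3d(c(0, 0, NA), c(1, 1, 1)),
               class = "xciescape_data_error")
  expect_error(distance_3d(c(0, 0), c(1, 1)), class = "xciescape_data_error")

  # invariance under rotation + translation applied to both points
  set.seed(11)
  for (i in 1:20) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    theta <- stats::runif(1, 0, 2 * pi)
    rot <- rbind(c(cos(theta), -sin(theta), 0),
                 c(sin(theta), cos(theta), 0),
                 c(0, 0, 1))
    shift <- stats::rnorm(3)
    expect_equal(distance_3d(as.vector(rot %*% a + shift),
                             as.vector(rot %*% b + shift)),
                 distance_3d(a, b), tolerance = 1e-12)
  }
})

test_that("nuclear area is the mean over Z sections", {
  expect_equal(nuclear_area(100), 100)
  expect_equal(nuclear_area(c(90, 100, 110)), 100)
  expect_error(nuclear_area(numeric()), class = "xciescape_data_error")
  expect_error(nuclear_area(c(100, -5)), class = "xciescape_data_error")

  geom <- tibble::tibble(nucleus_id = rep(c("a", "b"), each = 3),
                         z_index = rep(1:3, 2),
                         polygon_area = c(90, 100, 110, 10, 20, 30))
  areas <- nuclear_areas(geom)
  expect_equal(areas$mean_area, c(100, 20))
})

test_that("area filtering retains the configured fraction of nuclei", {
  pairs <- tibble::tibble(nucleus_id = c("a", "b"),
                          mean_area = c(100, 200), norm_distance = 1:2)
  expect_equal(filter_by_area(pairs)$retention, 0.5)
  expect_equal(filter_by_area(dplyr::mutate(pairs, mean_area = 100))$retention,
               1)
  # threshold is strict: exactly-at-threshold nuclei are dropped
  expect_equal(filter_by_area(dplyr::mutate(pairs, mean_area = 175))$retention,
               0)
  # default area model is quantile-matched so ~95% fall below 175 um^2
  cfg <- sim_config(seed = 71, n_cells = 4000L)
  sim <- simulate_nuclei(cfg, "escape_escape", "inactive")
  expect_equal(filter_by_area(sim$pairs)$retention, 0.95, tolerance = 0.02)
})

test_that("cumulative frequency curves are ECDFs with display truncation", {
  cf <- cumulative_frequency(c(3, 1, 2))
  expect_equal(cf$distance, c(1, 2, 3))
  expect_equal(cf$cum_prop, c(1, 2, 3) / 3)

  x <- stats::runif(100)
  tr <- cumulative_frequency(x, display_fraction = 0.7)
  expect_equal(nrow(tr), 70L)
  expect_equal(max(tr$distance), sort(x)[70])

  expect_error(cumulative_frequency(numeric()),
               class = "xciescape_data_error")
})

test_that("KS statistic equals the brute-force pooled-point supremum", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)

  set.seed(19)
  for (i in 1:50) {
    x <- stats::rgamma(sample(5:50, 1), shape = 2)
    y <- stats::rgamma(sample(5:50, 1), shape = sample(1:4, 1))
    fit <- ks_two_sample(x, y)
    expect_equal(fit$statistic, brute_force_ks_d(x, y), tolerance = 1e-12)
    # with ties: pooled evaluation still matches brute force
    xt <- round(x, 1); yt <- round(y, 1)
    expect_equal(suppressWarnings(ks_two_sample(xt, yt)$statistic),
                 brute_force_ks_d(xt, yt), tolerance = 1e-12)
  }
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(23)
  x <- stats::rnorm(60); y <- stats::rnorm(70, mean = 0.5)
  fit <- ks_two_sample(x, y)
  ref <- stats::ks.test(x, y, exact = FALSE)
  expect_equal(fit$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fit$p.value, ref$p.value, tolerance = 1e-6)

  # exact small-sample path
  xs <- stats::rnorm(8); ys <- stats::rnorm(9)
  fit_e <- ks_two_sample(xs, ys)
  expect_equal(fit_e$method, "exact")
  ref_e <- stats::ks.test(xs, ys, exact = TRUE)
  expect_equal(fit_e$p.value, ref_e$p.value, tolerance = 1e-9)
})

test_that("D is invariant under shared monotone transforms", {
  set.seed(29)
  x <- stats::rgamma(40, 3); y <- stats::rgamma(35, 2)
  d0 <- ks_two_sample(x, y)$statistic
  expect_equal(ks_two_sample(x / 120, y / 120)$statistic, d0)  # area norm
  expect_equal(ks_two_sample(log(x), log(y))$statistic, d0)
  expect_equal(ks_two_sample(sqrt(x), sqrt(y))$statistic, d0)
})

test_that("display truncation never changes the reported statistics", {
  set.seed(31)
  x <- stats::rgamma(100, 4, 4 / 0.6)
  y <- stats::rgamma(100, 4, 4 / 0.9)
  full <- ks_two_sample(x, y)
  # curves truncated for display are a view; the test uses full samples
  cx <- cumulative_frequency(x, display_fraction = 0.7)
  expect_lt(nrow(cx), length(x))
  again <- ks_two_sample(x, y)
  expect_equal(full$statistic, again$statistic)
  expect_equal(full$p.value, again$p.value)
})

test_that("generated separation is detected as a left shift", {
  cfg <- sim_config(seed = 37, n_cells = 120L)
  ee <- simulate_nuclei(cfg, "escape_escape", "inactive")
  ei <- simulate_nuclei(cfg, "escape_inactivated", "inactive")
  fit <- ks_two_sample(filter_by_area(ee$pairs)$pairs$norm_distance,
                       filter_by_area(ei$pairs)$pairs$norm_distance)
  expect_lt(fit$p.value, 0.02)
  # and the shift is towards smaller escapee-escapee distances
  expect_lt(stats::median(ee$pairs$norm_distance),
            stats::median(ei$pairs$norm_distance))
})
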