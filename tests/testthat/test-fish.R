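test_that("expected category probabilities follow the skewing model", {
  e <- expected_category_probs("transgene_escapes", 0.25, 1)
  expect_equal(unname(e$probs), c(0.25, 0.75, 0))

  e0 <- expected_category_probs("transgene_escapes", 0, 0.5)
  expect_equal(unname(e0$probs["xa_tg_expressed"]), 1)

  e8 <- expected_category_probs("transgene_escapes", 0.25, 0.8)
  expect_equal(unname(e8$probs), c(0.20, 0.75, 0.05))

  inact <- expected_category_probs("transgene_inactivated", 0.25, 1)
  expect_equal(unname(inact$probs["xi_two_foci"]), 0)

  dist <- expected_category_probs("distal_escape", 0.25, 1)
  expect_equal(unname(dist$probs), c(0.25, 0.75))

  expect_error(expected_category_probs("transgene_escapes", 1.5, 1),
               class = "xciescape_config_error")
})

test_that("category probabilities sum to one over a parameter grid", {
  grid <- expand.grid(
    hypothesis = c("transgene_escapes", "transgene_inactivated",
                   "distal_escape", "distal_inactivated"),
    p = c(0, 0.1, 0.25, 0.9, 1), d = c(0, 0.5, 1), fp = c(0, 0.02),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    e <- expected_category_probs(grid$hypothesis[i], grid$p[i], grid$d[i],
                                 grid$fp[i])
    expect_equal(sum(e$probs), 1, tolerance = 1e-12)
    expect_true(all(e$probs >= 0))
  }
})

test_that("chi-square goodness of fit matches hand and reference values", {
  exp_esc <- expected_category_probs("distal_escape", 0.25, 1)

  perfect <- chi_square_gof(c(xi_expression = 25, xa_only = 75), exp_esc)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p.value, 1)

  # hand computation: (22-25)^2/25 + (78-75)^2/75 = 0.48
  fit <- chi_square_gof(c(xi_expression = 22, xa_only = 78), exp_esc)
  expect_equal(fit$statistic, 0.48, tolerance = 1e-12)
  expect_equal(fit$df, 1L)
  expect_equal(fit$method, "asymptotic")

  # cross-check statistic and p-value against stats::chisq.test
  ref <- stats::chisq.test(c(22, 78), p = c(0.25, 0.75), correct = FALSE)
  expect_equal(fit$statistic, unname(ref$statistic))
  expect_equal(fit$p.value, unname(ref$p.value))

  expect_error(chi_square_gof(c(xi_expression = 0, xa_only = 0), exp_esc),
               class = "xciescape_data_error")
})

test_that("zero-expectation categories with observations are flagged p ~ 0", {
  inact <- expected_category_probs("distal_inactivated", 0.25, 1)
  fit <- chi_square_gof(c(xi_expression = 25, xa_only = 75), inact)
  expect_true(fit$degenerate)
  expect_equal(fit$p.value, 0)
  expect_equal(fit$statistic, Inf)

  # but a jointly-empty category is simply dropped
  esc <- expected_category_probs("transgene_escapes", 0.25, 1)
  ok <- chi_square_gof(c(xi_two_foci = 25, xa_tg_expressed = 75,
                         tg_silenced = 0), esc)
  expect_false(ok$degenerate)
  expect_equal(ok$df, 1L)
})

test_that("small expected counts trigger a seeded Monte-Carlo p-value", {
  exp_small <- expected_category_probs("distal_escape", 0.25, 1)
  fit <- chi_square_gof(c(xi_expression = 3, xa_only = 9), exp_small)
  expect_equal(fit$method, "monte_carlo")
  expect_true(fit$p.value > 0 && fit$p.value <= 1)
  # seeded: identical on repeat
  fit2 <- chi_square_gof(c(xi_expression = 3, xa_only = 9), exp_small)
  expect_equal(fit$p.value, fit2$p.value)
  # sanity: Monte-Carlo p close to the exact binomial tail probability
  expect_equal(fit$p.value, 1, tolerance = 0.05)
})

test_that("hypothesis classification retains the generating model", {
  cfg <- sim_config(seed = 50, skewing_p = 0.25, n_cells = 100L)
  cells <- simulate_fish_cells(cfg, "escape_gene")
  hyps <- list(
    expected_category_probs("transgene_escapes", 0.25, 1),
    expected_category_probs("transgene_inactivated", 0.25, 1)
  )
  cls <- classify_xci_status(cells, hyps, alpha = 0.001)
  expect_equal(cls$best, "transgene_escapes")
  td <- tidy(cls)
  expect_true(td$rejected[td$hypothesis == "transgene_inactivated"])
  expect_false(td$rejected[td$hypothesis == "transgene_escapes"])
  expect_equal(glance(cls)$n_rejected, 1L)
})

test_that("classification is indeterminate at tiny n or equal hypotheses", {
  # n = 5 nuclei cannot separate the hypotheses (Monte-Carlo small-count path)
  obs <- c(xi_two_foci = 1, xa_tg_expressed = 4, tg_silenced = 0)
  hyps <- list(
    expected_category_probs("transgene_escapes", 0.25, 1),
    expected_category_probs("transgene_inactivated", 0.25, 1, fp_rate = 0.05)
  )
  cls <- classify_xci_status(obs, hyps, alpha = 0.001)
  expect_equal(cls$best, "indeterminate")

  same <- list(expected_category_probs("transgene_escapes", 0.25, 1),
               expected_category_probs("transgene_escapes", 0.25, 1))
  obs2 <- c(xi_two_foci = 25, xa_tg_expressed = 75, tg_silenced = 0)
  expect_equal(classify_xci_status(obs2, same)$best, "indeterminate")

  expect_error(classify_xci_status(obs, hyps[1]),
               class = "xciescape_config_error")
})
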