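test_that("exact two-line data are recovered with zero SSE", {
  cc <- make_conductivity_curve(26.2, 70, 30, 100, n_points = 16,
                                rel_noise = 0, seed = 1)
  fit <- fit_segmented(cc, n_boot = 0)
  expect_equal(fit$cmc, 26.2, tolerance = 1e-9)
  expect_equal(fit$pre_slope, 70, tolerance = 1e-9)
  expect_equal(fit$post_slope, 30, tolerance = 1e-9)
  expect_lt(fit$SSE, 1e-16)
  # breakpoint lies between the concentrations flanking the chosen split
  x <- cc$concentrations
  expect_gte(fit$cmc, x[fit$split] - 1e-9)
  expect_lte(fit$cmc, x[fit$split + 1] + 1e-9)
  # constrained variant agrees on clean data
  fitc <- fit_segmented(cc, n_boot = 0, constrained = TRUE)
  expect_equal(fitc$cmc, 26.2, tolerance = 0.2)
})

test_that("degenerate and malformed inputs are rejected", {
  x <- seq(10, 50, length.out = 12)
  line <- conductivity_curve(x, 5 + 3 * x)
  expect_error(fit_segmented(line, n_boot = 0),
               class = "phsolv_degenerate_fit_error")
  expect_error(conductivity_curve(1:4, 1:4), class = "phsolv_input_error")
  expect_error(conductivity_curve(c(1, 2, 2, 3, 4, 5), rep(1, 6)),
               class = "phsolv_input_error")
  expect_error(make_conductivity_curve(26.2, 30, 70, 100),
               class = "phsolv_input_error")
  expect_error(make_conductivity_curve(26.2, 70, 30, 100, n_points = 4),
               class = "phsolv_input_error")
})

test_that("the estimator is affine-equivariant", {
  cc <- make_conductivity_curve(35.5, 70, 30, 120, n_points = 16,
                                rel_noise = 0.01, seed = 3)
  f0 <- fit_segmented(cc, n_boot = 0)
  f_kappa <- fit_segmented(conductivity_curve(cc$concentrations,
                                              cc$kappa * 3.7), n_boot = 0)
  expect_equal(f_kappa$cmc, f0$cmc, tolerance = 1e-10)
  f_conc <- fit_segmented(conductivity_curve(cc$concentrations * 0.25,
                                             cc$kappa), n_boot = 0)
  expect_equal(f_conc$cmc, 0.25 * f0$cmc, tolerance = 1e-10)
})

test_that("breakpoint recovery stays within the bootstrap uncertainty", {
  # scaled-down version of the simulation property (30 seeds, 300 resamples)
  hits <- 0L
  for (s in 1:30) {
    cc <- make_conductivity_curve(35.5, 70, 30, 120, n_points = 16,
                                  rel_noise = 0.01, seed = 1000 + s)
    fit <- fit_segmented(cc, n_boot = 300, seed = s)
    if (abs(fit$cmc - 35.5) <= 2 * fit$cmc_SD) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)
})

test_that("bootstrap is reproducible given a seed", {
  cc <- make_conductivity_curve(26.2, 70, 30, 100, n_points = 16,
                                rel_noise = 0.01, seed = 4)
  f1 <- fit_segmented(cc, n_boot = 100, seed = 42)
  f2 <- fit_segmented(cc, n_boot = 100, seed = 42)
  expect_identical(f1$cmc_SD, f2$cmc_SD)
})
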