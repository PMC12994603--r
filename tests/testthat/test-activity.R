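test_that("ionic strength is half the sum of c z^2", {
  expect_equal(ionic_strength(list(conc = c(0.15, 0.15), z = c(1, -1))), 0.15)
  expect_equal(ionic_strength(list(conc = c(0.10, 0.10), z = c(1, -1))), 0.10)
  # 0.05 M monovalent + 0.025 M divalent: 0.5*(0.05 + 0.025*4) = 0.075
  expect_equal(ionic_strength(list(conc = c(0.05, 0.025), z = c(1, -2))),
               0.075)
  expect_error(ionic_strength(list(conc = c(-0.1, 0.1), z = c(1, -1))),
               "negative")
})

test_that("Davies and salting-out coefficients evaluate as documented", {
  am <- activity_model()
  expect_equal(log_gamma(1, 0.15, am), -0.119, tolerance = 5e-3)
  expect_equal(squiet(log_gamma(0, 1.0, am)), 0.42)
  expect_equal(log_gamma(2, 0, am), 0)
  # continuous and non-increasing in I for charged species up to the
  # turning point of the Davies form (the linear 0.3 I term makes log gamma
  # rise again slightly above I ~ 0.39, so the monotone range ends there)
  for (z in 1:3) {
    lg <- vapply(seq(0, 0.35, length.out = 51), function(I)
      log_gamma(z, I, am), 0)
    expect_true(all(diff(lg) <= 1e-12))
  }
})

test_that("constant rescaling is symmetric and matches hand values", {
  am <- activity_model()
  # no-op at the reference ionic strength
  expect_identical(scale_logK(-2.338, c(1, 1), c(1, -1), 0.15, am), -2.338)
  # neutral-only reactions with Ks = 0 never shift
  am0 <- activity_model(Ks_neutral = 0)
  expect_equal(scale_logK(3.1, c(1, -1), c(0, 0), 0.45, am0), 3.1)
  # 1:1 salt of monovalent ions, 0.15 -> 0.50: logKsp shifts +0.031,
  # i.e. pKsp(BHCl) drops from 2.338 to about 2.307
  shift <- scale_logK(-2.338, c(1, 1), c(1, -1), 0.50, am) - (-2.338)
  expect_equal(shift, 0.0306, tolerance = 2e-3)
  # round-trip identity to 1e-12 across random reactions
  set.seed(11)
  for (i in 1:25) {
    nu <- sample(-3:3, 4, replace = TRUE)
    z <- sample(-3:3, 4, replace = TRUE)
    I <- runif(1, 0, 0.5)
    k0 <- runif(1, -10, 10)
    k1 <- scale_logK(k0, nu, z, I, am)
    expect_equal(scale_logK(k1, nu, z, am$I_ref, am, I_from = I), k0,
                 tolerance = 1e-12)
  }
})

test_that("operational pH converts to pcH and back", {
  expect_equal(operational_to_pcH(7.40, electrode_params()), 7.40,
               tolerance = 1e-10)
  expect_equal(operational_to_pcH(7.49, electrode_params(alpha = 0.09)),
               7.40, tolerance = 1e-10)
  expect_equal(operational_to_pcH(9.90, electrode_params(ks = 0.99)),
               10.00, tolerance = 1e-10)
  # exact inverse of the forward map including junction terms
  ep <- electrode_params(alpha = 0.08, ks = 0.995, jH = 0.5, jOH = -0.8,
                         pKw = 13.764)
  for (pcH in seq(0.5, 13, by = 0.5)) {
    reading <- pcH_to_operational(pcH, ep)
    expect_equal(operational_to_pcH(reading, ep), pcH, tolerance = 1e-10)
  }
  expect_error(operational_to_pcH(20, electrode_params()), "out of range")
  expect_error(electrode_params(ks = 0.5))
})

test_that("Davies use beyond 0.5 mol/L warns once per session", {
  phsolv:::reset_davies_warning()
  expect_warning(log_gamma(1, 1.7, activity_model()), "Davies")
  expect_no_warning(log_gamma(1, 1.7, activity_model()))
})
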