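make_noiseless_set <- function(model, recipe, grid, free) {
  cur <- squiet(simulate_logS_curve(recipe, model, grid))
  sat <- !cur$subsaturated
  titration_set("noiseless", recipe,
                data.frame(pcH = cur$pcH[sat], logS = cur$logS_model[sat],
                           sigma = 0.05),
                free = free)
}

test_that("noiseless data are refit exactly (zero-residual fit)", {
  m <- model_noact()
  d <- titration_designs(m)
  truth <- d$set3$truth
  truth$activity <- activity_model("none")
  ts <- make_noiseless_set(truth, d$set3$recipe,
                           seq(7.5, 11.5, length.out = 6), free = "pS0")
  start <- update_constants(truth, constants = c(pS0 = 4.2))
  res <- refine(ts, start)
  expect_equal(unname(res$estimates["pS0"]), 4.602, tolerance = 1e-4)
  expect_lt(res$GOF, 1e-6)
  expect_equal(res$n, 6)
})

test_that("zero-weight flags are equivalent to deleting the rows", {
  m <- model_noact()
  d <- titration_designs(m)
  truth <- d$set3$truth
  truth$activity <- activity_model("none")
  grid <- seq(7.5, 11.5, length.out = 8)
  des <- synthetic_design(d$set3$recipe, grid, truth, noise_sd = 0.05,
                          seed = 5, free = "pS0")
  ts <- make_titration_set(des)
  obs <- ts$observations
  flagged <- obs
  flagged$flag[7:8] <- "outlier_zero_weight"
  ts_flag <- titration_set("f", d$set3$recipe, flagged, free = "pS0")
  ts_cut <- titration_set("c", d$set3$recipe, obs[1:6, ], free = "pS0")
  start <- update_constants(truth, constants = c(pS0 = 4.4))
  r1 <- refine(ts_flag, start)
  r2 <- refine(ts_cut, start)
  expect_equal(r1$estimates, r2$estimates, tolerance = 1e-8)
  expect_equal(r1$n, r2$n)
})

test_that("refinement guards and objective monotonicity", {
  m <- model_noact()
  d <- titration_designs(m)
  truth <- d$set3$truth
  truth$activity <- activity_model("none")
  ts <- make_noiseless_set(truth, d$set3$recipe, c(8, 9, 10),
                           free = c("pS0", "logK310", "logK750"))
  expect_error(refine(ts, truth), class = "phsolv_underdetermined_error")
  ts2 <- make_noiseless_set(truth, d$set3$recipe,
                            seq(7.5, 11.5, length.out = 7), free = "pS0")
  set.seed(99)
  ts2$observations$logS <- ts2$observations$logS + stats::rnorm(7, 0, 0.05)
  res <- refine(ts2, update_constants(truth, constants = c(pS0 = 4.3)))
  expect_true(all(diff(res$trace) <= 0))
  empty <- ts2; empty$free <- character()
  expect_error(refine(empty, truth), class = "phsolv_input_error")
})

test_that("refined constants are recovered without bias at the assigned noise", {
  # scaled-down recovery study: activity off for speed, pS0 + trimer free
  m <- model_noact()
  d <- titration_designs(m)
  truth <- d$set3$truth
  truth$activity <- activity_model("none")
  grid <- seq(7.4, 11.9, length.out = 8)
  est <- sd_ <- numeric(10)
  for (i in seq_along(est)) {
    ts <- make_titration_set(synthetic_design(
      d$set3$recipe, grid, truth, noise_sd = 0.05, seed = 300 + i,
      free = c("pS0", "logK310")))
    start <- update_constants(truth, constants = c(pS0 = 4.8, logK310 = 8.5))
    r <- refine(ts, start)
    est[i] <- r$estimates[["pS0"]]
    sd_[i] <- r$SDs[["pS0"]]
  }
  expect_lt(abs(mean(est) - 4.602), mean(sd_))
  # roughly nominal coverage at +/- 2 SD
  expect_gte(mean(abs(est - 4.602) <= 2 * sd_), 0.8)
})

test_that("inverse-variance pooling follows 1/SD^2 weights", {
  pm <- pool_weighted_mean(c(1, 3), c(0.1, 0.1))
  expect_equal(pm$mean, 2)            # equal SDs: arithmetic mean
  expect_equal(pm$SD, 0.1 / sqrt(2))
  expect_error(pool_weighted_mean(numeric(0), numeric(0)),
               class = "phsolv_domain_error")
  expect_error(pool_weighted_mean(c(1, 2), c(0.1, -0.1)),
               class = "phsolv_input_error")
})

test_that("joint refinement of two sets concatenates their observations", {
  m <- model_noact()
  d <- titration_designs(m)
  truth <- d$set3$truth
  truth$activity <- activity_model("none")
  grid <- seq(7.5, 11.5, length.out = 5)
  tsA <- make_titration_set(synthetic_design(d$set3$recipe, grid, truth,
                                             noise_sd = 0.05, seed = 21,
                                             free = "pS0", name = "A"))
  tsB <- make_titration_set(synthetic_design(d$set3$recipe, grid, truth,
                                             noise_sd = 0.05, seed = 22,
                                             free = "pS0", name = "B"))
  start <- update_constants(truth, constants = c(pS0 = 4.4))
  res <- refine(list(tsA, tsB), start)
  expect_equal(res$n, 10)
  expect_equal(unname(res$estimates["pS0"]), 4.602, tolerance = 0.1)
})
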