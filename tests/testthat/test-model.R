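test_that("default model carries the pooled constants and validates", {
  m <- build_default_model()
  k <- m$constants
  expect_equal(unname(k["pKa"]), 9.52)
  expect_equal(unname(k["pS0"]), 4.602)
  expect_equal(unname(k["pKsp_BHCl"]), 2.338)
  expect_equal(unname(k["pKsp_BHH2PO4"]), 2.823)
  expect_equal(unname(k["pKsp_BH2HPO4"]), 6.812)
  expect_equal(unname(k["logK310"]), 8.728)
  expect_equal(unname(k["logK750"]), 9.970)
  expect_equal(unname(k["logK141"]), 0.374)
  expect_identical(validate_model(m), character(0))
})

test_that("validator reports charged solids, bad species charges, orphans", {
  m <- build_default_model()
  m2 <- m
  m2$solids[[1]]$n_cl <- 0  # BHCl without its chloride: net +1
  v <- validate_model(m2)
  expect_length(v, 1)
  expect_match(v, "BHCl")
  expect_match(v, "charge")

  m3 <- m
  m3$species[[7]]$charge <- 2L  # trimer is +1 = n_h - 3 n_p
  v3 <- validate_model(m3)
  expect_length(v3, 1)
  expect_match(v3, "B3H")

  # pKw is not housed in any species/solid: marking it free is an orphan
  v4 <- validate_model(update_constants(m, free = "pKw"))
  expect_length(v4, 1)
  expect_match(v4, "pKw")

  # a fixed constant must not carry an SD
  m5 <- m
  m5$sd[["pKa"]] <- 0.01
  expect_match(validate_model(m5), "pKa")

  # every tabulated refinable constant is housed in exactly one
  # species/solid: freeing them all at once must raise no violation
  refinables <- c("pKa", "pS0", "pKsp_BHCl", "pKsp_BHH2PO4",
                  "pKsp_BH2HPO4", "logK310", "logK750", "logK141")
  expect_identical(validate_model(update_constants(m, free = refinables)),
                   character(0))
})

test_that("Set-5 context marks pKsp(BHCl) refinable with SD 0.02", {
  d <- titration_designs()
  truth5 <- d$set5$truth
  expect_false(truth5$fixed[["pKsp_BHCl"]])
  expect_equal(unname(truth5$sd["pKsp_BHCl"]), 0.02)
  expect_equal(unname(truth5$constants["pKsp_BHCl"]), 2.338)
})

test_that("configuration round-trips byte-identically", {
  m <- build_default_model()
  f1 <- tempfile(fileext = ".ini")
  f2 <- tempfile(fileext = ".ini")
  write_model_config(m, f1)
  m2 <- read_model_config(f1)
  write_model_config(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(m$constants, m2$constants)
  # the bundled default is the writer's own serialisation
  bundled <- system.file("extdata", "imipramine_default.ini",
                         package = "phsolv")
  expect_identical(readLines(bundled), readLines(f1))
  # recipes survive the round trip
  m$recipes <- list(set3 = titration_designs(m)$set3$recipe)
  f3 <- tempfile(); f4 <- tempfile()
  write_model_config(m, f3)
  write_model_config(read_model_config(f3), f4)
  expect_identical(readLines(f3), readLines(f4))
})

test_that("medium recipes enforce their invariants", {
  expect_error(medium_recipe(-0.1), "non-negative")
  expect_error(medium_recipe(0.2, C_Cl_total = 0.1,
                             starting_material = "salt_BHCl"),
               "one chloride per drug")
  r <- medium_recipe(0.164, C_Cl_total = 0.314, C_Na_total = 0.15,
                     starting_material = "salt_BHCl")
  expect_s3_class(r, "medium_recipe")
  expect_error(update_constants(build_default_model(),
                                constants = c(nope = 1)), "unknown constant")
})

test_that("bundled designs reproduce the stated mass-to-volume recipes", {
  d <- titration_designs()
  # 52 mg/mL hydrochloride -> 0.164 mol/L
  expect_equal(d$set3$recipe$C_B_total, 0.164, tolerance = 2e-3)
  # 57 mg/mL hydrochloride -> 0.180 mol/L; chloride = drug + 0.049 M HCl
  expect_equal(d$set1_2$recipe$C_B_total, 0.1799, tolerance = 2e-3)
  expect_equal(d$set1_2$recipe$C_Cl_total - d$set1_2$recipe$C_B_total, 0.049)
  # 71 mg/mL free base in 1.70 M NaCl
  expect_equal(d$set5$recipe$C_B_total, 0.2532, tolerance = 2e-3)
  expect_equal(d$set5$recipe$C_Cl_total, 1.70)
  # per-set truth constants as tabulated
  expect_equal(unname(d$set6$truth$constants["pKsp_BHH2PO4"]), 2.829)
  expect_equal(unname(d$set1_2$truth$constants["logK750"]), 8.165)
})
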