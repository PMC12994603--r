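test_that("monomer speciation obeys the pKa with solids disabled", {
  m <- no_solids(no_aggregates(model_noact()))
  r <- medium_recipe(1e-4, starting_material = "free_base")
  st <- solve_at_fixed_pcH(r, m, 9.52)
  expect_equal(unname(st$species["B"]), 5e-5, tolerance = 1e-9)
  expect_equal(unname(st$species["BH"]), 5e-5, tolerance = 1e-9)
  st2 <- solve_at_fixed_pcH(r, m, 7.52)
  expect_equal(unname(st2$species["BH"] / st2$species["B"]), 100,
               tolerance = 1e-9)
})

test_that("mass balances and charge balance hold on converged states", {
  m <- build_default_model()
  d <- titration_designs(m)
  cases <- list(
    list(r = d$set3$recipe, pcH = c(5.0, 7.5, 9.0, 11.5)),
    list(r = d$set5$recipe, pcH = c(3.0, 6.0, 7.9)),
    list(r = d$set6$recipe, pcH = c(2.6, 4.5, 6.3)),
    list(r = d$set1_2$recipe, pcH = c(4.0, 6.5, 10.5)))
  for (cs in cases) {
    for (p in cs$pcH) {
      st <- squiet(solve_at_fixed_pcH(cs$r, m, p))
      sp <- st$species
      cm <- phsolv:::compile_model(m)
      nb <- cm$species$nb; np <- cm$species$np
      solids <- stats::setNames(rep(0, length(cm$solids$name)),
                                cm$solids$name)
      solids[names(st$solids)] <- st$solids
      B_tot <- sum(nb * sp[cm$species$name]) + sum(cm$solids$nb * solids)
      expect_equal(B_tot, cs$r$C_B_total, tolerance = 1e-10)
      if (cs$r$C_P_total > 0) {
        P_tot <- sum(np * sp[cm$species$name]) + sum(cm$solids$np * solids)
        expect_equal(P_tot, cs$r$C_P_total, tolerance = 1e-10)
      }
      if (cs$r$C_Cl_total > 0) {
        Cl_tot <- sp[["Cl"]] + sum(cm$solids$ncl * solids)
        expect_equal(Cl_tot, cs$r$C_Cl_total, tolerance = 1e-10)
      }
      # electroneutrality including the titrant slack ion
      net <- sum(st$species * st$charges)
      expect_lt(abs(net), 1e-10 * sum(st$species * abs(st$charges)) + 1e-15)
      # every present solid is exactly saturated, none is supersaturated
      si <- saturation_index(st, m)
      expect_true(all(si[st$solids_present] > -1e-6 &
                        si[st$solids_present] < 1e-6))
      expect_true(all(si[setdiff(names(si), st$solids_present)] < 1e-6))
    }
  }
})

test_that("solver matches the closed-form two-component toy to 1e-8", {
  m <- no_aggregates(model_noact())
  m <- update_constants(m, constants = c(pS0 = -Inf, pKsp_BHH2PO4 = -Inf,
                                         pKsp_BH2HPO4 = -Inf))
  for (C_B in c(0.05, 0.2)) {
    for (pcH in c(3, 4.5, 6, 7)) {
      r <- medium_recipe(C_B, C_Cl_total = 1.7, C_Na_total = 1.7,
                         starting_material = "free_base")
      st <- solve_at_fixed_pcH(r, m, pcH)
      expect_equal(st$S_dissolved, toy_BCl_solubility(C_B, 1.7, pcH),
                   tolerance = 1e-8)
    }
  }
})

test_that("phase selection leaves unsaturated states alone and sits on the boundary", {
  m <- no_aggregates(model_noact())
  # far below saturation: no solid
  r <- medium_recipe(1e-5, C_Cl_total = 0.01 + 1e-5, C_Na_total = 0.01,
                     starting_material = "salt_BHCl")
  st <- solve_at_fixed_pcH(r, m, 5)
  expect_length(st$solids_present, 0)
  expect_equal(st$S_dissolved, 1e-5, tolerance = 1e-10)
  # [BH+][Cl-] = Ksp at the zero-amount boundary: SI = 0 within grid noise
  C_Cl <- 0.15
  C_B <- 10^(-2.338) / C_Cl
  rb <- medium_recipe(C_B, C_Cl_total = C_Cl, C_Na_total = C_Cl,
                      starting_material = "free_base")
  stb <- solve_at_fixed_pcH(rb, m, 4)
  si <- saturation_index(stb, m)
  expect_lt(abs(si[["BHCl"]]), 1e-3)
  if (length(stb$solids_present)) {
    expect_lt(stb$solids[["BHCl"]], 1e-3 * C_B)
  }
})

test_that("the hydrochloride controls a Set-5-like acidic suspension", {
  m <- build_default_model()
  r <- medium_recipe(0.2, C_Cl_total = 1.70, C_Na_total = 1.70,
                     starting_material = "free_base")
  st <- squiet(solve_at_fixed_pcH(r, m, 3.0))
  expect_identical(st$solids_present, "BHCl")
  # order of magnitude set by Ksp/[Cl-]
  expect_equal(st$S_dissolved, 10^(-2.338) / 1.70, tolerance = 0.5)
})

test_that("simulated curves flag subsaturation and stay continuous", {
  m <- build_default_model()
  # all solids disabled: every point subsaturated
  r <- medium_recipe(1e-3, C_Cl_total = 0.15 + 1e-3, C_Na_total = 0.15,
                     starting_material = "salt_BHCl")
  cur <- simulate_logS_curve(r, no_solids(m), seq(4, 10, 1))
  expect_true(all(cur$subsaturated))
  expect_true(all(cur$logS_model == log10(1e-3)))
  # continuity across the dihydrogen -> hydrogen phosphate transition:
  # at 0.01 pcH spacing no step may exceed its neighbours by more than
  # 1e-3 (the curve itself has slope ~0.25/pH unit, so absolute steps are
  # ~2.5e-3; a phase-boundary discontinuity would show up as a spike)
  d <- titration_designs(m)
  fine <- squiet(simulate_logS_curve(d$set6$recipe, m, seq(5.7, 6.3, 0.01)))
  expect_true(any(fine$solids_present == "BHH2PO4") &&
                any(fine$solids_present == "BH2HPO4"))
  steps <- abs(diff(fine$logS_model))
  k <- length(steps)
  spike <- steps[2:(k - 1)] - pmax(steps[1:(k - 2)], steps[3:k])
  expect_lt(max(spike), 1e-3)
  expect_lt(max(steps), 0.02)
  expect_error(simulate_logS_curve(r, m, c(5, 4)), "sorted")
})

test_that("aggregates-off/activity-off profile equals Henderson-Hasselbalch", {
  m <- no_aggregates(model_noact())
  m <- update_constants(m, constants = c(pKsp_BHCl = -Inf,
                                         pKsp_BHH2PO4 = -Inf,
                                         pKsp_BH2HPO4 = -Inf))
  r <- medium_recipe(0.164, C_Cl_total = 0.314, C_Na_total = 0.15,
                     starting_material = "salt_BHCl")
  cur <- simulate_logS_curve(r, m, seq(7.45, 11.5, 0.25))
  expect_true(all(cur$solids_present == "B_s"))
  expect_lt(max(abs(cur$logS_model - cur$logS_HH)), 1e-9)
})

test_that("Henderson-Hasselbalch reference values", {
  expect_equal(henderson_hasselbalch_logS(13.5, 4.602, 9.52), -4.602,
               tolerance = 1e-4)
  expect_equal(henderson_hasselbalch_logS(9.52, 4.602, 9.52),
               -4.602 + log10(2))
  expect_equal(henderson_hasselbalch_logS(7.52, 4.602, 9.52),
               -4.602 + log10(101))
})

test_that("common-ion effect: BHCl-controlled solubility falls with chloride", {
  m <- no_aggregates(build_default_model())
  S <- vapply(seq(0.5, 2.5, by = 0.25), function(cl) {
    r <- medium_recipe(0.3, C_Cl_total = cl, C_Na_total = cl,
                       starting_material = "free_base")
    st <- squiet(solve_at_fixed_pcH(r, m, 4.0))
    expect_identical(st$solids_present, "BHCl")
    st$S_dissolved
  }, 0)
  expect_true(all(diff(S) < 0))
})

test_that("pHmax matches its closed form and guards its domain", {
  m <- build_default_model()
  # pKa + log10(S0 [Cl] / Ksp), activity off
  expect_equal(compute_pHmax(m, "BHCl", "B_s", anchors = list(Cl = 1.70)),
               9.52 + log10(10^-4.602 * 1.70 / 10^-2.338),
               tolerance = 1e-6)
  # one log unit less chloride moves the boundary one unit down
  expect_equal(compute_pHmax(m, "BHCl", "B_s", anchors = list(Cl = 0.17)),
               9.52 + log10(10^-4.602 * 0.17 / 10^-2.338),
               tolerance = 1e-6)
  expect_error(compute_pHmax(m, "BHCl", "BHCl", anchors = list(Cl = 1)),
               class = "phsolv_domain_error")
  # phosphate solid pair brackets the Set-6 transition window
  ph <- compute_pHmax(m, "BHH2PO4", "BH2HPO4", anchors = list(P = 1.5))
  expect_gt(ph, 4.5)
  expect_lt(ph, 7)
})

test_that("select_solid_phases re-derives the solid inventory of a state", {
  m <- build_default_model()
  d <- titration_designs(m)
  st <- squiet(solve_at_fixed_pcH(d$set5$recipe, m, 3.0))
  st2 <- squiet(select_solid_phases(st, m))
  expect_identical(st2$solids_present, st$solids_present)
  expect_equal(st2$S_dissolved, st$S_dissolved, tolerance = 1e-9)
})
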