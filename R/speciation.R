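# Mass-balance speciation solver with automatic solid-phase selection and
# ionic-strength self-consistency.
#
# Unknowns at fixed pcH, in log10 space for guaranteed positivity: the free
# base lB = log10[B], the free phosphate core lP = log10[PO4(3-)] (when the
# medium contains phosphate), the free chloride lCl (when it contains
# chloride), plus one linear amount per solid currently held at saturation.
# Residuals: B/P/Cl mass balances scaled by the totals, and one log10
# saturation condition per present solid. The electroneutrality slack
# (strong acid/base titrant, 'Na+ slack') is computed after the fact and
# enters only the ionic strength.

# rescale the compiled constant tables from I_ref to I
scale_compiled <- function(cm, act, I) {
  if (act$form == "none" || abs(I - act$I_ref) < .Machine$double.eps) {
    cm$pKw_I <- cm$pKw
    cm$species$logbeta_I <- cm$species$logbeta
    cm$solids$pKsp_I <- cm$solids$pKsp
    return(cm)
  }
  dlg <- function(z) log_gamma(z, I, act) - log_gamma(z, act$I_ref, act)
  sp <- cm$species
  # formation from core components B (neutral), H+ (z=1), PO4 (z=-3)
  sp$logbeta_I <- sp$logbeta -
    (dlg(sp$z) - sp$nb * dlg(0) - sp$nh * dlg(1) - sp$np * dlg(-3))
  so <- cm$solids
  zmap <- c(stats::setNames(sp$z, sp$name), Cl = -1)
  so$pKsp_I <- so$pKsp
  for (i in seq_along(so$name)) {
    e <- so$iap[[i]]
    so$pKsp_I[i] <- so$pKsp[i] + sum(e * dlg(zmap[names(e)]))
  }
  cm$pKw_I <- cm$pKw + 2 * dlg(1)
  cm$species <- sp
  cm$solids <- so
  cm
}

# log10 concentrations of the registry species given the core unknowns
species_logc <- function(cm, lB, lP, lH, has_P) {
  sp <- cm$species
  lPe <- if (has_P) lP else 0   # avoid 0 * -Inf = NaN; masked below
  lc <- cm$species$logbeta_I + sp$nb * lB + sp$nh * lH + sp$np * lPe
  if (!has_P) lc[sp$np > 0] <- -Inf
  names(lc) <- sp$name
  lc
}

solid_log_iap <- function(cm, i, logc, lCl) {
  e <- cm$solids$iap[[i]]
  lc <- c(logc, Cl = lCl)
  sum(e * lc[names(e)])
}

# Damped Newton solve at fixed pcH and fixed ionic strength for a given
# set of present solids. Returns list(lB, lP, lCl, m, conc, converged, iter).
newton_solve <- function(cm, recipe, pcH, present, control,
                         start = NULL) {
  sp <- cm$species
  C_B <- recipe$C_B_total; C_P <- recipe$C_P_total; C_Cl <- recipe$C_Cl_total
  has_P <- C_P > 0; has_Cl <- C_Cl > 0
  lH <- -pcH
  sidx <- match(present, cm$solids$name)
  npres <- length(sidx)
  active <- rep(TRUE, length(sp$name))
  if (!has_P) active <- active & sp$np == 0

  # layout of the unknown vector
  iB <- 1L
  iP <- if (has_P) 2L else 0L
  iCl <- if (has_Cl) (if (has_P) 3L else 2L) else 0L
  nu <- 1L + (has_P) + (has_Cl) + npres
  im <- if (npres) (nu - npres + 1L):nu else integer(0)

  r0 <- 10^(cm$species$logbeta_I[["BH"]] + lH)  # BH+/B ratio
  u <- numeric(nu)
  u[iB] <- log10(C_B / (1 + r0))
  if (has_P) {
    denom <- sum(10^(sp$logbeta_I[sp$np == 1 & sp$nb == 0] +
                       sp$nh[sp$np == 1 & sp$nb == 0] * lH))
    u[iP] <- log10(C_P / denom)
  }
  if (has_Cl) u[iCl] <- log10(C_Cl)
  if (!is.null(start)) {
    u[iB] <- start$lB
    if (has_P && is.finite(start$lP)) u[iP] <- start$lP
    if (has_Cl && is.finite(start$lCl)) u[iCl] <- start$lCl
  }

  resid <- function(u) {
    lB <- u[iB]
    lP <- if (has_P) u[iP] else -Inf
    lCl <- if (has_Cl) u[iCl] else -Inf
    m <- if (npres) u[im] else numeric(0)
    logc <- species_logc(cm, lB, lP, lH, has_P)
    conc <- 10^logc
    Fv <- (sum(sp$nb * conc, na.rm = TRUE) +
             (if (npres) sum(cm$solids$nb[sidx] * m) else 0) - C_B) / C_B
    if (has_P) {
      Fv <- c(Fv, (sum(sp$np * conc, na.rm = TRUE) +
                     (if (npres) sum(cm$solids$np[sidx] * m) else 0) - C_P) / C_P)
    }
    if (has_Cl) {
      Fv <- c(Fv, (10^lCl +
                     (if (npres) sum(cm$solids$ncl[sidx] * m) else 0) - C_Cl) / C_Cl)
    }
    for (k in seq_len(npres)) {
      Fv <- c(Fv, solid_log_iap(cm, sidx[k], logc, lCl) + cm$solids$pKsp_I[sidx[k]])
    }
    list(F = Fv, conc = conc, logc = logc, lB = lB, lP = lP, lCl = lCl, m = m)
  }

  jac <- function(st) {
    conc <- st$conc
    conc[!is.finite(conc)] <- 0
    J <- matrix(0, nu, nu)
    ln10 <- log(10)
    row <- 1L
    J[row, iB] <- ln10 * sum(sp$nb^2 * conc) / C_B
    if (has_P) J[row, iP] <- ln10 * sum(sp$nb * sp$np * conc) / C_B
    for (k in seq_len(npres)) J[row, im[k]] <- cm$solids$nb[sidx[k]] / C_B
    if (has_P) {
      row <- row + 1L
      J[row, iB] <- ln10 * sum(sp$np * sp$nb * conc) / C_P
      J[row, iP] <- ln10 * sum(sp$np^2 * conc) / C_P
      for (k in seq_len(npres)) J[row, im[k]] <- cm$solids$np[sidx[k]] / C_P
    }
    if (has_Cl) {
      row <- row + 1L
      J[row, iCl] <- ln10 * 10^st$lCl / C_Cl
      for (k in seq_len(npres)) J[row, im[k]] <- cm$solids$ncl[sidx[k]] / C_Cl
    }
    for (k in seq_len(npres)) {
      row <- row + 1L
      e <- cm$solids$iap[[sidx[k]]]
      enb <- enp <- ecl <- 0
      for (nm in names(e)) {
        if (nm == "Cl") { ecl <- ecl + e[[nm]]; next }
        j <- match(nm, sp$name)
        enb <- enb + e[[nm]] * sp$nb[j]
        enp <- enp + e[[nm]] * sp$np[j]
      }
      J[row, iB] <- enb
      if (has_P) J[row, iP] <- enp
      if (has_Cl) J[row, iCl] <- ecl
    }
    J
  }

  st <- resid(u)
  fn <- max(abs(st$F))
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_newton) {
    iter <- iter + 1L
    if (fn < control$tol_mass) { converged <- TRUE; break }
    J <- jac(st)
    step <- tryCatch(solve(J, -st$F), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- tryCatch(qr.solve(J + diag(1e-12, nu), -st$F),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    # cap log-space moves to keep Newton in its basin
    lg <- setdiff(seq_len(nu), im)
    cap <- max(abs(step[lg]), 0)
    if (cap > 3) step <- step * (3 / cap)
    lambda <- 1
    improved <- FALSE
    for (ls in 1:12) {
      st_new <- resid(u + lambda * step)
      fn_new <- max(abs(st_new$F))
      if (is.finite(fn_new) && fn_new < fn) {
        u <- u + lambda * step; st <- st_new; fn <- fn_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # accept a stagnating full step once in a while to escape plateaus
      st_new <- resid(u + step)
      if (all(is.finite(st_new$F))) {
        u <- u + step; st <- st_new; fn <- max(abs(st$F))
      } else break
    }
  }
  if (!converged && fn < 1e3 * control$tol_mass) converged <- TRUE
  list(lB = st$lB, lP = st$lP, lCl = st$lCl, m = st$m, conc = st$conc,
       logc = st$logc, F = st$F, converged = converged, iter = iter)
}

# candidate solids applicable to a medium
applicable_solids <- function(cm, recipe) {
  keep <- rep(TRUE, length(cm$solids$name))
  if (recipe$C_Cl_total <= 0) keep <- keep & cm$solids$ncl == 0
  if (recipe$C_P_total <= 0) keep <- keep & cm$solids$np == 0
  cm$solids$name[keep]
}

saturation_indices <- function(cm, sol, candidates) {
  vapply(candidates, function(nm) {
    i <- match(nm, cm$solids$name)
    solid_log_iap(cm, i, sol$logc, sol$lCl) + cm$solids$pKsp_I[i]
  }, 0)
}

# phase-selection loop at fixed ionic strength
solve_phases <- function(cm, recipe, pcH, control, start = NULL) {
  candidates <- applicable_solids(cm, recipe)
  present <- character(0)
  si_history <- list()
  sol <- newton_solve(cm, recipe, pcH, present, control, start = start)
  if (!sol$converged) {
    phsolv_error("phsolv_solver_error",
                 sprintf("speciation solver did not converge at pcH %.3f (residual %.3g after %d iterations)",
                         pcH, max(abs(sol$F)), sol$iter))
  }
  for (it in seq_len(control$max_phase)) {
    if (length(sol$m) && any(sol$m < -1e-12)) {
      drop <- present[which.min(sol$m)]
      present <- setdiff(present, drop)
      sol <- newton_solve(cm, recipe, pcH, present, control, start = sol)
      next
    }
    si <- saturation_indices(cm, sol, setdiff(candidates, present))
    si_history[[it]] <- si
    over <- si[si > control$tol_si]
    if (!length(over)) {
      # phase-rule check on the final assemblage: more than two coexisting
      # drug-bearing solids is not a physical equilibrium here
      drug_bearing <- sum(cm$solids$nb[match(present, cm$solids$name)] > 0 &
                            sol$m > control$tol_mass)
      if (drug_bearing > 2) {
        phsolv_error("phsolv_phase_error",
                     sprintf("%d drug-bearing solids coexist at pcH %.3f",
                             drug_bearing, pcH))
      }
      return(list(sol = sol, present = present))
    }
    add <- names(over)[which.max(over)]
    present <- c(present, add)
    sol <- newton_solve(cm, recipe, pcH, present, control, start = sol)
    if (!sol$converged) {
      phsolv_error("phsolv_solver_error",
                   sprintf("saturated solve did not converge at pcH %.3f with solids [%s]",
                           pcH, paste(present, collapse = ", ")))
    }
  }
  phsolv_error("phsolv_phase_error",
               paste0("phase selection oscillated at pcH ", signif(pcH, 6),
                      "; SI history: ",
                      paste(vapply(si_history, function(s)
                        paste(sprintf("%s=%.3g", names(s), s), collapse = ","),
                        ""), collapse = " | ")))
}

# assemble the public state object
build_state <- function(cm, recipe, pcH, sol, present, I, model) {
  sp <- cm$species
  conc <- sol$conc
  conc[!is.finite(conc)] <- 0
  names(conc) <- sp$name
  H <- 10^(-pcH)
  OH <- 10^(pcH - cm$pKw_I)
  Cl <- if (recipe$C_Cl_total > 0) 10^sol$lCl else 0
  Na <- recipe$C_Na_total
  allc <- c(conc, H = H, OH = OH, Cl = Cl, Na = Na)
  allz <- c(sp$z, H = 1, OH = -1, Cl = -1, Na = 1)
  net <- sum(allc * allz)
  # titrant slack: excess positive charge is balanced by a monovalent anion
  # (acid titrant), excess negative charge by a monovalent cation (base)
  allc <- c(allc, X = abs(net))
  allz <- c(allz, X = -sign(net))
  m <- stats::setNames(rep(0, length(cm$solids$name)), cm$solids$name)
  if (length(present)) m[present] <- sol$m
  S_dis <- sum(sp$nb * conc)
  structure(
    list(pcH = pcH,
         free = allc[c("H", "OH", "B", "Cl", "Na", "PO4", "X")],
         species = allc, charges = allz,
         solids = m[m != 0 | names(m) %in% present],
         solids_present = present,
         I = I,
         S_dissolved = S_dis,
         saturated = length(present) > 0,
         recipe = recipe,
         newton_iter = sol$iter,
         internal = list(lB = sol$lB, lP = sol$lP, lCl = sol$lCl)),
    class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> pcH %.3f, I %.4f mol/L\n", x$pcH, x$I))
  cat(sprintf("  dissolved drug S = %.6g mol/L (log S = %.4f)\n",
              x$S_dissolved, log10(x$S_dissolved)))
  if (length(x$solids_present)) {
    cat("  solids:", paste(sprintf("%s (%.4g mol/L)", names(x$solids),
                                   x$solids), collapse = ", "), "\n")
  } else cat("  solids: none (subsaturated)\n")
  invisible(x)
}

#' Solve the speciation problem at fixed pcH
#'
#' Finds the free concentrations satisfying the drug, phosphate and chloride
#' mass balances at the given pcH, precipitating solids as required
#' (largest-positive-saturation-index first) and iterating the activity
#' corrections until the ionic strength is self-consistent. The strong
#' acid/base titrant that holds the suspension at this pcH is represented
#' by an electroneutrality slack ion that contributes to the ionic strength
#' only.
#'
#' @param recipe A [medium_recipe()].
#' @param model A `speciation_model`.
#' @param pcH Concentration-scale pcH.
#' @param control See [solver_control()].
#' @return An `equilibrium_state` with free/derived concentrations, solid
#'   inventory (mol per litre of suspension), ionic strength and total
#'   dissolved drug `S_dissolved`.
#' @export
#' @examples
#' m <- build_default_model()
#' r <- medium_recipe(1e-4, starting_material = "free_base")
#' st <- solve_at_fixed_pcH(r, m, pcH = 9.52)
solve_at_fixed_pcH <- function(recipe, model, pcH,
                               control = solver_control()) {
  if (!inherits(recipe, "medium_recipe")) {
    phsolv_error("phsolv_input_error", "recipe must be a medium_recipe")
  }
  cm <- compile_model(model)
  act <- model$activity
  if (act$form == "none") {
    cm_I <- scale_compiled(cm, act, act$I_ref)
    ph <- solve_phases(cm_I, recipe, pcH, control)
    st <- build_state(cm_I, recipe, pcH, ph$sol, ph$present, NA_real_, model)
    st$I <- ionic_strength(st)
    return(st)
  }
  I <- max(act$I_ref,
           0.5 * (recipe$C_Na_total + recipe$C_Cl_total) + recipe$C_P_total)
  start <- NULL
  st <- NULL
  for (it in seq_len(control$max_I)) {
    cm_I <- scale_compiled(cm, act, I)
    ph <- solve_phases(cm_I, recipe, pcH, control, start = start)
    st <- build_state(cm_I, recipe, pcH, ph$sol, ph$present, I, model)
    I_new <- ionic_strength(st)
    if (abs(I_new - I) < control$tol_I) {
      st$I <- I_new
      return(st)
    }
    I <- if (it > 10) 0.5 * (I + I_new) else I_new
    start <- ph$sol
  }
  phsolv_error("phsolv_solver_error",
               sprintf("ionic-strength loop did not converge at pcH %.3f (last I %.5f)",
                       pcH, I))
}

#' Re-run solid-phase selection on a trial state
#'
#' Starting from a converged (possibly supersaturated, solid-free) trial
#' state, iteratively precipitates the candidate solid with the largest
#' positive saturation index SI = log10(IAP/Ksp), re-solves, and removes any
#' solid whose amount turns negative, until every SI is at or below the
#' threshold and all amounts are non-negative.
#'
#' @param state An `equilibrium_state`.
#' @param model The `speciation_model` the state was solved under.
#' @param control See [solver_control()].
#' @return The state with its equilibrium solid inventory.
#' @export
select_solid_phases <- function(state, model, control = solver_control()) {
  solve_at_fixed_pcH(state$recipe, model, state$pcH, control)
}

#' Saturation index of each candidate solid in a state
#'
#' @param state An `equilibrium_state`.
#' @param model The model it was solved under.
#' @return Named vector of SI = log10(IAP/Ksp); `-Inf` for solids whose
#'   ions are absent from the medium.
#' @export
saturation_index <- function(state, model) {
  cm <- compile_model(model)
  cm <- scale_compiled(cm, model$activity,
                       if (model$activity$form == "none") model$activity$I_ref
                       else state$I)
  logc <- log10(state$species[cm$species$name])
  names(logc) <- cm$species$name
  lCl <- log10(state$species[["Cl"]])
  vapply(seq_along(cm$solids$name), function(i) {
    solid_log_iap(cm, i, logc, lCl) + cm$solids$pKsp_I[i]
  }, 0, USE.NAMES = FALSE) -> si
  stats::setNames(si, cm$solids$name)
}

#' Simulate a log S - pcH solubility profile
#'
#' Forward-simulates the equilibrium model over a pcH grid. Where at least
#' one drug-bearing solid is present, `logS` is the total dissolved drug at
#' saturation; grid points where no solid forms are flagged subsaturated and
#' report the fully dissolved total. A Henderson-Hasselbalch reference curve
#' (monoprotic base, no aggregation, no activity correction) is included
#' for comparison.
#'
#' @param recipe A [medium_recipe()].
#' @param model A `speciation_model`.
#' @param pcH_grid Ascending numeric vector of pcH values.
#' @param control See [solver_control()].
#' @return A data.frame with columns `pcH`, `logS_model`, `logS_HH`,
#'   `solids_present`, `I`, `subsaturated`.
#' @export
simulate_logS_curve <- function(recipe, model, pcH_grid,
                                control = solver_control()) {
  if (is.unsorted(pcH_grid, strictly = FALSE)) {
    phsolv_error("phsolv_input_error", "pcH grid must be sorted ascending")
  }
  n <- length(pcH_grid)
  logS <- I <- numeric(n)
  solids <- character(n)
  subsat <- logical(n)
  for (i in seq_len(n)) {
    st <- tryCatch(solve_at_fixed_pcH(recipe, model, pcH_grid[i], control),
                   error = function(e) {
                     phsolv_error("phsolv_solver_error",
                                  sprintf("at pcH %.4f: %s", pcH_grid[i],
                                          conditionMessage(e)))
                   })
    drug_solid <- st$solids_present[
      vapply(st$solids_present, function(nm) {
        so <- model$solids[[match(nm, vapply(model$solids, `[[`, "", "name"))]]
        so$n_b > 0
      }, TRUE)]
    if (length(drug_solid)) {
      logS[i] <- log10(st$S_dissolved)
      subsat[i] <- FALSE
    } else {
      logS[i] <- log10(recipe$C_B_total)
      subsat[i] <- TRUE
    }
    solids[i] <- paste(st$solids_present, collapse = "+")
    I[i] <- st$I
  }
  data.frame(
    pcH = pcH_grid,
    logS_model = logS,
    logS_HH = henderson_hasselbalch_logS(pcH_grid,
                                         model$constants[["pS0"]],
                                         model$constants[["pKa"]]),
    solids_present = solids,
    I = I,
    subsaturated = subsat,
    stringsAsFactors = FALSE)
}

#' Henderson-Hasselbalch solubility of a monoprotic base
#'
#' `logS = -pS0 + log10(1 + 10^(pKa - pcH))`: the classical reference curve
#' with no aggregation, no salt limitation and no activity corrections.
#'
#' @param pcH pcH value(s).
#' @param pS0 Negative log10 intrinsic solubility (mol/L).
#' @param pKa Drug pKa.
#' @return logS (log10 mol/L).
#' @export
henderson_hasselbalch_logS <- function(pcH, pS0, pKa) {
  -pS0 + log10(1 + 10^(pKa - pcH))
}

#' pH of simultaneous saturation of two solids (pHmax)
#'
#' Finds the pcH at which two drug-bearing solids are both exactly
#' saturated, given anchor concentrations for the counterion pools: `Cl` is
#' the free chloride (mol/L) and `P` the total dissolved inorganic phosphate
#' (mol/L). With activity corrections off, the BHCl / free-base boundary has
#' the closed form `pHmax = pKa + log10(S0 * [Cl] / Ksp)`, which the
#' numerical result matches.
#'
#' @param model A `speciation_model`.
#' @param solid_a,solid_b Names of two different solids of the model.
#' @param anchors Named list of anchor concentrations (`Cl`, `P`).
#' @param I Ionic strength at which to evaluate the constants; `NULL`
#'   (default) evaluates them at reference without activity scaling.
#' @param interval pcH search bracket.
#' @return The pcH of solid-solid coexistence.
#' @export
#' @examples
#' m <- build_default_model()
#' compute_pHmax(m, "BHCl", "B_s", anchors = list(Cl = 1.70))
compute_pHmax <- function(model, solid_a, solid_b, anchors = list(),
                          I = NULL, interval = c(1, 13.5)) {
  if (identical(solid_a, solid_b)) {
    phsolv_error("phsolv_domain_error",
                 "pHmax requires two different solids")
  }
  cm <- compile_model(model)
  act <- model$activity
  cm <- if (is.null(I)) scale_compiled(cm, activity_model("none"), act$I_ref)
        else scale_compiled(cm, act, I)
  ia <- match(solid_a, cm$solids$name)
  ib <- match(solid_b, cm$solids$name)
  if (is.na(ia) || is.na(ib)) {
    phsolv_error("phsolv_domain_error", "unknown solid name")
  }
  if (cm$solids$nb[ia] == 0 || cm$solids$nb[ib] == 0) {
    phsolv_error("phsolv_domain_error", "both solids must contain the drug")
  }
  lCl <- if (!is.null(anchors$Cl)) log10(anchors$Cl) else -Inf
  sp <- cm$species
  si_a <- function(pcH) {
    lH <- -pcH
    has_P <- !is.null(anchors$P)
    lP <- if (has_P) {
      ppure <- sp$np == 1 & sp$nb == 0
      log10(anchors$P) - log10(sum(10^(sp$logbeta_I[ppure] + sp$nh[ppure] * lH)))
    } else -Inf
    # pin [B] by exact saturation of solid_b
    e <- cm$solids$iap[[ib]]
    const <- 0; kb <- 0
    for (nm in names(e)) {
      if (nm == "Cl") { const <- const + e[[nm]] * lCl; next }
      j <- match(nm, sp$name)
      const <- const + e[[nm]] * (sp$logbeta_I[j] + sp$nh[j] * lH +
                                    if (has_P) sp$np[j] * lP else 0)
      kb <- kb + e[[nm]] * sp$nb[j]
    }
    lB <- (-cm$solids$pKsp_I[ib] - const) / kb
    logc <- species_logc(cm, lB, lP, lH, has_P = has_P)
    solid_log_iap(cm, ia, logc, lCl) + cm$solids$pKsp_I[ia]
  }
  flo <- si_a(interval[1]); fhi <- si_a(interval[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    phsolv_error("phsolv_domain_error",
                 "no coexistence point for these solids in the pcH bracket")
  }
  stats::uniroot(si_a, interval, tol = 1e-10)$root
}
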