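#' Aqueous species definition
#'
#' Defines one dissolved species by its stoichiometry in the three building
#' blocks of the model -- free base B, protons H and phosphate P -- together
#' with a formation constant. The charge must equal `n_h - 3 * n_p`
#' (protons add +1, each phosphate core contributes -3).
#'
#' `reference_convention` states which reactants the quoted `logK_ref`
#' refers to:
#' \describe{
#'   \item{mass_action_core}{cumulative constant from B, H+ and PO4(3-).}
#'   \item{from_B_and_BH}{aggregates formed from free base and the
#'     protonated monomer, e.g. K310 = \[B2(BH+)\]/(\[B\]^2 \[BH+\]).}
#'   \item{from_BH_and_H3PO4}{ion-pair style complexes from BH+ and
#'     neutral phosphoric acid, e.g. K141 = \[BH+.H3PO4\]/(\[BH+\]\[H3PO4\]).}
#' }
#'
#' @param name Species label.
#' @param n_b,n_h,n_p Non-negative stoichiometric counts of free-base units,
#'   protons and phosphate units.
#' @param logK_ref Formation constant (log10, concentration scale at the
#'   reference ionic strength) under the stated convention; may be the name
#'   of a model constant, resolved at compile time.
#' @param reference_convention One of the conventions above.
#' @param constant Optional name of the model constant this species houses.
#' @return An object of class `aqueous_species`.
#' @export
aqueous_species <- function(name, n_b = 0, n_h = 0, n_p = 0,
                            logK_ref = 0,
                            reference_convention = c("mass_action_core",
                                                     "from_B_and_BH",
                                                     "from_BH_and_H3PO4"),
                            constant = NULL) {
  reference_convention <- match.arg(reference_convention)
  structure(
    list(name = name, n_b = n_b, n_h = n_h, n_p = n_p,
         charge = n_h - 3L * n_p, logK_ref = logK_ref,
         reference_convention = reference_convention, constant = constant),
    class = "aqueous_species")
}

#' Solid phase definition
#'
#' A precipitate characterised by its formula-unit stoichiometry and the
#' negative log of its ion-activity product (concentration scale at the
#' reference ionic strength). `iap` names the free species whose
#' concentrations enter the saturation product, with exponents; for the
#' neutral free-base solid the product is just `[B]` and `pKsp_ref = pS0`.
#'
#' @param name Solid label.
#' @param n_b,n_h,n_p,n_cl Formula-unit stoichiometry.
#' @param pKsp_ref Negative log10 solubility product at reference ionic
#'   strength; may be the name of a model constant.
#' @param iap Named numeric vector: species name -> exponent.
#' @param constant Optional name of the model constant this solid houses.
#' @return An object of class `solid_phase`.
#' @export
solid_phase <- function(name, n_b = 0, n_h = 0, n_p = 0, n_cl = 0,
                        pKsp_ref, iap, constant = NULL) {
  structure(
    list(name = name, n_b = n_b, n_h = n_h, n_p = n_p, n_cl = n_cl,
         pKsp_ref = pKsp_ref, iap = iap, constant = constant),
    class = "solid_phase")
}

# The imipramine model family: fixed registry of species and solids whose
# constants are looked up by name in model$constants.
default_species_registry <- function() {
  list(
    aqueous_species("B",    n_b = 1),
    aqueous_species("BH",   n_b = 1, n_h = 1, logK_ref = "pKa",
                    reference_convention = "mass_action_core",
                    constant = "pKa"),
    aqueous_species("H3PO4", n_h = 3, n_p = 1, logK_ref = "pKa123"),
    aqueous_species("H2PO4", n_h = 2, n_p = 1, logK_ref = "pKa23"),
    aqueous_species("HPO4",  n_h = 1, n_p = 1, logK_ref = "pKa3"),
    aqueous_species("PO4",   n_p = 1),
    aqueous_species("B3H",  n_b = 3, n_h = 1, logK_ref = "logK310",
                    reference_convention = "from_B_and_BH",
                    constant = "logK310"),
    aqueous_species("B7H5", n_b = 7, n_h = 5, logK_ref = "logK750",
                    reference_convention = "from_B_and_BH",
                    constant = "logK750"),
    aqueous_species("BH.H3PO4", n_b = 1, n_h = 4, n_p = 1,
                    logK_ref = "logK141",
                    reference_convention = "from_BH_and_H3PO4",
                    constant = "logK141")
  )
}

default_solid_registry <- function() {
  list(
    solid_phase("BHCl", n_b = 1, n_h = 1, n_cl = 1,
                pKsp_ref = "pKsp_BHCl", iap = c(BH = 1, Cl = 1),
                constant = "pKsp_BHCl"),
    solid_phase("BHH2PO4", n_b = 1, n_h = 3, n_p = 1,
                pKsp_ref = "pKsp_BHH2PO4", iap = c(BH = 1, H2PO4 = 1),
                constant = "pKsp_BHH2PO4"),
    solid_phase("BH2HPO4", n_b = 2, n_h = 3, n_p = 1,
                pKsp_ref = "pKsp_BH2HPO4", iap = c(BH = 2, HPO4 = 1),
                constant = "pKsp_BH2HPO4"),
    solid_phase("B_s", n_b = 1,
                pKsp_ref = "pS0", iap = c(B = 1),
                constant = "pS0")
  )
}

#' Build the default imipramine speciation model
#'
#' Loads the bundled configuration (constants at reference ionic strength
#' I_ref = 0.15 mol/L, Davies activity model with a salting-out term for
#' the neutral base, identity electrode calibration) and attaches the
#' species/solid registry: free base B, cation BH+, phosphoric acid ladder,
#' cationic trimer B2(BH+), heptamer B2(BH+)5, cation-phosphate complex
#' BH+.H3PO4; solids BHCl, (BH)H2PO4, (BH)2HPO4 and the free base.
#'
#' @param config Path to a model configuration file; defaults to the
#'   bundled `imipramine_default.ini`.
#' @return An object of class `speciation_model`.
#' @export
#' @examples
#' m <- build_default_model()
#' m$constants[["pKa"]]
build_default_model <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "imipramine_default.ini",
                          package = "phsolv", mustWork = TRUE)
  }
  read_model_config(config)
}

# Assemble a speciation_model from parsed configuration pieces.
new_speciation_model <- function(constants, sd = NULL, fixed = NULL,
                                 activity = activity_model(),
                                 electrode = electrode_params(),
                                 recipes = list()) {
  constants <- unlist(constants)
  if (is.null(sd)) sd <- stats::setNames(rep(NA_real_, length(constants)),
                                         names(constants))
  if (is.null(fixed)) {
    fixed <- stats::setNames(rep(TRUE, length(constants)), names(constants))
  }
  structure(
    list(constants = constants,
         sd = sd, fixed = fixed,
         species = default_species_registry(),
         solids = default_solid_registry(),
         activity = activity, electrode = electrode,
         recipes = recipes),
    class = "speciation_model")
}

#' @export
print.speciation_model <- function(x, ...) {
  cat("<speciation_model>\n")
  cat("  species:", paste(vapply(x$species, `[[`, "", "name"),
                          collapse = ", "), "\n")
  cat("  solids: ", paste(vapply(x$solids, `[[`, "", "name"),
                          collapse = ", "), "\n")
  cat("  constants:\n")
  for (nm in names(x$constants)) {
    cat(sprintf("    %-14s %8.4f %s%s\n", nm, x$constants[[nm]],
                if (isTRUE(x$fixed[[nm]])) "fixed" else "free",
                if (!is.na(x$sd[[nm]])) sprintf(" (sd %.3g)", x$sd[[nm]]) else ""))
  }
  invisible(x)
}

#' Update model constants, standard deviations and free/fixed status
#'
#' @param model A `speciation_model`.
#' @param constants Named numeric vector of constant values to replace.
#' @param sd Named numeric vector of standard deviations to set.
#' @param free Character vector of constants to mark free (refinable).
#' @param fixed Character vector of constants to mark fixed.
#' @return The updated model.
#' @export
update_constants <- function(model, constants = NULL, sd = NULL,
                             free = NULL, fixed = NULL) {
  check_known <- function(nms) {
    bad <- setdiff(nms, names(model$constants))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(constants)) {
    check_known(names(constants))
    model$constants[names(constants)] <- constants
  }
  if (!is.null(sd)) {
    check_known(names(sd))
    model$sd[names(sd)] <- sd
  }
  if (!is.null(free)) {
    check_known(free)
    model$fixed[free] <- FALSE
  }
  if (!is.null(fixed)) {
    check_known(fixed)
    model$fixed[fixed] <- TRUE
    model$sd[fixed] <- NA_real_  # fixed constants carry no SD
  }
  model
}

#' Validate a speciation model
#'
#' Checks the structural invariants of the model: non-negative species
#' stoichiometry, charge bookkeeping (charge = n_h - 3 n_p), electroneutral
#' solid formula units (n_h - 3 n_p - n_cl = 0), finite solubility products,
#' each refinable constant housed in exactly one species or solid, and no
#' standard deviation attached to a fixed constant.
#'
#' @param model A `speciation_model`.
#' @return Character vector of violations; empty if the model is valid.
#' @export
validate_model <- function(model) {
  v <- character()
  for (sp in model$species) {
    if (sp$n_b < 0 || sp$n_h < 0 || sp$n_p < 0) {
      v <- c(v, sprintf("species %s: negative stoichiometry", sp$name))
    }
    if (sp$charge != sp$n_h - 3 * sp$n_p) {
      v <- c(v, sprintf("species %s: charge %d inconsistent with n_h - 3 n_p = %d",
                        sp$name, sp$charge, sp$n_h - 3 * sp$n_p))
    }
  }
  for (so in model$solids) {
    q <- so$n_h - 3 * so$n_p - so$n_cl
    if (q != 0) {
      v <- c(v, sprintf("solid %s: formula unit has net charge %+d", so$name, q))
    }
    pk <- resolve_constant(model, so$pKsp_ref)
    if (!is.finite(pk)) {
      v <- c(v, sprintf("solid %s: pKsp is not finite", so$name))
    }
  }
  housed <- c(
    unlist(lapply(model$species, `[[`, "constant")),
    unlist(lapply(model$solids, `[[`, "constant"))
  )
  refinable <- names(model$constants)[!model$fixed[names(model$constants)]]
  for (nm in refinable) {
    k <- sum(housed == nm)
    if (k != 1) {
      v <- c(v, sprintf("free constant %s housed in %d species/solids (expect 1)",
                        nm, k))
    }
  }
  for (nm in names(model$constants)) {
    if (isTRUE(model$fixed[[nm]]) && !is.na(model$sd[[nm]])) {
      v <- c(v, sprintf("fixed constant %s carries an SD", nm))
    }
  }
  v
}

# Resolve a logK/pKsp reference that may be a number, a constant name, or
# one of the derived shorthand names pKa123/pKa23/pKa3.
resolve_constant <- function(model, ref) {
  if (is.numeric(ref)) return(ref)
  k <- model$constants
  switch(ref,
    pKa123 = k[["pKa1"]] + k[["pKa2"]] + k[["pKa3"]],
    pKa23 = k[["pKa2"]] + k[["pKa3"]],
    pKa3 = k[["pKa3"]],
    {
      if (!ref %in% names(k)) stop("unknown constant reference: ", ref)
      k[[ref]]
    })
}

# Compile the model into the flat numeric tables the solver consumes:
# cumulative core-convention formation constants logbeta (from B, H+,
# PO4(3-)) and solid pKsp values, all at reference ionic strength.
compile_model <- function(model) {
  k <- model$constants
  pKa <- k[["pKa"]]
  pKa123 <- k[["pKa1"]] + k[["pKa2"]] + k[["pKa3"]]
  n <- length(model$species)
  name <- character(n); nb <- nh <- np <- z <- logbeta <- numeric(n)
  for (i in seq_len(n)) {
    sp <- model$species[[i]]
    name[i] <- sp$name; nb[i] <- sp$n_b; nh[i] <- sp$n_h; np[i] <- sp$n_p
    z[i] <- sp$charge
    lk <- resolve_constant(model, sp$logK_ref)
    logbeta[i] <- switch(sp$reference_convention,
      mass_action_core = lk,
      # aggregates from B and BH+: each proton arrives as one BH+ unit
      from_B_and_BH = lk + sp$n_h * pKa,
      # complexes from BH+ and H3PO4 units
      from_BH_and_H3PO4 = lk + sp$n_b * pKa + sp$n_p * pKa123)
  }
  names(logbeta) <- names(z) <- names(nb) <- names(nh) <- names(np) <- name
  ns <- length(model$solids)
  sname <- character(ns); pksp <- numeric(ns)
  snb <- snh <- snp <- sncl <- numeric(ns)
  iap <- vector("list", ns)
  for (i in seq_len(ns)) {
    so <- model$solids[[i]]
    sname[i] <- so$name
    pksp[i] <- resolve_constant(model, so$pKsp_ref)
    snb[i] <- so$n_b; snh[i] <- so$n_h; snp[i] <- so$n_p; sncl[i] <- so$n_cl
    iap[[i]] <- so$iap
  }
  names(pksp) <- names(snb) <- names(snp) <- names(sncl) <- names(iap) <- sname
  list(species = list(name = name, nb = nb, nh = nh, np = np, z = z,
                      logbeta = logbeta),
       solids = list(name = sname, pKsp = pksp, nb = snb, nh = snh,
                     np = snp, ncl = sncl, iap = iap),
       pKw = k[["pKw"]])
}

#' Medium recipe
#'
#' Total (analytical) composition of one suspension, per litre. `C_Cl_total`
#' is the total chloride including any contributed by the drug salt: when
#' the starting material is the hydrochloride, each mole of drug brings one
#' mole of chloride and the constructor enforces `C_Cl_total >= C_B_total`.
#' At fixed pcH the strong acid/base titrant inventory is absorbed by the
#' electroneutrality slack, so `added_acid`/`added_base` are bookkeeping
#' fields only.
#'
#' @param C_B_total Total drug, mol/L.
#' @param C_P_total Total inorganic phosphate, mol/L.
#' @param C_Cl_total Total chloride, mol/L (including salt-derived).
#' @param C_Na_total Total sodium from weighed-in salts, mol/L.
#' @param added_acid,added_base Strong titrant, mol/L.
#' @param starting_material `"salt_BHCl"` or `"free_base"`.
#' @return An object of class `medium_recipe`.
#' @export
#' @examples
#' medium_recipe(0.164, C_Cl_total = 0.164 + 0.15, C_Na_total = 0.15,
#'               starting_material = "salt_BHCl")
medium_recipe <- function(C_B_total, C_P_total = 0, C_Cl_total = 0,
                          C_Na_total = 0, added_acid = 0, added_base = 0,
                          starting_material = c("salt_BHCl", "free_base")) {
  starting_material <- match.arg(starting_material)
  tot <- c(C_B_total, C_P_total, C_Cl_total, C_Na_total)
  if (any(!is.finite(tot)) || any(tot < 0)) {
    stop("recipe totals must be finite and non-negative")
  }
  if (starting_material == "salt_BHCl" &&
      C_Cl_total < C_B_total - 1e-12) {
    stop("salt_BHCl contributes one chloride per drug: C_Cl_total >= C_B_total")
  }
  structure(
    list(C_B_total = C_B_total, C_P_total = C_P_total,
         C_Cl_total = C_Cl_total, C_Na_total = C_Na_total,
         added_acid = added_acid, added_base = added_base,
         starting_material = starting_material),
    class = "medium_recipe")
}
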