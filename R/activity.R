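#' Activity-coefficient model
#'
#' Ionic-strength corrections used throughout the solver: the Davies
#' equation for charged species and a linear salting-out term for the
#' neutral drug, `log10 gamma(B) = Ks_neutral * I`. All equilibrium
#' constants are quoted on the concentration scale at the reference ionic
#' strength `I_ref` and rescaled to the working ionic strength point by
#' point.
#'
#' @param form `"davies"` or `"none"` (all activity coefficients unity).
#' @param A_DH Debye-Hueckel slope; 0.509 at 25 C in water.
#' @param Ks_neutral Salting-out coefficient of the neutral drug
#'   (dimensionless per mol/L); default 0.42.
#' @param I_ref Reference ionic strength, mol/L; default 0.15.
#' @return An object of class `activity_model`.
#' @export
activity_model <- function(form = c("davies", "none"), A_DH = 0.509,
                           Ks_neutral = 0.42, I_ref = 0.15) {
  form <- match.arg(form)
  stopifnot(I_ref > 0, Ks_neutral >= 0)
  structure(list(form = form, A_DH = A_DH, Ks_neutral = Ks_neutral,
                 I_ref = I_ref),
            class = "activity_model")
}

#' Electrode calibration parameters
#'
#' Four-parameter description of a glass electrode used to convert
#' operational pH-meter readings to the concentration scale:
#' `pH_read = alpha + ks * pcH + jH * 10^(-pcH) + jOH * 10^(pcH - pKw)`.
#' `alpha` absorbs the hydrogen-ion activity coefficient at the working
#' ionic strength, `ks` is the ratio of actual to Nernstian slope, and the
#' junction terms `jH`/`jOH` correct nonlinearity below pH 1.5 and above
#' pH 11.5.
#'
#' @param alpha Intercept, pH units.
#' @param ks Slope ratio; must lie in (0.8, 1.2).
#' @param jH,jOH Junction coefficients, pH L/mol.
#' @param pKw Water ionization constant at working conditions.
#' @return An object of class `electrode_params`.
#' @export
electrode_params <- function(alpha = 0, ks = 1, jH = 0, jOH = 0,
                             pKw = 13.764) {
  stopifnot(ks > 0.8, ks < 1.2, is.finite(jH), is.finite(jOH))
  structure(list(alpha = alpha, ks = ks, jH = jH, jOH = jOH, pKw = pKw),
            class = "electrode_params")
}

# warn once per session when the Davies equation is used beyond its
# nominal validity range
.phsolv_env <- new.env(parent = emptyenv())

davies_range_check <- function(I) {
  if (I > 0.5 && !isTRUE(.phsolv_env$davies_warned)) {
    .phsolv_env$davies_warned <- TRUE
    warning("Davies activity model applied at I = ", signif(I, 3),
            " mol/L, beyond its nominal 0.5 mol/L range; ",
            "treat activity corrections as approximate", call. = FALSE)
  }
  invisible(I)
}

reset_davies_warning <- function() {
  .phsolv_env$davies_warned <- FALSE
  invisible(NULL)
}

#' Log10 activity coefficient
#'
#' Davies form for ions, `-A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)`; for
#' neutral species (`z = 0`) the linear salting-out form `+Ks_neutral * I`,
#' so the neutral's effective activity rises with ionic strength.
#'
#' @param z Integer charge (vectorised).
#' @param I Ionic strength, mol/L (scalar, >= 0).
#' @param model An [activity_model()].
#' @return log10 activity coefficient(s).
#' @export
#' @examples
#' log_gamma(1, 0.15, activity_model())  # about -0.119
log_gamma <- function(z, I, model = activity_model()) {
  stopifnot(I >= 0)
  if (model$form == "none") return(rep(0, length(z)))
  davies_range_check(I)
  sq <- sqrt(I)
  ion <- -model$A_DH * z^2 * (sq / (1 + sq) - 0.3 * I)
  ifelse(z == 0, model$Ks_neutral * I, ion)
}

#' Ionic strength of an equilibrium state
#'
#' One half the sum of concentration times squared charge over all charged
#' aqueous species (including the electroneutrality slack ion that stands
#' in for the strong acid/base titrant).
#'
#' @param state An `equilibrium_state` (see [solve_at_fixed_pcH()]), or a
#'   named list with components `conc` and `z` of equal length.
#' @return Ionic strength, mol/L.
#' @export
ionic_strength <- function(state) {
  if (inherits(state, "equilibrium_state")) {
    conc <- state$species
    z <- state$charges
  } else {
    conc <- state$conc
    z <- state$z
  }
  if (any(conc < 0)) stop("invalid state: negative concentration")
  0.5 * sum(conc * z^2)
}

#' Rescale a concentration-scale equilibrium constant to another ionic strength
#'
#' Given `logK` at the reference ionic strength and the reaction
#' stoichiometry (signed coefficients, positive for products), returns the
#' concentration-scale constant at `I_target`:
#' `logK(I) = logK(I_ref) - sum(nu * (log_gamma(I) - log_gamma(I_ref)))`.
#' Applying the scaling I_ref -> I and then I -> I_ref recovers the input
#' exactly.
#'
#' @param logK_ref Constant (log10) at `model$I_ref`.
#' @param nu Signed stoichiometric coefficients (products positive).
#' @param z Charges of the corresponding species.
#' @param I_target Target ionic strength, mol/L.
#' @param model An [activity_model()].
#' @param I_from Source ionic strength; defaults to `model$I_ref`.
#' @return logK at `I_target`.
#' @export
#' @examples
#' # solubility product of a 1:1 salt of two monovalent ions:
#' # logKsp = -2.338 at I = 0.15 shifts by -2*(lg(0.50)-lg(0.15))
#' scale_logK(-2.338, nu = c(1, 1), z = c(1, -1), I_target = 0.50)
scale_logK <- function(logK_ref, nu, z, I_target, model = activity_model(),
                       I_from = model$I_ref) {
  stopifnot(length(nu) == length(z), I_target >= 0)
  d <- log_gamma(z, I_target, model) - log_gamma(z, I_from, model)
  logK_ref - sum(nu * d)
}

#' Convert an operational pH reading to concentration-scale pcH
#'
#' Inverts the four-parameter electrode map (see [electrode_params()]) by
#' safeguarded one-dimensional root finding; the map is monotone within the
#' working bracket.
#'
#' @param pH_reading Operational pH-meter value(s), each in (-1, 15).
#' @param params An [electrode_params()].
#' @return pcH = -log10 of the hydrogen-ion concentration.
#' @export
#' @examples
#' operational_to_pcH(7.49, electrode_params(alpha = 0.09))
operational_to_pcH <- function(pH_reading, params = electrode_params()) {
  fwd <- function(pcH) {
    params$alpha + params$ks * pcH + params$jH * 10^(-pcH) +
      params$jOH * 10^(pcH - params$pKw)
  }
  vapply(pH_reading, function(r) {
    if (!is.finite(r) || r <= -1 || r >= 15) {
      stop("pH reading out of range (-1, 15): ", r)
    }
    # the junction terms can bend the forward map outside the working
    # window, so locate every sign change on a grid and keep the root
    # nearest the junction-free estimate (r - alpha)/ks
    grid <- seq(-1, 15, length.out = 801)
    fg <- fwd(grid) - r
    sc <- which(fg[-1] * fg[-length(fg)] <= 0)
    if (!length(sc)) {
      stop("calibration error: no pcH root in (-1, 15) for reading ", r)
    }
    roots <- vapply(sc, function(i) {
      stats::uniroot(function(x) fwd(x) - r, grid[c(i, i + 1)],
                     tol = 1e-12, extendInt = "no")$root
    }, 0)
    naive <- (r - params$alpha) / params$ks
    roots[which.min(abs(roots - naive))]
  }, 0)
}

#' Forward electrode map: pcH to operational pH reading
#'
#' @param pcH Concentration-scale pcH value(s).
#' @param params An [electrode_params()].
#' @return Operational pH reading(s).
#' @export
pcH_to_operational <- function(pcH, params = electrode_params()) {
  params$alpha + params$ks * pcH + params$jH * 10^(-pcH) +
    params$jOH * 10^(pcH - params$pKw)
}
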