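# typed error conditions
phsolv_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "phsolv_error")))
}

#' Solver control settings
#'
#' @param tol_mass Relative mass-balance tolerance per component.
#' @param tol_sat Tolerance on the log10 saturation residual of a solid
#'   held at equilibrium.
#' @param tol_si Saturation-index threshold for precipitating a new solid.
#' @param tol_I Absolute convergence tolerance of the ionic-strength loop,
#'   mol/L.
#' @param max_newton Newton iteration cap per solve.
#' @param max_phase Phase-selection iteration cap.
#' @param max_I Ionic-strength loop cap.
#' @return A list of control settings.
#' @export
solver_control <- function(tol_mass = 1e-11, tol_sat = 1e-10, tol_si = 1e-6,
                           tol_I = 1e-6, max_newton = 200, max_phase = 30,
                           max_I = 100) {
  list(tol_mass = tol_mass, tol_sat = tol_sat, tol_si = tol_si,
       tol_I = tol_I, max_newton = max_newton, max_phase = max_phase,
       max_I = max_I)
}
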