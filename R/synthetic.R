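#' Synthetic titration design
#'
#' Describes one synthetic pH-ramp shake-flask experiment: the medium
#' recipe, the pcH grid, the ground-truth model, the log-solubility noise
#' level (default 0.05 log units, the assigned per-point SD of the
#' refinement weighting) and an optional degradation cutoff above which
#' points are flagged and zero-weighted.
#'
#' @param recipe A [medium_recipe()].
#' @param pcH_grid Ascending pcH values.
#' @param truth Ground-truth `speciation_model`.
#' @param noise_sd Gaussian noise SD on logS, log10 units; must be > 0
#'   (use [simulate_logS_curve()] for the noiseless curve).
#' @param seed Integer seed, recorded in the generated set.
#' @param degradation_cutoff Optional pcH above which points are flagged
#'   `"degraded"` (weight 0).
#' @param free Free-constant mask to attach to the generated set.
#' @param name Set label.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(recipe, pcH_grid, truth, noise_sd = 0.05,
                             seed = 1L, degradation_cutoff = NULL,
                             free = character(), name = "synthetic") {
  if (!is.null(noise_sd) && noise_sd <= 0) {
    phsolv_error("phsolv_input_error", "noise_sd must be positive")
  }
  structure(list(recipe = recipe, pcH_grid = pcH_grid, truth = truth,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 degradation_cutoff = degradation_cutoff,
                 free = free, name = name),
            class = "synthetic_design")
}

#' Generate a synthetic titration set
#'
#' Forward-simulates logS with the full equilibrium model at each grid
#' point, drops points where no solid forms (a subsaturated suspension
#' carries no solubility information), adds independent Gaussian noise
#' `N(0, noise_sd^2)` to logS, and applies degradation flags above the
#' cutoff. The seed is recorded in the result; identical seeds reproduce
#' identical sets.
#'
#' @param design A [synthetic_design()].
#' @param control See [solver_control()].
#' @return A [titration_set()] with attributes `seed`, `truth_curve` (the
#'   noiseless simulated curve) and `n_subsaturated`.
#' @export
make_titration_set <- function(design, control = solver_control()) {
  stopifnot(inherits(design, "synthetic_design"))
  curve <- simulate_logS_curve(design$recipe, design$truth, design$pcH_grid,
                               control)
  sat <- !curve$subsaturated
  if (!any(sat)) {
    phsolv_error("phsolv_input_error",
                 "no grid point is saturated; nothing to observe")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(design$seed)
  pcH <- curve$pcH[sat]
  logS <- curve$logS_model[sat] + stats::rnorm(sum(sat), 0, design$noise_sd)
  flag <- rep("ok", length(pcH))
  if (!is.null(design$degradation_cutoff)) {
    flag[pcH > design$degradation_cutoff] <- "degraded"
  }
  obs <- data.frame(pcH = pcH, logS = logS, sigma = design$noise_sd,
                    flag = flag, stringsAsFactors = FALSE)
  ts <- titration_set(design$name, design$recipe, obs, free = design$free)
  attr(ts, "seed") <- design$seed
  attr(ts, "truth_curve") <- curve
  attr(ts, "n_subsaturated") <- sum(!sat)
  ts
}

#' Generate a synthetic conductometric titration curve
#'
#' Two straight segments meeting at the true CMC (continuous at the
#' breakpoint, as in a real titration), sampled at `n_points`
#' concentrations spanning 0.3x to 2x the CMC, with multiplicative Gaussian
#' noise on the conductivity.
#'
#' @param true_cmc Breakpoint concentration.
#' @param pre_slope,post_slope Segment slopes (pre > post > 0 for an ionic
#'   surfactant).
#' @param intercept Conductivity at zero concentration (background
#'   electrolyte).
#' @param n_points Number of points, at least 6.
#' @param rel_noise Relative (multiplicative) noise SD, e.g. 0.01 for 1%.
#' @param seed Integer seed.
#' @param medium Label carried through to the curve.
#' @return A [conductivity_curve()].
#' @export
#' @examples
#' cc <- make_conductivity_curve(26.2, 70, 30, 100, 16, 0.01, seed = 7)
make_conductivity_curve <- function(true_cmc, pre_slope, post_slope,
                                    intercept, n_points = 16,
                                    rel_noise = 0.01, seed = 1L,
                                    medium = "") {
  if (!(pre_slope > post_slope) || post_slope <= 0) {
    phsolv_error("phsolv_input_error",
                 "slopes must satisfy pre_slope > post_slope > 0")
  }
  if (n_points < 6) {
    phsolv_error("phsolv_input_error", "n_points must be at least 6")
  }
  conc <- seq(0.3 * true_cmc, 2 * true_cmc, length.out = n_points)
  kappa <- intercept + pre_slope * pmin(conc, true_cmc) +
    post_slope * pmax(conc - true_cmc, 0)
  if (rel_noise > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    kappa <- kappa * (1 + stats::rnorm(n_points, 0, rel_noise))
  }
  conductivity_curve(conc, kappa, medium = medium)
}

#' Bundled pH-ramp titration designs
#'
#' Reconstructions of the six suspension series of the imipramine study:
#' per-set medium recipes from the stated mass-to-volume compositions
#' (masses converted with molar masses computed from standard atomic
#' weights: free base 280.41, hydrochloride 316.87 g/mol), per-set truth
#' constants and free/fixed masks, and the observed pcH windows.
#'
#' \describe{
#'   \item{set1_2}{57 mg BHCl per mL in 0.14 M NaH2PO4 + 0.049 M HCl;
#'     phosphate + chloride, low-to-high; decomposition above pH 10.}
#'   \item{set3}{52 mg BHCl per mL in 0.15 M NaCl; phosphate-free,
#'     low-to-high; free-base solid above pH 7.37.}
#'   \item{set4}{68 mg free base per mL in 1.69 M NaH2PO4 + 0.46 M NaOH;
#'     high-to-low.}
#'   \item{set5}{71 mg free base per mL in 1.70 M NaCl; high-to-low;
#'     hydrochloride solid below pHmax about 7.5.}
#'   \item{set6}{69 mg free base per mL in 0.6 M H3PO4 + 1.4 M NaH2PO4;
#'     chloride-free, low-to-high.}
#' }
#'
#' @param model Base model whose constants the per-set truth values
#'   override; default [build_default_model()].
#' @return Named list of designs; each has `recipe`, `pcH_range`, `truth`
#'   (a `speciation_model`), `free` (per-set refinable constants) and
#'   `degradation_cutoff` where applicable.
#' @export
titration_designs <- function(model = build_default_model()) {
  mm <- drug_molar_masses()
  mg <- function(x, form) x / 1000 / mm[[form]] * 1000  # mg per mL -> mol/L
  set_truth <- function(k, free, sd = NULL) {
    m <- update_constants(model, constants = k, free = free, sd = sd)
    m
  }
  C3 <- mg(52, "hydrochloride")
  C12 <- mg(57, "hydrochloride")
  C4 <- mg(68, "base")
  C5 <- mg(71, "base")
  C6 <- mg(69, "base")
  list(
    set1_2 = list(
      recipe = medium_recipe(C12, C_P_total = 0.14,
                             C_Cl_total = C12 + 0.049, C_Na_total = 0.14,
                             added_acid = 0.049,
                             starting_material = "salt_BHCl"),
      pcH_range = c(3.82, 11.43),
      truth = set_truth(c(logK141 = 3.039, pKsp_BH2HPO4 = 6.699,
                          logK310 = 8.735, logK750 = 8.165),
                        free = c("logK141", "pKsp_BH2HPO4", "logK310",
                                 "logK750")),
      free = c("logK141", "pKsp_BH2HPO4", "logK310", "logK750"),
      degradation_cutoff = 10),
    set3 = list(
      recipe = medium_recipe(C3, C_Cl_total = C3 + 0.15, C_Na_total = 0.15,
                             starting_material = "salt_BHCl"),
      pcH_range = c(7.37, 11.87),
      truth = set_truth(c(logK310 = 8.816, logK750 = 9.981),
                        free = c("pS0", "logK310", "logK750")),
      free = c("pS0", "logK310", "logK750"),
      degradation_cutoff = 9),
    set4 = list(
      recipe = medium_recipe(C4, C_P_total = 1.69,
                             C_Na_total = 1.69 + 0.46, added_base = 0.46,
                             starting_material = "free_base"),
      pcH_range = c(2.67, 6.27),
      truth = set_truth(c(logK141 = 0.364, pKsp_BHH2PO4 = 2.672,
                          pKsp_BH2HPO4 = 7.045),
                        free = c("logK141", "pKsp_BHH2PO4", "pKsp_BH2HPO4")),
      free = c("logK141", "pKsp_BHH2PO4", "pKsp_BH2HPO4"),
      degradation_cutoff = NULL),
    set5 = list(
      recipe = medium_recipe(C5, C_Cl_total = 1.70, C_Na_total = 1.70,
                             starting_material = "free_base"),
      pcH_range = c(2.62, 8.00),
      truth = set_truth(c(logK310 = 8.332, logK750 = 9.816),
                        free = c("pKsp_BHCl", "logK310", "logK750"),
                        sd = c(pKsp_BHCl = 0.02)),
      free = c("pKsp_BHCl", "logK310", "logK750"),
      degradation_cutoff = NULL),
    set6 = list(
      recipe = medium_recipe(C6, C_P_total = 2.0, C_Na_total = 1.4,
                             added_acid = 0,
                             starting_material = "free_base"),
      pcH_range = c(2.50, 6.37),
      truth = set_truth(c(logK141 = 0.324, pKsp_BHH2PO4 = 2.829,
                          pKsp_BH2HPO4 = 6.801),
                        free = c("logK141", "pKsp_BHH2PO4", "pKsp_BH2HPO4")),
      free = c("logK141", "pKsp_BHH2PO4", "pKsp_BH2HPO4"),
      degradation_cutoff = NULL)
  )
}
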