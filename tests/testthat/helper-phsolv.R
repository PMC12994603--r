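# shared fixtures: all built in code, no stored data

# default model with activity corrections switched off
model_noact <- function() {
  m <- build_default_model()
  m$activity <- activity_model("none")
  m
}

# disable aggregation species (formation constants -> -Inf)
no_aggregates <- function(model) {
  update_constants(model,
                   constants = c(logK310 = -Inf, logK750 = -Inf,
                                 logK141 = -Inf))
}

# disable all solids (Ksp -> Inf, i.e. pKsp -> -Inf)
no_solids <- function(model) {
  update_constants(model,
                   constants = c(pS0 = -Inf, pKsp_BHCl = -Inf,
                                 pKsp_BHH2PO4 = -Inf, pKsp_BH2HPO4 = -Inf))
}

# closed-form solution of the two-component toy (B + Cl, no aggregates, no
# phosphate, activity off, BHCl the only solid): total dissolved drug
toy_BCl_solubility <- function(C_B, C_Cl, pcH, pKa = 9.52, pKsp = 2.338) {
  r <- 10^(pKa - pcH)
  Ksp <- 10^(-pKsp)
  # salt present: r(1+r)B^2 + r(C_Cl - C_B)B - Ksp = 0
  a <- r * (1 + r)
  b <- r * (C_Cl - C_B)
  B <- (-b + sqrt(b^2 + 4 * a * Ksp)) / (2 * a)
  S <- B * (1 + r)
  if (C_B - S > 0) S else C_B  # otherwise everything dissolves
}

# quiet wrappers: the high-ionic-strength media warn once per session about
# the Davies range; tests that are not about the warning silence it
squiet <- function(expr) suppressWarnings(expr)
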