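---
title: "Equilibrium modelling of solubility-pH profiles with phsolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium modelling of solubility-pH profiles with phsolv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phsolv)
```

## The problem

Weakly basic, surface-active drugs such as the tricyclic antidepressants
show solubility-pH profiles that the textbook Henderson-Hasselbalch (HH)
relation cannot describe. Three effects intervene:

* **salt limitation / common-ion effect** — below the pH of maximum
  solubility (pH~max~) the solid in equilibrium with the solution is a salt
  (hydrochloride or a phosphate), so the dissolved total is pinned by a
  solubility product `Ksp` and *falls* as the counterion concentration
  rises, instead of rising indefinitely as HH predicts;
* **self-aggregation** — above its critical micelle concentration the
  cationic drug forms oligomers (modelled here as a cationic trimer and
  heptamer, plus a 1:1 cation-phosphoric acid complex), inflating the
  apparent solubility;
* **activity corrections** — the suspensions reach ionic strengths of
  1.4-1.7 mol/L, far from the 0.15 mol/L reference state on which the
  equilibrium constants are quoted.

`phsolv` implements the full speciation model behind such profiles for an
imipramine-like system, refines its constants from log S-pH titration
data, and provides the two auxiliary analyses used alongside: CMC
estimation from conductometric titrations and hydrate/salt assignment from
elemental analysis.

## The equilibrium model

All constants are concentration-scale quantities at a reference ionic
strength `I_ref = 0.15` mol/L. With B the free base, the aqueous species
are

* `BH+` with `pKa = 9.52`;
* the phosphoric acid ladder `H3PO4 / H2PO4- / HPO4^2- / PO4^3-`
  (`pKa1/2/3 = 1.95 / 6.74 / 11.60`, config defaults, editable);
* aggregates `B2(BH+)` (`logK310`), `B2(BH+)5` (`logK750`) and
  `BH+.H3PO4` (`logK141`), with the triple subscript giving the
  (B, H, PO4) stoichiometry;

and the candidate solids are BHCl, (BH)H2PO4, (BH)2HPO4 and the free base
B(s), whose `pKsp` values (the last being the intrinsic solubility `pS0`)
ship as the inverse-variance pooled values of the source study's per-set
refinements: `pS0 = 4.602`, `pKsp(BHCl) = 2.338`, `pKsp((BH)H2PO4) =
2.823`, `pKsp((BH)2HPO4) = 6.812`, `logK310 = 8.728`, `logK750 = 9.970`,
`logK141 = 0.374`.

### Aggregation-constant convention

The triple-index notation does not by itself fix the reference species.
`phsolv` adopts

    K310 = [B2(BH+)]  / ([B]^2 [BH+])
    K750 = [B2(BH+)5] / ([B]^2 [BH+]^5)
    K141 = [BH+.H3PO4] / ([BH+] [H3PO4])

which matches the species' description as *cationic* aggregates and the
magnitude of `logK141`. The convention is recorded on each
`aqueous_species` and is swappable. One consequence should be understood:
under this convention the tabulated constants make the aggregate terms
negligible below pH ~7 at millimolar free-base levels, so the model
*cannot* reproduce the observed complete dissolution of a 0.164 mol/L
hydrochloride suspension at pH < 7.4 — experimentally that dissolution is
micellar (the dissolved total exceeds the CMC of 26.2 mmol/L), a regime a
mass-action oligomer model with these constants does not reach. The
package therefore treats the acidic branch of chloride-rich media as
salt-limited, and all recovery claims are for data generated and refined
under one and the same convention.

## The solver

`solve_at_fixed_pcH()` works at fixed pcH (= -log10 [H+], concentration
scale), which reflects pH-ramp practice: the titrant inventory is whatever
was needed to hold the suspension there, represented by an
electroneutrality *slack* ion (monovalent, Na+-like for base titrant,
Cl--like for acid titrant) that contributes to the ionic strength but to
no equilibrium.

* Unknowns are log10 of the free base, free phosphate and free chloride —
  logarithms guarantee positivity — plus one linear amount per solid held
  at saturation.
* Residuals are the B/P/Cl mass balances scaled by their totals and one
  log10 saturation condition per present solid; the Jacobian is analytic
  (every species concentration is a monomial in the unknowns).
* A damped Newton iteration (step cap 3 log units, halving line search)
  converges to relative mass-balance residuals of 1e-11 (`solver_control()`
  exposes all tolerances; 200-iteration cap raises a typed solver error).
* **Phase selection**: starting from the solid-free solution, the candidate
  with the largest positive saturation index SI = log10(IAP/Ksp) is
  precipitated and the system re-solved; any solid whose amount turns
  negative is removed. Ties follow the acid-to-base order BHCl,
  (BH)H2PO4, (BH)2HPO4, B(s). Termination requires all SI <= 1e-6 and all
  amounts non-negative; a final assemblage with more than two drug-bearing
  solids is rejected as unphysical (two may legitimately coexist over a pcH
  interval when two counterion reservoirs deplete, as in the
  chloride-plus-phosphate media).
* **Ionic-strength loop**: constants are rescaled from `I_ref` to the
  current ionic strength, the system re-solved, and I recomputed until it
  changes by less than 1e-6 mol/L (simple substitution, switching to
  averaging after 10 iterations).

### Activity model

Charged species use the Davies equation (`A = 0.509` at 25 °C); the
neutral base uses a linear salting-out term `log10 gamma(B) = Ks * I` with
`Ks = 0.42`. The study's own high-I work used a Stokes-Robinson hydration
correction whose parameters are not published; Davies plus salting-out is
the shipped approximation, the model is pluggable (`activity_model()`),
and use beyond the Davies range (I > 0.5 mol/L) triggers a warning — once
per session, not per call, because refinement loops solve thousands of
states at I ~ 1.5-1.7 and per-call warnings would drown the log. The
Davies expression is non-monotone in I: its minimum is at I ~ 0.39, so
"activity corrections weaken" slightly between 0.39 and 0.5; this is a
property of the formula, not a bug.

`operational_to_pcH()` inverts the four-parameter electrode map
`pH_read = alpha + ks * pcH + jH * 10^(-pcH) + jOH * 10^(pcH - pKw)`. The
junction terms can bend the map outside the working window, so the inverse
locates all roots on (-1, 15) and keeps the one nearest the junction-free
estimate `(reading - alpha)/ks`.

### pH of maximum solubility

`compute_pHmax()` finds the pcH where two solids are simultaneously
saturated, bisecting on the saturation index of one solid while the other
pins the free-base concentration. In the activity-off limit the
BHCl/free-base boundary reduces to the closed form
`pHmax = pKa + log10(S0 [Cl-] / Ksp)`, which the numerical result matches
to 1e-6; at 1.70 mol/L chloride this gives 7.49, consistent with the
reported isolation of the hydrochloride below pH 7.5. Note the direction
of the common-ion effect: *less* chloride makes the salt more soluble and
moves the boundary *down* (0.17 mol/L gives 6.49).

## Refinement

`refine()` minimises `chi^2 = sum(((logS_obs - logS_calc)/sigma)^2)` over
the selected free constants (all in log units) by Levenberg-Marquardt with
a central-difference Jacobian (step 1e-4 log). Points flagged as outliers,
degraded or subsaturated carry zero weight — flagging and deleting rows
are provably equivalent. The goodness of fit is `GOF =
sqrt(chi2_min/(n - m))`; with the assigned per-point SD of 0.05 log units
correctly describing the noise, GOF averages ~1. Per-constant SDs come
from the GOF-scaled inverse Gauss-Newton normal matrix (covariance-based,
as labelled; a profile-likelihood alternative was out of scope). A
constant the data carry no information about — e.g. the heptamer constant
against a data set where the heptamer term is vanishingly small — is
reported with an infinite SD rather than a misleading finite one.
"Fixed" constants are held at their given values, excluded from `m`, and
never pooled. Multi-set joint refinement concatenates observation vectors.

`pool_weighted_mean()` pools per-set estimates with weights `1/SD^2` and
reports `SD_of_mean = 1/sqrt(sum(w))`. (The source table's printed SDs of
its weighted means match `1/sum(w)` instead; the means themselves — the
quantities asserted in the acceptance tests — agree either way.)

## CMC from conductometric titrations

`fit_segmented()` implements the classical construction: two independent
OLS lines over an exhaustive search of the split position (>= 3 points per
segment), breakpoint at the intersection. There is no continuity
constraint at the breakpoint by default (`constrained = TRUE` provides the
joined variant). Because the split index is discrete, the uncertainty is a
nonparametric bootstrap over points (default 1000 resamples, seeded)
rather than a delta-method SD. Parallel segments raise a degenerate-fit
error; the estimator is affine-equivariant, so the (physically large)
background conductivity of the 0.15 M NaCl / 0.10 M NaH2PO4 media affects
the intercept only.

## The synthetic-data generator

`make_titration_set()` emulates the pH-ramp shake-flask design: it
forward-simulates log S with the full equilibrium model on a pcH grid,
*drops* grid points where no solid forms (a subsaturated suspension
carries no solubility information), adds independent Gaussian noise of SD
0.05 log units — the noise level the study's weighting scheme assigns per
point — and optionally flags points above a degradation cutoff
(zero-weighted, mirroring how alkaline degradation was handled: flagged,
not value-perturbed, because the assays quantified the intact drug).
Bundled designs `set1_2 ... set6` reconstruct the six suspension series
from their stated compositions, converting masses with molar masses
computed at runtime from standard atomic weights (free base 280.41 g/mol,
hydrochloride 316.87 g/mol; e.g. 52 mg/mL hydrochloride -> 0.164 mol/L).

`make_conductivity_curve()` generates a two-segment conductivity curve,
continuous at the true CMC, over 16 points spanning 0.3x-2x the CMC
(the supplementary titration figures are not machine-readable; 12-20
points over that span is a realistic conductometric design) with 1 %
multiplicative noise by default. Slopes of 70 and 30 uS/cm per mmol/L
represent a strong ionic surfactant with ~60 % counterion binding above
the CMC.

What a green recovery test establishes — and what it does not: the
generator shares the speciation model with the refiner, so recovery tests
prove the estimation machinery (identifiability, weighting, uncertainty
calibration) under the stated noise, not the correctness of the chemical
model against nature. Real data add micellar aggregation beyond the
oligomer model, electrode drift, slow solid-form conversion and genuine
degradation, none of which are emulated beyond the zero-weight flags.

## Numerical choices and degenerate inputs

* Mass-balance tolerance 1e-11 relative (configurable), saturation
  residual 1e-10, SI threshold for precipitation 1e-6, ionic-strength
  loop 1e-6 mol/L.
* Disabling a solid is expressed as `pKsp = -Inf` (Ksp = infinity: never
  saturates); disabling an aggregate as `logK = -Inf`.
* Zero totals drop the corresponding unknown (no phosphate unknown in
  phosphate-free media); negative totals are input errors.
* `fit_segmented` requires >= 6 points and >= 3 per segment; bootstrap
  resamples with fewer than 6 distinct concentrations are skipped.
* Solubility observations with non-`ok` flags always carry weight zero;
  an underdetermined refinement (n <= m) is a typed error, not a warning.

## Known limitations

* No kinetics: precipitation, supersaturation decay and degradation rates
  are out of scope; the "oil" and crystalline free base are one phase with
  a single `pS0`.
* The Davies + salting-out activity model is an acknowledged approximation
  above I ~ 0.5 mol/L.
* Dilution by titrant volume is not modelled (recipes are per litre of
  suspension); the underlying 1.000 mL aliquot + microlitre titrant design
  makes this a sub-percent effect.
* Micellisation is represented only through the CMC analysis, not inside
  the speciation mass balances.
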