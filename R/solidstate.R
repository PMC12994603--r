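#' Theoretical elemental percentages of a formula
#'
#' Mass percentages of carbon and hydrogen (and every other element) from
#' standard atomic weights, as reported by combustion elemental analysis.
#'
#' @param formula Formula string, hydrate notation allowed (see
#'   [parse_formula()]).
#' @return List with `C`, `H` (percent), `molar_mass` (g/mol) and
#'   `percentages` (named vector over all elements, summing to 100).
#' @export
#' @examples
#' elemental_percentages("C19H24N2·2H2O")$C  # about 72.1
elemental_percentages <- function(formula) {
  cnt <- parse_formula(formula)
  w <- atomic_weights()[names(cnt)]
  mass <- sum(cnt * w)
  pct <- 100 * cnt * w / mass
  list(C = if ("C" %in% names(pct)) pct[["C"]] else 0,
       H = if ("H" %in% names(pct)) pct[["H"]] else 0,
       molar_mass = mass,
       percentages = pct)
}

#' Candidate salt/base hydrate composition
#'
#' @param label Human-readable label, e.g. `"(ImpH)2HPO4.2H2O"`.
#' @param formula Parseable formula string.
#' @return An object of class `candidate_composition` with theoretical C%,
#'   H%, water count and molar mass.
#' @export
candidate_composition <- function(label, formula) {
  ep <- elemental_percentages(formula)
  hyd <- regmatches(formula, regexec("([0-9]*)H2O$", gsub("[[:space:]]", "", formula)))[[1]]
  n_waters <- if (length(hyd) == 3 && nzchar(hyd[[2]])) as.integer(hyd[[2]])
              else if (length(hyd) == 3) 1L else 0L
  structure(list(label = label, formula = formula,
                 C = ep$C, H = ep$H, n_waters = n_waters,
                 molar_mass = ep$molar_mass),
            class = "candidate_composition")
}

#' Default candidate compositions for a medium
#'
#' Builds the candidate list used to interpret elemental analysis of solids
#' isolated from imipramine suspensions. Sample provenance restricts the
#' candidates: chloride-free media exclude the hydrochloride, phosphate-free
#' media exclude the phosphate salts, and `"base"` keeps only free-base
#' hydrates. Anhydrous forms and 1/2/4-hydrates are enumerated.
#'
#' @param medium `"phosphate"`, `"chloride"`, `"phosphate+chloride"` or
#'   `"base"`.
#' @return List of [candidate_composition()] objects.
#' @export
candidate_compositions <- function(medium = c("phosphate", "chloride",
                                              "phosphate+chloride", "base")) {
  medium <- match.arg(medium)
  base <- "C19H24N2"      # Imp free base
  baseH <- "C19H25N2"     # ImpH+ unit
  hyd <- function(f, n) if (n == 0) f else sprintf("%s.%dH2O", f, n)
  out <- list()
  add <- function(label, formula) out[[length(out) + 1L]] <<-
    candidate_composition(label, formula)
  for (n in c(0L, 2L, 4L)) {
    add(if (n) sprintf("Imp·%dH2O", n) else "Imp", hyd(base, n))
  }
  if (medium %in% c("phosphate", "phosphate+chloride")) {
    for (n in c(0L, 2L, 4L)) {
      add(if (n) sprintf("(ImpH)2HPO4·%dH2O", n) else "(ImpH)2HPO4",
          hyd(sprintf("(%s)2.HPO4", baseH), n))
      add(if (n) sprintf("ImpH·H2PO4·%dH2O", n) else "ImpH·H2PO4",
          hyd(sprintf("%s.H2PO4", baseH), n))
    }
  }
  if (medium %in% c("chloride", "phosphate+chloride")) {
    for (n in c(0L, 1L, 2L)) {
      add(if (n) sprintf("ImpHCl·%dH2O", n) else "ImpHCl",
          hyd("C19H24N2.HCl", n))
    }
  }
  out
}

#' Assign the nearest theoretical composition to observed C/H percentages
#'
#' Ranks candidate compositions by Euclidean distance in (C%, H%) space.
#' The hydrochloride and the free-base dihydrate have near-identical carbon
#' content, so carbon and hydrogen are always used jointly.
#'
#' @param observed_C,observed_H Observed mass percentages.
#' @param candidates List of [candidate_composition()]s, e.g. from
#'   [candidate_compositions()].
#' @return data.frame ranked by distance: `label`, `formula`, `C`, `H`,
#'   `n_waters`, `molar_mass`, `distance`.
#' @export
#' @examples
#' assign_composition(65.21, 7.65, candidate_compositions("phosphate"))[1, ]
assign_composition <- function(observed_C, observed_H, candidates) {
  if (!length(candidates)) {
    phsolv_error("phsolv_input_error", "candidate list is empty")
  }
  d <- vapply(candidates, function(cc) {
    sqrt((cc$C - observed_C)^2 + (cc$H - observed_H)^2)
  }, 0)
  df <- data.frame(
    label = vapply(candidates, `[[`, "", "label"),
    formula = vapply(candidates, `[[`, "", "formula"),
    C = vapply(candidates, `[[`, 0, "C"),
    H = vapply(candidates, `[[`, 0, "H"),
    n_waters = vapply(candidates, function(x) as.integer(x$n_waters), 0L),
    molar_mass = vapply(candidates, `[[`, 0, "molar_mass"),
    distance = d,
    stringsAsFactors = FALSE)
  df[order(df$distance), , drop = FALSE]
}
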