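#' Standard atomic weights
#'
#' Conventional (IUPAC 2021) standard atomic weights for the elements that
#' occur in small-molecule drugs and their common salts. Values are g/mol.
#'
#' @return Named numeric vector of atomic weights.
#' @export
#' @examples
#' atomic_weights()[c("C", "H", "N")]
atomic_weights <- function() {
  c(
    H = 1.008, C = 12.011, N = 14.007, O = 15.999,
    Na = 22.98976928, Mg = 24.305, P = 30.973761998, S = 32.06,
    Cl = 35.45, K = 39.0983, Ca = 40.078, Br = 79.904, I = 126.90447,
    F = 18.998403163
  )
}

# Parse one "unit" of a formula: element symbols with optional counts and
# parenthesised groups with multipliers, e.g. "(C19H25N2)2HPO4".
parse_formula_unit <- function(s) {
  counts <- c()
  add <- function(el, n) {
    counts[el] <<- if (el %in% names(counts)) counts[[el]] + n else n
    counts
  }
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      # find matching close paren
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        cj <- substr(s, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced parentheses in formula: ", s)
      inner <- substr(s, i + 1L, j - 2L)
      rest <- substr(s, j, n)
      mult <- regmatches(rest, regexpr("^[0-9]+", rest))
      k <- if (length(mult) && nzchar(mult)) as.integer(mult) else 1L
      sub_counts <- parse_formula_unit(inner)
      for (el in names(sub_counts)) add(el, sub_counts[[el]] * k)
      i <- j + if (length(mult)) nchar(mult) else 0L
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (i < n && grepl("^[a-z]$", substr(s, i + 1L, i + 1L))) {
        sym <- substr(s, i, i + 1L)
        i <- i + 1L
      }
      rest <- substr(s, i + 1L, n)
      cnt <- regmatches(rest, regexpr("^[0-9]+", rest))
      k <- if (length(cnt) && nzchar(cnt)) as.integer(cnt) else 1L
      add(sym, k)
      i <- i + 1L + if (length(cnt)) nchar(cnt) else 0L
    } else {
      stop("cannot parse formula near '", substr(s, i, n), "' in: ", s)
    }
  }
  counts
}

#' Parse a chemical formula into element counts
#'
#' Accepts plain Hill-style formulas (`"C19H24N2"`), parenthesised groups
#' with multipliers (`"(C19H25N2)2HPO4"`) and hydrate/adduct notation with
#' a middle dot, multiplication sign or plain `.` separator, each segment
#' optionally prefixed by an integer multiplier (`"C19H24N2.2H2O"`).
#'
#' @param formula Formula string.
#' @return Named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("C19H24N2·2H2O")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  # unify hydrate separators: middle dot, times sign, asterisk, period
  parts <- strsplit(s, "[·×*.]")[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty formula")
  total <- c()
  for (p in parts) {
    mult <- regmatches(p, regexpr("^[0-9]+", p))
    k <- if (length(mult) && nzchar(mult)) as.integer(mult) else 1L
    body <- sub("^[0-9]+", "", p)
    cnt <- parse_formula_unit(body)
    unknown <- setdiff(names(cnt), names(atomic_weights()))
    if (length(unknown)) {
      stop("unknown element(s) in formula '", formula, "': ",
           paste(unknown, collapse = ", "))
    }
    for (el in names(cnt)) {
      total[el] <- (if (el %in% names(total)) total[[el]] else 0) + cnt[[el]] * k
    }
  }
  total
}

#' Molar mass of a formula
#'
#' @param formula Formula string (see [parse_formula()]).
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' molar_mass("C19H24N2")        # imipramine free base
#' molar_mass("C19H24N2.HCl")    # imipramine hydrochloride
molar_mass <- function(formula) {
  cnt <- parse_formula(formula)
  sum(cnt * atomic_weights()[names(cnt)])
}

# Molar masses of the default drug forms, derived at runtime from standard
# atomic weights rather than stored as constants.
drug_molar_masses <- function() {
  c(base = molar_mass("C19H24N2"), hydrochloride = molar_mass("C19H24N2.HCl"))
}
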