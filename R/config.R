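# Structured-text (INI style) model configuration: sections [constants],
# [sd], [fixed], [activity], [electrode], [recipes]. Keys in [recipes] are
# dotted: set3.C_B_total = 0.164.

# canonical constant order; reader and writer both normalise to it so that
# serialize -> parse -> serialize round-trips byte-identically
.const_order <- c("pKa", "pKw", "pKa1", "pKa2", "pKa3",
                  "pS0", "pKsp_BHCl", "pKsp_BHH2PO4", "pKsp_BH2HPO4",
                  "logK310", "logK750", "logK141")

parse_ini <- function(lines) {
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("[#;].*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (is.null(section)) stop("config line ", i, " outside any [section]")
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line ", i, ": ", lines[[i]])
    out[[section]][[trimws(kv[[2]])]] <- trimws(kv[[3]])
  }
  out
}

num_or_string <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  if (is.na(y) && !identical(tolower(x), "nan")) x else y
}

#' Read a model configuration file
#'
#' Parses the structured-text configuration (see the bundled
#' `imipramine_default.ini` for the schema) and returns the corresponding
#' speciation model.
#'
#' @param path Path to the configuration file.
#' @return A `speciation_model`.
#' @export
read_model_config <- function(path) {
  ini <- parse_ini(readLines(path, warn = FALSE))
  if (is.null(ini$constants)) stop("config lacks a [constants] section")
  konst <- vapply(ini$constants, function(x) as.numeric(x), 0)
  miss <- setdiff(.const_order, names(konst))
  if (length(miss)) stop("missing constants in config: ",
                         paste(miss, collapse = ", "))
  konst <- konst[.const_order]
  sd <- stats::setNames(rep(NA_real_, length(konst)), names(konst))
  if (!is.null(ini$sd)) {
    for (nm in names(ini$sd)) sd[[nm]] <- as.numeric(ini$sd[[nm]])
  }
  fixed <- stats::setNames(rep(TRUE, length(konst)), names(konst))
  if (!is.null(ini$fixed)) {
    for (nm in names(ini$fixed)) {
      fixed[[nm]] <- tolower(ini$fixed[[nm]]) %in% c("true", "yes", "1")
    }
  }
  act <- ini$activity
  activity <- activity_model(
    form = if (is.null(act$form)) "davies" else act$form,
    A_DH = if (is.null(act$A_DH)) 0.509 else as.numeric(act$A_DH),
    Ks_neutral = if (is.null(act$Ks_neutral)) 0.42 else as.numeric(act$Ks_neutral),
    I_ref = if (is.null(act$I_ref)) 0.15 else as.numeric(act$I_ref))
  el <- ini$electrode
  gnum <- function(key, default) {
    if (is.null(el[[key]])) default else as.numeric(el[[key]])
  }
  electrode <- electrode_params(
    alpha = gnum("alpha", 0), ks = gnum("ks", 1),
    jH = gnum("jH", 0), jOH = gnum("jOH", 0),
    pKw = gnum("pKw", konst[["pKw"]]))
  recipes <- list()
  if (!is.null(ini$recipes)) {
    keys <- names(ini$recipes)
    sets <- unique(sub("\\..*$", "", keys))
    for (s in sets) {
      fields <- lapply(keys[startsWith(keys, paste0(s, "."))], function(k) {
        num_or_string(ini$recipes[[k]])
      })
      names(fields) <- sub("^[^.]+\\.", "", keys[startsWith(keys, paste0(s, "."))])
      recipes[[s]] <- do.call(medium_recipe, fields)
    }
  }
  new_speciation_model(konst, sd = sd, fixed = fixed,
                       activity = activity, electrode = electrode,
                       recipes = recipes)
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a model configuration file
#'
#' Serialises a speciation model to the structured-text configuration
#' format. Writing, re-reading and writing again produces byte-identical
#' output.
#'
#' @param model A `speciation_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  ln <- c("# phsolv model configuration", "", "[constants]")
  for (nm in .const_order) {
    ln <- c(ln, sprintf("%s = %s", nm, fmt_num(model$constants[[nm]])))
  }
  with_sd <- names(model$sd)[!is.na(model$sd)]
  if (length(with_sd)) {
    ln <- c(ln, "", "[sd]")
    for (nm in intersect(.const_order, with_sd)) {
      ln <- c(ln, sprintf("%s = %s", nm, fmt_num(model$sd[[nm]])))
    }
  }
  ln <- c(ln, "", "[fixed]")
  for (nm in .const_order) {
    ln <- c(ln, sprintf("%s = %s", nm,
                        if (isTRUE(model$fixed[[nm]])) "true" else "false"))
  }
  a <- model$activity
  ln <- c(ln, "", "[activity]",
          sprintf("form = %s", a$form),
          sprintf("A_DH = %s", fmt_num(a$A_DH)),
          sprintf("Ks_neutral = %s", fmt_num(a$Ks_neutral)),
          sprintf("I_ref = %s", fmt_num(a$I_ref)))
  e <- model$electrode
  ln <- c(ln, "", "[electrode]",
          sprintf("alpha = %s", fmt_num(e$alpha)),
          sprintf("ks = %s", fmt_num(e$ks)),
          sprintf("jH = %s", fmt_num(e$jH)),
          sprintf("jOH = %s", fmt_num(e$jOH)),
          sprintf("pKw = %s", fmt_num(e$pKw)))
  if (length(model$recipes)) {
    ln <- c(ln, "", "[recipes]")
    for (s in names(model$recipes)) {
      r <- model$recipes[[s]]
      for (f in c("C_B_total", "C_P_total", "C_Cl_total", "C_Na_total",
                  "added_acid", "added_base")) {
        ln <- c(ln, sprintf("%s.%s = %s", s, f, fmt_num(r[[f]])))
      }
      ln <- c(ln, sprintf("%s.starting_material = %s", s, r$starting_material))
    }
  }
  writeLines(ln, path)
  invisible(path)
}
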