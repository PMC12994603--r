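# Delimited-text I/O and run manifests.

#' Read solubility observations from delimited text
#'
#' Expects comma-separated text with a header. Mandatory columns: `set`,
#' one of `pH_op` (operational meter reading, converted through the
#' electrode parameters) or `pcH`, and one of `S` (mol/L, converted to
#' log10) or `logS`. Optional columns `weight` and `flag`; a non-`"ok"`
#' flag forces weight 0. Supplying both `pH_op` and `pcH`, or both `S` and
#' `logS`, is ambiguous and rejected. Malformed rows are rejected with
#' their line numbers.
#'
#' @param path Input file.
#' @param electrode [electrode_params()] used for `pH_op` conversion.
#' @param sigma Assigned SD per point, log10 units.
#' @return Named list (one element per set) of observation data.frames
#'   with columns `pcH`, `logS`, `sigma`, `weight`, `flag`.
#' @export
read_observations <- function(path, electrode = electrode_params(),
                              sigma = 0.05) {
  if (!file.exists(path)) {
    phsolv_error("phsolv_io_error", paste("no such file:", path))
  }
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        stringsAsFactors = FALSE)
  nm <- names(df)
  if (!"set" %in% nm) {
    phsolv_error("phsolv_format_error", "missing mandatory column: set")
  }
  has_pH <- "pH_op" %in% nm; has_pcH <- "pcH" %in% nm
  has_S <- "S" %in% nm; has_logS <- "logS" %in% nm
  if (has_pH && has_pcH) {
    phsolv_error("phsolv_format_error", "both pH_op and pcH present (ambiguous)")
  }
  if (!has_pH && !has_pcH) {
    phsolv_error("phsolv_format_error", "missing mandatory column: pH_op or pcH")
  }
  if (has_S && has_logS) {
    phsolv_error("phsolv_format_error", "both S and logS present (ambiguous)")
  }
  if (!has_S && !has_logS) {
    phsolv_error("phsolv_format_error", "missing mandatory column: S or logS")
  }
  pcH <- if (has_pcH) suppressWarnings(as.numeric(df$pcH))
         else suppressWarnings(as.numeric(df$pH_op))
  Sv <- if (has_logS) suppressWarnings(as.numeric(df$logS))
        else suppressWarnings(as.numeric(df$S))
  bad <- which(!is.finite(pcH) | !is.finite(Sv) | (has_S & Sv <= 0))
  if (length(bad)) {
    warning("rejecting malformed row(s) at data line(s): ",
            paste(bad, collapse = ", "))
    keep <- setdiff(seq_len(nrow(df)), bad)
    df <- df[keep, , drop = FALSE]
    pcH <- pcH[keep]; Sv <- Sv[keep]
  }
  if (has_pH) pcH <- operational_to_pcH(pcH, electrode)
  logS <- if (has_logS) Sv else log10(Sv)
  flag <- if ("flag" %in% nm) as.character(df$flag) else rep("ok", nrow(df))
  flag[!flag %in% c("ok", "outlier_zero_weight", "degraded", "subsaturated")] <-
    "outlier_zero_weight"
  weight <- if ("weight" %in% nm) as.numeric(df$weight) else rep(1, nrow(df))
  weight[flag != "ok"] <- 0
  out <- split(data.frame(pcH = pcH, logS = logS, sigma = sigma,
                          weight = weight, flag = flag,
                          stringsAsFactors = FALSE),
               as.character(df$set))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Read a conductometric titration table
#'
#' Two-column comma- or whitespace-delimited text (concentration, specific
#' conductivity); lines starting with `#` are comments and may declare
#' units.
#'
#' @param path Input file.
#' @param medium Medium label for the curve.
#' @return A [conductivity_curve()].
#' @export
read_conductivity <- function(path, medium = "") {
  if (!file.exists(path)) {
    phsolv_error("phsolv_io_error", paste("no such file:", path))
  }
  lines <- readLines(path, warn = FALSE)
  unit <- "mmol/L"
  u <- grep("^#.*unit", lines, value = TRUE)
  if (length(u)) unit <- trimws(sub(".*unit[s]?[:=]", "", u[[1]]))
  df <- utils::read.table(path, comment.char = "#", sep = "",
                          header = FALSE, col.names = c("conc", "kappa"),
                          fill = FALSE)
  if (!nrow(df)) {
    df <- utils::read.csv(path, comment.char = "#", header = FALSE,
                          col.names = c("conc", "kappa"))
  }
  conductivity_curve(df$conc, df$kappa, medium = medium, unit = unit)
}

run_manifest <- function(command, inputs = character(),
                         outputs = character(), seed = NA) {
  fields <- c(
    sprintf("command: %s", command),
    sprintf("package: phsolv %s",
            as.character(utils::packageVersion("phsolv"))),
    sprintf("seed: %s", as.character(seed)),
    sprintf("inputs: %s", paste(inputs, collapse = ", ")),
    sprintf("input_md5: %s",
            paste(vapply(inputs, function(p)
              if (file.exists(p)) unname(tools::md5sum(p)) else "missing", ""),
              collapse = ", ")),
    sprintf("outputs: %s", paste(outputs, collapse = ", ")))
  # stable hash of the deterministic fields (timestamp excluded)
  tf <- tempfile()
  writeLines(fields, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(fields = c(fields, sprintf("timestamp: %s",
                                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
       hash = hash)
}

write_manifest <- function(manifest, path) {
  writeLines(c(sprintf("manifest_hash: %s", manifest$hash), manifest$fields),
             paste0(path, ".manifest"))
  invisible(path)
}

sig6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

#' Write analysis results as delimited text
#'
#' Writes refined constants, simulated curves or CMC estimates with a fixed
#' column order, numbers at 6 significant digits, and a comment header
#' carrying the run-manifest hash. A sidecar `<path>.manifest` records the
#' command, package version, seed and input checksums.
#'
#' @param x A `refined_constants`, `cmc_estimate`, or curve data.frame from
#'   [simulate_logS_curve()].
#' @param path Output path.
#' @param command Command string recorded in the manifest.
#' @param inputs Input paths recorded (and checksummed) in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, command = "write_results",
                          inputs = character(), seed = NA) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x)) ||
      (is.list(x) && !length(x))) {
    phsolv_error("phsolv_io_error", "empty results object")
  }
  man <- run_manifest(command, inputs = inputs, outputs = path, seed = seed)
  hdr <- sprintf("# phsolv results; manifest %s", man$hash)
  body <-
    if (inherits(x, "refined_constants")) {
      c("constant,estimate,SD",
        vapply(names(x$estimates), function(nm)
          sprintf("%s,%s,%s", nm, sig6(x$estimates[[nm]]), sig6(x$SDs[[nm]])),
          ""),
        sprintf("# GOF,%s", sig6(x$GOF)),
        sprintf("# n,%d", x$n),
        sprintf("# I_avg,%s", sig6(x$I_avg)))
    } else if (inherits(x, "cmc_estimate")) {
      c("quantity,value,SD",
        sprintf("cmc,%s,%s", sig6(x$cmc), sig6(x$cmc_SD)),
        sprintf("pre_slope,%s,%s", sig6(x$pre_slope), sig6(x$pre_slope_SD)),
        sprintf("post_slope,%s,%s", sig6(x$post_slope), sig6(x$post_slope_SD)),
        sprintf("# split,%d", x$split),
        sprintf("# SSE,%s", sig6(x$SSE)),
        sprintf("# unit,%s", x$unit))
    } else if (is.data.frame(x)) {
      cols <- names(x)
      c(paste(cols, collapse = ","),
        vapply(seq_len(nrow(x)), function(i)
          paste(vapply(cols, function(cn) {
            v <- x[[cn]][i]
            if (is.numeric(v)) sig6(v) else as.character(v)
          }, ""), collapse = ","), ""))
    } else {
      phsolv_error("phsolv_io_error",
                   paste("cannot serialise object of class",
                         paste(class(x), collapse = "/")))
    }
  ok <- tryCatch({ writeLines(c(hdr, body), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) phsolv_error("phsolv_io_error", paste("cannot write", path))
  write_manifest(man, path)
  invisible(path)
}

#' Read back a refined-constants results file
#'
#' @param path File written by [write_results()] for a `refined_constants`.
#' @return data.frame with columns `constant`, `estimate`, `SD`.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
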