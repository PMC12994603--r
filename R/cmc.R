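#' Conductometric titration curve
#'
#' @param concentrations Strictly increasing surfactant concentrations
#'   (mmol/L by convention; any consistent unit works -- the breakpoint is
#'   reported in the same unit).
#' @param kappa Specific conductivities, uS/cm.
#' @param medium Optional medium label.
#' @param unit Concentration unit label, default `"mmol/L"`.
#' @return An object of class `conductivity_curve`.
#' @export
conductivity_curve <- function(concentrations, kappa, medium = "",
                               unit = "mmol/L") {
  if (length(concentrations) < 6) {
    phsolv_error("phsolv_input_error",
                 "a conductivity curve needs at least 6 points")
  }
  if (length(kappa) != length(concentrations)) {
    phsolv_error("phsolv_input_error",
                 "concentrations and kappa must have equal length")
  }
  if (any(diff(concentrations) <= 0)) {
    phsolv_error("phsolv_input_error",
                 "concentrations must be strictly increasing")
  }
  structure(list(concentrations = as.numeric(concentrations),
                 kappa = as.numeric(kappa), medium = medium, unit = unit),
            class = "conductivity_curve")
}

# ordinary least squares line through (x, y); returns c(intercept, slope)
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- sum((x - mx) * (y - my)) / sxx
  c(my - b * mx, b)
}

# best two-segment fit of y on x: exhaustive split search, >= min_pts per
# segment; returns NULL when degenerate
two_line_fit <- function(x, y, min_pts = 3, tol_parallel = 1e-8) {
  n <- length(x)
  best <- NULL
  for (j in min_pts:(n - min_pts)) {
    f1 <- ols_line(x[1:j], y[1:j])
    f2 <- ols_line(x[(j + 1):n], y[(j + 1):n])
    sse <- sum((y[1:j] - f1[1] - f1[2] * x[1:j])^2) +
      sum((y[(j + 1):n] - f2[1] - f2[2] * x[(j + 1):n])^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(split = j, a1 = f1[1], b1 = f1[2],
                   a2 = f2[1], b2 = f2[2], sse = sse)
    }
  }
  scale <- max(abs(best$b1), abs(best$b2), 1e-12)
  if (abs(best$b1 - best$b2) < tol_parallel * scale) return(NULL)
  best$cmc <- (best$a2 - best$a1) / (best$b1 - best$b2)
  best
}

#' Segmented two-line fit of a conductometric titration curve
#'
#' Classical CMC construction: an ordinary-least-squares line is fitted to
#' each side of every admissible split of the curve (at least 3 points per
#' segment), the split minimising the total SSE is kept, and the CMC is the
#' intersection of the two lines. The two lines are fitted independently
#' (no continuity constraint at the breakpoint); a continuity-constrained
#' variant is available via `constrained = TRUE`. The uncertainty is a
#' nonparametric bootstrap over points, because the split index is discrete.
#'
#' @param curve A [conductivity_curve()].
#' @param n_boot Bootstrap resamples for the CMC standard deviation.
#' @param seed Seed for the bootstrap; recorded in the result.
#' @param constrained Force the two segments to meet at the breakpoint.
#' @return An object of class `cmc_estimate`: `cmc`, `cmc_SD`, segment
#'   intercepts/slopes with bootstrap SDs, `split`, `SSE`.
#' @export
#' @examples
#' x <- seq(8, 52, length.out = 16)
#' y <- ifelse(x <= 26.2, 100 + 70 * x, 100 + 70 * 26.2 + 30 * (x - 26.2))
#' fit_segmented(conductivity_curve(x, y), n_boot = 100, seed = 1)
fit_segmented <- function(curve, n_boot = 1000, seed = NULL,
                          constrained = FALSE) {
  if (!inherits(curve, "conductivity_curve")) {
    phsolv_error("phsolv_input_error", "curve must be a conductivity_curve")
  }
  x <- curve$concentrations
  y <- curve$kappa
  n <- length(x)
  fit <- if (constrained) two_line_fit_constrained(x, y) else two_line_fit(x, y)
  if (is.null(fit)) {
    phsolv_error("phsolv_degenerate_fit_error",
                 "segments are parallel: no breakpoint (single straight line?)")
  }
  if (fit$cmc < x[1] || fit$cmc > x[n]) {
    phsolv_error("phsolv_degenerate_fit_error",
                 sprintf("breakpoint %.4g outside the observed range [%.4g, %.4g]",
                         fit$cmc, x[1], x[n]))
  }
  boot <- rep(NA_real_, n_boot)
  boot_b1 <- boot_b2 <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    for (b in seq_len(n_boot)) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      xb <- x[idx]; yb <- y[idx]
      ux <- !duplicated(xb)
      if (sum(ux) < 6) next
      fb <- tryCatch(
        if (constrained) two_line_fit_constrained(xb, yb) else two_line_fit(xb, yb),
        error = function(e) NULL)
      if (!is.null(fb) && is.finite(fb$cmc)) {
        boot[b] <- fb$cmc
        boot_b1[b] <- fb$b1; boot_b2[b] <- fb$b2
      }
    }
  }
  structure(
    list(cmc = fit$cmc,
         cmc_SD = stats::sd(boot, na.rm = TRUE),
         pre_slope = fit$b1, post_slope = fit$b2,
         pre_slope_SD = stats::sd(boot_b1, na.rm = TRUE),
         post_slope_SD = stats::sd(boot_b2, na.rm = TRUE),
         intercept_pre = fit$a1, intercept_post = fit$a2,
         split = fit$split, SSE = fit$sse,
         n_boot = n_boot, seed = seed,
         medium = curve$medium, unit = curve$unit),
    class = "cmc_estimate")
}

# continuity-constrained variant: for each candidate breakpoint position the
# model kappa = a + b1*x + (b2-b1)*(x-c)+ is linear in (a, b1, b2) given c;
# c is profiled over a grid between the flanking points of each split
two_line_fit_constrained <- function(x, y, min_pts = 3) {
  n <- length(x)
  best <- NULL
  for (j in min_pts:(n - min_pts)) {
    for (cc in seq(x[j], x[j + 1], length.out = 11)) {
      X <- cbind(1, x, pmax(x - cc, 0))
      fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(fit$residuals^2)
      if (is.null(best) || sse < best$sse) {
        cf <- fit$coefficients
        best <- list(split = j, a1 = cf[1], b1 = cf[2],
                     a2 = cf[1] - cf[3] * cc, b2 = cf[2] + cf[3],
                     sse = sse, cmc = cc)
      }
    }
  }
  if (is.null(best) ||
      abs(best$b1 - best$b2) < 1e-8 * max(abs(best$b1), abs(best$b2), 1e-12)) {
    return(NULL)
  }
  best
}

#' @export
print.cmc_estimate <- function(x, ...) {
  cat(sprintf("<cmc_estimate> CMC = %.3g +/- %.2g %s%s\n", x$cmc,
              x$cmc_SD, x$unit,
              if (nzchar(x$medium)) paste0(" (", x$medium, ")") else ""))
  cat(sprintf("  slopes %.4g -> %.4g, split after point %d, SSE %.4g, %d bootstrap resamples\n",
              x$pre_slope, x$post_slope, x$split, x$SSE, x$n_boot))
  invisible(x)
}
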