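#' Titration set
#'
#' One pH-ramp shake-flask data set: a medium recipe, solubility
#' observations and the free/fixed mask of the constants to refine against
#' it.
#'
#' @param name Set label.
#' @param recipe A [medium_recipe()].
#' @param observations A data.frame with columns `pcH`, `logS`, and
#'   optionally `sigma` (assigned SD, default 0.05 log units), `weight`
#'   (default 1) and `flag` (`"ok"`, `"outlier_zero_weight"`, `"degraded"`,
#'   `"subsaturated"`; any non-`"ok"` flag forces weight 0).
#' @param free Character vector of constants refined against this set.
#' @return An object of class `titration_set`.
#' @export
titration_set <- function(name, recipe, observations, free = character()) {
  obs <- as.data.frame(observations)
  if (!all(c("pcH", "logS") %in% names(obs))) {
    phsolv_error("phsolv_input_error",
                 "observations need columns pcH and logS")
  }
  if (!nrow(obs)) {
    phsolv_error("phsolv_input_error", "at least one observation required")
  }
  if (is.null(obs$sigma)) obs$sigma <- 0.05
  if (any(obs$sigma <= 0)) {
    phsolv_error("phsolv_input_error", "sigma must be positive")
  }
  if (is.null(obs$flag)) obs$flag <- "ok"
  if (is.null(obs$weight)) obs$weight <- 1
  obs$weight[obs$flag != "ok"] <- 0
  if (length(free) && sum(obs$weight > 0) < 1) {
    warning("titration set '", name, "' has no weight-carrying observations")
  }
  structure(list(name = name, recipe = recipe, observations = obs,
                 free = free),
            class = "titration_set")
}

# model logS at the observation pcH values; points where the model forms no
# solid are reported at the fully dissolved total
predict_logS <- function(sets, model, control = solver_control()) {
  out <- vector("list", length(sets))
  for (j in seq_along(sets)) {
    s <- sets[[j]]
    n <- nrow(s$observations)
    logS <- Ival <- numeric(n)
    for (i in seq_len(n)) {
      st <- solve_at_fixed_pcH(s$recipe, model, s$observations$pcH[i], control)
      logS[i] <- if (st$saturated) log10(st$S_dissolved)
                 else log10(s$recipe$C_B_total)
      Ival[i] <- st$I
    }
    out[[j]] <- list(logS = logS, I = Ival)
  }
  out
}

#' Refine equilibrium constants against log S - pcH observations
#'
#' Weighted nonlinear least squares: minimises
#' `chi2 = sum(((logS_obs - logS_calc) / sigma)^2)` over the free constants
#' by Levenberg-Marquardt on the constants in log units (central-difference
#' Jacobian, step 1e-4). Observations flagged non-`"ok"` carry zero weight.
#' Several sets may be refined jointly by passing a list; their free masks
#' are merged.
#'
#' @param set A `titration_set` or a list of them (joint refinement).
#' @param model Starting `speciation_model`; free constants are taken from
#'   the sets' free masks.
#' @param control Solver control, see [solver_control()].
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return An object of class `refined_constants`: `estimates`, `SDs`
#'   (from the scaled inverse Gauss-Newton normal matrix), `GOF`
#'   (`sqrt(chi2/(n - m))`), `n`, `I_avg`, `model` (updated), `trace`
#'   (chi-squared after each accepted step).
#' @export
refine <- function(set, model, control = solver_control(), max_iter = 50) {
  sets <- if (inherits(set, "titration_set")) list(set) else set
  free <- unique(unlist(lapply(sets, `[[`, "free")))
  if (!length(free)) {
    phsolv_error("phsolv_input_error", "no free constants to refine")
  }
  bad <- setdiff(free, names(model$constants))
  if (length(bad)) {
    phsolv_error("phsolv_input_error",
                 paste("unknown constant(s):", paste(bad, collapse = ", ")))
  }
  viol <- validate_model(update_constants(model, free = free))
  if (length(viol)) {
    phsolv_error("phsolv_input_error",
                 paste("invalid model:", paste(viol, collapse = "; ")))
  }
  obs_pcH <- unlist(lapply(sets, function(s) s$observations$pcH))
  obs_logS <- unlist(lapply(sets, function(s) s$observations$logS))
  sigma <- unlist(lapply(sets, function(s) s$observations$sigma))
  w <- unlist(lapply(sets, function(s) s$observations$weight))
  keep <- w > 0
  n <- sum(keep)
  m <- length(free)
  if (n <= m) {
    phsolv_error("phsolv_underdetermined_error",
                 sprintf("%d weighted observations cannot determine %d constants",
                         n, m))
  }

  theta <- model$constants[free]
  resid_at <- function(th) {
    mod <- update_constants(model, constants = stats::setNames(th, free))
    pr <- predict_logS(sets, mod, control)
    calc <- unlist(lapply(pr, `[[`, "logS"))
    list(r = ((obs_logS - calc) / sigma)[keep],
         I = unlist(lapply(pr, `[[`, "I"))[keep])
  }
  jac_at <- function(th) {
    h <- 1e-4
    J <- matrix(0, n, m)
    for (j in seq_len(m)) {
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      J[, j] <- (resid_at(tp)$r - resid_at(tm)$r) / (2 * h)
    }
    J
  }

  cur <- resid_at(theta)
  chi2 <- sum(cur$r^2)
  trace <- chi2
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    J <- jac_at(theta)
    JtJ <- crossprod(J)
    g <- crossprod(J, cur$r)
    accepted <- FALSE
    for (inner in 1:15) {
      A <- JtJ + lambda * (diag(diag(JtJ), m) + diag(1e-10, m))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        th_new <- theta + as.numeric(delta)
        new <- tryCatch(resid_at(th_new), error = function(e) NULL)
        if (!is.null(new)) {
          chi2_new <- sum(new$r^2)
          if (is.finite(chi2_new) && chi2_new <= chi2) {
            theta <- th_new; cur <- new
            improved <- chi2 - chi2_new
            chi2 <- chi2_new
            trace <- c(trace, chi2)
            lambda <- max(lambda / 3, 1e-12)
            accepted <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    if (improved < 1e-10 * (1 + chi2)) break
  }

  J <- jac_at(theta)
  JtJ <- crossprod(J)
  gof <- sqrt(chi2 / (n - m))
  sv <- svd(JtJ)
  tol <- max(sv$d, 0) * 1e-12
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  covm <- sv$v %*% (dinv * t(sv$u))
  sds <- gof * sqrt(pmax(diag(covm), 0))
  # a constant the data carry no information about gets an infinite SD
  sds[diag(JtJ) <= max(diag(JtJ)) * 1e-12] <- Inf
  names(sds) <- free

  structure(
    list(estimates = stats::setNames(as.numeric(theta), free),
         SDs = sds,
         GOF = gof, n = n, m = m,
         I_avg = mean(cur$I),
         chi2 = chi2,
         trace = trace,
         model = update_constants(model,
                                  constants = stats::setNames(theta, free),
                                  sd = sds[is.finite(sds)])),
    class = "refined_constants")
}

#' @export
print.refined_constants <- function(x, ...) {
  cat("<refined_constants>\n")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-14s %9.4f  (SD %.4g)\n", nm, x$estimates[[nm]],
                x$SDs[[nm]]))
  }
  cat(sprintf("  GOF %.3f on n = %d points (m = %d), I_avg = %.3f mol/L\n",
              x$GOF, x$n, x$m, x$I_avg))
  invisible(x)
}

#' Inverse-variance weighted mean
#'
#' Pools per-set estimates of one constant with weights `1/SD^2`:
#' `mean = sum(w x) / sum(w)`, `SD_of_mean = 1 / sqrt(sum(w))`. Entries
#' held fixed in a set must be excluded by the caller.
#'
#' @param values Numeric vector of per-set estimates.
#' @param SDs Positive numeric vector of their standard deviations.
#' @return List with `mean` and `SD`.
#' @export
#' @examples
#' pool_weighted_mean(c(2.672, 2.829), c(0.05, 0.01))$mean  # 2.823
pool_weighted_mean <- function(values, SDs) {
  if (!length(values)) {
    phsolv_error("phsolv_domain_error", "no values to pool")
  }
  if (length(values) != length(SDs) || any(SDs <= 0)) {
    phsolv_error("phsolv_input_error",
                 "values and SDs must have equal length with SDs > 0")
  }
  w <- 1 / SDs^2
  list(mean = sum(w * values) / sum(w), SD = 1 / sqrt(sum(w)))
}
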