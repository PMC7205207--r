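## Ross-Minton concentration-viscosity model.  The model is
##   eta(c) = eta0 * exp( iv*c / (1 - kv*iv*c) )
## with iv = intrinsic viscosity [eta] (ml/mg) and kv = k/v, the ratio of the
## crowding factor to the shape factor (only the ratio is identifiable).
## Viscosity diverges at the singular concentration c_sing = 1/(kv*iv); the
## admissible domain is [0, c_sing).  The exact algebraic inverse is
##   c(eta) = L / ( iv * (1 + kv*L) ),  L = ln(eta/eta0),
## which maps every finite eta > eta0 to a concentration below c_sing.

#' Ross-Minton viscosity at a concentration
#'
#' Evaluates \eqn{\eta(c) = \eta_0 \exp([\eta]c / (1 - (k/\nu)[\eta]c))}.
#' Errors when any concentration reaches the singular concentration
#' \eqn{1/((k/\nu)[\eta])}, beyond which the model is undefined.
#'
#' @param conc concentration(s), mg/ml.
#' @param intrinsic_viscosity intrinsic viscosity \eqn{[\eta]}, ml/mg.
#' @param k_over_v crowding/shape factor ratio \eqn{k/\nu}, dimensionless.
#' @param eta0 solvent viscosity, cP.
#' @return Viscosity in cP, same length as `conc`.
#'
#' @examples
#' rossMintonViscosity(100, 0.01, 0.5)   # 1.1 * exp(2)
#' @export
rossMintonViscosity <- function(conc, intrinsic_viscosity, k_over_v,
                                eta0 = 1.1) {
  stopifnot(intrinsic_viscosity > 0, k_over_v >= 0, eta0 > 0,
            all(conc >= 0))
  denom <- 1 - k_over_v * intrinsic_viscosity * conc
  if (any(denom <= 0)) {
    csing <- 1 / (k_over_v * intrinsic_viscosity)
    stop(sprintf(
      "concentration at/beyond the model singularity (%.4g mg/ml)", csing))
  }
  eta0 * exp(intrinsic_viscosity * conc / denom)
}

#' Concentration at a given Ross-Minton viscosity
#'
#' Exact inverse of [rossMintonViscosity()]:
#' \eqn{c = L / ([\eta](1 + (k/\nu)L))} with \eqn{L = \ln(\eta/\eta_0)}.
#' Defined for any viscosity above the solvent viscosity; the result always
#' lies below the singular concentration.
#'
#' @param viscosity target viscosity(ies), cP; must exceed `eta0`.
#' @inheritParams rossMintonViscosity
#' @return Concentration in mg/ml.
#' @export
rossMintonConcentration <- function(viscosity, intrinsic_viscosity, k_over_v,
                                    eta0 = 1.1) {
  stopifnot(intrinsic_viscosity > 0, k_over_v >= 0, eta0 > 0)
  if (any(viscosity <= eta0))
    stop("viscosity must exceed the solvent viscosity eta0 = ", eta0)
  L <- log(viscosity / eta0)
  L / (intrinsic_viscosity * (1 + k_over_v * L))
}

#' Validate a concentration-viscosity curve
#'
#' @param concentration concentrations, mg/ml (positive).
#' @param viscosity viscosities, cP (positive).
#' @param sd optional per-point standard deviations, cP.
#' @param n optional replicate counts.
#' @param molecule molecule name.
#' @return A data frame sorted by concentration, with class
#'   `"ViscosityCurve"` prepended.
#' @export
viscosityCurve <- function(concentration, viscosity, sd = NULL, n = NULL,
                           molecule = "unnamed") {
  stopifnot(length(concentration) == length(viscosity),
            all(concentration > 0), all(viscosity > 0))
  out <- data.frame(molecule = molecule, concentration = concentration,
                    viscosity = viscosity, stringsAsFactors = FALSE)
  if (!is.null(sd)) out$sd <- sd
  if (!is.null(n)) out$n <- n
  out <- out[order(out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ViscosityCurve", class(out))
  out
}

#' Read concentration-viscosity curves from CSV
#'
#' Expected columns: `molecule`, `concentration_mg_ml`, `viscosity_cP`, and
#' optionally `sd_cP` and `n` — the layout of a raw rheometer export with one
#' row per measured dilution.
#'
#' @param path CSV file path.
#' @return A named list of `ViscosityCurve` data frames, one per molecule.
#' @export
readViscosityCurves <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule", "concentration_mg_ml", "viscosity_cP")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  split_rows <- split(raw, raw$molecule)
  lapply(split_rows, function(d)
    viscosityCurve(d$concentration_mg_ml, d$viscosity_cP,
                   sd = if ("sd_cP" %in% names(d)) d$sd_cP,
                   n = if ("n" %in% names(d)) d$n,
                   molecule = d$molecule[1]))
}

## Deterministic initialisation: the model linearises exactly as
## 1/ln(eta/eta0) = (1/iv)*(1/c) - kv, so an ordinary regression of
## 1/L on 1/c gives starting values that are exact on noiseless data.
.rm_init <- function(conc, eta, eta0) {
  L <- log(eta / eta0)
  ok <- L > 0
  if (sum(ok) >= 2L) {
    co <- stats::coef(stats::lsfit(1 / conc[ok], 1 / L[ok]))
    iv0 <- 1 / co[2]
    kv0 <- -co[1]
  } else {
    iv0 <- NA_real_
    kv0 <- NA_real_
  }
  if (!is.finite(iv0) || iv0 <= 0)
    iv0 <- log(max(eta) / eta0) / max(conc)   # kv = 0 closed form
  if (!is.finite(kv0) || kv0 <= 0) kv0 <- 1e-4
  c(iv = unname(iv0), kv = unname(kv0))
}

#' Fit the Ross-Minton model to a viscosity curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nlsLM()]) for the intrinsic viscosity and the k/v ratio,
#' with the solvent viscosity held fixed.  By default the residuals are
#' minimised on the log-viscosity scale, which matches the multiplicative
#' error structure of cone-and-plate measurements (errors scale with the
#' reading) and keeps the fit well-conditioned over the model's huge dynamic
#' range; `scale = "linear"` minimises raw cP residuals instead.  The
#' coefficient of determination is always reported on the untransformed cP
#' scale.  Starting values come from the model's exact linearisation
#' (`1/ln(eta/eta0)` regressed on `1/c`) unless supplied.
#'
#' @param curve a `ViscosityCurve` (see [viscosityCurve()]) or any data frame
#'   with `concentration` and `viscosity` columns; at least 3 points at >= 2
#'   distinct concentrations are required for the 2-parameter fit.
#' @param eta0 solvent viscosity, cP (fixed, not fitted).
#' @param scale `"log"` (default) or `"linear"`: the scale residuals are
#'   minimised on.
#' @param weights optional per-point weights (e.g. `1/sd^2`); default
#'   unweighted.
#' @param start optional named vector `c(iv = , kv = )` of starting values.
#' @return A [RossMintonFit-class].
#'
#' @examples
#' curve <- simulateViscosityCurve(seed = 1)
#' fit <- fitRossMinton(curve)
#' fit
#' @export
fitRossMinton <- function(curve, eta0 = 1.1, scale = c("log", "linear"),
                          weights = NULL, start = NULL) {
  scale <- match.arg(scale)
  conc <- curve$concentration
  eta <- curve$viscosity
  stopifnot(all(conc > 0), all(eta > 0))
  if (length(conc) < 3L)
    stop("at least 3 points are required to fit the 2-parameter model")
  if (length(unique(conc)) < 2L)
    stop("all points share one concentration; the fit is unidentifiable")
  if (is.null(start)) start <- .rm_init(conc, eta, eta0)
  dat <- data.frame(conc = conc, eta = eta, leta = log(eta))
  ## the denominator is clamped away from zero so that optimiser excursions
  ## across the singularity yield huge (but finite) residuals, not NaN
  fo <- if (scale == "log")
    leta ~ log(eta0) + iv * conc / pmax(1 - kv * iv * conc, 1e-3)
  else
    eta ~ eta0 * exp(pmin(iv * conc / pmax(1 - kv * iv * conc, 1e-3), 250))
  args <- list(fo, data = dat,
               start = list(iv = unname(start[["iv"]]),
                            kv = unname(start[["kv"]])),
               lower = c(1e-8, 0),
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) stop("Ross-Minton fit failed: ", conditionMessage(e),
                             call. = FALSE))
  p <- stats::coef(fit)
  if (any(1 - p[["kv"]] * p[["iv"]] * conc <= 0))
    stop("converged parameters place data beyond the model singularity")
  eta_hat <- rossMintonViscosity(conc, p[["iv"]], p[["kv"]], eta0)
  r2 <- 1 - sum((eta - eta_hat)^2) / sum((eta - mean(eta))^2)
  conv <- fit$convInfo
  new("RossMintonFit",
      eta0 = eta0,
      intrinsicViscosity = p[["iv"]],
      kOverV = p[["kv"]],
      rSquared = r2,
      covariance = stats::vcov(fit),
      df = stats::df.residual(fit),
      scale = scale,
      converged = isTRUE(conv$isConv),
      iterations = as.integer(conv$finIter),
      curve = as.data.frame(curve))
}

#' @rdname RossMintonFit-accessors
#' @name RossMintonFit-accessors
#' @param object a [RossMintonFit-class].
#' @export
setMethod("intrinsicViscosity", "RossMintonFit",
          function(object) object@intrinsicViscosity)

#' @rdname RossMintonFit-accessors
#' @export
setMethod("kOverV", "RossMintonFit", function(object) object@kOverV)

#' @rdname RossMintonFit-accessors
#' @export
setMethod("rSquared", "RossMintonFit", function(object) object@rSquared)

#' @export
setMethod("coef", "RossMintonFit", function(object)
  c(intrinsic_viscosity = object@intrinsicViscosity,
    k_over_v = object@kOverV))

setMethod("show", "RossMintonFit", function(object) {
  cat("Ross-Minton fit (", object@scale, "-scale residuals)\n", sep = "")
  cat(sprintf("  [eta] = %.5f ml/mg   k/v = %.4f   eta0 = %.2f cP (fixed)\n",
              object@intrinsicViscosity, object@kOverV, object@eta0))
  cat(sprintf("  R^2 (cP scale) = %.4f over %d points; singular at %.1f mg/ml\n",
              object@rSquared, nrow(object@curve),
              1 / (object@kOverV * object@intrinsicViscosity)))
})

#' Predict viscosity from a fit
#'
#' @param fit a [RossMintonFit-class].
#' @param conc concentration(s), mg/ml.
#' @return Predicted viscosity in cP.  The result carries an `extrapolated`
#'   attribute flagging concentrations above the maximum measured one,
#'   mirroring the reporting convention that marks model values outside the
#'   measured range.
#' @export
predictViscosity <- function(fit, conc) {
  stopifnot(is(fit, "RossMintonFit"))
  out <- rossMintonViscosity(conc, fit@intrinsicViscosity, fit@kOverV,
                             fit@eta0)
  attr(out, "extrapolated") <- conc > max(fit@curve$concentration)
  out
}

#' Concentration at a viscosity threshold, with confidence interval
#'
#' Inverts the fitted model at a target viscosity (20 cP by default — the
#' usual syringeability ceiling) and attaches a first-order (delta-method)
#' confidence interval: the gradient of the inverse with respect to
#' \eqn{([\eta], k/\nu)} is propagated through the parameter covariance of
#' the fit, with a t quantile on the fit's residual degrees of freedom.
#'
#' @param fit a [RossMintonFit-class].
#' @param threshold target viscosity, cP; must exceed `eta0`.
#' @param level confidence level (default 0.95).
#' @return An object of class `ThresholdCrossing`: a list with
#'   `threshold`, `concentration`, `se`, `ci_low`, `ci_high`, `level`.
#' @export
concentrationAtThreshold <- function(fit, threshold = 20, level = 0.95) {
  stopifnot(is(fit, "RossMintonFit"))
  if (threshold <= fit@eta0)
    stop("threshold must exceed the solvent viscosity eta0 = ", fit@eta0)
  iv <- fit@intrinsicViscosity
  kv <- fit@kOverV
  L <- log(threshold / fit@eta0)
  cc <- L / (iv * (1 + kv * L))
  grad <- c(-cc / iv, -cc * L / (1 + kv * L))
  se <- sqrt(drop(t(grad) %*% fit@covariance %*% grad))
  tq <- stats::qt(1 - (1 - level) / 2, fit@df)
  structure(list(threshold = threshold, concentration = cc, se = se,
                 ci_low = cc - tq * se, ci_high = cc + tq * se,
                 level = level),
            class = "ThresholdCrossing")
}

#' @export
print.ThresholdCrossing <- function(x, ...) {
  cat(sprintf("Concentration at %.3g cP: %.1f mg/ml (%.0f%% CI %.1f - %.1f)\n",
              x$threshold, x$concentration, 100 * x$level, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' Batch Ross-Minton report for a set of curves
#'
#' Fits every curve and reports, per molecule, the fitted parameters, the cP
#' scale R-squared, the model viscosity at the reporting concentrations
#' (flagged extrapolated when they exceed the measured range), and the
#' threshold crossing with its confidence interval.
#'
#' @param curves a named list of `ViscosityCurve` frames (see
#'   [readViscosityCurves()]).
#' @param report_conc concentrations to report model viscosities at, mg/ml.
#' @param threshold viscosity threshold for the crossing estimate, cP.
#' @param ... passed on to [fitRossMinton()].
#' @return A data frame with one row per molecule.
#' @export
rossMintonReport <- function(curves, report_conc = c(100, 150),
                             threshold = 20, ...) {
  rows <- lapply(curves, function(curve) {
    fit <- fitRossMinton(curve, ...)
    v <- predictViscosity(fit, report_conc)
    cx <- concentrationAtThreshold(fit, threshold)
    row <- data.frame(molecule = curve$molecule[1],
                      intrinsic_viscosity = fit@intrinsicViscosity,
                      k_over_v = fit@kOverV, r2 = fit@rSquared,
                      stringsAsFactors = FALSE)
    for (i in seq_along(report_conc)) {
      row[[paste0("visc_", report_conc[i])]] <- v[i]
      row[[paste0("visc_", report_conc[i], "_extrapolated")]] <-
        attr(v, "extrapolated")[i]
    }
    row$conc_at_threshold <- cx$concentration
    row$ci_low <- cx$ci_low
    row$ci_high <- cx$ci_high
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
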