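# Dose-response IC50 estimation: four-parameter logistic on log-concentration
# with censoring conventions matched to plate-screen reporting. The
# Levenberg-Marquardt optimiser is used directly (nls.lm) rather than through
# the nls-object wrapper, which cannot represent exactly-determined
# zero-residual fits.

#' Four-parameter logistic dose-response curve
#'
#' \deqn{y(c) = lower + (upper - lower) / (1 + (ic50/c)^{hill})}
#' Increasing in concentration for `hill > 0`; `ic50` is the inflection
#' concentration (the 50\% point when `lower = 0`, `upper = 100`).
#'
#' @param conc Concentrations (> 0).
#' @param lower,upper Bottom and top asymptotes (percent inhibition).
#' @param hill Hill slope.
#' @param ic50 Inflection concentration.
#' @return Percent inhibition.
#' @export
logistic4 <- function(conc, lower, upper, hill, ic50) {
  lower + (upper - lower) / (1 + (ic50 / conc)^hill)
}

#' Fit an IC50 from a concentration-inhibition series
#'
#' Estimates the concentration giving 50\% growth inhibition. Censoring is
#' decided first, from the observations at the extremes of the tested range:
#' inhibition already at or above 50\% at the lowest tested concentration is
#' reported as left-censored (`"< min"`, the plate-report convention for
#' highly potent extracts), and inhibition still below 50\% at the highest as
#' right-censored (`"> max"`). Otherwise a four-parameter logistic is fitted
#' by Levenberg-Marquardt least squares on log-concentration
#' ([minpack.lm::nls.lm]) and the IC50
#' is the fitted curve's 50\% crossing; if the fit fails or is degenerate the
#' estimate falls back to log-linear interpolation between the two adjacent
#' points bracketing 50\%.
#'
#' @param conc Tested concentrations (ug/mL, > 0, unique).
#' @param inhibition Percent growth inhibition at each concentration (may
#'   stray outside `[0, 100]` through noise).
#' @return Object of class `ic50_fit`: a list with elements `ic50`, `censor`
#'   (`"exact"`, `"below_min"` or `"above_max"`), `method`
#'   (`"logistic4"`, `"interpolation"` or `"censored"`), `fit_params`
#'   (named vector `lower`, `upper`, `hill`, `ic50` when fitted) and `data`.
#' @examples
#' conc <- c(10, 25, 50, 100)
#' fit <- fit_ic50(conc, logistic4(conc, 0, 100, 1, 15))
#' coef(fit)
#' @export
fit_ic50 <- function(conc, inhibition) {
  if (length(conc) != length(inhibition)) stop("conc and inhibition differ in length")
  if (length(conc) < 2) stop("need at least 2 dose-response points")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(conc)) stop("concentrations must be unique")
  o <- order(conc)
  conc <- conc[o]; y <- inhibition[o]
  dat <- data.frame(conc = conc, inhibition = y)

  mk <- function(value, censor, method, params = NULL) {
    structure(list(ic50 = value, censor = censor, method = method,
                   fit_params = params, data = dat), class = "ic50_fit")
  }
  if (y[1] >= 50) return(mk(conc[1], "below_min", "censored"))
  if (y[length(y)] < 50) return(mk(conc[length(conc)], "above_max", "censored"))

  fit <- tryCatch({
    start <- c(lower = max(-100, min(0, min(y))),
               upper = min(250, max(100, max(y))),
               hill = 1, lic50 = interpolate_l50(conc, y))
    resid_fn <- function(p) {
      y - (p[["lower"]] + (p[["upper"]] - p[["lower"]]) /
             (1 + exp(p[["hill"]] * (p[["lic50"]] - log(conc)))))
    }
    m <- minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(lower = -100, upper = 51, hill = 0.05, lic50 = log(min(conc)) - 5),
      upper = c(lower = 49, upper = 250, hill = 20, lic50 = log(max(conc)) + 5),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    if (!m$info %in% 1:4 || any(!is.finite(m$par))) stop("no convergence")
    p <- m$par
    params <- c(lower = unname(p["lower"]), upper = unname(p["upper"]),
                hill = unname(p["hill"]), ic50 = exp(unname(p["lic50"])))
    c50 <- crossing50(params)
    if (!is.finite(c50) || c50 <= 0) stop("no 50% crossing")
    mk(c50, "exact", "logistic4", params)
  }, error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  mk(exp(interpolate_l50(conc, y)), "exact", "interpolation")
}

# Concentration at which a fitted 4PL crosses 50%.
crossing50 <- function(p) {
  ratio <- (p[["upper"]] - 50) / (50 - p[["lower"]])
  p[["ic50"]] / ratio^(1 / p[["hill"]])
}

# log-concentration where the polyline through (log c, y) first crosses 50.
interpolate_l50 <- function(conc, y) {
  lc <- log(conc)
  hit <- which(y == 50)
  if (length(hit)) return(lc[hit[1]])
  i <- which(y[-length(y)] < 50 & y[-1] > 50)[1]
  if (is.na(i)) stop("no pair of points bracketing 50%")
  lc[i] + (50 - y[i]) * (lc[i + 1] - lc[i]) / (y[i + 1] - y[i])
}

#' @export
print.ic50_fit <- function(x, digits = 3, ...) {
  lab <- switch(x$censor,
                below_min = paste0("< ", format(x$ic50)),
                above_max = paste0("> ", format(x$ic50)),
                format(round(x$ic50, digits)))
  cat("IC50:", lab, "ug/mL (", x$method, ")\n")
  if (!is.null(x$fit_params)) {
    cat("4PL parameters:\n"); print(round(x$fit_params, digits))
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  if (!is.null(object$fit_params)) object$fit_params else c(ic50 = object$ic50)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  p <- object$fit_params
  if (is.null(p)) stop("no fitted curve available for a ", object$method, " estimate")
  logistic4(conc, p[["lower"]], p[["upper"]], p[["hill"]], p[["ic50"]])
}
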