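#' Linear trend fit of focal pressure against a swept parameter
#'
#' Ordinary least squares of `y = m x + b`, the model used for every
#' structural and for the density/speed acoustic trends.  `x` can be a
#' [run_sweep()] result, in which case the swept value is regressed against
#' the focal peak in kPa.
#'
#' @param x Numeric sweep values, or a `fus_sweep`.
#' @param y Focal pressures (kPa by convention); ignored when `x` is a sweep.
#' @return An object of class `fus_fit` supporting [predict()],
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @examples
#' fit_linear(c(1, 2, 3), c(3, 5, 7))  # slope 2, intercept 1
#' @export
fit_linear <- function(x, y = NULL) {
  d <- fit_data(x, y)
  if (nrow(d) < 3) abort("need at least 3 points for a linear fit")
  if (diff(range(d$x)) == 0) abort("degenerate-x error: all x equal",
                                   class = "fus_degenerate_x")
  m <- lm(y ~ x, data = d)
  new_fit("linear", d,
          coefficients = c(slope = unname(coef(m)[2]),
                           intercept = unname(coef(m)[1])),
          fitted = unname(predict(m)), lm = m)
}

#' Power-law trend fit
#'
#' Nonlinear least squares for `y = a x^b + c`, the model used for the
#' absorption-coefficient trend.  Starting values: `c0` slightly below
#' `min(y)`, `b0` from the log-log slope of `y - c0`, `a0` from the first
#' point; the exponent is bounded to `[-2, 2]`.
#'
#' @inheritParams fit_linear
#' @return A `fus_fit`.
#' @export
fit_power <- function(x, y = NULL) {
  d <- fit_data(x, y)
  if (nrow(d) < 4) abort("need at least 4 points for a power fit")
  if (any(d$x <= 0)) abort("power fit needs x > 0")
  c0 <- min(d$y) - 0.05 * diff(range(d$y))
  lf <- lm(log(y - c0) ~ log(x), data = d)
  b0 <- max(-2, min(2, unname(coef(lf)[2])))
  a0 <- (d$y[1] - c0) / d$x[1]^b0
  m <- minpack.lm::nlsLM(
    y ~ a * x^b + cc, data = d,
    start = list(a = a0, b = b0, cc = c0),
    lower = c(a = -Inf, b = -2, cc = -Inf),
    upper = c(a = Inf, b = 2, cc = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(m)
  new_fit("power", d,
          coefficients = c(a = unname(cf["a"]), b = unname(cf["b"]),
                           c = unname(cf["cc"])),
          fitted = unname(predict(m)), nls = m)
}

fit_data <- function(x, y) {
  if (inherits(x, "fus_sweep")) {
    xv <- x$value
    yv <- x$peak_kpa
  } else {
    xv <- as.numeric(x)
    yv <- as.numeric(y)
  }
  ok <- !is.na(yv)
  tibble(x = xv[ok], y = yv[ok])
}

new_fit <- function(form, data, coefficients, fitted, ...) {
  ss_res <- sum((data$y - fitted)^2)
  ss_tot <- sum((data$y - mean(data$y))^2)
  structure(list(model_form = form, coefficients = coefficients,
                 data = data, fitted = fitted,
                 residuals = data$y - fitted,
                 r_squared = 1 - ss_res / ss_tot, ...),
            class = "fus_fit")
}

#' @export
print.fus_fit <- function(x, ...) {
  cf <- x$coefficients
  eq <- if (x$model_form == "linear")
    sprintf("y = %.4g x + %.4g", cf["slope"], cf["intercept"])
  else sprintf("y = %.4g x^%.4g + %.4g", cf["a"], cf["b"], cf["c"])
  cat(sprintf("<fus_fit %s> %s  (R^2 = %.4f, n = %d)\n",
              x$model_form, eq, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
predict.fus_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
  else if (is.list(newdata)) newdata$x else as.numeric(newdata)
  cf <- object$coefficients
  if (object$model_form == "linear") cf["slope"] * x + cf["intercept"]
  else cf["a"] * x^cf["b"] + cf["c"]
}

#' @importFrom generics tidy
#' @export
tidy.fus_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @importFrom generics glance
#' @export
glance.fus_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, model_form = x$model_form,
         nobs = nrow(x$data), sigma = sd(x$residuals))
}

#' Unit attenuation implied by a linear trend
#'
#' Converts a linear focal-pressure trend into a dB loss per unit parameter
#' step, referenced to the fitted intercept ("initial" pressure):
#' `20 log10(b / (b - |m| step))`.  This intercept-referenced convention is
#' documented prominently because other references (e.g. first-sample
#' referencing) give slightly different numbers.
#'
#' @param fit A linear `fus_fit`.
#' @param step Parameter increment (same unit as the fit's x; default 1).
#' @return Attenuation in dB per `step`.
#' @export
unit_attenuation <- function(fit, step = 1) {
  if (fit$model_form != "linear") abort("unit attenuation needs a linear fit")
  m <- fit$coefficients[["slope"]]; b <- fit$coefficients[["intercept"]]
  if (b - abs(m) * step <= 0)
    abort("domain error: intercept minus one step's loss is not positive")
  20 * log10(b / (b - abs(m) * step))
}

#' Agreement between two fitted trends
#'
#' Pearson correlation of the two fitted curves evaluated at the sweep
#' values — the agreement statistic quoted alongside each pair of fits.
#'
#' @param fit_a,fit_b `fus_fit` objects.
#' @param x Values at which to evaluate both curves.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_fit_agreement <- function(fit_a, fit_b, x) {
  ya <- predict(fit_a, x); yb <- predict(fit_b, x)
  tol <- 1e-10
  if (sd(ya) <= tol * (abs(mean(ya)) + 1) ||
      sd(yb) <= tol * (abs(mean(yb)) + 1))
    abort("undefined-r error: a fitted curve is constant",
          class = "fus_undefined_r")
  cor(ya, yb)
}

#' Published comparison trend fits
#'
#' Reference linear-trend coefficients for the bench (hydrophone) and
#' finite-element comparison arms of the structural sweeps, kept only so
#' that fitted-curve agreement statistics can be reported next to a
#' simulated sweep.  Units: x in mm, y in kPa.
#'
#' @param parameter `"thickness"`, `"curvature"` or `"distance"`.
#' @param arm `"experiment"` or `"fem"`.
#' @return A linear `fus_fit` with the published coefficients and no data.
#' @export
reference_fit <- function(parameter = c("thickness", "curvature", "distance"),
                          arm = c("experiment", "fem")) {
  parameter <- match.arg(parameter); arm <- match.arg(arm)
  cf <- list(
    thickness = list(experiment = c(-15.09, 360.7), fem = c(-14.26, 346)),
    curvature = list(experiment = c(-0.868, 286.9), fem = c(-0.315, 258.9)),
    distance  = list(experiment = c(-2.695, 268),   fem = c(-0.639, 248.2))
  )[[parameter]][[arm]]
  structure(list(model_form = "linear",
                 coefficients = c(slope = cf[1], intercept = cf[2]),
                 data = tibble(x = numeric(), y = numeric()),
                 fitted = numeric(), residuals = numeric(),
                 r_squared = NA_real_),
            class = "fus_fit")
}
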