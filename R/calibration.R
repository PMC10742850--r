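# Calibration computations: the water-feed balance and linear standard
# curves (tracer concentration vs a colour feature; feed-unit rpm vs g/min
# maps).  Moisture contents are fractions internally; the CLI accepts
# percentages.

#' Specify a feed condition for the water-feed balance
#'
#' @param v_mf Material feeding speed, g/min, >= 0.
#' @param c_in Initial (raw material) moisture content, fraction in `[0, 1)`.
#' @param c_ex Expected (target) moisture content, fraction in `[c_in, 1)`.
#' @return An object of class `feed_spec`.
#' @export
feed_spec <- function(v_mf, c_in, c_ex) {
  check_number(v_mf, "v_mf", lower = 0)
  check_number(c_in, "c_in", lower = 0, upper = 1, strict_upper = TRUE)
  if (!is.numeric(c_ex) || length(c_ex) != 1L || !is.finite(c_ex) ||
      c_ex >= 1) {
    abort("c_ex must be a fraction < 1", "extrurtd_domain_error")
  }
  if (c_ex < c_in) {
    abort("c_ex < c_in would require a negative water feed rate",
          "extrurtd_negative_rate")
  }
  structure(list(v_mf = v_mf, c_in = c_in, c_ex = c_ex), class = "feed_spec")
}

#' Water feeding speed from the moisture balance
#'
#' `V_wf = (C_ex - C_in) / (1 - C_ex) * V_mf`: the water addition rate that
#' brings material of moisture `C_in` up to moisture `C_ex` at a dry-feed
#' rate `V_mf`.
#'
#' @param spec A [feed_spec()].
#' @return Water feeding speed in g/min.
#' @export
water_feed_rate <- function(spec) {
  stopifnot(inherits(spec, "feed_spec"))
  (spec$c_ex - spec$c_in) / (1 - spec$c_ex) * spec$v_mf
}

#' Fit a linear calibration map by ordinary least squares
#'
#' @param x Predictor values (e.g. tracer concentration in mg/g, or set
#'   feeder rpm); length >= 3 and not constant.
#' @param y Response values (e.g. colour feature, or measured g/min).
#' @param kind `"standard_curve"` or `"feed_map"`.
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared` and `kind`.
#' @export
fit_linear_map <- function(x, y, kind = c("standard_curve", "feed_map")) {
  kind <- match.arg(kind)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("x and y must be finite numeric vectors of equal length >= 3",
          "extrurtd_domain_error")
  }
  if (stats::sd(x) == 0) {
    abort("x is constant: the linear map is degenerate",
          "extrurtd_degenerate_fit")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  structure(
    list(slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         r_squared = r2, kind = kind),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve:%s> y = %.6g * x + %.6g (R^2 = %.4f)\n",
              x$kind, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a standard curve: colour feature to tracer concentration
#'
#' The standard curve is fitted as `feature = slope * concentration +
#' intercept`; this solves for concentration and clips negative results to
#' zero (with attribute `clipped = TRUE`).
#'
#' @param curve A [fit_linear_map()] result.
#' @param feature_value Measured colour-feature value(s).
#' @return Concentration(s) in mg/g.
#' @export
invert_standard_curve <- function(curve, feature_value) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    abort("standard curve has zero slope and cannot be inverted",
          "extrurtd_degenerate_fit")
  }
  conc <- (feature_value - curve$intercept) / curve$slope
  clipped <- conc < 0
  conc <- pmax(conc, 0)
  if (any(clipped)) attr(conc, "clipped") <- TRUE
  conc
}
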