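# Residence time distribution analysis of pulse-tracer experiments.
#
# A tracer pulse is injected at the extruder inlet and product samples are
# collected at the die on a (typically 10 s) grid.  The sampled concentration
# curve C(t) is normalized to the exit-age density E(t), integrated to the
# cumulative distribution F(t), summarized by its first two moments (mean
# residence time MRT and variance), rendered dimensionless in theta = t/MRT,
# and finally converted to a Peclet number by inverting the closed-vessel
# axial-dispersion relation
#     sigma_theta^2 = 2/Pe - (2/Pe^2) (1 - exp(-Pe)).
#
# Discretization follows the segment-sum convention: integrals are
# approximated by sums of C_i * dt_i with dt_i = t_i - t_{i-1} and
# dt_1 = t_2 - t_1.  A trapezoid alternative is available via `method`.

#' Construct a tracer concentration time series
#'
#' @param times Sampling times in seconds; strictly increasing, length >= 2.
#' @param concentrations Tracer concentrations in mg tracer per g extrudate;
#'   finite and non-negative, with at least one positive value.
#' @param run_label Free-text label for the run.
#' @return An object of class `tracer_series`.
#' @export
tracer_series <- function(times, concentrations, run_label = "") {
  if (!is.numeric(times) || !is.numeric(concentrations)) {
    abort("times and concentrations must be numeric", "extrurtd_domain_error")
  }
  if (length(times) < 2L || length(times) != length(concentrations)) {
    abort("need >= 2 samples with one concentration per time",
          "extrurtd_domain_error")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort("times must be finite and strictly increasing",
          "extrurtd_domain_error")
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    abort("concentrations must be finite and >= 0", "extrurtd_domain_error")
  }
  if (all(concentrations == 0)) {
    abort("all concentrations are zero: series cannot be normalized",
          "extrurtd_unnormalizable")
  }
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         run_label = as.character(run_label)[1L]),
    class = "tracer_series")
}

#' @export
print.tracer_series <- function(x, ...) {
  cat(sprintf("<tracer_series> %s: %d samples, t in [%g, %g] s, peak %.4g mg/g\n",
              if (nzchar(x$run_label)) x$run_label else "(unlabelled)",
              length(x$times), min(x$times), max(x$times),
              max(x$concentrations)))
  invisible(x)
}

# Segment widths: dt_i = t_i - t_{i-1}; the first segment reuses the width
# of the second so every sample carries a weight.
segment_widths <- function(times) {
  dt <- diff(times)
  c(dt[1L], dt)
}

integration_weights <- function(times, method = c("segment", "trapezoid")) {
  method <- match.arg(method)
  n <- length(times)
  if (method == "segment") return(segment_widths(times))
  dt <- diff(times)
  w <- numeric(n)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}

# Baseline handling: subtract, clip negatives to zero.
apply_baseline <- function(series, baseline) {
  check_number(baseline, "baseline", lower = 0)
  if (baseline >= max(series$concentrations)) {
    abort("baseline must be below the peak concentration",
          "extrurtd_domain_error")
  }
  pmax(series$concentrations - baseline, 0)
}

#' Trim trailing samples at or below baseline
#'
#' Emulates the sampling rule of stopping collection once no tracer colour
#' remains: trailing samples whose concentration is below `baseline + eps`
#' are dropped (interior zeros are kept).
#'
#' @param series A [tracer_series()].
#' @param baseline Background concentration in mg/g.
#' @param eps Detection threshold above baseline, mg/g.
#' @return A `tracer_series` with trailing background samples removed.
#' @export
trim_trailing_baseline <- function(series, baseline = 0, eps = 1e-6) {
  stopifnot(inherits(series, "tracer_series"))
  keep <- which(series$concentrations >= baseline + eps)
  if (length(keep) == 0L) {
    abort("no sample exceeds baseline + eps", "extrurtd_unnormalizable")
  }
  last <- max(keep)
  if (last < 2L) last <- 2L
  tracer_series(series$times[seq_len(last)],
                series$concentrations[seq_len(last)],
                series$run_label)
}

#' Normalize a tracer curve to the exit-age density E(t)
#'
#' E_i = C_i / sum_j C_j dt_j, so that sum_i E_i dt_i = 1.
#'
#' @inheritParams trim_trailing_baseline
#' @param method Discretization of the integral: `"segment"` (C_i dt_i sums,
#'   the default) or `"trapezoid"`.
#' @return An object of class `rtd_curves` with fields `times`, `E` and the
#'   integration weights; `F` and the dimensionless fields are filled by
#'   [cumulative_F()] and [dimensionless()].
#' @export
normalize_to_E <- function(series, baseline = 0,
                           method = c("segment", "trapezoid")) {
  stopifnot(inherits(series, "tracer_series"))
  method <- match.arg(method)
  conc <- apply_baseline(series, baseline)
  w <- integration_weights(series$times, method)
  denom <- sum(conc * w)
  if (denom <= 0) {
    abort("signal is zero after baseline subtraction",
          "extrurtd_unnormalizable")
  }
  structure(
    list(times = series$times, E = conc / denom, F = NULL,
         theta = NULL, E_theta = NULL, F_theta = NULL,
         weights = w, method = method),
    class = "rtd_curves")
}

#' Cumulative residence time distribution F(t)
#'
#' F_i = sum_{j <= i} E_j dt_j; nondecreasing with terminal value 1.
#'
#' @param curves An `rtd_curves` object from [normalize_to_E()].
#' @return The same object with the `F` field filled.
#' @export
cumulative_F <- function(curves) {
  stopifnot(inherits(curves, "rtd_curves"), !is.null(curves$E))
  curves$F <- cumsum(curves$E * curves$weights)
  if (!is.null(curves$theta)) curves$F_theta <- curves$F
  curves
}

rtd_moments <- function(series, baseline, method) {
  conc <- apply_baseline(series, baseline)
  w <- integration_weights(series$times, method)
  t <- series$times
  denom <- sum(conc * w)
  if (denom <= 0) {
    abort("signal is zero after baseline subtraction",
          "extrurtd_unnormalizable")
  }
  m1 <- sum(conc * t * w) / denom
  m2 <- sum(conc * t^2 * w) / denom
  list(mrt = m1, m2 = m2)
}

#' Mean residence time
#'
#' First moment of the exit-age density:
#' MRT = sum C_i t_i dt_i / sum C_i dt_i.
#'
#' @inheritParams normalize_to_E
#' @return MRT in seconds.
#' @export
mean_residence_time <- function(series, baseline = 0,
                                method = c("segment", "trapezoid")) {
  stopifnot(inherits(series, "tracer_series"))
  rtd_moments(series, baseline, match.arg(method))$mrt
}

#' Variance of the residence time distribution
#'
#' sigma^2 = sum C_i t_i^2 dt_i / sum C_i dt_i - MRT^2.
#'
#' @inheritParams normalize_to_E
#' @param mrt Mean residence time of the same series, seconds.
#' @return Variance in seconds^2.
#' @export
rtd_variance <- function(series, mrt, baseline = 0,
                         method = c("segment", "trapezoid")) {
  stopifnot(inherits(series, "tracer_series"))
  check_number(mrt, "mrt", lower = 0, strict_lower = TRUE)
  m <- rtd_moments(series, baseline, match.arg(method))
  v <- m$m2 - mrt^2
  if (v < -1e-9 * max(1, mrt^2)) {
    abort("negative variance: mrt is inconsistent with the series",
          "extrurtd_numerical_inconsistency")
  }
  max(v, 0)
}

#' Dimensionless residence time curves
#'
#' theta = t/MRT, E(theta) = MRT * E(t), F(theta) = F(t).
#'
#' @param curves An `rtd_curves` object (with `F` if already computed).
#' @param mrt Mean residence time in seconds, > 0.
#' @return The curves object with `theta`, `E_theta` and `F_theta` filled.
#' @export
dimensionless <- function(curves, mrt) {
  stopifnot(inherits(curves, "rtd_curves"))
  check_number(mrt, "mrt", lower = 0, strict_lower = TRUE)
  curves$theta <- curves$times / mrt
  curves$E_theta <- mrt * curves$E
  if (!is.null(curves$F)) curves$F_theta <- curves$F
  curves
}

#' Closed-vessel dispersion relation: Peclet number to sigma_theta^2
#'
#' Evaluates `2/Pe - (2/Pe^2) (1 - exp(-Pe))`, the dimensionless RTD
#' variance of the axial-dispersion model with closed-closed boundaries.
#' Strictly decreasing: -> 1 as Pe -> 0+ (fully mixed) and -> 0 as
#' Pe -> Inf (plug flow).  Evaluated in the cancellation-free form
#' `2 (Pe + expm1(-Pe)) / Pe^2`, with a series fallback for tiny Pe.
#'
#' @param pe Peclet number(s), > 0.
#' @return sigma_theta^2 in (0, 1).
#' @export
peclet_forward <- function(pe) {
  if (!is.numeric(pe) || length(pe) == 0L || any(!is.finite(pe)) ||
      any(pe <= 0)) {
    abort("pe must be finite and > 0", "extrurtd_domain_error")
  }
  out <- 2 * (pe + expm1(-pe)) / pe^2
  tiny <- pe < 1e-4
  if (any(tiny)) out[tiny] <- 1 - pe[tiny] / 3 + pe[tiny]^2 / 12
  out
}

#' Invert the closed-vessel dispersion relation
#'
#' Finds the unique Pe with [peclet_forward()]`(Pe) == sigma_theta2` by
#' bracketed root-finding; the relation is monotone so the bracket
#' `[1e-6, 1e6]` (expanded if needed) always contains the root.
#'
#' @param sigma_theta2 Dimensionless RTD variance, in (0, 1).
#' @param tol Maximum allowed residual on sigma_theta^2.
#' @return The Peclet number.
#' @export
solve_peclet <- function(sigma_theta2, tol = 1e-10) {
  check_number(sigma_theta2, "sigma_theta2")
  if (sigma_theta2 >= 1) {
    abort("sigma_theta2 >= 1: more dispersed than a single ideal mixer, no closed-vessel solution",
          "extrurtd_no_solution")
  }
  if (sigma_theta2 <= 0) {
    abort("sigma_theta2 must be > 0", "extrurtd_domain_error")
  }
  lower <- 1e-6
  upper <- 1e6
  while (peclet_forward(upper) > sigma_theta2 && upper < 1e12) upper <- upper * 10
  while (peclet_forward(lower) < sigma_theta2 && lower > 1e-12) lower <- lower / 10
  root <- stats::uniroot(function(p) peclet_forward(p) - sigma_theta2,
                         lower = lower, upper = upper, tol = 1e-14)$root
  if (abs(peclet_forward(root) - sigma_theta2) > tol) {
    abort("root-finder failed to reach the requested residual",
          "extrurtd_numerical_inconsistency")
  }
  root
}

#' Full RTD analysis of one tracer run
#'
#' Composes baseline handling, E/F normalization, moments, dimensionless
#' curves and Peclet inversion into one summary.
#'
#' @inheritParams normalize_to_E
#' @param trim Drop trailing baseline samples first (see
#'   [trim_trailing_baseline()]).
#' @return An object of class `rtd_summary` with fields `mrt` (s),
#'   `variance` (s^2), `sigma_theta2`, `peclet` (NA when unsolvable),
#'   `peclet_solvable`, `curves` and `run_label`.
#' @export
analyze_run <- function(series, baseline = 0, trim = TRUE,
                        method = c("segment", "trapezoid")) {
  stopifnot(inherits(series, "tracer_series"))
  method <- match.arg(method)
  if (trim) series <- trim_trailing_baseline(series, baseline)
  curves <- cumulative_F(normalize_to_E(series, baseline, method))
  mrt <- mean_residence_time(series, baseline, method)
  variance <- rtd_variance(series, mrt, baseline, method)
  curves <- dimensionless(curves, mrt)
  sigma_theta2 <- variance / mrt^2
  solvable <- sigma_theta2 > 0 && sigma_theta2 < 1
  peclet <- if (solvable) solve_peclet(sigma_theta2) else NA_real_
  structure(
    list(mrt = mrt, variance = variance, sigma_theta2 = sigma_theta2,
         peclet = peclet, peclet_solvable = solvable, curves = curves,
         run_label = series$run_label),
    class = "rtd_summary")
}

#' @export
print.rtd_summary <- function(x, ...) {
  cat(sprintf("<rtd_summary> %s\n",
              if (nzchar(x$run_label)) x$run_label else "(unlabelled)"))
  cat(sprintf("  MRT        %10.2f s\n", x$mrt))
  cat(sprintf("  variance   %10.2f s^2\n", x$variance))
  cat(sprintf("  sigma_t^2  %10.5f\n", x$sigma_theta2))
  if (x$peclet_solvable) {
    cat(sprintf("  Peclet     %10.2f\n", x$peclet))
  } else {
    cat("  Peclet     unsolvable (sigma_theta^2 outside (0,1))\n")
  }
  invisible(x)
}

#' Percentage reduction between two quantities
#'
#' `100 * (before - after) / before`, as used to report mean-residence-time
#' reductions between operating conditions.
#'
#' @param before Reference value, > 0.
#' @param after Comparison value.
#' @return Signed percentage reduction.
#' @export
relative_change <- function(before, after) {
  check_number(before, "before", lower = 0, strict_lower = TRUE)
  check_number(after, "after")
  100 * (before - after) / before
}
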