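#' Steady-state yield of one decay component
#'
#' The photon yield attributed to component `i` of a global fit is
#' `tau_i * sum_lambda max(das_i, 0) * dlambda` over the chosen window —
#' the steady-state contribution of that component, with negative
#' (energy-transfer rise) lobes excluded. Set `weight_by_tau = FALSE` for
#' the amplitude-only definition.
#'
#' @param fit A `das_fit`.
#' @param component Component index (in ascending-lifetime order), or
#'   `"slow"` for the largest lifetime.
#' @param window_nm Length-2 wavelength window, nm (default: full fitted
#'   range).
#' @param weight_by_tau Multiply the integrated amplitude by the lifetime
#'   (default `TRUE`).
#' @return Yield in arbitrary units (counts x nm x ns).
#' @export
component_yield <- function(fit, component = "slow", window_nm = NULL,
                            weight_by_tau = TRUE) {
  stopifnot(inherits(fit, "das_fit"))
  i <- if (identical(component, "slow")) which.max(fit$lifetimes_ns)
       else as.integer(component)
  if (i < 1 || i > fit$n_components) stop_pbsq("no such component: ", component)
  wl <- fit$wavelengths_nm
  window_nm <- window_nm %||% range(wl)
  sel <- wl >= window_nm[1] & wl <= window_nm[2]
  if (!any(sel)) stop_pbsq("empty wavelength window")
  dl <- if (sum(sel) > 1) mean(diff(wl[sel])) else 1
  amp <- sum(pmax(fit$das[i, sel], 0)) * dl
  if (weight_by_tau) amp * fit$lifetimes_ns[i] else amp
}

#' Quenching efficiency from paired global fits
#'
#' Efficiency of quenching is the relative reduction of the slow
#' (nanosecond) component's yield:
#' `E = 1 - Y_slow(quenched) / Y_slow(unquenched)`, clipped to `[0, 1]`
#' with a warning if numerical noise pushes it outside.
#'
#' @param unquenched,quenched `das_fit` objects for the two conditions.
#' @param window_nm Wavelength window passed to [component_yield()].
#' @param weight_by_tau See [component_yield()].
#' @return Object of class `quench_result` with fields `E`,
#'   `yield_unquenched`, `yield_quenched`, `tau_slow_ns` (both fits).
#' @export
quench_efficiency <- function(unquenched, quenched, window_nm = NULL,
                              weight_by_tau = TRUE) {
  stopifnot(inherits(unquenched, "das_fit"), inherits(quenched, "das_fit"))
  tu <- max(unquenched$lifetimes_ns)
  tq <- max(quenched$lifetimes_ns)
  if (max(tu, tq) / min(tu, tq) > 3)
    warning("slow-component lifetimes differ by more than 3x across conditions; ",
            "the yield comparison may not be component-to-component")
  yu <- component_yield(unquenched, "slow", window_nm, weight_by_tau)
  yq <- component_yield(quenched, "slow", window_nm, weight_by_tau)
  if (yu <= 0) stop_pbsq("unquenched slow-component yield is zero")
  E <- 1 - yq / yu
  if (E < 0 || E > 1) {
    warning("efficiency ", signif(E, 4), " outside [0, 1]; clipping")
    E <- min(max(E, 0), 1)
  }
  structure(list(E = E, yield_unquenched = yu, yield_quenched = yq,
                 tau_slow_ns = c(unquenched = tu, quenched = tq)),
            class = "quench_result")
}

#' @export
print.quench_result <- function(x, ...) {
  cat(sprintf("Quenching efficiency E = %.3f (slow-component yield %.4g -> %.4g, tau %.3g / %.3g ns)\n",
              x$E, x$yield_unquenched, x$yield_quenched,
              x$tau_slow_ns[1], x$tau_slow_ns[2]))
  invisible(x)
}

#' Jin's additivity statistic for two quenchers
#'
#' Compares the combined quenching efficiency with the Bliss-independent
#' composition of the single efficiencies:
#' `Q = E_combined / (E_alpha + E_beta - E_alpha * E_beta)`.
#' Classification: `Q < 0.85` antagonism; `0.85 <= Q <= 1.15` additive;
#' `Q >= 1.15` synergism (boundaries inclusive for the additive band).
#'
#' @param E_alpha,E_beta Single-quencher efficiencies, each in (0, 1).
#' @param E_combined Efficiency of the combination, in (0, 1].
#' @return Object of class `jin_result` with fields `E_alpha`, `E_beta`,
#'   `E_combined`, `Q`, `classification`.
#' @examples
#' jin_q(0.5, 0.5, 0.75)  # Q = 1, additive
#' @export
jin_q <- function(E_alpha, E_beta, E_combined) {
  for (e in c(E_alpha, E_beta))
    if (!is.finite(e) || e <= 0 || e >= 1)
      stop_pbsq("single-quencher efficiencies must lie strictly in (0, 1)")
  if (!is.finite(E_combined) || E_combined <= 0)
    stop_pbsq("combined efficiency must be positive")
  denom <- E_alpha + E_beta - E_alpha * E_beta
  if (denom <= 0) stop_pbsq("Bliss denominator must be positive")
  Q <- E_combined / denom
  classification <- if (Q < 0.85) "antagonism"
                    else if (Q <= 1.15) "additive" else "synergism"
  structure(list(E_alpha = E_alpha, E_beta = E_beta, E_combined = E_combined,
                 Q = Q, classification = classification),
            class = "jin_result")
}

#' @export
print.jin_result <- function(x, ...) {
  cat(sprintf("Jin's Q = %.3f (%s): E_alpha = %.3f, E_beta = %.3f, E_combined = %.3f\n",
              x$Q, x$classification, x$E_alpha, x$E_beta, x$E_combined))
  invisible(x)
}

#' Fit a quenching induction time course
#'
#' Least-squares fit of `F(t)/F(0) = 1 - E_max (1 - exp(-k_act t))` to a
#' fluorescence trace. The time of twofold fluorescence reduction is
#' solved analytically, `t_half = -log(1 - 0.5 / E_max) / k_act`, and is
#' defined only when `E_max > 0.5`.
#'
#' @param trace Data frame with columns `t_s` and `F` (fluorescence, any
#'   units; normalised internally by the fitted F(0) = value at t = 0).
#' @return Object of class `npq_fit` with `k_act_s`, `E_max`, `t_half_s`
#'   (`NA` when undefined), `fitted`, `residuals`.
#' @export
fit_npq_timecourse <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("t_s", "F") %in% names(trace)))
  if (nrow(trace) < 10) stop_pbsq("need at least 10 points")
  if (trace$F[which.min(trace$t_s)] <= 0) stop_pbsq("trace must start positive")
  if (any(trace$F <= 0)) stop_pbsq("trace must be positive")
  f0 <- trace$F[which.min(trace$t_s)]
  d <- data.frame(t = trace$t_s, y = trace$F / f0)
  drop_total <- 1 - min(d$y)
  start <- list(E = min(max(drop_total, 1e-3), 0.999),
                k = 1 / max(stats::median(d$t), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - E * (1 - exp(-k * t)), data = d, start = start,
                      lower = c(E = 0, k = 0), upper = c(E = 1, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    E <- unname(co["E"]); k <- unname(co["k"])
    fv <- stats::fitted(fit)
  } else {
    # degenerate traces (e.g. flat, E ~ 0) have a singular gradient; fall
    # back to bounded direct minimisation of the same least squares
    sse <- function(p) {
      E <- stats::plogis(p[1]); k <- exp(p[2])
      sum((d$y - (1 - E * (1 - exp(-k * d$t))))^2)
    }
    o <- stats::optim(c(stats::qlogis(max(start$E, 1e-6)), log(start$k)), sse,
                      method = "Nelder-Mead")
    E <- stats::plogis(o$par[1]); k <- exp(o$par[2])
    if (E < 1e-6) E <- 0
    fv <- 1 - E * (1 - exp(-k * d$t))
  }
  t_half <- if (E > 0.5 && k > 0) -log(1 - 0.5 / E) / k else NA_real_
  structure(list(k_act_s = k, E_max = E, t_half_s = t_half,
                 fitted = fv * f0, residuals = (d$y - fv) * f0, nls = fit),
            class = "npq_fit")
}

#' @export
print.npq_fit <- function(x, ...) {
  cat(sprintf("NPQ time-course fit: E_max = %.3f, k_act = %.4g s^-1, t_half = %s\n",
              x$E_max, x$k_act_s,
              if (is.na(x$t_half_s)) "undefined (E_max <= 0.5)"
              else sprintf("%.3g s", x$t_half_s)))
  invisible(x)
}

#' Arrhenius fit of photocycle time constants
#'
#' Ordinary least squares of `ln(1/t)` on `1000 / T(K)` over a
#' temperature series of R->O recovery time constants. The activation
#' energy follows from the slope: `Ea = -slope * R` in kJ/mol
#' (R = 8.314 J mol^-1 K^-1). Duplicate temperatures are averaged.
#'
#' @param temperature_C Temperatures, degrees Celsius (>= 3 distinct).
#' @param time_constant_s Recovery time constants, s (> 0).
#' @return Object of class `arrhenius_fit` with `Ea_kJmol`, `lnA`,
#'   `r_squared`, `rates_s` (named by temperature), and the `lm` fit.
#' @export
arrhenius_fit <- function(temperature_C, time_constant_s) {
  stopifnot(length(temperature_C) == length(time_constant_s))
  if (any(time_constant_s <= 0)) stop_pbsq("time constants must be positive")
  k <- tapply(1 / time_constant_s, temperature_C, mean)
  TC <- as.numeric(names(k))
  if (length(TC) < 3) stop_pbsq("need at least 3 distinct temperatures")
  TK <- TC + 273.15
  x <- 1000 / TK
  fit <- stats::lm(log(k) ~ x)
  sl <- unname(stats::coef(fit)[2])
  structure(list(Ea_kJmol = -sl * 8.314,
                 lnA = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 rates_s = stats::setNames(as.numeric(k), TC),
                 lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures: Ea = %.2f kJ/mol, lnA = %.3f, R^2 = %.4f\n",
              length(x$rates_s), x$Ea_kJmol, x$lnA, x$r_squared))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...)
  c(Ea_kJmol = object$Ea_kJmol, lnA = object$lnA)

#' Arrhenius plot
#'
#' @param x An `arrhenius_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.arrhenius_fit <- function(x, ...) {
  TC <- as.numeric(names(x$rates_s))
  xx <- 1000 / (TC + 273.15)
  graphics::plot(xx, log(x$rates_s), xlab = "1000 / T (1/K)",
                 ylab = "ln k (1/s)", ...)
  graphics::abline(x$lm, col = 2)
  invisible(x)
}
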