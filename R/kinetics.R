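#' Rotational free-energy barrier with its temperature
#'
#' A `barrier_spec` couples a free energy of activation for bond rotation
#' (kJ mol^-1) with the temperature (K) at which it applies, so that
#' barrier/rate conversions are always done at a stated temperature.
#'
#' @param dG_double_dagger Free energy of activation, kJ mol^-1. Must be > 0.
#' @param temperature Absolute temperature, K. Must be > 0.
#' @return An object of class `barrier_spec`.
#' @examples
#' barrier_spec(79, 313.15)   # labile oxidized state at 40 C
#' barrier_spec(136, 373.15)  # configurationally stable reduced state
#' @seealso [eyring_rate()], [barrier_from_rate()]
#' @export
barrier_spec <- function(dG_double_dagger, temperature) {
  stopifnot(is.numeric(dG_double_dagger), is.numeric(temperature),
            length(dG_double_dagger) == 1L, length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a positive number of kelvin", call. = FALSE)
  }
  if (!is.finite(dG_double_dagger) || dG_double_dagger <= 0) {
    stop("`dG_double_dagger` must be positive (kJ mol^-1)", call. = FALSE)
  }
  structure(
    list(dG_double_dagger = dG_double_dagger, temperature = temperature),
    class = "barrier_spec"
  )
}

#' @export
print.barrier_spec <- function(x, ...) {
  cat(sprintf("Rotational barrier: dG' = %.4g kJ/mol at %.2f K (k = %.4g /s)\n",
              x$dG_double_dagger, x$temperature, eyring_rate(x)))
  invisible(x)
}

#' Rate constants and operating conditions of the cyclic redox network
#'
#' Bundles the elementary rate parameters of the motor's dissipative redox
#' cycle with the standard operating conditions. Defaults are the measured
#' values under the standard conditions (40 C, 10 mM motor, 100 mM
#' ammonia-borane fuel): the enantiomerization coefficient of the oxidized
#' state, the second-order borane reduction constant, the pseudo-zero-order
#' enzymatic oxidation velocity, and the average oxidation enantioselectivity
#' inferred from the isotopomer experiments.
#'
#' @param k_enant First-order enantiomerization rate constant of the oxidized
#'   state, per direction (Sa -> Ra), s^-1.
#' @param k_red2 Second-order reduction rate constant, mM^-1 s^-1.
#' @param v_ox Pseudo-zero-order oxidation velocity, mM s^-1.
#' @param ee_ox Oxidation enantioselectivity as a signed fraction in [-1, 1];
#'   positive means the oxidation prefers the Sa-configured aldehyde.
#' @param conc_motor_total Total motor concentration, mM.
#' @param conc_fuel0 Initial fuel (H3N-BH3) concentration, mM.
#' @param k_fuel_bg First-order background fuel-decomposition rate constant,
#'   s^-1 (the fuel-to-waste side reaction; no measured constant, default 0).
#' @param temperature Operating temperature, K.
#' @return An object of class `rate_parameters`.
#' @examples
#' rate_parameters()                       # standard operating conditions
#' rate_parameters(ee_ox = 0, conc_fuel0 = 50)
#' @export
rate_parameters <- function(k_enant = 0.42,
                            k_red2 = 2.1e-3,
                            v_ox = 5.59e-4,
                            ee_ox = 0.876,
                            conc_motor_total = 10,
                            conc_fuel0 = 100,
                            k_fuel_bg = 0,
                            temperature = .T_OPERATING) {
  rates <- c(k_enant = k_enant, k_red2 = k_red2, v_ox = v_ox,
             k_fuel_bg = k_fuel_bg)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(ee_ox) || abs(ee_ox) > 1) {
    stop("`ee_ox` must lie in [-1, 1]", call. = FALSE)
  }
  if (!is.finite(conc_motor_total) || conc_motor_total <= 0) {
    stop("`conc_motor_total` must be > 0 mM", call. = FALSE)
  }
  if (!is.finite(conc_fuel0) || conc_fuel0 < 0) {
    stop("`conc_fuel0` must be >= 0 mM", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be > 0 K", call. = FALSE)
  }
  structure(
    list(k_enant = k_enant, k_red2 = k_red2, v_ox = v_ox, ee_ox = ee_ox,
         conc_motor_total = conc_motor_total, conc_fuel0 = conc_fuel0,
         k_fuel_bg = k_fuel_bg, temperature = temperature),
    class = "rate_parameters"
  )
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Cyclic redox network rate parameters\n")
  cat(sprintf("  k_enant  %.3g /s (per direction)\n", x$k_enant))
  cat(sprintf("  k_red2   %.3g /mM/s\n", x$k_red2))
  cat(sprintf("  v_ox     %.3g mM/s\n", x$v_ox))
  cat(sprintf("  ee_ox    %.3f\n", x$ee_ox))
  cat(sprintf("  motor    %.3g mM, fuel0 %.3g mM, T %.2f K\n",
              x$conc_motor_total, x$conc_fuel0, x$temperature))
  invisible(x)
}

#' Eyring conversion of a rotational barrier to a rate constant
#'
#' Converts a free energy of activation to a first-order rate constant via
#' the Eyring equation, k = (kB T / h) exp(-dG' / (R T)), with transmission
#' coefficient 1. For the motor's oxidized state, the 79 kJ/mol barrier at
#' 40 C converts to ~0.42 s^-1, the per-direction enantiomerization rate
#' constant.
#'
#' @param barrier A [barrier_spec()].
#' @return First-order rate constant, s^-1.
#' @examples
#' eyring_rate(barrier_spec(79, 313.15))   # ~0.43 /s
#' @export
eyring_rate <- function(barrier) {
  if (!inherits(barrier, "barrier_spec")) {
    barrier <- barrier_spec(barrier$dG_double_dagger, barrier$temperature)
  }
  TK <- barrier$temperature
  (.kB * TK / .h) * exp(-barrier$dG_double_dagger * 1000 / (.Rgas * TK))
}

#' Barrier implied by a first-order rate constant (inverse Eyring)
#'
#' @param k First-order rate constant, s^-1. Must be > 0.
#' @param temperature Absolute temperature, K.
#' @return A [barrier_spec()] such that `eyring_rate()` recovers `k`.
#' @examples
#' barrier_from_rate(0.42, 313.15)  # ~79 kJ/mol
#' @export
barrier_from_rate <- function(k, temperature) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (!is.finite(k) || k <= 0) {
    stop("`k` must be a positive rate constant (s^-1)", call. = FALSE)
  }
  dG <- .Rgas * temperature * log(.kB * temperature / (.h * k)) / 1000
  barrier_spec(dG, temperature)
}

#' Lower bound on a rotational barrier from an observed absence of racemization
#'
#' If an enantioenriched atropisomer shows at most a fraction
#' `max_ee_loss_fraction` of ee loss after `duration` at `temperature`, the
#' per-direction enantiomerization rate constant satisfies
#' exp(-2 k t) >= 1 - loss, which bounds the barrier from below through the
#' Eyring relation. The detection threshold is an explicit argument because
#' it depends on the analytical method.
#'
#' @param duration Observation time, s.
#' @param temperature K.
#' @param max_ee_loss_fraction Largest ee loss (fraction of initial ee) that
#'   would have gone undetected; in (0, 1). Default 0.05.
#' @return A [barrier_spec()]: the smallest barrier consistent with the
#'   observation.
#' @examples
#' # two days at 100 C with < 5% ee loss
#' min_barrier_from_no_racemization(2 * 86400, 373.15)
#' @export
min_barrier_from_no_racemization <- function(duration, temperature,
                                             max_ee_loss_fraction = 0.05) {
  stopifnot(is.numeric(duration), is.numeric(max_ee_loss_fraction))
  if (duration <= 0) stop("`duration` must be > 0 s", call. = FALSE)
  if (max_ee_loss_fraction <= 0 || max_ee_loss_fraction >= 1) {
    stop("`max_ee_loss_fraction` must lie in (0, 1)", call. = FALSE)
  }
  # largest k_enant consistent with ee retention >= 1 - loss
  k_max <- -log(1 - max_ee_loss_fraction) / (2 * duration)
  barrier_from_rate(k_max, temperature)
}

#' Racemization half-life of the oxidized state
#'
#' Under the two-state enantiomerization model ee decays as exp(-2 k t), so
#' the ee half-life is ln(2) / (2 k_enant).
#'
#' @param k_enant Per-direction enantiomerization rate constant, s^-1.
#' @return Half-life, s.
#' @examples
#' racemization_halflife(0.42)  # sub-second: "racemizes too fast" for HPLC
#' @export
racemization_halflife <- function(k_enant) {
  if (!is.numeric(k_enant) || length(k_enant) != 1L || !is.finite(k_enant) ||
      k_enant <= 0) {
    stop("`k_enant` must be a positive rate constant (s^-1)", call. = FALSE)
  }
  log(2) / (2 * k_enant)
}

#' Probability that the transient aldehyde is reduced from the opposite
#' enantiomer
#'
#' The freshly formed, rapidly enantiomerizing aldehyde flips between its Sa
#' and Ra conformers (rate `k_enant` per direction) while reduction (pseudo
#' first-order rate `k_red_eff = k_red2 * [fuel]`) absorbs it back to the
#' reduced state. The probability that absorption occurs from the enantiomer
#' opposite to the one formed - i.e. that the cycle commits a 180 degree step -
#' is the odd-number-of-flips absorption probability of the two-state chain,
#'
#'   p = k_enant / (k_red_eff + 2 k_enant).
#'
#' p is bounded by 1/2 (complete racemization before reduction) and is 0 when
#' the aldehyde cannot flip.
#'
#' @param k_enant Per-direction enantiomerization rate constant, s^-1 (>= 0).
#' @param k_red_eff Effective first-order reduction rate, s^-1 (> 0).
#' @return Probability in [0, 0.5).
#' @examples
#' flip_probability(0.42, 2.1e-3 * 100)  # 0.40 at standard conditions
#' @export
flip_probability <- function(k_enant, k_red_eff) {
  stopifnot(is.numeric(k_enant), is.numeric(k_red_eff))
  if (any(k_enant < 0)) stop("`k_enant` must be >= 0", call. = FALSE)
  if (any(k_red_eff <= 0)) {
    stop("`k_red_eff` must be > 0 (no reduction channel: aldehyde never absorbed)",
         call. = FALSE)
  }
  k_enant / (k_red_eff + 2 * k_enant)
}

#' Check the rate hierarchy required for directional rotation
#'
#' Directional (rather than oscillatory) motion requires the hierarchy
#' r_enant > r_red > r_ox. Because the oxidized state is vanishingly dilute at
#' steady state, only the ratio of the first two is defined absolutely; it is
#' computed at the rate-law level as (k_red2 * [fuel]) / k_enant and must be
#' < 1. The r_red vs r_ox comparison is reported as a note (the resting state
#' of the network is the reduced species, so r_red >> r_ox is a structural
#' assumption, not a measured ratio).
#'
#' @param params A [rate_parameters()] object.
#' @return An object of class `hierarchy_report` with fields
#'   `ratio_red_over_enant`, `hierarchy_satisfied`, `notes`.
#' @examples
#' hierarchy_report(rate_parameters())  # ratio 0.50, satisfied
#' @export
hierarchy_report <- function(params) {
  stopifnot(inherits(params, "rate_parameters"))
  if (params$k_enant == 0) {
    stop("`k_enant` is zero: ratio r_red/r_enant undefined", call. = FALSE)
  }
  ratio <- (params$k_red2 * params$conc_fuel0) / params$k_enant
  satisfied <- ratio < 1
  notes <- character()
  if (params$conc_fuel0 == 0) {
    notes <- c(notes, "no fuel present: reduction channel absent, the cycle cannot turn over")
  }
  ss <- if (params$k_red2 > 0 && params$conc_fuel0 > 0) {
    params$v_ox / (params$k_red2 * params$conc_fuel0)
  } else {
    NA_real_
  }
  notes <- c(notes, sprintf(
    "r_red >> r_ox assumed (reduced state is the resting state); steady-state oxidized conc %.3g mM (%.3g%% of total)",
    ss, 100 * ss / params$conc_motor_total))
  structure(
    list(ratio_red_over_enant = ratio,
         hierarchy_satisfied = satisfied,
         notes = paste(notes, collapse = "; ")),
    class = "hierarchy_report"
  )
}

#' @export
print.hierarchy_report <- function(x, ...) {
  cat(sprintf("r_red/r_enant = %.3g -> hierarchy %s\n", x$ratio_red_over_enant,
              if (x$hierarchy_satisfied) "satisfied" else "NOT satisfied"))
  cat("note:", x$notes, "\n")
  invisible(x)
}

# Shared shape for fit results; JSON-serializable via fit_to_json().
new_rate_fit <- function(estimate, stderr, n, r_squared, method,
                         flagged = FALSE, note = "") {
  structure(
    list(estimate = estimate, stderr = stderr, n = n, r_squared = r_squared,
         method = method, flagged = flagged, note = note),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g +/- %.3g (n = %d, R^2 = %.4f)%s\n",
              x$method, x$estimate, x$stderr, x$n, x$r_squared,
              if (x$flagged) " [flagged]" else ""))
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Fit a pseudo-zero-order oxidation velocity from a progress curve
#'
#' Least-squares slope of product concentration vs time, the standard analysis
#' of an enzymatic oxidation whose substrate and co-substrate are effectively
#' constant. If the curve saturates, the fit is restricted to the longest
#' initial window in which no significant curvature is detected (quadratic
#' lack-of-fit test at `curvature_alpha`).
#'
#' @param times Times, s. Strictly increasing, length >= 3.
#' @param concentrations Product concentrations, mM.
#' @param window If `TRUE` (default), restrict to the initial linear window.
#' @param curvature_alpha Significance level of the quadratic lack-of-fit test
#'   used to delimit the linear window.
#' @return A `rate_fit` with the slope magnitude (mM s^-1), its standard
#'   error, the number of points used, and R^2.
#' @examples
#' t <- seq(0, 3600, length.out = 20)
#' fit_pseudo_zero_order(t, 5.59e-4 * t)
#' @export
fit_pseudo_zero_order <- function(times, concentrations, window = TRUE,
                                  curvature_alpha = 0.01) {
  stopifnot(is.numeric(times), is.numeric(concentrations))
  if (length(times) != length(concentrations)) {
    stop("`times` and `concentrations` must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("need at least 3 points to fit a slope", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  n_all <- length(times)
  n_use <- n_all
  if (window && n_all >= 5L) {
    n_use <- .initial_linear_window(times, concentrations, curvature_alpha)
  }
  t <- times[seq_len(n_use)]
  y <- concentrations[seq_len(n_use)]
  if (n_use < n_all) {
    # residual curvature within the retained window would bias the secant
    # slope downward; report the tangent at t = 0 from a quadratic fit
    fit <- stats::lm(y ~ t + I(t^2))
    sm <- .quiet_summary(fit)
    slope <- unname(stats::coef(fit)["t"])
    se <- unname(sm$coefficients["t", "Std. Error"])
    note <- sprintf(
      "curvature detected: initial-rate (quadratic) fit on first %d of %d points",
      n_use, n_all)
  } else {
    fit <- stats::lm(y ~ t)
    sm <- .quiet_summary(fit)
    slope <- unname(stats::coef(fit)["t"])
    se <- unname(sm$coefficients["t", "Std. Error"])
    note <- ""
  }
  new_rate_fit(abs(slope), se, n_use, sm$r.squared,
               method = "pseudo_zero_order", note = note)
}

# summary.lm warns on numerically exact fits; that case is expected here
.quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# Longest initial segment with no significant quadratic curvature.
.initial_linear_window <- function(times, y, alpha) {
  n <- length(times)
  scale_y <- max(abs(y), .Machine$double.eps)
  for (k in n:4) {
    t_k <- times[seq_len(k)]
    y_k <- y[seq_len(k)]
    fit2 <- stats::lm(y_k ~ t_k + I(t_k^2))
    sm <- .quiet_summary(fit2)
    # numerically exact line: residual sd ~ 0 -> accept the full window
    if (sm$sigma < 1e-10 * scale_y) return(k)
    p_quad <- sm$coefficients["I(t_k^2)", "Pr(>|t|)"]
    if (is.na(p_quad) || p_quad > alpha) return(k)
  }
  4L
}

#' Fit a second-order reduction rate constant from a pseudo-first-order decay
#'
#' With fuel in large excess the reduction of the aldehyde follows an
#' exponential decay with observed constant `k_obs = k_red2 * [fuel]` (the
#' UV-vis progress-curve analysis). Fits `c0 * exp(-k_obs t)` by nonlinear
#' least squares (Levenberg-Marquardt, log-linear start) and returns
#' `k_red2 = k_obs / fuel_conc`.
#'
#' @param times s, length >= 4.
#' @param aldehyde_conc mM, all > 0.
#' @param fuel_conc mM, constant fuel concentration (large excess).
#' @return A `rate_fit` with `estimate = k_red2` (mM^-1 s^-1). Decays that are
#'   statistically indistinguishable from flat are returned with
#'   `flagged = TRUE`.
#' @examples
#' t <- seq(0, 30, length.out = 30)
#' fit_pseudo_first_order_reduction(t, 0.1 * exp(-0.21 * t), fuel_conc = 100)
#' @export
fit_pseudo_first_order_reduction <- function(times, aldehyde_conc, fuel_conc) {
  stopifnot(is.numeric(times), is.numeric(aldehyde_conc))
  if (length(times) != length(aldehyde_conc)) {
    stop("`times` and `aldehyde_conc` must have equal length", call. = FALSE)
  }
  if (length(times) < 4L) {
    stop("need at least 4 points for an exponential fit", call. = FALSE)
  }
  if (any(aldehyde_conc <= 0) || fuel_conc <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (fuel_conc < 10 * max(aldehyde_conc)) {
    warning("fuel is not in large excess over aldehyde; pseudo-first-order assumption dubious")
  }
  # log-linear start values
  lfit <- stats::lm(log(aldehyde_conc) ~ times)
  k0 <- max(-unname(stats::coef(lfit)["times"]), 0)
  c0 <- exp(unname(stats::coef(lfit)["(Intercept)"]))
  df <- data.frame(t = times, y = aldehyde_conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-k * t), data = df,
                      start = list(a = c0, k = k0),
                      lower = c(a = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # flat or pathological data: report the log-linear slope with its SE
    sm <- .quiet_summary(lfit)
    k_obs <- max(-unname(stats::coef(lfit)["times"]), 0)
    se_obs <- unname(sm$coefficients["times", "Std. Error"])
    return(new_rate_fit(k_obs / fuel_conc, se_obs / fuel_conc,
                        length(times), sm$r.squared,
                        method = "pseudo_first_order_reduction",
                        flagged = TRUE,
                        note = "exponential fit failed; log-linear fallback"))
  }
  sm <- summary(fit)
  k_obs <- unname(stats::coef(fit)["k"])
  se_obs <- sm$coefficients["k", "Std. Error"]
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((aldehyde_conc - mean(aldehyde_conc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  flagged <- !is.finite(se_obs) || !(k_obs > 2 * se_obs)
  new_rate_fit(k_obs / fuel_conc, se_obs / fuel_conc, length(times), r2,
               method = "pseudo_first_order_reduction", flagged = flagged,
               note = if (flagged) "decay not distinguishable from flat" else "")
}
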