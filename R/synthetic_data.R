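# truncate Gaussian-perturbed values to a physical range
.noisy <- function(x, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(x + stats::rnorm(length(x), 0, sd), lower), upper)
}

#' Synthetic deracemization time course (HPLC yield/ee emulation)
#'
#' Generates triplicate yield and ee series from the deterministic network
#' model plus independent Gaussian noise truncated to the valid ranges,
#' emulating HPLC monitoring of a cyclic deracemization. Ground truth is
#' recorded in the `truth` attribute so recovery tests are self-validating.
#'
#' @param spec A deracemization [network_spec()].
#' @param t_grid Sampling times, s.
#' @param conc_total,fuel0 Initial substrate and fuel, mM.
#' @param noise_sd Fractional noise (absolute sd on yield and ee), >= 0.
#' @param n_rep Number of replicate series (default 3, matching triplicate
#'   experiments).
#' @param seed Integer RNG seed.
#' @return Data frame: `time_s`, then `yield_<r>` and `ee_<r>` per replicate;
#'   attributes `truth` (the noiseless `time_course`) and `seed`.
#' @examples
#' sp <- network_spec("deracemization", selectivity_s = 30)
#' g <- gen_deracemization_timecourse(sp, seq(0, 86400, 7200), seed = 1)
#' @export
gen_deracemization_timecourse <- function(spec,
                                          t_grid = seq(0, 24 * 3600,
                                                       length.out = 13),
                                          conc_total = 10, fuel0 = 100,
                                          noise_sd = 0.02, n_rep = 3,
                                          seed = 1L) {
  stopifnot(inherits(spec, "network_spec"),
            spec$topology == "deracemization", noise_sd >= 0, n_rep >= 1)
  st <- network_state(spec, conc_total = conc_total, fuel0 = fuel0)
  truth <- simulate_network(spec, st, t_grid)
  out <- data.frame(time_s = truth$time_s)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      out[[paste0("yield_", r)]] <- .noisy(truth$yield, noise_sd, 0, 1)
      out[[paste0("ee_", r)]] <- .noisy(truth$ee, noise_sd, -1, 1)
    }
  })
  structure(out, truth = truth, seed = seed)
}

#' Synthetic pseudo-first-order reduction progress curve (UV-vis emulation)
#'
#' Exponential decay of the aldehyde with observed constant
#' `k_obs = k_red2 * fuel`, plus Gaussian noise with sd `noise_sd * c0`,
#' truncated at 0 and at a small positive floor so log-based fits stay
#' defined.
#'
#' @param k_red2 True second-order reduction constant, mM^-1 s^-1.
#' @param fuel Constant fuel concentration, mM (large excess).
#' @param c0 Initial aldehyde concentration, mM.
#' @param t_max Duration, s (default 5 half-lives of the decay).
#' @param noise_sd Fractional noise relative to `c0`.
#' @param n_points Number of samples (>= 3).
#' @param seed Integer RNG seed.
#' @return Data frame `time_s`, `conc_mM`; attributes `truth` (list with
#'   `k_red2`, `fuel`, `c0`) and `seed`.
#' @export
gen_reduction_progress <- function(k_red2 = 2.1e-3, fuel = 100, c0 = 0.1,
                                   t_max = NULL, noise_sd = 0.01,
                                   n_points = 30, seed = 1L) {
  stopifnot(k_red2 > 0, fuel > 0, c0 > 0, noise_sd >= 0, n_points >= 3)
  k_obs <- k_red2 * fuel
  if (is.null(t_max)) t_max <- 5 * log(2) / k_obs
  t <- seq(0, t_max, length.out = n_points)
  y <- c0 * exp(-k_obs * t)
  y <- with_seed(seed, .noisy(y, noise_sd * c0, lower = 1e-9 * c0))
  structure(data.frame(time_s = t, conc_mM = y),
            truth = list(k_red2 = k_red2, fuel = fuel, c0 = c0), seed = seed)
}

#' Synthetic pseudo-zero-order oxidation progress curve (HPLC emulation)
#'
#' Product concentration growing linearly at `v_ox`, optionally rolling over
#' into a saturating exponential approach to `c_max` (substrate exhaustion),
#' plus Gaussian noise with sd `noise_sd * range`.
#'
#' @param v_ox True oxidation velocity, mM s^-1.
#' @param t_max Duration, s.
#' @param noise_sd Fractional noise relative to the signal range.
#' @param n_points Number of samples (>= 3).
#' @param saturating If `TRUE`, generate `c_max (1 - exp(-v_ox t / c_max))`.
#' @param c_max Plateau concentration for the saturating curve, mM.
#' @param seed Integer RNG seed.
#' @return Data frame `time_s`, `conc_mM`; attributes `truth`, `seed`.
#' @export
gen_oxidation_progress <- function(v_ox = 5.59e-4, t_max = 3600,
                                   noise_sd = 0.02, n_points = 20,
                                   saturating = FALSE, c_max = 1,
                                   seed = 1L) {
  stopifnot(v_ox > 0, t_max > 0, noise_sd >= 0, n_points >= 3)
  t <- seq(0, t_max, length.out = n_points)
  y <- if (saturating) c_max * (1 - exp(-v_ox * t / c_max)) else v_ox * t
  y <- with_seed(seed, .noisy(y, noise_sd * diff(range(y)), lower = 0))
  structure(data.frame(time_s = t, conc_mM = y),
            truth = list(v_ox = v_ox, saturating = saturating, c_max = c_max),
            seed = seed)
}

#' Synthetic NMR deuterium-distribution integrals
#'
#' Generates replicate isotopomer observations for both label configurations
#' from the parallel-channel forward model at given (s, KIE), with Gaussian
#' noise on the aldehydic fraction (truncated to [0, 1], renormalized).
#'
#' @param s True selectivity ratio.
#' @param kie True kinetic isotope effect.
#' @param noise_sd Integral noise sd (fractional), >= 0.
#' @param n_rep Replicates per configuration.
#' @param purity Label purity passed to [forward_cdo_fraction()].
#' @param seed Integer RNG seed.
#' @return Data frame with columns `label_config`, `rep`, `frac_CDO`,
#'   `frac_CD2OH`, `integral_sd`; attributes `truth`, `seed`.
#' @examples
#' gen_nmr_integrals(15.9, 1.20, noise_sd = 0, n_rep = 1)
#' @export
gen_nmr_integrals <- function(s = 15.9, kie = 1.20, noise_sd = 0,
                              n_rep = 3, purity = 1, seed = 1L) {
  stopifnot(s > 0, kie > 0, noise_sd >= 0, n_rep >= 1)
  cfgs <- c("Sa", "Ra")
  truth <- vapply(cfgs, function(cf) forward_cdo_fraction(s, kie, cf, purity),
                  numeric(1))
  out <- with_seed(seed, {
    do.call(rbind, lapply(cfgs, function(cf) {
      f <- .noisy(rep(truth[[cf]], n_rep), noise_sd, 0, 1)
      data.frame(label_config = cf, rep = seq_len(n_rep),
                 frac_CDO = f, frac_CD2OH = 1 - f, integral_sd = noise_sd)
    }))
  })
  rownames(out) <- NULL
  structure(out, truth = list(s = s, kie = kie, purity = purity), seed = seed)
}

#' Average replicate NMR integrals into one observation per configuration
#'
#' @param df Output of [gen_nmr_integrals()] (or a data frame with the same
#'   columns).
#' @return Named list of [isotopomer_observation()] objects (`Sa`, `Ra`).
#' @export
collapse_nmr_replicates <- function(df) {
  stopifnot(all(c("label_config", "frac_CDO", "integral_sd") %in% names(df)))
  obs <- lapply(split(df, df$label_config), function(d) {
    f <- mean(d$frac_CDO)
    isotopomer_observation(d$label_config[1], f, 1 - f,
                           integral_sd = d$integral_sd[1])
  })
  obs[c("Sa", "Ra")[c("Sa", "Ra") %in% names(obs)]]
}
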