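#' Deuterium-distribution observation from an isotopomer oxidation
#'
#' Records the outcome of oxidizing an enantiopure benzylic-D2 isotopomer of
#' the motor: the fraction of the deuterium label found at the aldehydic
#' (CDO) position versus the remaining benzylic alcohol (CD2OH) position of
#' the product monoaldehyde, by NMR integration. Oxidation of the labelled
#' arm transfers the label to CDO; oxidation of the unlabelled arm leaves it
#' at CD2OH, so the split reports which enantiomer of the aldehyde was formed.
#'
#' @param label_config `"Sa"` or `"Ra"`: axial configuration of the labelled
#'   substrate. For the Sa isotopomer the enzyme-preferred (fast) oxidation
#'   channel carries the label to CDO.
#' @param frac_CDO Fraction of label at the aldehydic position, in [0, 1].
#' @param frac_CD2OH Fraction at the benzylic alcohol position. Must sum with
#'   `frac_CDO` to 1 within the integral uncertainty; the pair is renormalized.
#' @param integral_sd NMR integral uncertainty (fractional standard
#'   deviation), >= 0.
#' @return An object of class `isotopomer_observation`.
#' @examples
#' isotopomer_observation("Sa", 0.93, 0.07)
#' isotopomer_observation("Ra", 0.05, 0.95)
#' @export
isotopomer_observation <- function(label_config = c("Sa", "Ra"),
                                   frac_CDO, frac_CD2OH,
                                   integral_sd = 0) {
  label_config <- match.arg(label_config)
  stopifnot(is.numeric(frac_CDO), is.numeric(frac_CD2OH), integral_sd >= 0)
  if (frac_CDO < 0 || frac_CDO > 1 || frac_CD2OH < 0 || frac_CD2OH > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  tot <- frac_CDO + frac_CD2OH
  if (abs(tot - 1) > max(3 * integral_sd, 1e-8)) {
    stop(sprintf("fractions sum to %.4f, not 1 within the integral uncertainty",
                 tot), call. = FALSE)
  }
  structure(
    list(label_config = label_config,
         frac_CDO = frac_CDO / tot, frac_CD2OH = frac_CD2OH / tot,
         integral_sd = integral_sd),
    class = "isotopomer_observation"
  )
}

#' @export
print.isotopomer_observation <- function(x, ...) {
  cat(sprintf("(%s)-D2 isotopomer oxidation: CDO:CD2OH = %.3g:%.3g (sd %.3g)\n",
              x$label_config, x$frac_CDO, x$frac_CD2OH, x$integral_sd))
  invisible(x)
}

#' Forward model: expected aldehydic label fraction
#'
#' Two parallel irreversible first-order oxidation channels drain a common
#' substrate pool, with selectivity `s = r_ox(Sa)/r_ox(Ra)` and the labelled
#' channel slowed by the primary kinetic isotope effect `kie` (C-D cleavage).
#' Because the channels are parallel and first order, the product ratio
#' equals the rate ratio at any conversion. For the Sa-labelled substrate the
#' fast channel is labelled, `frac_CDO = (s/kie) / (s/kie + 1)`; for the
#' Ra-labelled substrate the slow channel is labelled,
#' `frac_CDO = (1/kie) / (1/kie + s)`. An optional label purity below 1 mixes
#' in the 50:50 prediction for unlabelled substrate.
#'
#' @param s Selectivity ratio r_ox(Sa)/r_ox(Ra), > 0.
#' @param kie Kinetic isotope effect (H rate / D rate), > 0.
#' @param label_config `"Sa"` or `"Ra"`.
#' @param purity Fraction of substrate carrying the D2 label, in (0, 1].
#' @return Expected fraction of label at the aldehydic position, in (0, 1).
#' @examples
#' forward_cdo_fraction(15.9, 1.20, "Sa")  # ~0.93
#' forward_cdo_fraction(15.9, 1.20, "Ra")  # ~0.05
#' @export
forward_cdo_fraction <- function(s, kie = 1, label_config = c("Sa", "Ra"),
                                 purity = 1) {
  label_config <- match.arg(label_config)
  if (any(s <= 0) || any(kie <= 0)) {
    stop("`s` and `kie` must be positive", call. = FALSE)
  }
  stopifnot(purity > 0, purity <= 1)
  f <- if (label_config == "Sa") {
    (s / kie) / (s / kie + 1)
  } else {
    (1 / kie) / (1 / kie + s)
  }
  purity * f + (1 - purity) * 0.5
}

new_selectivity_estimate <- function(s, ee, kie, method, ci_ee = NULL) {
  structure(
    list(selectivity_s = s, ee = ee, kie = kie, ci_ee = ci_ee,
         method = method),
    class = "selectivity_estimate"
  )
}

#' @export
print.selectivity_estimate <- function(x, ...) {
  cat(sprintf("Oxidation selectivity (%s): s = %.4g, ee = %.1f%%, KIE = %.3g\n",
              x$method, x$selectivity_s, 100 * x$ee, x$kie))
  if (!is.null(x$ci_ee)) {
    cat(sprintf("  ee %.0f%% CI: [%.1f%%, %.1f%%]\n",
                100 * attr(x$ci_ee, "conf"), 100 * x$ci_ee[1], 100 * x$ci_ee[2]))
  }
  invisible(x)
}

#' Per-experiment enantioselectivity estimate (KIE neglected)
#'
#' Direct ratio estimate from a single isotopomer experiment, assuming no
#' kinetic isotope effect: for the Sa-labelled substrate
#' `s = frac_CDO / frac_CD2OH`; for Ra, `s = frac_CD2OH / frac_CDO`.
#' `ee = (s - 1)/(s + 1)` with the Sa-channel-fast sign convention.
#'
#' @param obs An [isotopomer_observation()].
#' @return A `selectivity_estimate` with `kie = 1` (assumed).
#' @examples
#' ee_per_experiment_no_kie(isotopomer_observation("Sa", 0.93, 0.07))
#' @export
ee_per_experiment_no_kie <- function(obs) {
  stopifnot(inherits(obs, "isotopomer_observation"))
  denom <- if (obs$label_config == "Sa") obs$frac_CD2OH else obs$frac_CDO
  numer <- if (obs$label_config == "Sa") obs$frac_CDO else obs$frac_CD2OH
  if (denom == 0) {
    stop(sprintf(
      "degenerate observation: minor fraction is 0, only a one-sided bound s > %.3g is available",
      numer / max(obs$integral_sd, .Machine$double.eps)), call. = FALSE)
  }
  s <- numer / denom
  new_selectivity_estimate(s, (s - 1) / (s + 1), kie = 1,
                           method = "per_experiment_no_kie")
}

#' Joint enantioselectivity and KIE from the two isotopomer experiments
#'
#' The Sa-labelled experiment measures `ratio_Sa = s / kie` and the
#' Ra-labelled experiment measures `ratio_Ra_inv = s * kie` (the label slows
#' the channel it rides on), a just-identified system solved exactly:
#' `s = sqrt(ratio_Sa * ratio_Ra_inv)`, `kie = sqrt(ratio_Ra_inv / ratio_Sa)`.
#'
#' @param obs_Sa [isotopomer_observation()] with `label_config = "Sa"`.
#' @param obs_Ra [isotopomer_observation()] with `label_config = "Ra"`.
#' @return A `selectivity_estimate` with fields `selectivity_s`, `ee`, `kie`.
#' @examples
#' joint_ee_kie(isotopomer_observation("Sa", 0.93, 0.07),
#'              isotopomer_observation("Ra", 0.05, 0.95))
#' @export
joint_ee_kie <- function(obs_Sa, obs_Ra) {
  stopifnot(inherits(obs_Sa, "isotopomer_observation"),
            inherits(obs_Ra, "isotopomer_observation"))
  if (obs_Sa$label_config != "Sa" || obs_Ra$label_config != "Ra") {
    stop("need one observation per label configuration (Sa then Ra)",
         call. = FALSE)
  }
  if (obs_Sa$frac_CD2OH == 0 || obs_Ra$frac_CDO == 0) {
    stop("degenerate observation: a minor fraction is 0", call. = FALSE)
  }
  ratio_Sa <- obs_Sa$frac_CDO / obs_Sa$frac_CD2OH        # s / kie
  ratio_Ra_inv <- obs_Ra$frac_CD2OH / obs_Ra$frac_CDO    # s * kie
  prod <- ratio_Sa * ratio_Ra_inv
  if (prod <= 0) stop("observations inconsistent with a positive selectivity",
                      call. = FALSE)
  s <- sqrt(prod)
  kie <- sqrt(ratio_Ra_inv / ratio_Sa)
  new_selectivity_estimate(s, (s - 1) / (s + 1), kie,
                           method = "joint_two_experiment")
}

#' Bootstrap confidence interval for the ee estimate
#'
#' Resamples the NMR integrals (Gaussian perturbation of the aldehydic
#' fraction with the stated integral uncertainty, truncated to [0, 1] and
#' renormalized) and recomputes the estimator, returning a percentile CI on
#' the ee. The point estimate is the estimate on the unperturbed data. With
#' one observation the per-experiment estimator is bootstrapped; with two,
#' the joint estimator.
#'
#' @param obs_Sa An [isotopomer_observation()] (any configuration if used
#'   alone).
#' @param obs_Ra Optional second observation for the joint estimator.
#' @param n_boot Number of bootstrap replicates (>= 1000).
#' @param seed Integer RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return The point `selectivity_estimate` with `ci_ee` filled in.
#' @examples
#' bootstrap_ci(isotopomer_observation("Sa", 0.93, 0.07, integral_sd = 0.02),
#'              n_boot = 1000, seed = 1)
#' @export
bootstrap_ci <- function(obs_Sa, obs_Ra = NULL, n_boot = 5000, seed = 1L,
                         conf = 0.95) {
  stopifnot(inherits(obs_Sa, "isotopomer_observation"), n_boot >= 1000)
  point <- if (is.null(obs_Ra)) {
    ee_per_experiment_no_kie(obs_Sa)
  } else {
    joint_ee_kie(obs_Sa, obs_Ra)
  }
  perturb <- function(obs) {
    f <- obs$frac_CDO + stats::rnorm(n_boot, 0, obs$integral_sd)
    f <- pmin(pmax(f, 0), 1)
    f
  }
  ees <- with_seed(seed, {
    fS <- perturb(obs_Sa)
    if (is.null(obs_Ra)) {
      num <- if (obs_Sa$label_config == "Sa") fS else 1 - fS
      s <- num / (1 - num)
      (s - 1) / (s + 1)
    } else {
      fR <- perturb(obs_Ra)
      ratio_Sa <- fS / (1 - fS)
      ratio_Ra_inv <- (1 - fR) / fR
      s <- sqrt(ratio_Sa * ratio_Ra_inv)
      (s - 1) / (s + 1)
    }
  })
  ees <- ees[is.finite(ees)]
  ci <- stats::quantile(ees, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  point$ci_ee <- structure(ci, conf = conf)
  point
}
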