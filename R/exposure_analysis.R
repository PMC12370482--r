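# Radiant-exposure arithmetic, Bunsen-Roscoe reciprocity testing, exact
# binomial damage-frequency intervals, and concurrent-exposure interaction
# classification.

#' Radiant exposure
#'
#' `H = E * tau` (W cm^-2 times seconds gives J cm^-2). Radiant exposure is a
#' proxy for delivered photon count at fixed wavelength.
#'
#' @param irradiance_W_cm2 irradiance (>= 0)
#' @param duration_s exposure duration (>= 0)
#' @return radiant exposure in J cm^-2
#' @export
radiant_exposure <- function(irradiance_W_cm2, duration_s) {
  if (any(irradiance_W_cm2 < 0) || any(duration_s < 0))
    .ll_error("irradiance and duration must be >= 0", "laserlesion_parameter_error")
  irradiance_W_cm2 * duration_s
}

#' Bundle an ED50 estimate with its exposure duration
#'
#' Input adapter for [test_reciprocity()]: accepts either a [fit_probit()]
#' result or a plain ED50 number, plus the duration and optionally the 95%
#' fiducial limits on the irradiance scale.
#'
#' @param fit a `probit_fit` or a single ED50 value (W cm^-2)
#' @param duration_s exposure duration, seconds
#' @param fl optional `c(lower, upper)` fiducial limits; computed from the fit
#'   when one is supplied
#' @return object of class `reciprocity_input`
#' @export
reciprocity_input <- function(fit, duration_s, fl = NULL) {
  if (inherits(fit, "probit_fit")) {
    ed50 <- ed_dose(fit, 0.5)
    if (is.null(fl))
      fl <- tryCatch(fiducial_limits(fit, 0.5),
                     laserlesion_unbounded_limits_error = function(e) NULL)
  } else {
    ed50 <- as.numeric(fit)
  }
  structure(list(ed50 = ed50, duration_s = duration_s, fl = fl),
            class = "reciprocity_input")
}

#' Test irradiance reciprocity between two exposure durations
#'
#' Under a purely photochemical (Bunsen-Roscoe) process the threshold radiant
#' exposure `H = ED50 * tau` is constant across durations. The two fits are
#' reciprocal when `|H_A - H_B| / mean(H)` is within `tolerance` (default
#' 10%). When fiducial limits are available the report also states whether the
#' irradiance-scale intervals are disjoint (the significance check that the
#' two ED50 irradiances genuinely differ).
#'
#' @param a,b [reciprocity_input()] objects (or `probit_fit`s wrapped by the
#'   caller) at two different durations, same wavelength
#' @param tolerance relative tolerance on the radiant-exposure mismatch
#' @return list: `reciprocal`, `h` (the two radiant exposures),
#'   `relative_difference`, `fl_disjoint` (NA when limits missing),
#'   `tolerance`
#' @export
test_reciprocity <- function(a, b, tolerance = 0.10) {
  stopifnot(inherits(a, "reciprocity_input"), inherits(b, "reciprocity_input"))
  if (a$duration_s == b$duration_s)
    .ll_error("reciprocity requires two different exposure durations",
              "laserlesion_invalid_comparison_error")
  h <- c(radiant_exposure(a$ed50, a$duration_s), radiant_exposure(b$ed50, b$duration_s))
  rel <- abs(h[1] - h[2]) / mean(h)
  fl_disjoint <- if (!is.null(a$fl) && !is.null(b$fl)) {
    (max(a$fl) < min(b$fl)) || (max(b$fl) < min(a$fl))
  } else NA
  list(reciprocal = rel <= tolerance, h = h, relative_difference = rel,
       fl_disjoint = fl_disjoint, tolerance = tolerance)
}

#' Damage frequency with exact binomial interval
#'
#' Reports the positive fraction as a percentage (rounded half away from zero
#' for display; the raw ratio is retained) with a Clopper-Pearson 95%
#' interval.
#'
#' @param positives,total non-negative counts, `total > 0`
#' @return object of class `frequency_result`: `positives`, `total`,
#'   `frequency_pct` (rounded), `frequency_raw_pct`, `ci95_pct`
#' @export
damage_frequency <- function(positives, total) {
  if (total <= 0) .ll_error("total must be > 0", "laserlesion_parameter_error")
  if (positives < 0 || positives > total)
    .ll_error("positives must be in [0, total]", "laserlesion_parameter_error")
  raw <- 100 * positives / total
  ci <- as.numeric(binom.test(positives, total)$conf.int) * 100
  structure(list(positives = positives, total = total,
                 frequency_pct = sign(raw) * floor(abs(raw) + 0.5),
                 frequency_raw_pct = raw, ci95_pct = ci),
            class = "frequency_result")
}

#' @export
print.frequency_result <- function(x, ...) {
  cat(sprintf("<frequency_result> %d/%d = %d%% (95%% CI %.1f-%.1f%%)\n",
              x$positives, x$total, x$frequency_pct, x$ci95_pct[1], x$ci95_pct[2]))
  invisible(x)
}

#' Classify the interaction of two concurrent damage mechanisms
#'
#' Given the planned single-agent damage probabilities `pA` and `pB`, the
#' independence expectation is `1 - (1-pA)(1-pB)` and the additive expectation
#' is `min(1, pA + pB)`. The observed positive count is placed by exact
#' binomial acceptance bands: below the 95% band of the independent
#' expectation is inhibitory, inside it is independent, above it but within
#' the additive band is additive, and above the additive band is synergistic.
#' (When `pA + pB` equals the independence expectation, as with a single
#' active agent, the additive class is empty and anything above the band is
#' synergistic.)
#'
#' @param pA,pB planned single-agent probabilities in [0, 1]
#' @param positives,total observed counts
#' @return object of class `interaction_result`: `expected_independent_pct`,
#'   `expected_additive_pct`, `observed` ([damage_frequency()] result),
#'   `label`, `p_value_vs_independent`
#' @export
classify_interaction <- function(pA, pB, positives, total) {
  if (pA < 0 || pA > 1 || pB < 0 || pB > 1)
    .ll_error("pA and pB must be probabilities", "laserlesion_parameter_error")
  obs <- damage_frequency(positives, total)
  p_ind <- 1 - (1 - pA) * (1 - pB)
  p_add <- min(1, pA + pB)
  lo_ind <- qbinom(0.025, total, p_ind)
  hi_ind <- qbinom(0.975, total, p_ind)
  hi_add <- qbinom(0.975, total, p_add)
  label <- if (positives < lo_ind) "inhibitory"
    else if (positives <= hi_ind) "independent"
    else if (positives <= hi_add) "additive"
    else "synergistic"
  pval <- binom.test(positives, total, p = p_ind)$p.value
  structure(list(expected_independent_pct = 100 * p_ind,
                 expected_additive_pct = 100 * p_add,
                 observed = obs, label = label,
                 p_value_vs_independent = pval),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> %s (observed %d/%d; independent %.0f%%, additive %.0f%%; p = %.3g)\n",
              x$label, x$observed$positives, x$observed$total,
              x$expected_independent_pct, x$expected_additive_pct,
              x$p_value_vs_independent))
  invisible(x)
}

#' Difference in threshold peak temperature rise
#'
#' Control minus test, in degrees C. When per-exposure samples are supplied,
#' a Welch two-sample t-test is attached.
#'
#' @param dT_control,dT_test scalar temperature rises (means), degrees C
#' @param samples_control,samples_test optional per-exposure vectors
#' @return list: `delta_dT`, and `welch` (htest or NULL)
#' @export
delta_threshold_dT <- function(dT_control, dT_test,
                               samples_control = NULL, samples_test = NULL) {
  welch <- if (!is.null(samples_control) && !is.null(samples_test))
    t.test(samples_control, samples_test) else NULL
  list(delta_dT = dT_control - dT_test, welch = welch)
}

#' @importFrom stats qbinom sd
NULL
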