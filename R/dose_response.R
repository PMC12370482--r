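# Probit dose-response analysis: maximum-likelihood fit on log10(dose),
# ED_p estimation, Fieller fiducial limits with Finney's heterogeneity
# correction, the slope / fiducial-width quality gates, and detection of
# deterministic (crossover-free) responses.

records_to_xy <- function(records) {
  validate_exposure_records(records)
  keep <- records$outcome %in% c("0", "1")
  data.frame(dose = records$irradiance_W_cm2[keep],
             y = as.integer(records$outcome[keep]))
}

#' Fit a probit dose-response model
#'
#' Maximum-likelihood probit regression of the binary outcome on
#' `x = log10(dose)`: `P(damage) = Phi(b0 + b1 x)`. The slope `b1` is in
#' probits per log10 decade. Heterogeneity (Pearson chi-square / df) is
#' computed over dose groups. Completely separated data (every positive dose
#' above every negative) cannot identify a finite slope; this raises a
#' separation error directing the caller to [detect_deterministic()].
#'
#' @param records an [exposure_records()] data.frame; excluded rows are
#'   dropped (and counted in `n_excluded`)
#' @return object of class `probit_fit`: `intercept`, `slope`, `vcov`,
#'   `heterogeneity` (chi-square/df), `het_df`, `n_used`, `n_excluded`,
#'   `converged`
#' @export
fit_probit <- function(records) {
  xy <- records_to_xy(records)
  if (any(xy$dose <= 0))
    .ll_error("doses must be > 0 for the log10 metameter", "laserlesion_parameter_error")
  if (sum(xy$y == 1) < 2 || sum(xy$y == 0) < 2)
    .ll_error("need at least 2 positive and 2 negative records", "laserlesion_parameter_error")
  if (max(xy$dose[xy$y == 0]) < min(xy$dose[xy$y == 1]))
    .ll_error(paste("complete separation: no damage crossovers, the probit fit",
                    "cannot converge; use detect_deterministic()"),
              "laserlesion_separation_error")
  x <- log10(xy$dose)
  fit <- suppressWarnings(glm(xy$y ~ x, family = binomial(link = "probit")))
  b <- unname(coef(fit))
  conv <- isTRUE(fit$converged) && all(is.finite(b)) && abs(b[2]) < 1e3
  if (!conv)
    .ll_error("probit fit did not converge (quasi-separation?); use detect_deterministic()",
              "laserlesion_separation_error")
  # Pearson heterogeneity over dose groups (Finney): needs replicated doses
  grp <- split(xy, xy$dose)
  p_hat <- pnorm(b[1] + b[2] * log10(as.numeric(names(grp))))
  n_g <- vapply(grp, nrow, integer(1))
  r_g <- vapply(grp, function(g) sum(g$y), numeric(1))
  ok <- p_hat > 1e-12 & p_hat < 1 - 1e-12
  chisq <- sum(((r_g - n_g * p_hat)^2 / (n_g * p_hat * (1 - p_hat)))[ok])
  df <- max(sum(ok) - 2L, 0L)
  structure(list(intercept = b[1], slope = b[2], vcov = unname(vcov(fit)),
                 heterogeneity = if (df > 0) chisq / df else NA_real_,
                 het_df = df, n_used = nrow(xy),
                 n_excluded = sum(records$outcome == "excluded"),
                 converged = TRUE),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> slope %.2f probits/decade, ED50 %.4g (n = %d)\n",
              x$slope, ed_dose(x, 0.5), x$n_used))
  invisible(x)
}

#' Effective dose for a response probability
#'
#' `ED(p) = 10^((qnorm(p) - b0) / b1)`.
#'
#' @param fit a [fit_probit()] result
#' @param p response probability (vectorised)
#' @return dose(s) on the irradiance scale
#' @export
ed_dose <- function(fit, p) {
  stopifnot(inherits(fit, "probit_fit"))
  10^((qnorm(p) - fit$intercept) / fit$slope)
}

#' Fiducial limits for an ED estimate (Fieller / Finney)
#'
#' Fieller's theorem applied to the ratio `m = (qnorm(p) - b0) / b1` on the
#' log10 scale, returned on the dose scale. When the Pearson heterogeneity
#' factor exceeds 1 (and its df allow), the variance matrix is inflated by it
#' and the normal deviate is replaced by Student's t (Finney's correction).
#' `g >= 1` means the slope is not significantly different from zero at the
#' chosen level; limits are then unbounded and an error is raised.
#'
#' @param fit a [fit_probit()] result
#' @param p response probability
#' @param level confidence level (default 0.95)
#' @return named vector `c(lower, upper)` on the dose scale
#' @export
fiducial_limits <- function(fit, p, level = 0.95) {
  stopifnot(inherits(fit, "probit_fit"))
  h <- fit$heterogeneity
  use_h <- is.finite(h) && h > 1 && fit$het_df > 0
  V <- fit$vcov * if (use_h) h else 1
  tcrit <- if (use_h) qt(1 - (1 - level) / 2, fit$het_df) else qnorm(1 - (1 - level) / 2)
  b <- fit$slope
  m <- (qnorm(p) - fit$intercept) / b
  v11 <- V[1, 1]; v12 <- V[1, 2]; v22 <- V[2, 2]
  g <- tcrit^2 * v22 / b^2
  if (g >= 1)
    .ll_error("fiducial limits unbounded (g >= 1: slope not distinguishable from 0)",
              "laserlesion_unbounded_limits_error")
  disc <- v11 + 2 * m * v12 + m^2 * v22 - g * (v11 - v12^2 / v22)
  half <- tcrit / (abs(b) * (1 - g)) * sqrt(max(disc, 0))
  center <- m + g / (1 - g) * (m + v12 / v22)
  lims <- 10^(center + c(-1, 1) * half)
  names(lims) <- c("lower", "upper")
  lims
}

#' Damage-threshold quality gates
#'
#' A fit is final when the probit slope exceeds 5 and, for every probability
#' of interest, both fiducial limits lie within +-30% of the ED value.
#'
#' @param fit a [fit_probit()] result
#' @param p_list probabilities to gate on (default `c(0.25, 0.5)`)
#' @param slope_min slope gate (default 5)
#' @param rel_fl_max relative fiducial-limit gate (default 0.30)
#' @return list: `pass` (logical), `reasons` (character), `detail` (data.frame
#'   per p: ed, lower, upper, rel_width)
#' @export
check_criteria <- function(fit, p_list = c(0.25, 0.5), slope_min = 5,
                           rel_fl_max = 0.30) {
  stopifnot(inherits(fit, "probit_fit"))
  reasons <- character(0)
  if (!(fit$slope > slope_min)) reasons <- c(reasons, "slope")
  rows <- lapply(p_list, function(p) {
    ed <- ed_dose(fit, p)
    fl <- tryCatch(fiducial_limits(fit, p),
                   laserlesion_unbounded_limits_error = function(e) c(lower = NA, upper = NA))
    rel <- max(abs(fl - ed)) / ed
    data.frame(p = p, ed = ed, lower = fl[["lower"]], upper = fl[["upper"]],
               rel_width = rel)
  })
  detail <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (any(!is.finite(detail$rel_width)) || any(detail$rel_width > rel_fl_max))
    reasons <- c(reasons, "fiducial width")
  list(pass = length(reasons) == 0, reasons = reasons, detail = detail)
}

#' Detect a deterministic (crossover-free) dose response
#'
#' The crossover range is `[min positive dose, max negative dose]`, sorted.
#' The response is deterministic when that range is narrower than the relative
#' dose uncertainty (default 3.2%, the stated irradiance uncertainty), or when
#' the probit fit cannot converge for lack of crossovers. The deterministic
#' threshold is the midpoint of the range.
#'
#' @param records an [exposure_records()] data.frame
#' @param dose_uncertainty relative dose uncertainty (default 0.032)
#' @return object of class `determinism_report`: `is_deterministic`,
#'   `crossover_range`, `deterministic_threshold`, `n_crossovers`,
#'   `probit_converged`
#' @export
detect_deterministic <- function(records, dose_uncertainty = 0.032) {
  xy <- records_to_xy(records)
  if (!any(xy$y == 1) || !any(xy$y == 0))
    .ll_error("need at least one positive and one negative record",
              "laserlesion_parameter_error")
  lo <- min(xy$dose[xy$y == 1])   # min positive
  hi <- max(xy$dose[xy$y == 0])   # max negative
  rng <- sort(c(lo, hi))
  midpoint <- mean(rng)
  width <- diff(rng)
  n_cross <- sum(xy$dose >= rng[1] & xy$dose <= rng[2])
  probit_ok <- tryCatch({ fit_probit(records); TRUE },
                        laserlesion_error = function(e) FALSE)
  deterministic <- (width <= dose_uncertainty * midpoint) || !probit_ok
  structure(list(is_deterministic = deterministic,
                 crossover_range = rng,
                 deterministic_threshold = midpoint,
                 n_crossovers = n_cross,
                 probit_converged = probit_ok),
            class = "determinism_report")
}

#' @export
print.determinism_report <- function(x, ...) {
  cat(sprintf("<determinism_report> %s; threshold %.4g (range %.4g-%.4g, %d in-range records)\n",
              if (x$is_deterministic) "deterministic" else "probabilistic",
              x$deterministic_threshold, x$crossover_range[1], x$crossover_range[2],
              x$n_crossovers))
  invisible(x)
}
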