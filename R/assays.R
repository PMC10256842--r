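#' Fit a logistic growth model to an OD600 curve
#'
#' Least-squares fit of the three-parameter logistic
#' `OD(t) = K / (1 + exp(-r (t - t_m)))`. The lag time is the
#' tangent-intercept definition: the time at which the tangent through the
#' inflection point crosses the initial OD level (a threshold-crossing
#' alternative is available). Flat curves return `r = 0` with the lag
#' flagged undefined.
#'
#' @param curve Tibble `time` (hours, strictly increasing), `od` (>= 0); at
#'   least 6 points.
#' @param lag_method `"tangent"` (default) or `"threshold"`.
#' @param threshold OD increment over the initial level defining the
#'   threshold crossing (default 5% of fitted K).
#' @return A `growth_fit` object: `r` (1/hr), `lag` (hr), `K` (OD), `t_mid`,
#'   `residual_norm`, `flat`, plus the data.
#' @examples
#' fit_logistic_growth(simulate_growth_curve(r = 0.6, lag = 2, K = 1))$r
#' @export
fit_logistic_growth <- function(curve, lag_method = c("tangent", "threshold"),
                                threshold = NULL) {
  lag_method <- match.arg(lag_method)
  time <- curve$time
  od <- curve$od
  assert_that(length(time) >= 6, "need at least 6 time points")
  if (any(diff(time) <= 0)) {
    stop_metarescue("time vector must be strictly increasing", "metarescue_bad_time")
  }
  assert_that(all(od >= 0), "OD values must be nonnegative")
  if (diff(range(od)) < 1e-8) {
    fit <- structure(
      list(
        r = 0, lag = NA_real_, K = mean(od), t_mid = NA_real_,
        residual_norm = 0, flat = TRUE, lag_method = lag_method,
        data = tibble(time = time, od = od, fitted = mean(od))
      ),
      class = "growth_fit"
    )
    return(fit)
  }
  K0 <- max(od) * 1.02
  # crude slope-based starting values
  dod <- diff(od) / diff(time)
  r0 <- max(4 * max(dod) / K0, 0.05)
  tm0 <- time[which.min(abs(od - K0 / 2))]
  nls_fit <- minpack.lm::nlsLM(
    od ~ K / (1 + exp(-r * (time - tm))),
    start = list(K = K0, r = r0, tm = tm0),
    lower = c(K = max(od) / 2, r = 1e-6, tm = min(time) - diff(range(time))),
    upper = c(K = 10 * max(od), r = 50, tm = max(time) + diff(range(time))),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(nls_fit)
  fitted <- stats::predict(nls_fit)
  od0_fit <- cf[["K"]] / (1 + exp(-cf[["r"]] * (time[1] - cf[["tm"]])))
  lag <- if (lag_method == "tangent") {
    # tangent at the inflection: slope rK/4 through (tm, K/2)
    cf[["tm"]] - (cf[["K"]] / 2 - od0_fit) * 4 / (cf[["r"]] * cf[["K"]])
  } else {
    thr <- od0_fit + (threshold %||% (0.05 * cf[["K"]]))
    cross <- which(fitted >= thr)
    if (length(cross) == 0) NA_real_ else time[cross[1]]
  }
  structure(
    list(
      r = unname(cf[["r"]]), lag = max(unname(lag), 0), K = unname(cf[["K"]]),
      t_mid = unname(cf[["tm"]]),
      residual_norm = sqrt(sum((od - fitted)^2)),
      flat = FALSE, lag_method = lag_method,
      data = tibble(time = time, od = od, fitted = fitted)
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit>  r = %.4g 1/hr, lag = %s hr, K = %.4g OD\n",
    x$r, if (is.na(x$lag)) "NA" else sprintf("%.3g", x$lag), x$K
  ))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("r", "lag", "K", "t_mid"),
    estimate = c(x$r, x$lag, x$K, x$t_mid),
    unit = c("1/hr", "hr", "OD600", "hr")
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    r = x$r, lag = x$lag, K = x$K,
    residual_norm = x$residual_norm, flat = x$flat, n = nrow(x$data)
  )
}

#' Percent residual enzyme activity from luminescence signals
#'
#' Linear rescaling of an ATP-proportional chemiluminescence signal between
#' the no-reaction control (substrate absent: ATP intact, activity 0%) and
#' the zero-inhibitor control (full reaction: maximal ATP consumption,
#' activity 100%):
#' `100 * (signal - no_reaction) / (zero_inhibitor - no_reaction)`.
#' Values are deliberately not clipped to `[0, 100]`: with noisy signals,
#' clipping would bias downstream dose-response fits.
#'
#' @param signal Signal(s) at the inhibitor concentration(s) of interest.
#' @param zero_inhibitor_signal Signal of the uninhibited reaction.
#' @param no_reaction_signal Signal with the reaction not initiated.
#' @return Percent activity (vectorized over `signal`).
#' @export
percent_activity <- function(signal, zero_inhibitor_signal, no_reaction_signal) {
  if (zero_inhibitor_signal == no_reaction_signal) {
    stop_metarescue(
      "reference signals are equal: percent activity undefined",
      "metarescue_undefined_activity"
    )
  }
  (signal - no_reaction_signal) / (zero_inhibitor_signal - no_reaction_signal) * 100
}

#' Fit an inhibition dose-response curve and extract the IC50
#'
#' Converts raw luminescence signals to percent activity via
#' [percent_activity()] and fits a four-parameter logistic
#' `A(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)` with asymptotes
#' bounded to `[-10, 110]`%. The reported IC50 is the fitted half-transition
#' concentration; evaluating the fitted curve there gives the midpoint of
#' the asymptotes (50% for a full-range curve).
#'
#' @param dose_response Tibble `concentration`, `signal`; reference signals
#'   are taken from attributes `zero_inhibitor_signal` / `no_reaction_signal`
#'   (as produced by [simulate_dose_response()]) unless given explicitly.
#' @param zero_inhibitor_signal,no_reaction_signal Optional explicit
#'   reference signals; the zero-inhibitor default is the mean signal at
#'   concentration 0.
#' @return An `activity_fit` object: `ic50`, `hill`, `top`, `bottom`,
#'   `residual_norm` and the per-concentration data with activities.
#' @export
fit_ic50 <- function(dose_response, zero_inhibitor_signal = NULL,
                     no_reaction_signal = NULL) {
  conc <- dose_response$concentration
  signal <- dose_response$signal
  zero_inhibitor_signal <- zero_inhibitor_signal %||%
    attr(dose_response, "zero_inhibitor_signal") %||%
    mean(signal[conc == 0])
  no_reaction_signal <- no_reaction_signal %||% attr(dose_response, "no_reaction_signal")
  assert_that(
    !is.null(no_reaction_signal),
    "no_reaction_signal required (attribute or argument)"
  )
  assert_that(length(unique(conc)) >= 4, "need >= 4 distinct concentrations")
  activity <- percent_activity(signal, zero_inhibitor_signal, no_reaction_signal)
  pos <- conc > 0
  if (min(activity) > 50 || max(activity) < 50) {
    stop_metarescue(
      "activities do not span the 50% transition; IC50 not identifiable",
      "metarescue_no_transition"
    )
  }
  run_means <- tapply(activity, conc, mean)
  if (any(diff(run_means[order(as.numeric(names(run_means)))]) > 15)) {
    warn("activity is non-monotone in concentration beyond noise level")
  }
  ic50_0 <- conc[pos][which.min(abs(activity[pos] - 50))]
  fit_once <- function(start) {
    minpack.lm::nlsLM(
      activity ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
      start = start,
      lower = c(top = -10, bottom = -10, ic50 = min(conc[pos]) / 100, hill = 0.1),
      upper = c(top = 110, bottom = 110, ic50 = max(conc) * 100, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }
  # starts deliberately off any exact interpolant: a perfect noise-free start
  # makes the initial Jacobian singular
  fit <- tryCatch(
    fit_once(list(top = 99, bottom = 1, ic50 = ic50_0 * 1.1, hill = 0.9)),
    error = function(e) fit_once(list(top = 95, bottom = 5, ic50 = ic50_0 * 0.7, hill = 1.3))
  )
  cf <- stats::coef(fit)
  structure(
    list(
      ic50 = unname(cf[["ic50"]]), hill = unname(cf[["hill"]]),
      top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
      zero_inhibitor_signal = zero_inhibitor_signal,
      no_reaction_signal = no_reaction_signal,
      residual_norm = sqrt(sum(stats::residuals(fit)^2)),
      data = tibble(
        concentration = conc, signal = signal, activity = activity,
        fitted = stats::predict(fit)
      )
    ),
    class = "activity_fit"
  )
}

#' Evaluate the fitted percent-activity curve at given concentrations
#'
#' @param fit An [fit_ic50()] result.
#' @param concentration Concentration(s).
#' @return Fitted percent activity.
#' @export
activity_at <- function(fit, concentration) {
  assert_that(inherits(fit, "activity_fit"), "fit must be an activity_fit")
  fit$bottom + (fit$top - fit$bottom) / (1 + (concentration / fit$ic50)^fit$hill)
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf(
    "<activity_fit>  IC50 = %.4g, hill = %.3g, asymptotes %.3g%% -> %.3g%%\n",
    x$ic50, x$hill, x$top, x$bottom
  ))
  invisible(x)
}

#' @export
tidy.activity_fit <- function(x, ...) {
  tibble(
    term = c("ic50", "hill", "top", "bottom"),
    estimate = c(x$ic50, x$hill, x$top, x$bottom)
  )
}

#' @export
glance.activity_fit <- function(x, ...) {
  tibble(
    ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
    residual_norm = x$residual_norm, n = nrow(x$data)
  )
}

#' Cheng-Prusoff inhibition constant from an IC50
#'
#' For a competitive inhibitor assayed at substrate concentration `[S]` with
#' Michaelis constant `Km`: `Ki = IC50 / (1 + [S] / Km)`. `Ki` is always
#' below the IC50 and approaches it as the substrate becomes negligible
#' relative to `Km`.
#'
#' @param ic50 Half-maximal inhibitory concentration (> 0).
#' @param substrate_conc Assay substrate concentration, same units (> 0).
#' @param km Michaelis constant of the substrate (> 0).
#' @return Ki in the units of `ic50`.
#' @examples
#' ki_cheng_prusoff(39.23, substrate_conc = 18, km = 1.7854)
#' @export
ki_cheng_prusoff <- function(ic50, substrate_conc, km) {
  assert_that(
    is_number(ic50) && ic50 > 0 &&
      is_number(substrate_conc) && substrate_conc > 0 &&
      is_number(km) && km > 0,
    "ic50, substrate_conc and km must all be > 0"
  )
  ic50 / (1 + substrate_conc / km)
}

#' Compare two cell-length distributions
#'
#' Medians, means and the box-plot percentile summary (10/25/75/90) for each
#' sample, plus a one-sided Mann-Whitney p-value. Cell lengths are typically
#' non-normal (log-normal-like with a resolution floor), hence the rank
#' test. `alternative = "greater"` tests whether sample `b` tends to exceed
#' sample `a`.
#'
#' @param a,b Numeric length samples (micrometers); >= 30 cells each
#'   recommended.
#' @param alternative Passed to [mann_whitney_one_sided()] as the direction
#'   of `b` relative to `a`.
#' @return A `cell_length_comparison`: tibble `sample`, `n`, `mean`,
#'   `median`, `p10`, `p25`, `p75`, `p90` with the p-value and alternative
#'   as attributes (also in `print()`).
#' @export
compare_cell_lengths <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  assert_that(length(a) >= 1 && length(b) >= 1, "empty sample")
  summarise_one <- function(x, label) {
    q <- quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
    tibble(
      sample = label, n = length(x), mean = mean(x), median = median(x),
      p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4]
    )
  }
  out <- dplyr::bind_rows(summarise_one(a, "a"), summarise_one(b, "b"))
  mw <- mann_whitney_one_sided(b, a, alternative)
  attr(out, "p_value") <- mw$p_value
  attr(out, "statistic") <- mw$statistic
  attr(out, "alternative") <- alternative
  class(out) <- c("cell_length_comparison", class(out))
  out
}

#' @export
print.cell_length_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf(
    "one-sided Mann-Whitney (b %s a): p = %.4g\n",
    attr(x, "alternative"), attr(x, "p_value")
  ))
  invisible(x)
}
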