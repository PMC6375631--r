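#' Primer-extension curve under dynamic enzyme deactivation
#'
#' Fraction of primer/template DNA extended after time `t` by an enzyme that
#' synthesizes with pseudo-first-order rate constant `k` while its active
#' concentration is depleted by a Poisson deactivation process with rate `D`.
#' Integrating `dP/dt = k e^(-D t) (1 - P)` gives
#' \deqn{P(t) = 1 - \exp\{-(k/D)(1 - e^{-D t})\},}
#' with the no-deactivation limit `1 - exp(-k t)` as `D -> 0` and plateau
#' `1 - exp(-k/D)` as `t -> Inf`. An alternative published variant of the
#' integrated equation, `ln(1 - P) = -k t + k (e^{-D t} - D t - 1)/D`, is
#' available via `form = "as-printed"`; note its short-time slope is `-3 k t`
#' rather than `-k t`, so it is kept only for comparison (see the package
#' vignette).
#'
#' @param t Time in minutes (vector, `>= 0`).
#' @param k Pseudo-first-order synthesis rate constant, min^-1 (`>= 0`).
#' @param D Dynamic deactivation rate, min^-1 (`>= 0`).
#' @param form `"depletion"` (default, the self-consistent integral) or
#'   `"as-printed"` (the variant above).
#' @return Fraction extended, same length as `t`, in `[0, 1]`.
#' @examples
#' pe_model(90, k = 0.008, D = 0.028)      # ~0.231
#' pe_model(Inf, k = 0.008, D = 0.028)     # plateau ~0.2485
#' pe_model(60, k = 0.008, D = 0)          # ~0.381, no-deactivation limit
#' @export
pe_model <- function(t, k, D, form = c("depletion", "as-printed")) {
  form <- match.arg(form)
  if (any(!is.finite(t) & !is.infinite(t))) stop("'t' must be numeric")
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (length(k) != 1L || !is.finite(k) || k < 0) stop("'k' must be a single nonnegative number")
  if (length(D) != 1L || !is.finite(D) || D < 0) stop("'D' must be a single nonnegative number")
  if (form == "depletion") {
    -expm1(-k * .active_time(t, D))
  } else {
    # as printed: ln(1-P) = -k t + k (e^{-D t} - D t - 1)/D; D -> 0 limit is -3 k t
    corr <- if (D == 0) -2 * t else (exp(-D * t) - D * t - 1) / D
    corr[is.infinite(t)] <- -Inf
    p <- 1 - exp(-k * t + k * corr)
    p[k == 0] <- 0
    p
  }
}

# integral_0^t exp(-D s) ds, stable as D -> 0 (equals t in the limit)
.active_time <- function(t, D) {
  x <- D * t
  out <- ifelse(x < 1e-8, t * (1 - x / 2), -expm1(-x) / D)
  if (D > 0) out[is.infinite(t)] <- 1 / D else out[is.infinite(t)] <- Inf
  out
}

#' Initial synthesis rate from the short-time linearization
#'
#' At short times the extension curve obeys `-ln(1 - P) ~ k t`, so the
#' least-squares slope of `-ln(1 - pe)` against time over the earliest points
#' estimates the intrinsic synthesis rate constant `k` before deactivation
#' becomes significant. The default window is the first three points with
#' `pe < 0.1` (falling back to the first three points if fewer qualify).
#'
#' @param times Times in minutes, strictly increasing.
#' @param pe Fraction extended at each time, in `[0, 1]`.
#' @param window_n Number of early points to use (`>= 2`); `NULL` for the
#'   default window.
#' @return Estimated `k` in min^-1.
#' @export
fit_initial_rate <- function(times, pe, window_n = NULL) {
  .check_timecourse(times, pe)
  usable <- pe < 1
  if (any(!usable)) {
    warning("dropping ", sum(!usable), " point(s) with pe = 1 from the initial-rate window")
    times <- times[usable]
    pe <- pe[usable]
  }
  if (is.null(window_n)) {
    early <- which(pe < 0.1)
    idx <- if (length(early) >= 2L) utils::head(early, 3L) else seq_len(min(3L, length(pe)))
  } else {
    if (window_n < 2L) stop("'window_n' must be at least 2")
    idx <- seq_len(min(window_n, length(pe)))
  }
  if (length(idx) < 2L) stop("fewer than 2 usable points in the initial-rate window")
  y <- -log1p(-pe[idx])
  unname(stats::coef(stats::lm(y ~ times[idx]))[2L])
}

#' Fit the two-parameter dynamic-deactivation model to a time course
#'
#' Nonlinear least-squares fit of [pe_model()] to an extension time course.
#' The synthesis rate `k` is seeded from [fit_initial_rate()] and both `k` and
#' `D` are then free, bounded below by zero (Levenberg-Marquardt via
#' \pkg{minpack.lm}). When per-point standard deviations are supplied the fit
#' is inverse-variance weighted.
#'
#' @param times Times in minutes, strictly increasing, at least 4 points.
#' @param pe Fraction extended at each time.
#' @param pe_sd Optional per-point standard deviation (replicate SD) used as
#'   inverse-variance weights.
#' @param k_init,D_init Starting values; `k_init = NULL` seeds from the
#'   initial-rate fit.
#' @param window_n Passed to [fit_initial_rate()] when seeding `k`.
#' @param form Model variant, see [pe_model()].
#' @return An object of class `"deact_fit"`: a list with elements `k`, `D`,
#'   `k_se`, `D_se`, `residual_rms`, `converged`, `window_n`, `data`, `form`.
#'   Supports `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @examples
#' t <- c(0, 15, 30, 60, 90, 120, 180, 240, 300)
#' p <- pe_model(t, 0.008, 0.028)
#' fit <- fit_deactivation(t, p)
#' coef(fit)  # recovers k = 0.008, D = 0.028
#' @export
fit_deactivation <- function(times, pe, pe_sd = NULL, k_init = NULL,
                             D_init = 0.01, window_n = NULL,
                             form = c("depletion", "as-printed")) {
  form <- match.arg(form)
  .check_timecourse(times, pe)
  if (length(times) < 4L) stop("need at least 4 time points to fit k and D")
  if (is.null(k_init)) k_init <- fit_initial_rate(times, pe, window_n)
  if (k_init <= 0) k_init <- 1e-4
  if (D_init <= 0) stop("'D_init' must be positive")
  w <- if (is.null(pe_sd)) rep(1, length(pe)) else {
    if (length(pe_sd) != length(pe) || any(pe_sd <= 0)) stop("'pe_sd' must be positive, one per point")
    1 / pe_sd^2
  }
  df <- data.frame(t = times, p = pe)
  sw <- sqrt(w)
  fit <- minpack.lm::nls.lm(
    par = c(k = k_init, D = D_init),
    fn = function(par) sw * (df$p - pe_model(df$t, par[1], par[2], form = form)),
    lower = c(0, 0), upper = c(Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  )
  converged <- fit$info %in% 1:4
  if (!converged) stop("deactivation fit did not converge: ", fit$message)
  est <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k = NA_real_, D = NA_real_))
  res <- df$p - pe_model(df$t, est["k"], est["D"], form = form)
  structure(list(
    k = unname(est["k"]), D = unname(est["D"]),
    k_se = unname(se["k"]), D_se = unname(se["D"]),
    residual_rms = sqrt(mean(res^2)),
    converged = converged,
    window_n = if (is.null(window_n)) NA_integer_ else as.integer(window_n),
    form = form,
    data = df,
    fitted = df$p - res,
    call = match.call()
  ), class = "deact_fit")
}

#' @export
print.deact_fit <- function(x, digits = 4, ...) {
  cat("Dynamic-deactivation fit (", x$form, " form)\n", sep = "")
  cat(sprintf("  k = %.*g min^-1 (SE %.2g)\n", digits, x$k, x$k_se))
  cat(sprintf("  D = %.*g min^-1 (SE %.2g)\n", digits, x$D, x$D_se))
  cat(sprintf("  plateau P(Inf) = %.*g; residual RMS = %.3g; n = %d points\n",
              digits, plateau(x), x$residual_rms, nrow(x$data)))
  invisible(x)
}

#' @export
summary.deact_fit <- function(object, ...) {
  out <- list(
    coefficients = cbind(Estimate = c(k = object$k, D = object$D),
                         `Std. Error` = c(object$k_se, object$D_se)),
    plateau = plateau(object),
    residual_rms = object$residual_rms,
    n = nrow(object$data),
    converged = object$converged,
    form = object$form
  )
  class(out) <- "summary.deact_fit"
  out
}

#' @export
print.summary.deact_fit <- function(x, ...) {
  cat("Dynamic-deactivation model: P(t) = 1 - exp{-(k/D)(1 - e^(-D t))}\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Plateau %.4g, residual RMS %.3g over %d points (%s form)\n",
              x$plateau, x$residual_rms, x$n, x$form))
  invisible(x)
}

#' @export
coef.deact_fit <- function(object, ...) c(k = object$k, D = object$D)

#' @export
residuals.deact_fit <- function(object, ...) object$data$p - object$fitted

#' Predicted fraction extended from a fitted deactivation model
#' @param object A `"deact_fit"`.
#' @param times Times (minutes) at which to predict; defaults to the data.
#' @param ... Unused.
#' @export
predict.deact_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$t
  pe_model(times, object$k, object$D, form = object$form)
}

#' @export
plot.deact_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$p, xlab = "Time (min)", ylab = "Fraction extended",
                 ylim = c(0, max(x$data$p, plateau(x)) * 1.05), ...)
  tt <- seq(0, max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = plateau(x), lty = 3)
  invisible(x)
}

#' Long-time extension plateau of a deactivation model
#'
#' `1 - exp(-k/D)`; equals 1 when `D = 0`.
#' @param object Either a `"deact_fit"` or the rate `k` (with `D` supplied).
#' @param D Deactivation rate, if `object` is numeric `k`.
#' @export
plateau <- function(object, D = NULL) {
  if (inherits(object, "deact_fit")) {
    k <- object$k; D <- object$D
  } else {
    k <- object
    if (is.null(D)) stop("supply 'D' when 'object' is the rate k")
  }
  if (D == 0) return(if (k > 0) 1 else 0)
  -expm1(-k / D)
}

#' Fraction of primer extended from gel band intensities
#'
#' Integrated intensity of all extended-product bands divided by the total
#' lane intensity (unextended plus extended).
#'
#' @param unextended Intensity of the unextended primer band (scalar `>= 0`).
#' @param extended Intensities of the extended-product bands (vector, possibly
#'   empty, all `>= 0`).
#' @return Fraction extended in `[0, 1]`.
#' @examples
#' percent_extended(80, 20)          # 0.20, one round at 5-fold DNA excess
#' percent_extended(10, c(5, 5, 10, 10))  # 0.75
#' @export
percent_extended <- function(unextended, extended = numeric(0)) {
  if (length(unextended) != 1L || unextended < 0) stop("'unextended' must be a single nonnegative intensity")
  if (any(extended < 0)) stop("band intensities must be nonnegative")
  total <- unextended + sum(extended)
  if (total <= 0) stop("all band intensities are zero; cannot form a fraction")
  sum(extended) / total
}

#' Static deactivation rate from an activity-decay series
#'
#' Initial static deactivation rate estimated from the loss of relative
#' activity at a reference incubation time (default 30 min). Under the
#' exponential-decay convention the rate is `-ln(A(t_ref)) / t_ref`; a linear
#' convention `(1 - A(t_ref)) / t_ref` is available. Activity at `t_ref` is
#' linearly interpolated if not sampled exactly.
#'
#' @param times Incubation times in minutes (must bracket `t_ref`, include 0).
#' @param rel_activity Activity relative to `t = 0`.
#' @param t_ref Reference time, minutes.
#' @param method `"exponential"` (default) or `"linear"`.
#' @return Rate in min^-1.
#' @examples
#' static_rate(c(0, 30), c(1, exp(-0.45)))  # 0.015 min^-1
#' @export
static_rate <- function(times, rel_activity, t_ref = 30,
                        method = c("exponential", "linear")) {
  method <- match.arg(method)
  if (length(times) != length(rel_activity)) stop("'times' and 'rel_activity' lengths differ")
  if (min(times) > 0 || max(times) < t_ref) stop("series must span t = 0 to t_ref = ", t_ref)
  a_ref <- stats::approx(times, rel_activity, xout = t_ref, ties = "ordered")$y
  if (a_ref <= 0) stop("relative activity at t_ref is nonpositive; rate undefined")
  if (method == "exponential") -log(a_ref) / t_ref else (1 - a_ref) / t_ref
}

#' Two-point Arrhenius activation energy
#'
#' Activation energy from rates measured at two temperatures,
#' `Ea = R ln(rate_high/rate_low) / (1/T_low - 1/T_high)` with temperatures in
#' Kelvin (`K = degC + 273.15`) and `R = 1.9872e-3 kcal mol^-1 K^-1`.
#'
#' @param rate_low Rate at the lower temperature, min^-1 (> 0).
#' @param temp_low_c Lower temperature, degrees Celsius.
#' @param rate_high Rate at the higher temperature, min^-1 (> 0).
#' @param temp_high_c Higher temperature, degrees Celsius.
#' @return A list of class `"arrhenius"`: `ea` (kcal/mol), `rate_low`,
#'   `rate_high`, `T_low`, `T_high` (Kelvin).
#' @examples
#' arrhenius_ea(0.008, 30, 0.015, 37)$ea  # ~16.8 kcal/mol
#' @export
arrhenius_ea <- function(rate_low, temp_low_c, rate_high, temp_high_c) {
  if (rate_low <= 0 || rate_high <= 0) stop("rates must be positive")
  if (temp_low_c == temp_high_c) stop("temperatures must be distinct")
  if (temp_low_c > temp_high_c) stop("'temp_low_c' must be below 'temp_high_c'")
  R <- 1.9872e-3 # kcal mol^-1 K^-1
  t_lo <- temp_low_c + 273.15
  t_hi <- temp_high_c + 273.15
  ea <- R * log(rate_high / rate_low) / (1 / t_lo - 1 / t_hi)
  structure(list(ea = ea, rate_low = rate_low, rate_high = rate_high,
                 T_low = t_lo, T_high = t_hi), class = "arrhenius")
}

#' @export
print.arrhenius <- function(x, ...) {
  cat(sprintf("Arrhenius two-point estimate: Ea = %.3g kcal/mol\n", x$ea))
  cat(sprintf("  rates %.3g min^-1 @ %.2f K, %.3g min^-1 @ %.2f K\n",
              x$rate_low, x$T_low, x$rate_high, x$T_high))
  invisible(x)
}

#' Predicted rounds of DNA synthesis before deactivation
#'
#' With p/t DNA in `dna_excess`-fold molar excess over enzyme, one complete
#' round of synthesis extends a fraction `1/dna_excess` of the primers. The
#' number of rounds completed before dynamic deactivation halts synthesis is
#' the extension plateau divided by the per-round fraction.
#'
#' @param k Synthesis rate constant, min^-1.
#' @param D Dynamic deactivation rate, min^-1. `D = 0` gives plateau 1, so the
#'   enzyme cycles through all available DNA (`rounds = dna_excess`).
#' @param dna_excess Molar excess of p/t DNA over enzyme (`>= 1`).
#' @return Rounds of synthesis (dimensionless).
#' @examples
#' predict_rounds(0.008, 0.028, 5)  # ~1.2, a single round at 37 C
#' predict_rounds(0.012, 0.01, 5)   # ~3.5 rounds at 30 C
#' @export
predict_rounds <- function(k, D, dna_excess) {
  if (dna_excess < 1) stop("'dna_excess' must be at least 1")
  if (k < 0 || D < 0) stop("rates must be nonnegative")
  plateau(k, D) * dna_excess
}

.check_timecourse <- function(times, pe) {
  if (length(times) != length(pe)) stop("'times' and 'pe' lengths differ")
  if (any(times < 0)) stop("times must be nonnegative")
  d <- diff(times)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("times must be strictly increasing; offending index ", bad)
  }
  if (any(pe < 0 | pe > 1)) stop("'pe' must lie in [0, 1]")
  invisible(TRUE)
}
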