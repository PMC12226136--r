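# Quantitative activity layer: Michaelis-Menten fitting with fluorescence
# calibration and inner-filter correction hooks, active-site titration with
# a tight-binding inhibitor (x-intercept of the initial linear region), and
# progress-curve specificity constants under the sub-saturating
# single-exponential model.

#' Convert a fluorescence rate into a product formation rate
#'
#' RFU/s are converted to molar/s by dividing by the calibration factor
#' (RFU per molar of product, derived from complete digestion of a substrate
#' standard). Inner-filter corrections enter as per-well multiplicative
#' factors supplied by the user (unity when absorbance is negligible).
#'
#' @param rfu_rate Observed rate(s), RFU/s.
#' @param calibration RFU per molar product (> 0).
#' @param ife_factor Multiplicative inner-filter correction(s), default 1.
#' @return Initial velocity v0 in molar/s.
#' @export
calibrate_rfu <- function(rfu_rate, calibration, ife_factor = 1) {
  if (any(calibration <= 0)) stop("calibration must be positive")
  rfu_rate * ife_factor / calibration
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of v0 = Vmax [S] / (Km + [S]) via
#' Levenberg-Marquardt, with starting values from a Hanes-Woolf
#' linearisation. When the active enzyme concentration is supplied, the
#' turnover number kcat = Vmax / [E] and the specificity constant
#' kcat/Km are derived.
#'
#' @param substrate_conc Substrate concentrations (molar), >= 4 distinct.
#' @param v0 Initial velocities (molar/s), same length.
#' @param enzyme_conc_active Optional active enzyme concentration (molar).
#' @return List of class `mm_fit`: `Km`, `Vmax`, `Km_se`, `Vmax_se`,
#'   `kcat`, `kcat_se`, `kcat_over_Km`, `fitted`, `model`.
#' @export
fit_mm <- function(substrate_conc, v0, enzyme_conc_active = NULL) {
  stopifnot(length(substrate_conc) == length(v0))
  if (length(unique(substrate_conc)) < 4L) {
    stop("need at least 4 distinct substrate concentrations")
  }
  if (any(substrate_conc <= 0)) stop("substrate concentrations must be > 0")
  if (any(v0 < 0)) stop("initial rates must be nonnegative")
  df <- data.frame(S = substrate_conc, v = v0)
  # Hanes-Woolf: S/v = S/Vmax + Km/Vmax, linear in S
  ok <- df$v > 0
  hw <- stats::lm(I(S / v) ~ S, data = df[ok, , drop = FALSE])
  start_vmax <- 1 / max(stats::coef(hw)[2L], .Machine$double.eps)
  start_km <- max(stats::coef(hw)[1L] * start_vmax, min(df$S) / 10)
  fit <- minpack.lm::nlsLM(
    v ~ Vmax * S / (Km + S), data = df,
    start = list(Vmax = start_vmax, Km = start_km),
    lower = c(Vmax = 0, Km = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  if (any(est <= 0)) stop("non-positive parameter estimate")
  out <- list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
              Km_se = unname(se["Km"]), Vmax_se = unname(se["Vmax"]),
              kcat = NA_real_, kcat_se = NA_real_, kcat_over_Km = NA_real_,
              enzyme_conc_active = enzyme_conc_active,
              fitted = stats::fitted(fit), model = fit)
  if (!is.null(enzyme_conc_active)) {
    if (enzyme_conc_active <= 0) stop("enzyme concentration must be > 0")
    out$kcat <- out$Vmax / enzyme_conc_active
    out$kcat_se <- out$Vmax_se / enzyme_conc_active
    out$kcat_over_Km <- out$kcat / out$Km
  }
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g M, Vmax = %.4g M/s", x$Km, x$Vmax))
  if (!is.na(x$kcat)) {
    cat(sprintf(", kcat = %.4g 1/s, kcat/Km = %.4g 1/(M s)",
                x$kcat, x$kcat_over_Km))
  }
  cat("\n")
  invisible(x)
}

#' Specificity constant from turnover number and Michaelis constant
#'
#' @param kcat Turnover number (1/s).
#' @param Km Michaelis constant (molar).
#' @return kcat / Km in 1/(M s).
#' @export
specificity_constant <- function(kcat, Km) {
  if (any(kcat <= 0) || any(Km <= 0)) stop("kcat and Km must be positive")
  kcat / Km
}

#' Active-site titration with a tight-binding inhibitor
#'
#' Residual activity (% of uninhibited control) declines linearly with the
#' concentration of a 1:1 stoichiometric tight-binding inhibitor until the
#' enzyme is exhausted; the x-intercept of a least-squares line through the
#' initial linear portion is the active enzyme concentration.
#'
#' @param inhibitor_conc Inhibitor concentrations (molar), ascending.
#' @param residual_activity Residual activity (%, 100 at zero inhibitor).
#' @param linear_region Optional integer indices of the points to fit; by
#'   default all points with residual activity >= `min_activity`.
#' @param min_activity Default linear-region cutoff (default 20, percent).
#' @return List of class `titration_fit`: `active_conc` (molar), `slope`,
#'   `intercept`, `linear_region`, `model`.
#' @export
fit_titration <- function(inhibitor_conc, residual_activity,
                          linear_region = NULL, min_activity = 20) {
  stopifnot(length(inhibitor_conc) == length(residual_activity))
  if (is.null(linear_region)) {
    linear_region <- which(residual_activity >= min_activity)
  }
  if (length(linear_region) < 3L) {
    stop("need at least 3 points in the linear region")
  }
  x <- inhibitor_conc[linear_region]
  y <- residual_activity[linear_region]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0) {
    stop("non-negative slope: no titration endpoint")
  }
  structure(list(active_conc = -intercept / slope, slope = slope,
                 intercept = intercept, linear_region = linear_region,
                 model = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> active concentration = %.4g M (%d points)\n",
              x$active_conc, length(x$linear_region)))
  invisible(x)
}

#' Specificity constant from a product progress curve
#'
#' Under sub-saturating substrate (S0 << Km) product formation follows
#' P(t) = S0 (1 - exp(-(kcat/Km) E t)); the single fitted rate constant is
#' the specificity constant kcat/Km.
#'
#' @param time Time points (s), >= 4.
#' @param product_conc Product concentrations (molar).
#' @param S0 Initial substrate concentration (molar).
#' @param enzyme_conc_active Active enzyme concentration (molar).
#' @return List of class `progress_fit`: `kcat_over_Km` (1/(M s)), `se`,
#'   `fitted`, `model`.
#' @export
fit_progress <- function(time, product_conc, S0, enzyme_conc_active) {
  stopifnot(length(time) == length(product_conc))
  if (length(time) < 4L) stop("need at least 4 time points")
  if (S0 <= 0 || enzyme_conc_active <= 0) {
    stop("S0 and enzyme concentration must be positive")
  }
  if (any(product_conc > S0 * 1.05)) {
    stop("product exceeds initial substrate beyond assay tolerance")
  }
  df <- data.frame(t = time, P = product_conc, S0 = S0,
                   E = enzyme_conc_active)
  # start from the fraction converted at the last informative point
  frac <- pmin(pmax(df$P / S0, 1e-6), 0.999)
  k0 <- stats::median(-log(1 - frac[df$t > 0]) /
                        (enzyme_conc_active * df$t[df$t > 0]))
  fit <- minpack.lm::nlsLM(
    P ~ S0 * (1 - exp(-k * E * t)), data = df,
    start = list(k = max(k0, .Machine$double.eps)), lower = c(k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  k <- unname(stats::coef(fit)["k"])
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(kcat_over_Km = k, se = se, fitted = stats::fitted(fit),
                 model = fit),
            class = "progress_fit")
}

#' @export
print.progress_fit <- function(x, ...) {
  cat(sprintf("<progress_fit> kcat/Km = %.4g 1/(M s)\n", x$kcat_over_Km))
  invisible(x)
}

#' Fold comparison of activities against a reference
#'
#' @param values Named numeric vector or list of positive values (e.g.
#'   specificity constants per enzyme).
#' @param reference Name of the reference entry.
#' @return Data.frame with `label`, `value`, `fold` (value/reference),
#'   `direction` (`"higher"`/`"lower"`/`"equal"`) and `fold_label` such as
#'   `"165-fold higher"`.
#' @export
fold_compare <- function(values, reference) {
  values <- unlist(values)
  if (!reference %in% names(values)) {
    stop("reference '", reference, "' not among values")
  }
  if (any(values <= 0)) stop("all values must be positive")
  ref <- values[[reference]]
  fold <- values / ref
  direction <- ifelse(fold > 1, "higher", ifelse(fold < 1, "lower", "equal"))
  mag <- ifelse(fold >= 1, fold, 1 / fold)
  data.frame(
    label = names(values), value = as.numeric(values),
    fold = as.numeric(fold), direction = direction,
    fold_label = ifelse(direction == "equal", "1-fold",
                        sprintf("%.3g-fold %s", mag, direction)),
    stringsAsFactors = FALSE, row.names = NULL)
}
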