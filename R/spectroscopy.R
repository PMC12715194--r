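#' Mean residue ellipticity
#'
#' Converts a raw circular-dichroism signal into mean residue
#' ellipticity, `[theta]_MR = 100 * theta / (C * N * l)`, in
#' deg cm^2 dmol^-1.
#'
#' @param theta Ellipticity in millidegrees. Vectorised.
#' @param c_molar Protein concentration in mol/L (> 0).
#' @param n_residues Number of amino-acid residues in the construct (> 0).
#' @param path_cm Cuvette path length in cm (> 0).
#' @return Mean residue ellipticity.
#' @examples
#' mean_residue_ellipticity(-10, 3.5e-6, 392, 0.1)
#' @export
mean_residue_ellipticity <- function(theta, c_molar, n_residues, path_cm) {
  if (c_molar <= 0 || n_residues <= 0 || path_cm <= 0)
    stop("concentration, residue count and path length must be > 0")
  100 * theta / (c_molar * n_residues * path_cm)
}

## Two-state cold-transition fraction. With dH < 0 the transited fraction
## rises on cooling below t_mid; f = 0.5 exactly at t_mid.
two_state_fraction <- function(temperature_C, dH, t_mid_C) {
  tk <- celsius_to_kelvin(temperature_C)
  tm <- celsius_to_kelvin(t_mid_C)
  1 / (1 + exp((dH / R_KCAL) * (1 / tk - 1 / tm)))
}

two_state_signal <- function(temperature_C, dH, t_mid_C,
                             bf0, bf1, bu0, bu1) {
  fu <- two_state_fraction(temperature_C, dH, t_mid_C)
  (bf0 + bf1 * temperature_C) * (1 - fu) + (bu0 + bu1 * temperature_C) * fu
}

#' Fit a two-state thermal transition with linear baselines
#'
#' Nonlinear least squares of
#' `signal(T) = b_f(T) (1 - f) + b_u(T) f` with
#' `f(T) = 1 / (1 + exp[(dH/R)(1/T - 1/T_mid)])` (temperatures in Kelvin
#' internally) and linear native/transited baselines
#' `b(T) = b0 + b1 * T` (in degC). A van't Hoff two-state model with the
#' heat-capacity change of the transition fixed at zero. For a
#' cold-induced transition the fitted `dH` is negative.
#'
#' @param temperature_C Temperature series (degC), >= 5 points spanning
#'   the transition.
#' @param signal Melt signal (e.g. mean residue ellipticity at 222 nm).
#' @param start Optional named list of starting values
#'   (`dH, t_mid, bf0, bf1, bu0, bu1`); sensible defaults are derived
#'   from the data.
#' @return Object of class `"melt_fit"`: `dH` (kcal/mol), `t_mid` (degC),
#'   `baselines`, asymptotic 95 percent `ci` for `dH` and `t_mid`,
#'   `r_squared`, and the underlying `nls` fit.
#' @export
fit_two_state_melt <- function(temperature_C, signal, start = NULL) {
  stopifnot(length(temperature_C) == length(signal))
  if (length(unique(temperature_C)) < 5L)
    stop("melt fit needs >= 5 distinct temperatures spanning the transition")
  if (stats::sd(signal) == 0)
    stop("degenerate melt fit: signal is flat")
  dat <- data.frame(t = temperature_C, y = signal)
  if (is.null(start)) {
    mid_sig <- (max(signal) + min(signal)) / 2
    t_mid0 <- dat$t[which.min(abs(signal - mid_sig))]
    lo <- dat$t <= stats::quantile(dat$t, 0.2)
    hi <- dat$t >= stats::quantile(dat$t, 0.8)
    ## cold-induced transition: warm end is the native baseline
    bf0 <- mean(signal[hi]); bu0 <- mean(signal[lo])
    start <- list(dH = -40, t_mid = t_mid0, bf0 = bf0, bf1 = 0,
                  bu0 = bu0, bu1 = 0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_state_signal(t, dH, t_mid, bf0, bf1, bu0, bu1),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("melt fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  if (co[["t_mid"]] < min(dat$t) || co[["t_mid"]] > max(dat$t))
    warning("fitted midpoint lies outside the data range")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 6), names(co)))
  z <- stats::qnorm(0.975)
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((dat$y - mean(dat$y))^2)
  structure(list(
    dH = unname(co[["dH"]]),
    t_mid = unname(co[["t_mid"]]),
    baselines = co[c("bf0", "bf1", "bu0", "bu1")],
    ci = list(dH = co[["dH"]] + c(-1, 1) * z * se[["dH"]],
              t_mid = co[["t_mid"]] + c(-1, 1) * z * se[["t_mid"]]),
    r_squared = r2,
    nls = fit), class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit\n  dH    = %.1f kcal/mol (95%% CI %.1f to %.1f)\n",
              x$dH, x$ci$dH[1], x$ci$dH[2]))
  cat(sprintf("  T_mid = %.2f degC (95%% CI %.2f to %.2f)\n  R^2   = %.5f\n",
              x$t_mid, x$ci$t_mid[1], x$ci$t_mid[2], x$r_squared))
  invisible(x)
}

#' Emission peak position by local quadratic interpolation
#'
#' Finds the spectrum maximum and refines it with a quadratic fit over a
#' +/- `half_window`-point window around the argmax, giving sub-nanometre
#' precision on sampled spectra. A plateau of equal maxima is resolved to
#' the centroid of the plateau before refinement.
#'
#' @param wavelength Wavelength grid (nm), increasing, >= 5 points.
#' @param intensity Emission intensities (>= 0).
#' @param half_window Points on each side used in the quadratic fit
#'   (default 3).
#' @return Peak wavelength in nm.
#' @export
emission_peak <- function(wavelength, intensity, half_window = 3L) {
  stopifnot(length(wavelength) == length(intensity))
  if (length(wavelength) < 5L) stop("need >= 5 points around the maximum")
  if (is.unsorted(wavelength)) {
    o <- order(wavelength)
    wavelength <- wavelength[o]; intensity <- intensity[o]
  }
  imax <- which(intensity == max(intensity))
  i0 <- round(mean(imax))          # plateau tie-break: window centroid
  if (i0 == 1L || i0 == length(wavelength))
    stop("no interior maximum: spectrum is monotone at its edge")
  idx <- max(1L, i0 - half_window):min(length(wavelength), i0 + half_window)
  qf <- stats::lm(y ~ x + I(x^2),
                  data = data.frame(x = wavelength[idx], y = intensity[idx]))
  a <- stats::coef(qf)
  if (!is.finite(a[3]) || a[3] >= 0) return(wavelength[i0])
  peak <- -a[2] / (2 * a[3])
  ## keep the refinement local: fall back to the grid argmax if the
  ## parabola vertex escapes the window
  if (peak < wavelength[idx[1]] || peak > wavelength[idx[length(idx)]])
    peak <- wavelength[i0]
  unname(peak)
}

#' Temperature series of emission-peak shifts
#'
#' Peak positions of a set of emission spectra, reported as shifts
#' relative to the spectrum at the highest temperature. Negative shifts
#' are blue shifts (cooling-induced burial changes of tryptophan
#' environments shift emission to shorter wavelengths).
#'
#' @param spectra List of spectra; each element is a data.frame with
#'   columns `wavelength` and `intensity` and a `temperature_C` attribute
#'   (or supply `temperatures`).
#' @param temperatures Optional numeric vector of temperatures (degC)
#'   overriding the attributes.
#' @return data.frame with `temperature_C`, `peak_nm`, `shift_nm`, sorted
#'   by temperature.
#' @export
peak_shift_series <- function(spectra, temperatures = NULL) {
  if (is.null(temperatures))
    temperatures <- vapply(spectra, function(s) {
      tt <- attr(s, "temperature_C")
      if (is.null(tt)) NA_real_ else as.numeric(tt)
    }, numeric(1))
  if (anyNA(temperatures))
    stop("every spectrum needs a temperature (attribute or `temperatures`)")
  if (length(spectra) < 2L) stop("need spectra at >= 2 temperatures")
  if (anyDuplicated(temperatures))
    stop("duplicate temperatures; average replicates before calling")
  peaks <- vapply(spectra, function(s) emission_peak(s$wavelength, s$intensity),
                  numeric(1))
  o <- order(temperatures)
  ref <- peaks[o][length(o)]       # highest temperature is the reference
  data.frame(temperature_C = temperatures[o],
             peak_nm = peaks[o],
             shift_nm = peaks[o] - ref)
}
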