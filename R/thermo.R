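#' @title Gas constant in kcal/(mol K)
#' @description Exported so downstream scripts use the same constant as the
#'   fits: 1.98720425e-3 kcal/(mol K).
#' @export
R_KCAL <- 1.98720425e-3

celsius_to_kelvin <- function(t_c) t_c + 273.15

#' Open probability from a temperature-ramped current trace
#'
#' Currents recorded at +80 mV are normalised to the current under
#' saturating (1 mM) menthol, taken to correspond to maximal channel
#' opening, so `Po = I / I_menthol_max`. Values are clipped into
#' `(eps, 1 - eps)` so that downstream `ln Keq` stays finite; the number
#' of clipped points is recorded in the `"n_clipped"` attribute.
#'
#' @param current Current series (pA).
#' @param menthol_max_current Saturating-menthol current (pA, > 0).
#' @param eps Clipping margin (default 1e-4).
#' @param negative_tolerance Currents more negative than
#'   `-negative_tolerance * menthol_max_current` raise an error; small
#'   negative excursions (baseline noise) are clipped up.
#' @return Numeric Po series with attribute `n_clipped`.
#' @export
normalize_to_po <- function(current, menthol_max_current, eps = 1e-4,
                            negative_tolerance = 0.05) {
  if (!is.numeric(menthol_max_current) || menthol_max_current <= 0)
    stop("menthol_max_current must be > 0")
  if (any(current < -negative_tolerance * menthol_max_current, na.rm = TRUE))
    stop("currents are negative beyond tolerance; check polarity/leak")
  po <- current / menthol_max_current
  clipped <- po <= eps | po >= 1 - eps
  po <- pmin(pmax(po, eps), 1 - eps)
  attr(po, "clipped") <- clipped
  attr(po, "n_clipped") <- sum(clipped, na.rm = TRUE)
  po
}

#' Two-state open/closed equilibrium constant from open probability
#'
#' `Keq = Po / (1 - Po)` for the closed <-> open equilibrium.
#'
#' @param po Open probability in (0, 1). Vectorised.
#' @return Equilibrium constant series.
#' @export
keq_from_po <- function(po) {
  po <- as.numeric(po)
  if (any(po <= 0 | po >= 1, na.rm = TRUE)) stop("po must lie strictly in (0, 1)")
  po / (1 - po)
}

#' @rdname keq_from_po
#' @param keq Equilibrium constant (> 0).
#' @export
po_from_keq <- function(keq) {
  if (any(keq <= 0, na.rm = TRUE)) stop("keq must be > 0")
  keq / (1 + keq)
}

#' Van't Hoff fit of gating enthalpy and entropy
#'
#' Ordinary least squares of `ln Keq` on `1/T`:
#' `ln Keq = -dH/(R T) + dS/R`, so `dH = -slope * R` and
#' `dS = intercept * R` with R = 1.98720425e-3 kcal/(mol K).
#' Cold-activated channels give negative dH and dS; no sign convention is
#' imposed by the fit.
#'
#' @param temperatures_K Temperatures in Kelvin (>= 2 distinct values).
#' @param keq Equilibrium constants (> 0), same length.
#' @param window Optional Celsius interval `c(lo, hi)` restricting the fit
#'   to the linear van't Hoff region of a ramp; default uses all points.
#' @return Object of class `"vant_hoff_fit"`: list with `dH` (kcal/mol),
#'   `dS` (kcal/(mol K)), `r_squared`, `n_points`, `temperature_window`,
#'   and the underlying `lm` fit.
#' @export
vant_hoff_fit <- function(temperatures_K, keq, window = NULL) {
  stopifnot(length(temperatures_K) == length(keq))
  if (any(keq <= 0)) stop("keq must be > 0")
  if (any(temperatures_K <= 0)) stop("temperatures must be in Kelvin and > 0")
  keep <- rep(TRUE, length(keq))
  if (!is.null(window)) {
    t_c <- temperatures_K - 273.15
    keep <- t_c >= min(window) & t_c <= max(window)
  }
  tk <- temperatures_K[keep]
  kq <- keq[keep]
  if (length(unique(tk)) < 2L)
    stop("van't Hoff fit needs at least 2 distinct temperatures")
  fit <- stats::lm(log(kq) ~ I(1 / tk))
  co <- stats::coef(fit)
  tss <- sum((log(kq) - mean(log(kq)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(dH = unname(-co[2] * R_KCAL),
                 dS = unname(co[1] * R_KCAL),
                 r_squared = r2,
                 n_points = length(kq),
                 temperature_window = if (is.null(window)) range(tk - 273.15)
                                      else as.numeric(window),
                 lm = fit),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("Van't Hoff fit (", x$n_points, " points, ",
      sprintf("%.1f to %.1f degC", x$temperature_window[1],
              x$temperature_window[2]), ")\n", sep = "")
  cat(sprintf("  dH = %.2f kcal/mol\n  dS = %.4f kcal/(mol K)\n  R^2 = %.6f\n",
              x$dH, x$dS, x$r_squared))
  invisible(x)
}

#' Fit gating thermodynamics directly from a current ramp
#'
#' Convenience wrapper: menthol normalisation, Keq conversion and the
#' van't Hoff fit in one call. Points clipped by the Po normalisation
#' (channel essentially fully open or fully closed, where `ln Keq`
#' carries no information) are excluded from the fit by default; the
#' number excluded is reported in the result.
#'
#' @param trace A current trace as returned by [simulate_current_ramp()]:
#'   data.frame with `temperature_C`, `current`, plus attribute
#'   `menthol_max_current` (or pass it explicitly).
#' @param menthol_max_current Saturating menthol current; defaults to the
#'   trace attribute.
#' @param drop_clipped Exclude saturated/silent points (default `TRUE`).
#' @inheritParams vant_hoff_fit
#' @return A `"vant_hoff_fit"` object with an extra `n_clipped` field.
#' @export
fit_gating_thermo <- function(trace, menthol_max_current =
                                attr(trace, "menthol_max_current"),
                              window = NULL, drop_clipped = TRUE) {
  po <- normalize_to_po(trace$current, menthol_max_current)
  keep <- if (drop_clipped) !attr(po, "clipped") else rep(TRUE, length(po))
  if (sum(keep) < 2L)
    stop("fewer than 2 usable (unclipped) points; the ramp never leaves ",
         "saturation - check menthol_max_current or the temperature range")
  fit <- vant_hoff_fit(celsius_to_kelvin(trace$temperature_C[keep]),
                       keq_from_po(as.numeric(po)[keep]), window = window)
  fit$n_clipped <- attr(po, "n_clipped")
  fit
}

#' Heat-capacity-dependent Gibbs energy of gating
#'
#' Evaluates
#' `dG(T) = dH0 + dCp (T - T0) - dS0 T - T dCp ln(T / T0)`
#' pointwise. With a positive gating dCp the curve is a downward-opening
#' (inverted-U) stability curve whose two zero crossings delimit heat- and
#' cold-activated regimes; a negative dCp gives the upward-opening mirror
#' image.
#'
#' @param temperatures_K Temperatures (Kelvin, > 0).
#' @param dH0 Reference enthalpy change (kcal/mol) at `t0`.
#' @param dS0 Reference entropy change (kcal/(mol K)) at `t0`.
#' @param dCp Heat-capacity change (kcal/(mol K)).
#' @param t0 Reference temperature (Kelvin, default 298.15).
#' @return dG series in kcal/mol.
#' @examples
#' gibbs_curve(298.15, dH0 = -3, dS0 = -0.01, dCp = 3)  # -0.0185
#' @export
gibbs_curve <- function(temperatures_K, dH0, dS0, dCp, t0 = 298.15) {
  if (any(temperatures_K <= 0) || t0 <= 0)
    stop("temperatures must be positive (Kelvin)")
  dH0 + dCp * (temperatures_K - t0) - dS0 * temperatures_K -
    temperatures_K * dCp * log(temperatures_K / t0)
}
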