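#' Hydrogen-bond energy assumptions for hydration-shell accounting
#'
#' The bounds bracket published estimates of water hydrogen-bond strength
#' (1.5 to 9.5 kcal/mol), with one hydrogen bond formed or broken per
#' water molecule entering or leaving a residue's hydration shell.
#'
#' @param e_min Lower bond energy bound, kcal/mol (default 1.5).
#' @param e_max Upper bound, kcal/mol (default 9.5); must be `>= e_min`.
#' @param bonds_per_water Hydrogen bonds per water (default 1).
#' @return Object of class `"hbond_assumptions"`.
#' @export
hbond_assumptions <- function(e_min = 1.5, e_max = 9.5, bonds_per_water = 1) {
  if (!(e_min > 0 && e_min <= e_max)) stop("need 0 < e_min <= e_max")
  if (bonds_per_water <= 0) stop("bonds_per_water must be > 0")
  structure(list(e_min = e_min, e_max = e_max,
                 bonds_per_water = bonds_per_water),
            class = "hbond_assumptions")
}

#' Energy range implied by a change in hydration-shell water count
#'
#' Converts a change of `delta_waters` contacting water molecules at a
#' residue into an enthalpy-scale range:
#' `low = delta * bonds * e_min`, `high = delta * bonds * e_max`.
#' Fractional counts (MD ensemble averages) are accepted.
#'
#' @param delta_waters Magnitude of the water-count change (>= 0).
#' @param assumptions An [hbond_assumptions()] object.
#' @return Object of class `"energy_range"`: `low`, `high` in kcal/mol.
#' @examples
#' energy_range(10)               # 15 to 95 kcal/mol
#' energy_range(8)                # 12 to 76 kcal/mol
#' @export
energy_range <- function(delta_waters, assumptions = hbond_assumptions()) {
  if (delta_waters < 0) stop("delta_waters must be >= 0")
  structure(list(low = delta_waters * assumptions$bonds_per_water * assumptions$e_min,
                 high = delta_waters * assumptions$bonds_per_water * assumptions$e_max),
            class = "energy_range")
}

#' Scale a per-subunit energy range to the whole channel
#'
#' The channel is a homotetramer, so a residue's buried/exposed change
#' occurs in four copies; both bounds scale linearly.
#'
#' @param per_subunit An [energy_range()] for one subunit.
#' @param n_subunits Number of subunits (default 4).
#' @return An `"energy_range"` for the assembled channel.
#' @examples
#' tetramer_energy_range(energy_range(8))   # 48 to 304 kcal/mol
#' @export
tetramer_energy_range <- function(per_subunit, n_subunits = 4) {
  stopifnot(inherits(per_subunit, "energy_range"))
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  structure(list(low = per_subunit$low * n_subunits,
                 high = per_subunit$high * n_subunits),
            class = "energy_range")
}

#' Can a hydration energy range account for the gating enthalpy?
#'
#' `TRUE` when the upper bound of the range reaches the target enthalpy
#' magnitude (`high >= |dH|`; the gating dH of cold activation is
#' negative, so the comparison is on magnitudes, and equality counts as
#' sufficient).
#'
#' @param range An [energy_range()].
#' @param dH_target Gating enthalpy magnitude in kcal/mol (> 0).
#' @return Logical.
#' @examples
#' sufficiency_check(tetramer_energy_range(energy_range(8)), 112)  # TRUE
#' @export
sufficiency_check <- function(range, dH_target) {
  stopifnot(inherits(range, "energy_range"))
  if (dH_target <= 0) stop("dH_target is a magnitude and must be > 0")
  range$high >= dH_target
}

#' @export
print.energy_range <- function(x, ...) {
  cat(sprintf("Energy range: %.1f to %.1f kcal/mol\n", x$low, x$high))
  invisible(x)
}
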