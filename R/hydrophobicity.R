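## Built-in side-chain hydrophobicity (SCH) scales, as transfer free
## energies in kcal/mol. Orientation: hydrophobic side chains carry the
## lower (more negative) values, polar/charged the higher ones.
##
## hessa: translocon-mediated membrane insertion dG_app, central-position
## values (Hessa et al. 2005, biological scale).
## moon_fleming: side-chain water-to-bilayer transfer free energies from
## OmpLA folding (Moon & Fleming 2011). Published variants of both scales
## differ slightly; custom scales may be supplied wherever a scale is
## accepted.
.sch_scales <- list(
  hessa = c(A = 0.11, C = -0.13, D = 3.49, E = 2.68, F = -0.32,
            G = 0.74, H = 2.06, I = -0.60, K = 2.71, L = -0.55,
            M = -0.10, N = 2.05, P = 2.23, Q = 2.36, R = 2.58,
            S = 0.84, T = 0.52, V = -0.31, W = 0.30, Y = 0.68),
  moon_fleming = c(A = 0.00, C = -0.83, D = 3.64, E = 3.63, F = -2.20,
                   G = 1.15, H = 2.33, I = -1.56, K = 5.39, L = -1.81,
                   M = -0.76, N = 3.47, P = 3.03, Q = 2.87, R = 3.71,
                   S = 1.83, T = 1.78, V = -0.78, W = -2.09, Y = -0.71)
)

#' Side-chain hydrophobicity scales
#'
#' Returns a named numeric vector mapping the 20 canonical amino acids
#' (one-letter codes) to side-chain transfer free energies in kcal/mol,
#' oriented so hydrophobic residues have lower values than polar or
#' charged ones. Two built-in scales are provided: the translocon
#' insertion scale (`"hessa"`) and the OmpLA water-to-bilayer scale
#' (`"moon_fleming"`). A custom scale may be passed as a named vector
#' covering all 20 residues.
#'
#' @param name `"hessa"`, `"moon_fleming"`, or a named numeric vector.
#' @return Named numeric vector of length 20 with attribute `"scale_name"`.
#' @export
hydrophobicity_scale <- function(name = c("hessa", "moon_fleming")) {
  if (is.numeric(name)) {
    aa <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
    if (!all(aa %in% names(name)))
      stop("custom scale must name all 20 canonical residues")
    sc <- name[aa]
    attr(sc, "scale_name") <- "custom"
    return(sc)
  }
  name <- match.arg(name)
  sc <- .sch_scales[[name]]
  attr(sc, "scale_name") <- name
  sc
}

#' Slope factor of gating enthalpy against side-chain hydrophobicity
#'
#' For a set of functional mutants at one site, the slope of the
#' ordinary-least-squares fit of gating `dH` (kcal/mol, from the van't
#' Hoff analysis) against the SCH value of the residue occupying the
#' site. Under the hydrophobic-scale orientation used here, a positive
#' slope at a cold-exposed site (more hydrophobic residue, more negative
#' dH) supports the water-protein-interaction picture of cold sensing;
#' a negative slope plays the same role at sites that become buried.
#'
#' @param residues One-letter amino-acid codes of the mutants (wild type
#'   included), length >= 2.
#' @param dH Gating enthalpies (kcal/mol), same length.
#' @param scale A scale from [hydrophobicity_scale()].
#' @param site Optional site label carried through to the result.
#' @return Object of class `"site_slope"`: `site`, `slope_factor`,
#'   `r_squared`, `n_mutants`, `scale_name`.
#' @export
slope_factor <- function(residues, dH, scale = hydrophobicity_scale("hessa"),
                         site = NA) {
  stopifnot(length(residues) == length(dH))
  if (length(residues) < 2L) stop("need >= 2 mutants at the site")
  if (!all(residues %in% names(scale)))
    stop("non-canonical residue code: ",
         paste(setdiff(residues, names(scale)), collapse = ", "))
  sch <- as.numeric(scale[residues])
  if (length(unique(sch)) < 2L)
    stop("degenerate slope: all mutants share one hydrophobicity value")
  fit <- stats::lm(dH ~ sch)
  tss <- sum((dH - mean(dH))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(site = site,
                 slope_factor = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n_mutants = length(dH),
                 scale_name = attr(scale, "scale_name")),
            class = "site_slope")
}

#' @export
print.site_slope <- function(x, ...) {
  cat(sprintf("Site %s: slope factor %.2f (R^2 %.3f, n = %d, scale %s)\n",
              as.character(x$site), x$slope_factor, x$r_squared,
              x$n_mutants, x$scale_name))
  invisible(x)
}

#' Quadrant consistency of a site with the water-protein hypothesis
#'
#' A site supports the hypothesis when its footprinting fold change and
#' its hydrophobicity slope point the same way: more exposed in the cold
#' (`fc > 1`) with a positive slope, or more buried (`fc < 1`) with a
#' negative slope (the first and third quadrants of the FC-vs-slope
#' plane). Boundary cases (`fc == 1` or `slope == 0`) are
#' "indeterminate" and are excluded from aggregate proportions.
#'
#' @param fc Positive fold change(s) from [residue_fc_table()].
#' @param slope Slope factor(s) from [slope_factor()].
#' @return Character vector in
#'   `{consistent, inconsistent, indeterminate}`.
#' @export
classify_consistency <- function(fc, slope) {
  stopifnot(length(fc) == length(slope))
  if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be positive")
  ifelse(fc == 1 | slope == 0, "indeterminate",
         ifelse((fc > 1) == (slope > 0), "consistent", "inconsistent"))
}

#' Proportion of sites consistent with the hypothesis above a slope cutoff
#'
#' Among sites whose slope-factor magnitude exceeds `slope_threshold`
#' (strictly), the fraction classified consistent. Indeterminate sites
#' are excluded from both numerator and denominator and counted
#' separately. With `signed = TRUE` the filter is `slope > threshold`
#' instead of `|slope| > threshold`.
#'
#' @param fc Fold changes per site.
#' @param slope Slope factors per site, same length.
#' @param slope_threshold Magnitude cutoff (default 0).
#' @param signed Use signed filtering (default `FALSE`, magnitude).
#' @return List: `proportion` (NA if no site passes the filter),
#'   `n_consistent`, `n_considered`, `n_indeterminate`, `slope_threshold`.
#' @export
consistency_proportion <- function(fc, slope, slope_threshold = 0,
                                   signed = FALSE) {
  stopifnot(length(fc) == length(slope))
  pass <- if (signed) slope > slope_threshold else abs(slope) > slope_threshold
  cls <- classify_consistency(fc[pass], slope[pass])
  det <- cls != "indeterminate"
  n_cons <- sum(cls[det] == "consistent")
  n_det <- sum(det)
  if (n_det == 0L)
    warning("no determinate site passes the slope threshold ", slope_threshold)
  list(proportion = if (n_det > 0L) n_cons / n_det else NA_real_,
       n_consistent = n_cons,
       n_considered = n_det,
       n_indeterminate = sum(!det),
       slope_threshold = slope_threshold)
}

#' Consistency table across several slope thresholds
#'
#' @param sites data.frame with columns `site`, `fc`, `slope_factor`
#'   (e.g. assembled from [slope_factor()] results merged with the
#'   residue FC report).
#' @param thresholds Numeric vector of slope-magnitude cutoffs.
#' @inheritParams consistency_proportion
#' @return data.frame with one row per threshold: `slope_threshold`,
#'   `proportion`, `n_consistent`, `n_considered`, `n_indeterminate`.
#' @export
consistency_table <- function(sites, thresholds = c(0, 5, 10),
                              signed = FALSE) {
  stopifnot(all(c("fc", "slope_factor") %in% names(sites)))
  rows <- lapply(thresholds, function(th) {
    p <- suppressWarnings(
      consistency_proportion(sites$fc, sites$slope_factor, th, signed))
    data.frame(slope_threshold = th, proportion = p$proportion,
               n_consistent = p$n_consistent, n_considered = p$n_considered,
               n_indeterminate = p$n_indeterminate)
  })
  do.call(rbind, rows)
}
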