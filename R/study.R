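#' Simulate a complete hypothesis-testing study
#'
#' Generates the paired inputs of the validation chain: a footprinting
#' dataset with planted exposure changes, and, for every planted site, a
#' series of side-chain mutants whose gating enthalpies follow a planted
#' linear dependence on side-chain hydrophobicity, realised as two-state
#' current ramps. By default the study is built fully under the
#' water-protein-interaction picture: exposed sites receive positive
#' planted slopes and buried sites negative ones, so the downstream
#' consistency proportion is 1 at every slope threshold. Sites listed in
#' `inconsistent_sites` get the opposite slope sign, for studies with
#' known mixed ground truth.
#'
#' @param footprint_config A [footprint_sim_config()].
#' @param slope_magnitude Magnitude of the planted dH-vs-SCH slope
#'   (kcal/mol per kcal/mol, default 15).
#' @param inconsistent_sites Planted sites whose slope sign is flipped
#'   against the hypothesis (default none).
#' @param mutant_residues Residues tried at every site (wild type is
#'   added from the simulated protein sequence); default
#'   `c("L", "A", "S", "H")` spans the hydrophobicity scales.
#' @param dH_wt Wild-type gating enthalpy, kcal/mol (default -80).
#' @param t_half_C Ramp midpoint temperature for every mutant, degC
#'   (default 18; sets `dS = dH / T_half`).
#' @param ramp_noise_sd Current noise passed to the ramp generator (pA).
#' @param scale Hydrophobicity scale used to plant the dH values.
#' @param seed Integer seed (fanned out to the per-site ramp seeds).
#' @return List of class `"cold_scan_study"`: `footprint` (a
#'   `"footprint_sim"`), `mutants` (data.frame `site, residue, dH_true,
#'   dS_true`), `ramps` (list of current traces keyed `"site_residue"`),
#'   `truth` (per-site planted slope and consistency label).
#' @export
simulate_study <- function(footprint_config = footprint_sim_config(),
                           slope_magnitude = 15,
                           inconsistent_sites = integer(0),
                           mutant_residues = c("L", "A", "S", "H"),
                           dH_wt = -80, t_half_C = 18,
                           ramp_noise_sd = 0,
                           scale = hydrophobicity_scale("hessa"),
                           seed = footprint_config$seed) {
  fp <- simulate_footprint(footprint_config)
  sites <- c(footprint_config$sites_exposed, footprint_config$sites_buried)
  exposed <- sites %in% footprint_config$sites_exposed
  slope_true <- ifelse(exposed, slope_magnitude, -slope_magnitude)
  flip <- sites %in% inconsistent_sites
  slope_true[flip] <- -slope_true[flip]
  t_half_K <- celsius_to_kelvin(t_half_C)
  mutants <- list(); ramps <- list()
  for (k in seq_along(sites)) {
    site <- sites[k]
    wt <- substr(fp$protein, site, site)
    res_set <- unique(c(wt, mutant_residues))
    sch <- as.numeric(scale[res_set])
    dH_true <- dH_wt + slope_true[k] * (sch - as.numeric(scale[wt]))
    dS_true <- dH_true / t_half_K
    for (j in seq_along(res_set)) {
      cfg <- gating_sim_config(dH = dH_true[j], dS = dS_true[j],
                               noise_sd = ramp_noise_sd,
                               seed = seed + 1000L + 37L * k + j)
      ramps[[paste0(site, "_", res_set[j])]] <- simulate_current_ramp(cfg)
    }
    mutants[[k]] <- data.frame(site = site, residue = res_set,
                               dH_true = dH_true, dS_true = dS_true)
  }
  truth <- data.frame(site = sites,
                      fc_true = fp$truth$fc_true[sites],
                      slope_true = slope_true,
                      consistent_true =
                        classify_consistency(fp$truth$fc_true[sites],
                                             slope_true))
  structure(list(footprint = fp, mutants = do.call(rbind, mutants),
                 ramps = ramps, truth = truth, scale = scale),
            class = "cold_scan_study")
}

#' Fit gating thermodynamics for every mutant ramp of a study
#'
#' @param study A `"cold_scan_study"` from [simulate_study()].
#' @return data.frame `site, residue, dH, dS, r_squared`.
#' @export
fit_study_thermo <- function(study) {
  stopifnot(inherits(study, "cold_scan_study"))
  rows <- lapply(seq_len(nrow(study$mutants)), function(i) {
    key <- paste0(study$mutants$site[i], "_", study$mutants$residue[i])
    fit <- fit_gating_thermo(study$ramps[[key]])
    data.frame(site = study$mutants$site[i],
               residue = study$mutants$residue[i],
               dH = fit$dH, dS = fit$dS, r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}

#' Slope factors and hypothesis consistency for a fitted study
#'
#' Combines per-site slope factors (fitted gating dH against SCH across
#' mutants) with the residue fold changes recovered from the
#' footprinting table, classifies each site by quadrant, and aggregates
#' consistency proportions across slope thresholds.
#'
#' @param study A `"cold_scan_study"`.
#' @param thermo Fitted mutant table from [fit_study_thermo()] (computed
#'   if missing).
#' @param fc_report Residue FC report from [residue_fc_table()] on the
#'   study's footprint table (computed if missing).
#' @param thresholds Slope-magnitude cutoffs (default `c(0, 5, 10)`).
#' @return List: `sites` (data.frame `site, fc, slope_factor, r_squared,
#'   n_mutants, consistency`), `proportions` (from
#'   [consistency_table()]).
#' @export
analyze_study <- function(study, thermo = NULL, fc_report = NULL,
                          thresholds = c(0, 5, 10)) {
  stopifnot(inherits(study, "cold_scan_study"))
  if (is.null(thermo)) thermo <- fit_study_thermo(study)
  if (is.null(fc_report)) fc_report <- residue_fc_table(study$footprint$table)
  sites <- unique(thermo$site)
  rows <- lapply(sites, function(s) {
    sub <- thermo[thermo$site == s, ]
    sl <- slope_factor(sub$residue, sub$dH, scale = study$scale, site = s)
    fc <- fc_report$fc_mean[fc_report$residue == s]
    if (length(fc) != 1L) fc <- NA_real_
    data.frame(site = s, fc = fc, slope_factor = sl$slope_factor,
               r_squared = sl$r_squared, n_mutants = sl$n_mutants)
  })
  sites_df <- do.call(rbind, rows)
  sites_df$consistency <- classify_consistency(sites_df$fc,
                                               sites_df$slope_factor)
  list(sites = sites_df,
       proportions = consistency_table(sites_df, thresholds))
}
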