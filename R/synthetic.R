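## Synthetic-data generators. Every downstream stage is exercised on
## seeded data with known ground truth; each generator has a zero-noise
## mode in which its matched estimator recovers the generating
## parameters to numerical precision.

#' Configuration for a synthetic footprinting dataset
#'
#' Emulates the design of the footprinting experiment: three treatment
#' conditions (C untreated, F Fe-EDTA, O Fenton-oxidized) at 4 and 30
#' degC with >= 3 biological replicates, one singly-oxidized peptide per
#' probed residue plus its unmodified partner, and multiplicative
#' lognormal intensity noise (MS intensities are positive and roughly
#' lognormal). Selected sites carry a planted 4-vs-30 degC fold change.
#'
#' @param n_residues Protein length (default 60).
#' @param sites_exposed Residue indices planted with `fc_exposed` (> 1).
#' @param sites_buried Residue indices planted with `fc_buried` (< 1);
#'   must be disjoint from `sites_exposed`.
#' @param fc_exposed,fc_buried Planted fold changes (default 1.25 / 0.80);
#'   scalars or vectors recycled along the corresponding site list.
#' @param true_oxi_fraction_base Oxidation fraction of the O condition at
#'   30 degC (default 0.10); control conditions oxidize at fixed small
#'   multiples of this base, identically at both temperatures.
#' @param n_replicates Biological replicates (default 3, minimum 3).
#' @param noise_cv Coefficient of variation of the lognormal intensity
#'   noise (default 0.10; 0 gives exact intensities).
#' @param n_double_oxidized Number of extra doubly-oxidized decoy
#'   peptides (default 0); these must be removed by the single-oxidation
#'   filter.
#' @param seed Integer seed.
#' @return Object of class `"footprint_sim_config"`.
#' @export
footprint_sim_config <- function(n_residues = 60,
                                 sites_exposed = c(10, 25),
                                 sites_buried = c(40),
                                 fc_exposed = 1.25,
                                 fc_buried = 0.80,
                                 true_oxi_fraction_base = 0.10,
                                 n_replicates = 3,
                                 noise_cv = 0.10,
                                 n_double_oxidized = 0,
                                 seed = 1L) {
  if (length(intersect(sites_exposed, sites_buried)))
    stop("exposed and buried site lists must be disjoint")
  if (any(c(fc_exposed, fc_buried) <= 0)) stop("planted FC must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_replicates < 3) stop("need >= 3 replicates")
  if (!(true_oxi_fraction_base > 0 && true_oxi_fraction_base < 1))
    stop("true_oxi_fraction_base must be in (0, 1)")
  if (true_oxi_fraction_base * max(fc_exposed, fc_buried, 1) >= 1)
    stop("base oxidation fraction times planted FC must stay below 1")
  if (any(c(sites_exposed, sites_buried) > n_residues))
    stop("planted sites must lie within the protein")
  structure(as.list(environment()), class = "footprint_sim_config")
}

lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Simulate a peptide intensity table with planted exposure changes
#'
#' Each probed residue is observed on its own tryptic-like peptide
#' (9 residues, clipped at the termini) as a singly-oxidized record plus
#' the peptide's unmodified partner,
#' under every condition x temperature x replicate. The oxidation
#' fraction of the O condition at 4 degC is the 30 degC base times the
#' planted fold change; control fractions are temperature-invariant, so
#' the planted value propagates exactly through relative oxidation and
#' fold change when `noise_cv = 0`.
#'
#' @param config A [footprint_sim_config()].
#' @return List of class `"footprint_sim"`: `table` (the peptide
#'   intensity table) and `truth` (sidecar data.frame `residue`,
#'   `fc_true`, `call_true`; never joined into the table itself).
#' @export
simulate_footprint <- function(config = footprint_sim_config()) {
  stopifnot(inherits(config, "footprint_sim_config"))
  set.seed(config$seed)
  n <- config$n_residues
  protein <- paste(sample(c("A","D","E","F","G","H","I","K","L","M",
                            "N","P","Q","R","S","T","V","W","Y"),
                          n, replace = TRUE), collapse = "")
  sites <- seq_len(n)
  fc_true <- rep(1, n)
  fc_true[config$sites_exposed] <- rep_len(config$fc_exposed,
                                           length(config$sites_exposed))
  fc_true[config$sites_buried] <- rep_len(config$fc_buried,
                                          length(config$sites_buried))
  base <- config$true_oxi_fraction_base
  ctrl_frac <- c(C = 0.05 * base, F = 0.08 * base)
  total_intensity <- 1e6
  rows <- list()
  for (site in sites) {
    p_start <- max(1L, site - 4L)
    p_end <- min(n, site + 4L)
    pep <- substr(protein, p_start, p_end)
    for (cond in c("C", "F", "O")) for (temp in c(4, 30))
      for (rep_i in seq_len(config$n_replicates)) {
        frac <- if (cond == "O") {
          if (temp == 4) base * fc_true[site] else base
        } else ctrl_frac[[cond]]
        noise <- lognorm_noise(2, config$noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_sequence = pep,
          protein_position = p_start,
          oxidized_residue = c(site, NA_integer_),
          n_oxidations_on_peptide = c(1L, 0L),
          condition = cond,
          temperature_C = temp,
          replicate = rep_i,
          intensity = total_intensity * c(frac, 1 - frac) * noise)
      }
  }
  if (config$n_double_oxidized > 0) {
    decoy_sites <- sample(sites, config$n_double_oxidized, replace = TRUE)
    for (site in decoy_sites) {
      p_start <- max(1L, site - 4L)
      pep <- substr(protein, p_start, min(n, site + 4L))
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_sequence = pep, protein_position = p_start,
        oxidized_residue = site, n_oxidations_on_peptide = 2L,
        condition = "O", temperature_C = 4, replicate = 1L,
        intensity = total_intensity * 0.01)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  truth <- data.frame(residue = sites, fc_true = fc_true,
                      call_true = call_exposure_change(fc_true))
  structure(list(table = table, truth = truth, protein = protein),
            class = "footprint_sim")
}

#' Configuration for a synthetic cold-activation current ramp
#'
#' Two-state gating currents: `Keq(T) = exp(-dH/(R T) + dS/R)`,
#' `I(T) = i_max * Keq/(1 + Keq) + noise`, temperatures in Kelvin
#' internally. Cold-activating parameters have negative `dH` and `dS`.
#'
#' @param dH Gating enthalpy, kcal/mol (default -100, cold-activating).
#' @param dS Gating entropy, kcal/(mol K) (default chosen so the
#'   midpoint sits near 18 degC).
#' @param temp_grid Ramp temperatures in degC, strictly monotone
#'   (default 30 down to 5 in 1-degree steps).
#' @param i_max Saturating-menthol current, pA (> 0, default 1000).
#' @param noise_sd Gaussian current noise s.d., pA (default 0).
#' @param seed Integer seed.
#' @return Object of class `"gating_sim_config"`.
#' @export
gating_sim_config <- function(dH = -100, dS = dH / (273.15 + 18),
                              temp_grid = seq(30, 5, by = -1),
                              i_max = 1000, noise_sd = 0, seed = 1L) {
  d <- diff(temp_grid)
  if (length(temp_grid) == 0) stop("temp_grid must be non-empty")
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("temp_grid must be strictly monotone")
  if (i_max <= 0) stop("i_max must be > 0")
  structure(as.list(environment())[c("dH", "dS", "temp_grid", "i_max",
                                     "noise_sd", "seed")],
            class = "gating_sim_config")
}

#' Simulate a temperature-ramped whole-cell current
#'
#' @param config A [gating_sim_config()].
#' @return data.frame `temperature_C`, `current` (pA) with attributes
#'   `menthol_max_current` and `truth` (the generating `dH`, `dS`).
#' @export
simulate_current_ramp <- function(config = gating_sim_config()) {
  stopifnot(inherits(config, "gating_sim_config"))
  set.seed(config$seed)
  tk <- celsius_to_kelvin(config$temp_grid)
  keq <- exp(-config$dH / (R_KCAL * tk) + config$dS / R_KCAL)
  current <- config$i_max * keq / (1 + keq)
  if (config$noise_sd > 0)
    current <- current + stats::rnorm(length(current), 0, config$noise_sd)
  out <- data.frame(temperature_C = config$temp_grid, current = current)
  attr(out, "menthol_max_current") <- config$i_max
  attr(out, "truth") <- list(dH = config$dH, dS = config$dS)
  out
}

#' Configuration for a synthetic two-state thermal melt
#'
#' @param dH_unfold Transition enthalpy, kcal/mol (default -44,
#'   cold-induced).
#' @param t_mid Midpoint temperature, degC (default 31.3); must lie
#'   inside `temp_grid`.
#' @param baselines Named list `bf0, bf1, bu0, bu1`: native and transited
#'   linear baselines (signal units, slope per degC).
#' @param temp_grid Temperatures in degC (default 10 to 50 by 2).
#' @param noise_sd Gaussian signal noise s.d. (default 0).
#' @param seed Integer seed.
#' @return Object of class `"melt_sim_config"`.
#' @export
melt_sim_config <- function(dH_unfold = -44, t_mid = 31.3,
                            baselines = list(bf0 = -6000, bf1 = 10,
                                             bu0 = -11000, bu1 = 5),
                            temp_grid = seq(10, 50, by = 2),
                            noise_sd = 0, seed = 1L) {
  if (t_mid < min(temp_grid) || t_mid > max(temp_grid))
    stop("t_mid must lie within the simulated temperature range")
  stopifnot(all(c("bf0", "bf1", "bu0", "bu1") %in% names(baselines)))
  structure(as.list(environment())[c("dH_unfold", "t_mid", "baselines",
                                     "temp_grid", "noise_sd", "seed")],
            class = "melt_sim_config")
}

#' Simulate a two-state melt curve with linear baselines
#'
#' @param config A [melt_sim_config()].
#' @return data.frame `temperature_C`, `signal` with attribute `truth`.
#' @export
simulate_cd_melt <- function(config = melt_sim_config()) {
  stopifnot(inherits(config, "melt_sim_config"))
  set.seed(config$seed)
  b <- config$baselines
  sig <- two_state_signal(config$temp_grid, config$dH_unfold, config$t_mid,
                          b$bf0, b$bf1, b$bu0, b$bu1)
  if (config$noise_sd > 0)
    sig <- sig + stats::rnorm(length(sig), 0, config$noise_sd)
  out <- data.frame(temperature_C = config$temp_grid, signal = sig)
  attr(out, "truth") <- list(dH_unfold = config$dH_unfold,
                             t_mid = config$t_mid)
  out
}

#' Simulate tryptophan emission spectra with a planted peak shift
#'
#' Gaussian emission bands whose centre moves linearly with temperature
#' (negative `shift_per_degC` models the cooling-induced blue shift).
#'
#' @param temperatures Spectrum temperatures, degC.
#' @param peak_warm Peak position at the warmest temperature, nm
#'   (default 340).
#' @param shift_per_degC Peak displacement per degC of cooling below the
#'   warmest temperature (default 0.15 nm, i.e. blue shift on cooling).
#' @param width Gaussian s.d. in nm (default 12).
#' @param wavelengths Wavelength grid (default 300 to 400 by 1 nm).
#' @param noise_sd Additive intensity noise s.d. (default 0).
#' @param seed Integer seed.
#' @return List of spectra (data.frames `wavelength`, `intensity` with a
#'   `temperature_C` attribute) with attribute `truth` (planted peaks).
#' @export
simulate_emission_spectra <- function(temperatures = seq(10, 30, by = 2),
                                      peak_warm = 340, shift_per_degC = 0.15,
                                      width = 12,
                                      wavelengths = seq(300, 400, by = 1),
                                      noise_sd = 0, seed = 1L) {
  set.seed(seed)
  t_ref <- max(temperatures)
  peaks <- peak_warm - shift_per_degC * (t_ref - temperatures)
  spectra <- lapply(seq_along(temperatures), function(i) {
    int <- exp(-(wavelengths - peaks[i])^2 / (2 * width^2))
    if (noise_sd > 0) int <- pmax(int + stats::rnorm(length(int), 0, noise_sd), 0)
    s <- data.frame(wavelength = wavelengths, intensity = int)
    attr(s, "temperature_C") <- temperatures[i]
    s
  })
  attr(spectra, "truth") <- data.frame(temperature_C = temperatures,
                                       peak_nm = peaks)
  spectra
}

#' Configuration for a synthetic coordinate ensemble
#'
#' Residues are placed on rings around the channel (z) axis, one ring
#' position per subunit, stacked along z; each residue fluctuates
#' isotropically (Gaussian, per-axis s.d. `sigma`) about its reference
#' position. Optional water oxygens are planted strictly inside the
#' contact cutoff of chosen residues (subunit 1) so that water-contact
#' counts are known exactly.
#'
#' @param n_residues Residues per subunit (default 20).
#' @param n_subunits Subunits (default 4).
#' @param n_snapshots Ensemble size M (default 100, >= 1).
#' @param sigma Per-axis fluctuation s.d., Angstrom; scalar or length
#'   `n_residues` (default 0.5; >= 0).
#' @param ring_radii Ring radius per residue, Angstrom; scalar or vector
#'   (default 20).
#' @param z_spacing Axial spacing between consecutive residues,
#'   Angstrom (default 6; keeps planted waters out of neighbouring
#'   residues' cutoff spheres).
#' @param water_counts Optional integer vector (length `n_residues`) of
#'   waters to plant within the cutoff of each residue.
#' @param water_cutoff Cutoff the planted waters must respect (default
#'   3.5 Angstrom; waters are placed between 0.5 and 0.68 * cutoff from
#'   the target Calpha).
#' @param seed Integer seed.
#' @return Object of class `"ensemble_sim_config"`.
#' @export
ensemble_sim_config <- function(n_residues = 20, n_subunits = 4,
                                n_snapshots = 100, sigma = 0.5,
                                ring_radii = 20, z_spacing = 6,
                                water_counts = NULL, water_cutoff = 3.5,
                                seed = 1L) {
  if (n_snapshots < 1) stop("need >= 1 snapshot")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  sigma <- rep_len(sigma, n_residues)
  ring_radii <- rep_len(ring_radii, n_residues)
  if (!is.null(water_counts)) {
    water_counts <- rep_len(as.integer(water_counts), n_residues)
    if (any(water_counts < 0)) stop("water counts must be >= 0")
  }
  structure(list(n_residues = n_residues, n_subunits = n_subunits,
                 n_snapshots = n_snapshots, sigma = sigma,
                 ring_radii = ring_radii, z_spacing = z_spacing,
                 water_counts = water_counts, water_cutoff = water_cutoff,
                 seed = seed),
            class = "ensemble_sim_config")
}

#' Simulate a Gaussian-fluctuation coordinate ensemble
#'
#' @param config An [ensemble_sim_config()].
#' @return A [coord_ensemble()] whose reference is the ideal (noise-free)
#'   ring geometry; planted truth (sigma, ring radii, water counts) in
#'   the `"truth"` attribute.
#' @export
simulate_ensemble <- function(config = ensemble_sim_config()) {
  stopifnot(inherits(config, "ensemble_sim_config"))
  set.seed(config$seed)
  nr <- config$n_residues; ns <- config$n_subunits
  n_atoms <- nr * ns
  residue <- rep(seq_len(nr), times = ns)
  subunit <- rep(seq_len(ns), each = nr)
  ang <- 2 * pi * (subunit - 1) / ns + 0.05 * residue
  ref <- cbind(config$ring_radii[residue] * cos(ang),
               config$ring_radii[residue] * sin(ang),
               config$z_spacing * residue)
  m <- config$n_snapshots
  coords <- array(NA_real_, c(m, n_atoms, 3))
  sig_atom <- config$sigma[residue]
  for (i in seq_len(m))
    coords[i, , ] <- ref + stats::rnorm(n_atoms * 3) * sig_atom
  waters <- NULL
  if (!is.null(config$water_counts) && any(config$water_counts > 0)) {
    ## waters are planted around the snapshot's own Calpha so the target
    ## residue's contact count is exact regardless of sigma
    waters <- vector("list", m)
    for (i in seq_len(m)) {
      wlist <- list()
      for (r in which(config$water_counts > 0)) {
        k <- config$water_counts[r]
        target <- coords[i, residue == r & subunit == 1, ]
        dir <- matrix(stats::rnorm(3 * k), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        rad <- stats::runif(k, 0.5, 0.68 * config$water_cutoff)
        wlist[[length(wlist) + 1L]] <-
          sweep(dir * rad, 2, target, "+")
      }
      waters[[i]] <- do.call(rbind, wlist)
    }
  }
  ens <- coord_ensemble(coords, residue, subunit, waters = waters,
                        reference = ref)
  attr(ens, "truth") <- list(sigma = config$sigma,
                             ring_radii = config$ring_radii,
                             water_counts = config$water_counts)
  ens
}
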