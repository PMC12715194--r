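#!/usr/bin/env Rscript
## Does side-chain hydrophobicity at buried/exposed-change sites tune
## cold sensitivity the way water-protein interactions predict?
## Builds a synthetic mutant study (one mutant series per planted site,
## gating dH linear in hydrophobicity), fits each ramp, computes per-site
## slope factors, and aggregates quadrant consistency across slope
## thresholds under both built-in hydrophobicity scales.

library(coldscan)
dir.create("results", showWarnings = FALSE)

fp <- footprint_sim_config(n_residues = 80,
                           sites_exposed = c(10, 24, 38, 52),
                           sites_buried = c(61, 70),
                           noise_cv = 0, seed = 401)
all_sites <- list()
all_props <- list()
for (scale_name in c("hessa", "moon_fleming")) {
  study <- simulate_study(fp, scale = hydrophobicity_scale(scale_name),
                          seed = 403)
  an <- analyze_study(study, thresholds = c(0, 5, 10))
  an$sites$scale <- scale_name
  an$proportions$scale <- scale_name
  all_sites[[scale_name]] <- an$sites
  all_props[[scale_name]] <- an$proportions
  cat(sprintf("%s scale: %s\n", scale_name,
              paste(sprintf("%.0f%% consistent at slope > %g",
                            100 * an$proportions$proportion,
                            an$proportions$slope_threshold),
                    collapse = "; ")))
}
sites <- do.call(rbind, all_sites)
props <- do.call(rbind, all_props)
write.table(sites, "results/site_slopes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(props, "results/consistency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Every planted site falls in the first/third quadrant (study built\n")
cat("fully under the hypothesis), so the proportions are 100% throughout.\n")
cat("Wrote results/site_slopes.tsv, results/consistency.tsv\n")
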