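#!/usr/bin/env Rscript
## Residue-exposure screen from hydroxyl-radical footprinting intensities.
## Simulates a DIA-quantified oxidation dataset (three conditions x two
## temperatures x three replicates) with 33 planted buried/exposed
## changes across a 120-residue stretch, then recovers residue-level
## fold changes and exposure calls with the 1.20/0.83 thresholds.
## The screen is run twice: noise-free (the chain is exact) and at 10%
## intensity noise, which shows how measurement noise propagates through
## the FC ratio and what the +/-20% threshold window does and does not
## absorb.

library(coldscan)
dir.create("results", showWarnings = FALSE)

base_cfg <- function(noise_cv, seed) footprint_sim_config(
  n_residues = 120,
  sites_exposed = c(37, seq(5, 100, by = 5)),
  sites_buried = c(3, 9, 21, 27, 33, 39, 51, 57, 63, 69, 81, 87),
  fc_exposed = c(1.25, rep(c(1.3, 1.45, 1.6, 1.35), 5)),
  fc_buried = rep(c(0.60, 0.70, 0.78), 4),
  noise_cv = noise_cv, seed = seed)

screen <- function(noise_cv, seed, label) {
  sim <- simulate_footprint(base_cfg(noise_cv, seed))
  rep <- residue_fc_table(sim$table)
  both <- merge(rep, sim$truth, by = "residue")
  planted <- both[both$call_true != "unchanged", ]
  unplanted <- both[both$call_true == "unchanged", ]
  cat(sprintf("[%s] called changed: %d of %d planted\n", label,
              sum(both$call != "unchanged"), nrow(planted)))
  cat(sprintf("[%s] planted sites recovered in the right direction: %d/%d\n",
              label, sum(planted$call == planted$call_true), nrow(planted)))
  cat(sprintf("[%s] false calls among unchanged residues: %d/%d\n",
              label, sum(unplanted$call != "unchanged"), nrow(unplanted)))
  cat(sprintf("[%s] site 37 (planted FC 1.25): FC = %.3f, call %s\n",
              label, rep$fc_mean[rep$residue == 37],
              rep$call[rep$residue == 37]))
  rep
}

cat("-- noise-free screen: the quantification chain is exact --\n")
exact <- screen(0, 101, "exact")

cat("-- 10% multiplicative intensity noise, 3 replicates --\n")
cat("   (noise on six intensity ratios compounds to ~25% FC noise per\n")
cat("   replicate, so a +/-20% FC window admits false calls; replicate\n")
cat("   means and s.e.m. columns in the report quantify this)\n")
noisy <- screen(0.10, 102, "noisy")

write.table(noisy, "results/footprint_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(exact, "results/footprint_screen_noiseless.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/footprint_screen.tsv (+ noiseless reference)\n")
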