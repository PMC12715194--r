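#!/usr/bin/env Rscript
## Structural-ensemble descriptors of cold-induced packing: per-residue
## RMSF and its fractional cold/warm change (20% significance band),
## radial Rg change (negative = contraction), and hydration-shell
## water-contact changes, on cold/warm Gaussian-fluctuation ensembles
## with a planted eight-water gain at residue 10.

library(coldscan)
dir.create("results", showWarnings = FALSE)

nres <- 20
wc_cold <- rep(0L, nres); wc_cold[10] <- 8L
cold <- simulate_ensemble(ensemble_sim_config(
  n_residues = nres, n_snapshots = 200, sigma = 0.4, ring_radii = 19,
  water_counts = wc_cold, seed = 501))
warm <- simulate_ensemble(ensemble_sim_config(
  n_residues = nres, n_snapshots = 200, sigma = 0.6, ring_radii = 20,
  seed = 502))
report <- suppressWarnings(ensemble_report(cold, warm, cutoff = 3.5))
write.table(report, "results/ensemble_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Residues with significant RMSF quieting in the cold: %d of %d\n",
            sum(report$significant), nres))
cat(sprintf("Mean radial Rg change (cold - warm): %.2f Angstrom (contraction)\n",
            mean(report$radial_rg_delta)))
cat(sprintf("Water-contact gain at residue 10: %+.1f waters\n",
            report$delta_waters[10]))

## ensembles round-trip through multi-model PDB
pdb <- tempfile(fileext = ".pdb")
write_ensemble_pdb(cold, pdb)
back <- read_ensemble_pdb(pdb)
cat(sprintf("PDB round trip: max coordinate deviation %.4f Angstrom\n",
            max(abs(back$coords - cold$coords))))
cat("Wrote results/ensemble_profiles.tsv\n")
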