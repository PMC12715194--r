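#!/usr/bin/env Rscript
## Are hydration-shell changes big enough to drive cold activation?
## Converts the water-contact changes measured in 05 into hydrogen-bond
## energy ranges and checks them against measured gating enthalpies.

library(coldscan)
dir.create("results", showWarnings = FALSE)

profiles <- read.delim("results/ensemble_profiles.tsv")
dmax <- max(abs(profiles$delta_waters), na.rm = TRUE)
per_subunit <- energy_range(dmax)
channel <- tetramer_energy_range(per_subunit)
cat(sprintf("Largest water-contact change: %.1f waters per subunit\n", dmax))
cat(sprintf("Per-subunit energy range: %.0f to %.0f kcal/mol\n",
            per_subunit$low, per_subunit$high))
cat(sprintf("Tetramer energy range: %.0f to %.0f kcal/mol\n",
            channel$low, channel$high))
for (target in c(57.8, 112))
  cat(sprintf("  covers |dH| = %.1f kcal/mol: %s\n", target,
              sufficiency_check(channel, target)))
## the canonical ten-water worked example
r10 <- energy_range(10)
cat(sprintf("Ten waters: %.0f to %.0f kcal/mol per subunit\n",
            r10$low, r10$high))
out <- data.frame(delta_waters = dmax,
                  per_subunit_low = per_subunit$low,
                  per_subunit_high = per_subunit$high,
                  channel_low = channel$low, channel_high = channel$high,
                  sufficient_57_8 = sufficiency_check(channel, 57.8),
                  sufficient_112 = sufficiency_check(channel, 112))
write.table(out, "results/hydration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/hydration.tsv\n")
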