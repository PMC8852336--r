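#!/usr/bin/env Rscript
# Stage 5: how many participants does the stability estimate itself need?
#
# Collapses the band-power array to a single global region, then repeats
# the stability analysis on random participant subsets of increasing size
# (25 draws per size here) and summarizes the across-draw dispersion
# (MAD) of the median time-by-ICC curves. A shrinking MAD with sample
# size indicates the group-level stability estimate has converged.

library(specstab)

bp <- read_band_power("results/band_power.csv")
sched <- permutation_schedule(dim(bp$values)[4], n_permutations = 100, seed = 41)

ss <- subsample_stability(bp, sizes = c(5, 10, 20, 40), n_subsamples = 25,
                          schedule = sched, seed = 43)
utils::write.csv(ss, "results/subsample_stability.csv", row.names = FALSE)

disp <- stats::aggregate(mad_icc ~ size, data = ss, FUN = mean)
message("mean across-draw MAD of the median ICC curve, by sample size:")
print(disp, row.names = FALSE)
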