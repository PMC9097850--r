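#!/usr/bin/env Rscript
# Generate the synthetic tMCAO study and write it to disk.
#
# The design mirrors the emulated experiment: SHAM/tMCAO x {12h, 24h, 3d,
# 7d} x {CX, HIP, DS}, n = 8 per condition x time group, six candidate
# reference genes. The preset destabilizes Actb (5-fold), B2m (~7-fold,
# plus an early rise in the core) and Gapdh (2-fold, core only) in the
# occluded animals, and doubles every gene's dispersion in the core region.

library(rgstab)

seed <- 1
dir.create("results", showWarnings = FALSE)

design <- tmcao_preset(seed = seed)
print(design)

m <- simulate_ct(design)
print(m)
write_ct_table(m, "results/synthetic_ct.csv")

message("wrote results/synthetic_ct.csv (",
        nrow(m$ct), " samples x ", ncol(m$ct), " genes)")
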