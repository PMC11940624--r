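#!/usr/bin/env Rscript
# Step 1: generate the synthetic ultrasound cohort the analysis runs on.
#
# The generator emulates the study cohort's structure: 50 lesions from
# carriers of pathogenic/likely-pathogenic variants and 38 from
# non-carriers, a class effect planted ONLY in speckle texture
# (correlation length 2.4 vs 1.2 px), Ki67-high rates 46/50 vs 26/38,
# and two acquisition machines assigned independently of class.
# Images and masks are written as PNG with a CSV manifest.

suppressPackageStartupMessages(library(usradiomics))

seed <- 1L
out_dir <- "results/cohort"

cfg <- cohort_config(seed = seed)
cohort <- simulate_cohort(cfg)
manifest <- write_cohort(cohort, out_dir)

cat(sprintf("wrote %d lesions to %s\n", nrow(manifest), out_dir))
cat(sprintf("  positive (P/LP) %d / negative %d\n",
            sum(manifest$label == 1), sum(manifest$label == 0)))
cat(sprintf("  Ki67-high: %d pos, %d neg\n",
            sum(manifest$ki67_high[manifest$label == 1]),
            sum(manifest$ki67_high[manifest$label == 0])))
print(table(machine = manifest$machine, label = manifest$label))
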