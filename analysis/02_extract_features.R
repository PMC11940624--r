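#!/usr/bin/env Rscript
# Step 2: read the cohort from disk and extract the Mazda-convention
# texture features for both ROI scopes (tumor; tumor + peritumoral ring
# minus the skin exclusion band), then screen for a machine batch
# effect. Run analysis/01_simulate_cohort.R first.

suppressPackageStartupMessages(library(usradiomics))

manifest <- read.csv("results/cohort/cohort.csv", stringsAsFactors = FALSE)
reg <- feature_registry()
cat(sprintf("feature registry: %d features (%s)\n", nrow(reg),
            paste(sprintf("%s %d", names(table(reg$family)),
                          table(reg$family)), collapse = ", ")))

t1 <- t2 <- matrix(NA_real_, nrow(manifest), nrow(reg),
                   dimnames = list(manifest$id, reg$name))
for (i in seq_len(nrow(manifest))) {
  img <- load_image(manifest$image_path[i], manifest$spacing_mm[i])
  tum <- load_mask(manifest$tumor_mask_path[i], img, role = "tumor")
  exc <- load_mask(manifest$exclusion_mask_path[i], img, role = "exclusion")
  fv <- suppressWarnings(
    extract_features(img, tum, exc, margin_mm = 5))
  t1[i, ] <- fv$tumor
  t2[i, ] <- fv$tumor_plus_peritumoral
}

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(id = manifest$id, t1, check.names = FALSE),
          "results/features_tumor.csv", row.names = FALSE)
write.csv(data.frame(id = manifest$id, t2, check.names = FALSE),
          "results/features_peritumoral.csv", row.names = FALSE)
write.csv(reg, "results/feature_manifest.csv", row.names = FALSE)

defined1 <- sum(colSums(is.na(t1)) == 0)
defined2 <- sum(colSums(is.na(t2)) == 0)
cat(sprintf("tumor table: %d/%d features defined on every lesion\n",
            defined1, nrow(reg)))
cat(sprintf("tumor+peritumoral table: %d/%d defined\n", defined2, nrow(reg)))

# machine batch-effect screen (the acquisition device should not leak
# into the features: machines are assigned independently of class)
bt <- batch_effect_test(t1, manifest$machine)
write.csv(bt$table, "results/batch_effect_tumor.csv", row.names = FALSE)
cat(sprintf("batch-effect screen (tumor): min p = %.3f -> %s\n", bt$min_p,
            if (bt$no_batch_effect) "no batch effect at the 0.050 screen"
            else "some features differ between machines"))
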