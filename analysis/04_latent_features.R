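#!/usr/bin/env Rscript
# Stage 4 — latent phenotype extraction.
#
# Reduces every fitted curve and its growth-rate curve to the 14 latent
# phenotypes (inflection point value and timing, maximum value, peak
# growth rate and its half-maximum window, rate-curve area and slopes),
# pooled into a plots x features matrix.
library(latentyield)

fits <- readRDS("scratch/fits.rds")
pool <- feature_pool(fits)
feat_cols <- setdiff(names(pool), c("plot_id", "genotype", "year"))
cat(sprintf("feature pool: %d plots x %d features (%d traits x 2 families x 14)\n",
            nrow(pool), length(feat_cols), length(feat_cols) / 28))
write.csv(pool, "results/latent_features.csv", row.names = FALSE)
write.csv(latent_feature_codes(), "results/latent_feature_codes.csv",
          row.names = FALSE)
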