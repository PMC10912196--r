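#!/usr/bin/env Rscript
# Stage 3 — growth-curve fitting.
#
# Imputes the rare missing plot-by-date cells with same-date trait means,
# then fits logistic and Gompertz sigmoids to every plot x trait series
# against days after planting.
library(latentyield)

traits <- read.csv("results/traits.csv", colClasses = c(year = "character"))
traits <- impute_missing(traits)
cat(sprintf("imputed %d of %d cells (%.2f%%)\n", sum(traits$imputed),
            nrow(traits), 100 * mean(traits$imputed)))

fits <- fit_trait_curves(traits)
summary_tab <- aggregate(r2_fit ~ trait + family, fits, median)
print(summary_tab)
cat(sprintf("fitted %d curves; %.1f%% converged\n", nrow(fits),
            100 * mean(fits$converged)))

dir.create("scratch", showWarnings = FALSE)
saveRDS(fits, "scratch/fits.rds")  # fit objects carry a list-column
write.csv(fits[setdiff(names(fits), "fit")], "results/fit_summary.csv",
          row.names = FALSE)
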