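#!/usr/bin/env Rscript
# Stage 5 — feature selection.
#
# Iterative VIF pruning at threshold 5 removes the fully collinear bulk
# of the 168 candidates, then recursive feature elimination sweeps
# feature-count limits 1-30 per learner, picking the smallest limit whose
# mean test adjusted R2 sits within 0.005 of the sweep peak.
library(latentyield)

seed <- 1
pool <- read.csv("results/latent_features.csv",
                 colClasses = c(year = "character"))
yield <- read.csv("results/yield.csv")
feat_cols <- setdiff(names(pool), c("plot_id", "genotype", "year"))
y <- yield$yield[match(pool$plot_id, yield$plot_id)]

vf <- vif_filter(pool[feat_cols], threshold = 5)
cat(sprintf("VIF: %d of %d features survive\n", ncol(vf$features),
            length(feat_cols)))
write.csv(vf$report, "results/vif_report.csv", row.names = FALSE)

selected <- list()
for (nm in c("rf", "xgb")) {
  spec <- if (nm == "rf") rf_spec() else xgb_spec()
  sw <- rfe_sweep(vf$features, y, spec, limits = 1:30, iterations = 5,
                  seed = seed + 7)
  cat(sprintf("%s: chosen limit %d (peak mean test adj R2 %.3f): %s\n",
              nm, sw$chosen_limit, max(sw$curve$mean_test_adj_r2),
              paste(sw$selected, collapse = ", ")))
  sw$curve$model <- nm
  selected[[nm]] <- list(curve = sw$curve, features = sw$selected)
}
write.csv(do.call(rbind, lapply(selected, `[[`, "curve")),
          "results/rfe_sweep.csv", row.names = FALSE)
jsonlite::write_json(lapply(selected, `[[`, "features"),
                     "results/selected_features.json", pretty = TRUE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  d <- do.call(rbind, lapply(selected, `[[`, "curve"))
  p <- ggplot(d, aes(limit, mean_test_adj_r2, colour = model)) +
    geom_line() + geom_point(size = 0.8) +
    geom_line(aes(y = mean_train_adj_r2), linetype = 2) +
    labs(x = "number of features", y = "mean adjusted R²",
         title = "RFE sweep (solid: test, dashed: train)") +
    theme_minimal()
  ggsave("results/rfe_sweep.png", p, width = 6, height = 4, dpi = 150)
}
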