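#!/usr/bin/env Rscript
# Stage 6 — ensemble yield models.
#
# Trains the random forest (depth 10, 400 trees) and gradient boosting
# (learning rate 0.06, depth 3, min child weight 5) on each learner's
# RFE-selected features; validates by 200-state Monte-Carlo
# cross-validation (70/30) and 10-fold CV; the best random state's model
# predicts yield for every plot.
library(latentyield)

seed <- 1
mccv_iters <- 200   # raise to 1000 to mirror the full protocol
pool <- read.csv("results/latent_features.csv",
                 colClasses = c(year = "character"))
yield <- read.csv("results/yield.csv")
sel <- jsonlite::read_json("results/selected_features.json",
                           simplifyVector = TRUE)
y <- yield$yield[match(pool$plot_id, yield$plot_id)]

all_preds <- list(); scores <- list()
for (nm in names(sel)) {
  spec <- if (nm == "rf") rf_spec() else xgb_spec()
  x <- pool[sel[[nm]]]
  cv <- mccv(spec, x, y, iterations = mccv_iters, seed = seed + 11)
  kf <- kfold(spec, x, y, k = 10, seed = seed + 13)
  cat(sprintf("%s: MCCV train/test adj R2 = %.3f / %.3f; 10-fold %.3f; best state %d\n",
              nm, cv$summary$mean_train_adj_r2, cv$summary$mean_test_adj_r2,
              kf$mean_test_adj_r2, cv$best_iteration))
  scores[[nm]] <- data.frame(model = nm, cv$summary,
                             kfold_test_adj_r2 = kf$mean_test_adj_r2,
                             best_iteration = cv$best_iteration)
  p <- predict_all(cv, x, plot_ids = pool$plot_id)
  p$model <- nm
  p$measured_yield <- y
  p$year <- pool$year
  p$genotype <- pool$genotype
  all_preds[[nm]] <- p
}
write.csv(do.call(rbind, scores), "results/cv_scores.csv", row.names = FALSE)
write.csv(do.call(rbind, all_preds), "results/predictions.csv",
          row.names = FALSE)
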