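#!/usr/bin/env Rscript
# Stage 1 — simulate the two-year trial.
#
# 73 genotypes x 3 replicates per year (RCBD), 12 flights in 2021 and 18
# in 2022 spanning 10-130 days after planting, 1% of plot-by-date
# observations lost at random. Yield is generated from five latent
# features of each plot's true canopy-cover curve plus genotype, year and
# residual effects, so every downstream stage has a known answer.
library(latentyield)

seed <- 1
dir.create("results", showWarnings = FALSE)

design <- trial_design(year_effects = c("2021" = 0.4, "2022" = -0.4))
truth <- draw_genotype_truth(73, seed = seed + 1000)
sim <- simulate_trial(design, truth, yield_model_truth(), seed = seed)

write.csv(sim$traits, "results/traits.csv", row.names = FALSE)
write.csv(sim$yield, "results/yield.csv", row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, n_plots = nrow(sim$yield),
       n_trait_rows = nrow(sim$traits),
       residual_sd = sim$truth$residual_sd,
       yield_coefficients = as.list(yield_model_truth()$coefficients)),
  "results/simulation_truth_summary.json", auto_unbox = TRUE, pretty = TRUE)

full_grid <- sum(sapply(design$dap_schedule, length) * 73 * 3)
cat(sprintf("simulated %d plots, %d trait rows (%.1f%% of the %d-cell grid)\n",
            nrow(sim$yield), nrow(sim$traits),
            100 * nrow(sim$traits) / full_grid, full_grid))
cat(sprintf("yield: mean %.2f t/ha, sd %.2f, range %.2f-%.2f\n",
            mean(sim$yield$yield), sd(sim$yield$yield),
            min(sim$yield$yield), max(sim$yield$yield)))
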