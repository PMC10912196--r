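#!/usr/bin/env Rscript
# Stage 7 — breeding-oriented evaluation.
#
# Per-flight trait-yield correlation series, estimated-vs-measured
# regressions (overall and per year), repeatability from variance
# components, and 4-bin (Excellent/Good/Mediocre/Poor) confusion matrices
# on genotype means.
library(latentyield)

traits <- read.csv("results/traits.csv", colClasses = c(year = "character"))
yield <- read.csv("results/yield.csv")
preds <- read.csv("results/predictions.csv",
                  colClasses = c(year = "character"))

pf <- perflight_correlations(traits, yield)
write.csv(pf, "results/perflight_correlations.csv", row.names = FALSE)
best <- pf[which.max(abs(pf$r)), ]
cat(sprintf("strongest per-flight correlation: %s at DAP %d in %s (r = %.2f)\n",
            best$trait, best$dap, best$year, best$r))

eval_rows <- list(); conf <- list()
measured_means <- tapply(yield$yield, yield$genotype, mean)
measured_bins <- bin_genotypes(measured_means)
for (nm in unique(preds$model)) {
  p <- preds[preds$model == nm, ]
  overall <- regress_estimated_vs_measured(p, "overall")
  per_year <- regress_estimated_vs_measured(p, "per_year")
  reg <- rbind(overall, per_year)
  reg$model <- nm
  rep_rows <- do.call(rbind, lapply(unique(p$year), function(yr) {
    s <- p$year == yr
    data.frame(model = nm, year = yr,
               R_estimated = repeatability(p$estimated_yield[s],
                                           p$genotype[s])$R,
               R_measured = repeatability(p$measured_yield[s],
                                          p$genotype[s])$R)
  }))
  est_means <- tapply(p$estimated_yield, p$genotype, mean)
  cm <- confusion_matrix(measured_bins,
                         bin_genotypes(est_means[names(measured_means)]))
  cat(sprintf("%s: overall R2 %.2f (%s per year); agreement %.2f; catastrophic %d\n",
              nm, overall$r2,
              paste(sprintf("%s %.2f", per_year$group, per_year$r2),
                    collapse = ", "),
              cm$agreement, cm$catastrophic))
  eval_rows[[nm]] <- list(reg = reg, rep = rep_rows)
  conf[[nm]] <- as.data.frame(cm$matrix)
  conf[[nm]]$model <- nm
}
write.csv(do.call(rbind, lapply(eval_rows, `[[`, "reg")),
          "results/regressions.csv", row.names = FALSE)
write.csv(do.call(rbind, lapply(eval_rows, `[[`, "rep")),
          "results/repeatability.csv", row.names = FALSE)
write.csv(do.call(rbind, conf), "results/confusion_matrices.csv",
          row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p1 <- ggplot(pf, aes(dap, r, colour = trait)) +
    geom_line() + facet_wrap(~year) + theme_minimal() +
    labs(x = "days after planting", y = "Pearson r with yield",
         title = "Per-flight trait-yield correlations")
  ggsave("results/perflight_correlations.png", p1, width = 7, height = 3.5,
         dpi = 150)
  p2 <- ggplot(preds, aes(measured_yield, estimated_yield,
                          colour = set_label)) +
    geom_point(size = 0.7) + geom_abline(linetype = 2) +
    facet_grid(model ~ year) + theme_minimal() +
    labs(x = "measured yield (t/ha)", y = "estimated yield (t/ha)")
  ggsave("results/estimated_vs_measured.png", p2, width = 7, height = 5,
         dpi = 150)
}
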