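#' Per-flight Pearson correlations between traits and yield
#'
#' For every year, flight date and trait, the Pearson correlation between
#' the plots' trait values on that date and their final yield. Dates with
#' fewer than 3 plots or zero trait variance report \code{NA}.
#'
#' @param traits Trait table (\code{plot_id}, \code{year}, \code{dap} plus
#'   trait columns).
#' @param yield Yield table (\code{plot_id}, \code{yield}).
#' @param trait_cols Traits to correlate.
#' @return Long data frame: \code{year}, \code{dap}, \code{trait}, \code{r},
#'   \code{n}.
#' @export
perflight_correlations <- function(traits, yield,
                                   trait_cols = c("CC", "CH", "CV", "ExG")) {
  trait_cols <- intersect(trait_cols, names(traits))
  m <- merge(traits, yield[c("plot_id", "yield")], by = "plot_id")
  out <- list()
  for (yr in unique(m$year)) for (dp in sort(unique(m$dap[m$year == yr]))) {
    sub <- m[m$year == yr & m$dap == dp, ]
    for (tc in trait_cols) {
      v <- sub[[tc]]; ok <- !is.na(v) & !is.na(sub$yield)
      r <- if (sum(ok) < 3 || stats::sd(v[ok]) == 0 ||
               stats::sd(sub$yield[ok]) == 0) NA_real_
           else stats::cor(v[ok], sub$yield[ok])
      out[[length(out) + 1L]] <- data.frame(year = yr, dap = dp, trait = tc,
                                            r = r, n = sum(ok))
    }
  }
  do.call(rbind, out)
}

#' Regress estimated yield on measured yield
#'
#' Ordinary least squares of the model's estimates against the field
#' measurements, overall or within each year. Per-year fits guard against
#' the inflation that arises when two years with very different yield
#' levels anchor a single pooled regression.
#'
#' @param predictions Data frame with \code{measured_yield} and
#'   \code{estimated_yield} (and \code{year} for per-year grouping).
#' @param grouping \code{"overall"} or \code{"per_year"}.
#' @return Data frame: \code{group}, \code{slope}, \code{intercept},
#'   \code{r2}, \code{n}.
#' @export
regress_estimated_vs_measured <- function(predictions,
                                          grouping = c("overall", "per_year")) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "overall") list(overall = predictions)
            else split(predictions, predictions$year)
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 3) stop("need at least 3 points per group")
    if (stats::sd(d$measured_yield) == 0)
      stop("constant measured yield in group ", g)
    fit <- stats::lm(estimated_yield ~ measured_yield, data = d)
    data.frame(group = g, slope = stats::coef(fit)[[2]],
               intercept = stats::coef(fit)[[1]],
               r2 = summary(fit)$r.squared, n = nrow(d))
  })
  do.call(rbind, out)
}

#' Repeatability from one-way random-genotype variance components
#'
#' Method-of-moments on the one-way ANOVA: the residual variance is the
#' within-genotype mean square; the genotypic variance is
#' \eqn{(MS_{between} - MS_{within}) / \bar r} with \eqn{\bar r} the mean
#' number of replicates per genotype, truncated at zero (and flagged) when
#' the estimate is negative. Repeatability on an entry-mean basis is
#' \eqn{R = \sigma^2_g / (\sigma^2_g + \sigma^2_e / \bar r)}.
#'
#' @param values Plot-level values (e.g. yield).
#' @param genotype Genotype labels, same length.
#' @return List: \code{sigma2_g}, \code{sigma2_e}, \code{r_reps},
#'   \code{R}, \code{truncated}.
#' @export
repeatability <- function(values, genotype) {
  ok <- !is.na(values)
  values <- values[ok]; genotype <- as.character(genotype)[ok]
  counts <- table(genotype)
  if (length(counts) < 2 || sum(counts >= 2) < 2)
    stop("need at least 2 genotypes with at least 2 replicates")
  g <- length(counts); N <- length(values)
  gm <- tapply(values, genotype, mean)
  ms_within <- sum((values - gm[genotype])^2) / (N - g)
  grand <- mean(values)
  ms_between <- sum(counts * (gm[names(counts)] - grand)^2) / (g - 1)
  r_bar <- mean(counts)
  sigma2_g <- (ms_between - ms_within) / r_bar
  truncated <- sigma2_g < 0
  if (truncated) sigma2_g <- 0
  R <- if (sigma2_g + ms_within / r_bar == 0) 1
       else sigma2_g / (sigma2_g + ms_within / r_bar)
  list(sigma2_g = sigma2_g, sigma2_e = ms_within, r_reps = r_bar,
       R = R, truncated = truncated)
}

#' Assign genotypes to percentile yield bins
#'
#' Genotype means are ranked and partitioned: Excellent = top 10%,
#' Good = 11th-25th percentile, Mediocre = 26th-50th, Poor = bottom half.
#' Cumulative boundaries are rounded half up so the partition is exact for
#' any genotype count; ties in the means are broken by stable genotype-id
#' order.
#'
#' @param means Named numeric vector of genotype mean yields.
#' @return Factor (levels Excellent, Good, Mediocre, Poor) named by
#'   genotype.
#' @export
bin_genotypes <- function(means) {
  n <- length(means)
  if (n < 4) stop("need at least 4 genotypes to form 4 bins")
  if (is.null(names(means))) names(means) <- as.character(seq_len(n))
  ord <- order(-means, names(means))  # stable: ties by genotype id
  cuts <- round_half_up(n * c(0.10, 0.25, 0.50))
  cuts <- pmax(cuts, c(1, 2, 3))  # tiny n: keep bins non-degenerate
  bin <- character(n)
  rank_pos <- integer(n); rank_pos[ord] <- seq_len(n)
  bin[rank_pos <= cuts[1]] <- "Excellent"
  bin[rank_pos > cuts[1] & rank_pos <= cuts[2]] <- "Good"
  bin[rank_pos > cuts[2] & rank_pos <= cuts[3]] <- "Mediocre"
  bin[rank_pos > cuts[3]] <- "Poor"
  stats::setNames(factor(bin, levels = c("Excellent", "Good", "Mediocre",
                                         "Poor")), names(means))
}

#' Confusion matrix of measured vs estimated yield bins
#'
#' Rows are the measured-yield bins, columns the estimated-yield bins.
#' Also reports the count of catastrophic selection errors: Excellent
#' genotypes estimated Poor or Poor genotypes estimated Excellent.
#'
#' @param measured,estimated Bin factors from [bin_genotypes()], named by
#'   the same genotype set.
#' @return List: \code{matrix} (4x4 table), \code{catastrophic},
#'   \code{agreement} (diagonal fraction).
#' @export
confusion_matrix <- function(measured, estimated) {
  if (!setequal(names(measured), names(estimated)))
    stop("measured and estimated bins cover different genotype sets")
  estimated <- estimated[names(measured)]
  m <- table(measured = measured, estimated = estimated)
  list(matrix = m,
       catastrophic = m["Excellent", "Poor"] + m["Poor", "Excellent"],
       agreement = sum(diag(m)) / sum(m))
}
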