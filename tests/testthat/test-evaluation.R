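make_preds <- function(measured, estimated, year = "2021") {
  data.frame(plot_id = seq_along(measured), year = year,
             measured_yield = measured, estimated_yield = estimated)
}

test_that("per-flight correlations recover exact linear relations", {
  yield <- data.frame(plot_id = paste0("p", 1:6),
                      yield = c(2, 3, 4, 5, 6, 7))
  traits <- data.frame(plot_id = rep(yield$plot_id, 2),
                       year = "2021", dap = rep(c(30, 60), each = 6))
  traits$CC <- ifelse(traits$dap == 30, 2 * rep(yield$yield, 2) + 1,
                      -rep(yield$yield, 2))
  traits$CH <- 0.4  # zero variance on every date
  out <- perflight_correlations(traits, yield, trait_cols = c("CC", "CH"))
  expect_equal(out$r[out$trait == "CC" & out$dap == 30], 1)
  expect_equal(out$r[out$trait == "CC" & out$dap == 60], -1)
  expect_true(all(is.na(out$r[out$trait == "CH"])))

  # brute-force covariance formula oracle
  x <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.3)
  traits2 <- data.frame(plot_id = yield$plot_id, year = "2021", dap = 50,
                        CC = x)
  r <- perflight_correlations(traits2, yield, trait_cols = "CC")$r
  oracle <- sum((x - mean(x)) * (yield$yield - mean(yield$yield))) /
    sqrt(sum((x - mean(x))^2) * sum((yield$yield - mean(yield$yield))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
})

test_that("estimated-vs-measured regression behaves at the identities", {
  y <- latentyield:::with_seed(23, runif(30, 2, 6))
  perfect <- suppressWarnings(regress_estimated_vs_measured(make_preds(y, y)))
  expect_equal(perfect$slope, 1, tolerance = 1e-12)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  expect_equal(perfect$r2, 1, tolerance = 1e-12)

  shuffled <- latentyield:::with_seed(24, sample(y))
  null <- regress_estimated_vs_measured(make_preds(y, shuffled))
  expect_lt(null$r2, 0.15)

  expect_error(regress_estimated_vs_measured(make_preds(rep(3, 10),
                                                        runif(10))),
               "constant")
})

test_that("two separated year clusters inflate the pooled R2", {
  set.seed(25)
  n <- 40
  m1 <- runif(n, 2, 3);  e1 <- m1 + rnorm(n, 0, 0.4)
  m2 <- runif(n, 7, 8);  e2 <- m2 + rnorm(n, 0, 0.4)
  preds <- rbind(make_preds(m1, e1, year = "2021"),
                 make_preds(m2, e2, year = "2022"))
  pooled <- regress_estimated_vs_measured(preds, "overall")
  per_year <- regress_estimated_vs_measured(preds, "per_year")
  expect_gt(pooled$r2, mean(per_year$r2))
})

test_that("repeatability matches an ANOVA oracle and its closed cases", {
  # zero within-genotype variance: perfect repeatability
  vals <- rep(c(1, 2, 3, 4), each = 3)
  geno <- rep(letters[1:4], each = 3)
  expect_equal(repeatability(vals, geno)$R, 1)

  # sigma2_g = sigma2_e = 1 with 3 reps: expected R = 1/(1 + 1/3) = 0.75
  set.seed(26)
  g <- rep(sprintf("g%02d", 1:60), each = 3)
  y <- rep(rnorm(60, 0, 1), each = 3) + rnorm(180, 0, 1)
  out <- repeatability(y, g)
  # independent oracle: variance components from stats::aov mean squares
  ms <- summary(stats::aov(y ~ factor(g)))[[1]]$`Mean Sq`
  sg <- (ms[1] - ms[2]) / 3
  expect_equal(out$sigma2_g, sg, tolerance = 1e-10)
  expect_equal(out$sigma2_e, ms[2], tolerance = 1e-10)
  expect_equal(out$R, sg / (sg + ms[2] / 3), tolerance = 1e-10)
  expect_equal(out$R, 0.75, tolerance = 0.15)

  # permuting genotype labels destroys repeatability
  yp <- latentyield:::with_seed(27, sample(y))
  expect_lt(repeatability(yp, g)$R, 0.15)

  # affine invariance
  out2 <- repeatability(1000 + 12 * y, g)
  expect_equal(out2$R, out$R, tolerance = 1e-10)

  expect_error(repeatability(1:4, c("a", "b", "c", "d")), "replicates")
})

test_that("repeatability recovers known variance components at trial scale", {
  sg2 <- 0.16; se2 <- 0.09  # R = 0.16 / (0.16 + 0.03) = 0.842
  set.seed(28)
  g <- rep(sprintf("g%02d", 1:73), each = 3)
  y <- rep(rnorm(73, 4, sqrt(sg2)), each = 3) + rnorm(219, 0, sqrt(se2))
  out <- repeatability(y, g)
  expect_lt(abs(out$R - sg2 / (sg2 + se2 / 3)), 0.1)
})

test_that("yield bins follow the percentile boundaries exactly", {
  means <- setNames(seq(10, 0.1, length.out = 100), sprintf("g%03d", 1:100))
  bins <- bin_genotypes(means)
  expect_equal(as.vector(table(bins)), c(10, 15, 25, 50))
  expect_setequal(names(bins)[bins == "Excellent"], sprintf("g%03d", 1:10))

  bins20 <- bin_genotypes(setNames(rnorm(20), paste0("x", 1:20)))
  expect_equal(as.vector(table(bins20)), c(2, 3, 5, 10))

  # partition: every genotype in exactly one bin, for assorted counts
  for (n in c(4, 7, 20, 73, 100)) {
    b <- bin_genotypes(setNames(latentyield:::with_seed(n, rnorm(n)),
                                seq_len(n)))
    expect_equal(sum(table(b)), n)
    expect_false(any(is.na(b)))
  }
  expect_error(bin_genotypes(c(a = 1, b = 2, c = 3)), "4 genotypes")
})

test_that("confusion matrices count agreement, margins and catastrophes", {
  means <- setNames(seq(20, 1, length.out = 20), sprintf("g%02d", 1:20))
  bins <- bin_genotypes(means)
  perfect <- confusion_matrix(bins, bins)
  expect_equal(as.vector(diag(perfect$matrix)), as.vector(table(bins)))
  expect_equal(sum(perfect$matrix), 20)
  expect_equal(perfect$catastrophic, 0)
  expect_equal(perfect$agreement, 1)

  # reversed ranking: all mass off-diagonal, catastrophic errors present
  reversed <- bin_genotypes(-means)
  worst <- confusion_matrix(bins, reversed)
  expect_equal(sum(diag(worst$matrix)), 0)
  expect_equal(worst$matrix["Excellent", "Poor"], 2,
               ignore_attr = TRUE)  # both Excellent genotypes land in Poor
  expect_gte(worst$catastrophic, 2)

  # margins always match the bin sizes
  est <- bin_genotypes(setNames(latentyield:::with_seed(29, rnorm(20)),
                                names(means)))
  cm <- confusion_matrix(bins, est)
  expect_equal(as.vector(rowSums(cm$matrix)), as.vector(table(bins)))
  expect_equal(as.vector(colSums(cm$matrix)), as.vector(table(est)))

  # one Poor genotype estimated Excellent: catastrophic count of 1
  est2 <- bins
  poor_one <- names(bins)[bins == "Poor"][1]
  exc_one <- names(bins)[bins == "Excellent"][1]
  est2[poor_one] <- "Excellent"
  est2[exc_one] <- "Good"
  cm2 <- confusion_matrix(bins, est2)
  expect_equal(cm2$catastrophic, 1, ignore_attr = TRUE)

  expect_error(confusion_matrix(bins, est[1:10]), "different genotype sets")
})
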