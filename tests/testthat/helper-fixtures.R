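# Shared fixtures, all generated in code.

gompertz_fit <- function(N0 = 1, beta = 5, alpha = 0.1, window = c(0, 130)) {
  list(family = "gompertz", params = c(N0 = N0, beta = beta, alpha = alpha),
       window = window)
}

logistic_fit <- function(K = 1, N0 = 0.02, r = 0.15, window = c(0, 130)) {
  list(family = "logistic", params = c(K = K, N0 = N0, r = r),
       window = window)
}

# One-year trial at the study scale, with knobs for noise.
small_design <- function(n_genotypes = 10, n_flights = 12, missing_rate = 0) {
  trial_design(n_genotypes = n_genotypes, n_reps = 3,
               dap_schedule = list(
                 "2021" = round(seq(10, 130, length.out = n_flights))),
               missing_rate = missing_rate)
}

noiseless_truth <- function(n_genotypes = 10, seed = 1, yield_effect_sd = 0) {
  draw_genotype_truth(n_genotypes, seed = seed, plot_noise_cv = 0,
                      yield_effect_sd = yield_effect_sd,
                      measurement_noise = c(CC = 0, CH = 0, CH90 = 0, ExG = 0))
}

# Build an RGB tile from per-pixel HSV in the half-degree convention.
tile_from_hsv <- function(h, s, v, n = 4) {
  cols <- grDevices::col2rgb(grDevices::hsv(h / 180, s / 255, v / 255)) / 255
  array(rep(cols, each = n * n), dim = c(n, n, 3))
}

# Linear-signal feature fixture: 3 informative features + decoys.
signal_fixture <- function(n = 100, n_decoys = 20, noise_sd = 0.2, seed = 3) {
  latentyield:::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * (3 + n_decoys)), n))
    names(x) <- c("x1", "x2", "x3",
                  if (n_decoys > 0) paste0("d", seq_len(n_decoys)))
    y <- 2 * x$x1 - x$x2 + 0.5 * x$x3 + rnorm(n, 0, noise_sd)
    list(x = x, y = y)
  })
}
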