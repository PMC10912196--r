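#' Define a multi-year replicated trial layout
#'
#' The layout mirrors a replicated variety trial phenotyped by repeated
#' UAV flights: each genotype appears once per replicate block (RCBD),
#' every surviving plot is observed on each flight date, and a small
#' completely-at-random fraction of plot-by-date observations is lost.
#'
#' @param n_genotypes Number of genotypes (default 73).
#' @param n_reps Replicates per genotype (default 3).
#' @param dap_schedule Named list (one element per year label) of strictly
#'   increasing flight dates in days after planting. Defaults to 12 dates
#'   in year "2021" and 18 in "2022", spanning 10-130 DAP.
#' @param missing_rate Probability an observation is dropped; in [0, 0.2).
#' @param year_effects Named additive yield offset per year (tons/ha).
#' @return A \code{trial_design} list.
#' @export
trial_design <- function(n_genotypes = 73, n_reps = 3,
                         dap_schedule = list(
                           "2021" = round(seq(10, 130, length.out = 12)),
                           "2022" = round(seq(10, 130, length.out = 18))),
                         missing_rate = 0.01,
                         year_effects = NULL) {
  stopifnot(n_genotypes >= 1, n_reps >= 1, length(dap_schedule) >= 1,
            missing_rate >= 0, missing_rate < 0.2)
  for (dd in dap_schedule) {
    if (length(dd) == 0) stop("dap_schedule must contain at least one date")
    if (any(diff(dd) <= 0)) stop("dap_schedule must be strictly increasing")
    if (any(dd < 0 | dd > 200)) stop("DAP values outside a plausible season")
  }
  years <- names(dap_schedule)
  if (is.null(years)) stop("dap_schedule must be a named list (year labels)")
  if (is.null(year_effects)) year_effects <- stats::setNames(rep(0, length(years)), years)
  stopifnot(all(years %in% names(year_effects)))
  structure(list(n_genotypes = n_genotypes, n_reps = n_reps,
                 years = years, dap_schedule = dap_schedule,
                 missing_rate = missing_rate, year_effects = year_effects),
            class = "trial_design")
}

default_trait_medians <- function() {
  list(CC   = c(N0 = 0.90, beta = 8,  alpha = 0.080),
       CH   = c(N0 = 0.45, beta = 10, alpha = 0.070),
       CH90 = c(N0 = 0.55, beta = 10, alpha = 0.070),
       ExG  = c(N0 = 0.80, beta = 6,  alpha = 0.090))
}

#' Draw per-genotype growth-curve ground truth
#'
#' Genotype-level Gompertz parameters for each directly simulated trait
#' (CC, CH, CH90, ExG; canopy volume is derived as CC x CH) are drawn
#' log-normally around trait medians with a common genotype-level
#' coefficient of variation, plus an additive genotype yield effect.
#'
#' @param n_genotypes Number of genotypes.
#' @param seed Integer seed; fixes all draws.
#' @param medians Named list of per-trait \code{c(N0, beta, alpha)} medians.
#' @param cv_genotype Log-normal CV of genotype parameters (default 0.10).
#' @param yield_effect_sd SD of the additive genotype yield effect, t/ha.
#' @param plot_noise_cv Log-normal CV of plot-level parameter noise.
#' @param measurement_noise Named per-trait SD of additive observation noise.
#' @return A \code{genotype_truth} list.
#' @export
draw_genotype_truth <- function(n_genotypes, seed,
                                medians = default_trait_medians(),
                                cv_genotype = 0.10,
                                yield_effect_sd = 0.35,
                                plot_noise_cv = 0.05,
                                measurement_noise = c(CC = 0.02, CH = 0.02,
                                                      CH90 = 0.02, ExG = 0.02)) {
  stopifnot(n_genotypes >= 1, cv_genotype >= 0, yield_effect_sd >= 0,
            plot_noise_cv >= 0, all(measurement_noise >= 0))
  gids <- sprintf("G%03d", seq_len(n_genotypes))
  with_seed(seed, {
    params <- lapply(medians, function(med) {
      m <- sapply(names(med), function(pn)
        med[[pn]] * exp(stats::rnorm(n_genotypes, 0, cv_genotype)))
      rownames(m) <- gids
      m
    })
    if (!is.null(params$CC)) params$CC[, "N0"] <- pmin(params$CC[, "N0"], 0.99)
    effects <- stats::setNames(stats::rnorm(n_genotypes, 0, yield_effect_sd), gids)
    structure(list(genotypes = gids, params = params,
                   yield_effects = effects,
                   plot_noise_cv = plot_noise_cv,
                   measurement_noise = measurement_noise),
              class = "genotype_truth")
  })
}

#' Define the true mapping from latent phenotypes to yield
#'
#' Expected yield is a linear function of designated latent features of the
#' plot's *true* (noise-free) growth curves, named with the
#' \code{trait_family_feature} scheme (e.g. \code{CC_gompertz_f9}), plus an
#' intercept, the genotype effect, a year offset and Gaussian residual.
#'
#' @param coefficients Named coefficient vector over latent feature names
#'   (at least 3 nonzero). The defaults couple yield to five canopy-cover
#'   curve features with comparable variance contributions — positively to
#'   canopy size and peak growth rate (f1, f7, f11), negatively to late
#'   phenology (f4, f9) — so that, with the default genotype and residual
#'   effects, the latent-feature signal is the dominant yield component,
#'   as in the trials this generator emulates.
#' @param intercept Baseline yield, tons/ha.
#' @param residual_sd Residual SD, tons/ha (ignored when \code{target_r2}
#'   is given).
#' @param target_r2 Optional: set the residual SD so the latent-feature
#'   signal explains this fraction of yield variance (exact in expectation
#'   when the genotype yield-effect SD is 0).
#' @return A \code{yield_model_truth} list.
#' @export
yield_model_truth <- function(coefficients = c(CC_gompertz_f1 = 5.5,
                                               CC_gompertz_f4 = -0.07,
                                               CC_gompertz_f7 = 65,
                                               CC_gompertz_f9 = -0.04,
                                               CC_gompertz_f11 = 1.0),
                              intercept = 4.0, residual_sd = 0.30,
                              target_r2 = NULL) {
  stopifnot(sum(coefficients != 0) >= 3, residual_sd >= 0)
  if (!is.null(target_r2)) stopifnot(target_r2 > 0, target_r2 < 1)
  ok <- grepl("^[A-Za-z0-9]+_(logistic|gompertz)_f([1-9]|1[0-4])$",
              names(coefficients))
  if (!all(ok)) stop("bad coefficient names: ",
                     paste(names(coefficients)[!ok], collapse = ", "))
  structure(list(coefficients = coefficients, intercept = intercept,
                 residual_sd = residual_sd, target_r2 = target_r2),
            class = "yield_model_truth")
}

#' Simulate a full multi-year trial with known ground truth
#'
#' Produces (i) a long trait table, one row per surviving plot x flight
#' date with CC, CH, CH90, CV = CC x CH, CV90 = CC x CH90 and ExG; (ii) a
#' plot-level yield table; (iii) a truth record retaining every generating
#' parameter, the plot-level true latent features and the yield components.
#' All randomness is fixed by \code{seed}; the caller's RNG state is left
#' untouched.
#'
#' @param design A [trial_design()].
#' @param truth A [draw_genotype_truth()] result.
#' @param yield_truth A [yield_model_truth()].
#' @param seed Integer seed.
#' @return List with \code{traits}, \code{yield}, \code{truth} elements.
#' @export
simulate_trial <- function(design, truth, yield_truth, seed) {
  stopifnot(inherits(design, "trial_design"),
            inherits(truth, "genotype_truth"),
            inherits(yield_truth, "yield_model_truth"))
  if (length(truth$genotypes) < design$n_genotypes)
    stop("truth covers fewer genotypes than the design requires")
  if (!is.null(truth$params$CC) && any(truth$params$CC[, "N0"] > 1))
    stop("CC asymptotes above 1 are not a valid canopy cover")

  gids <- truth$genotypes[seq_len(design$n_genotypes)]
  sim_traits <- names(truth$params)
  coef_feats <- parse_feature_names(names(yield_truth$coefficients))
  if (!all(coef_feats$trait %in% c(sim_traits, "CV", "CV90")))
    stop("yield coefficients reference traits not simulated")

  with_seed(seed, {
    trait_rows <- list(); yield_rows <- list(); plot_truth <- list()
    for (yr in design$years) {
      daps <- design$dap_schedule[[yr]]
      window <- range(daps)
      for (g in gids) for (rep_i in seq_len(design$n_reps)) {
        pid <- sprintf("Y%s_%s_R%d", yr, g, rep_i)
        # plot-level true parameters: genotype curve x log-normal noise
        pp <- lapply(sim_traits, function(tc) {
          v <- truth$params[[tc]][g, ] *
            exp(stats::rnorm(3, 0, truth$plot_noise_cv))
          if (tc == "CC") v[["N0"]] <- min(v[["N0"]], 0.999)
          v
        })
        names(pp) <- sim_traits
        true_curves <- sapply(sim_traits, function(tc)
          evaluate_curve(pp[[tc]], "gompertz", daps))
        obs <- sapply(sim_traits, function(tc) {
          e <- stats::rnorm(length(daps), 0, truth$measurement_noise[[tc]])
          true_curves[, tc] + e
        })
        obs <- as.data.frame(obs)
        obs$CC <- pmin(pmax(obs$CC, 0), 1)
        obs$CH <- pmax(obs$CH, 0); obs$CH90 <- pmax(obs$CH90, 0)
        obs$ExG <- pmin(pmax(obs$ExG, 0), 1)
        df <- data.frame(plot_id = pid, genotype = g, rep = rep_i,
                         year = yr, dap = daps,
                         CC = obs$CC, CH = obs$CH, CH90 = obs$CH90,
                         CV = obs$CC * obs$CH, CV90 = obs$CC * obs$CH90,
                         ExG = obs$ExG, stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(df)) >= design$missing_rate
        trait_rows[[pid]] <- df[keep, , drop = FALSE]
        feats <- true_latent_features(pp, coef_feats, window)
        plot_truth[[pid]] <- list(params = pp, features = feats)
        yield_rows[[pid]] <- data.frame(
          plot_id = pid, genotype = g, rep = rep_i, year = yr,
          lp = yield_truth$intercept +
            sum(yield_truth$coefficients * feats[names(yield_truth$coefficients)]) +
            design$year_effects[[yr]],
          geno_effect = truth$yield_effects[[g]],
          stringsAsFactors = FALSE)
      }
    }
    traits <- do.call(rbind, trait_rows)
    yield <- do.call(rbind, yield_rows)
    rownames(traits) <- rownames(yield) <- NULL

    residual_sd <- yield_truth$residual_sd
    if (!is.null(yield_truth$target_r2)) {
      sig <- stats::sd(yield$lp)
      residual_sd <- sig * sqrt((1 - yield_truth$target_r2) /
                                  yield_truth$target_r2)
    }
    yield$residual <- stats::rnorm(nrow(yield), 0, residual_sd)
    yield$yield <- yield$lp + yield$geno_effect + yield$residual

    list(traits = traits,
         yield = yield[c("plot_id", "genotype", "rep", "year", "yield")],
         truth = list(design = design, genotype_truth = truth,
                      yield_truth = yield_truth, seed = seed,
                      residual_sd = residual_sd,
                      plots = plot_truth,
                      yield_components = yield))
  })
}

parse_feature_names <- function(nm) {
  parts <- strsplit(nm, "_")
  data.frame(name = nm,
             trait = vapply(parts, `[`, "", 1),
             family = vapply(parts, `[`, "", 2),
             code = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

# Closed-path latent features of a plot's true curves, for the traits and
# families a yield model references.
true_latent_features <- function(plot_params, coef_feats, window) {
  out <- numeric(nrow(coef_feats)); names(out) <- coef_feats$name
  combos <- unique(coef_feats[c("trait", "family")])
  for (i in seq_len(nrow(combos))) {
    tc <- combos$trait[i]; fam <- combos$family[i]
    if (fam != "gompertz")
      stop("true yield features are defined on the generating (gompertz) curves")
    fit <- list(family = "gompertz", params = plot_params[[tc]], window = window)
    fs <- extract_features(fit)
    sel <- coef_feats$trait == tc & coef_feats$family == fam
    out[coef_feats$name[sel]] <- fs[coef_feats$code[sel]]
  }
  out
}

#' Render a synthetic plot tile pair (RGB + DEM)
#'
#' A fixture generator for the trait-extraction stage: a tile with exactly
#' \code{round(cc_target * npix)} canopy pixels of a single green hue
#' (inside the default HSV segmentation bounds) over soil of a single
#' brown hue (outside them), and a co-registered single-band elevation
#' tile equal to \code{ground} on soil and \code{ground + height_target}
#' on canopy.
#'
#' @param cc_target Canopy cover fraction in [0, 1].
#' @param height_target Canopy height above ground, meters.
#' @param image_size Tile side, pixels (square tile).
#' @param seed Seed for the canopy pixel placement.
#' @param ground Ground elevation, meters.
#' @return List with \code{rgb} (image_size x image_size x 3 array in
#'   [0, 1]) and \code{dem} (matrix, meters).
#' @export
render_plot_tile <- function(cc_target, height_target, image_size = 100,
                             seed = 1, ground = 0.10) {
  stopifnot(cc_target >= 0, cc_target <= 1, height_target >= 0,
            image_size >= 2)
  npix <- image_size^2
  n_canopy <- round(cc_target * npix)
  canopy_rgb <- c(40, 180, 60) / 255   # hue 64 in the 0-180 convention
  soil_rgb <- c(150, 100, 60) / 255    # hue 13: below the lower bound
  rgb <- array(rep(soil_rgb, each = npix), dim = c(image_size, image_size, 3))
  dem <- matrix(ground, image_size, image_size)
  if (n_canopy > 0) {
    idx <- with_seed(seed, sample.int(npix, n_canopy))
    for (ch in 1:3) {
      plane <- rgb[, , ch]; plane[idx] <- canopy_rgb[ch]; rgb[, , ch] <- plane
    }
    dem[idx] <- ground + height_target
  }
  list(rgb = rgb, dem = dem)
}

#' Write a rendered tile pair to disk
#'
#' RGB as 8-bit PNG, DEM as 32-bit float single-band TIFF.
#'
#' @param tile A [render_plot_tile()] result.
#' @param rgb_path,dem_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_tile_pair <- function(tile, rgb_path, dem_path) {
  png::writePNG(tile$rgb, rgb_path)
  tiff::writeTIFF(tile$dem, dem_path, bits.per.sample = 32,
                  reduce = FALSE)
  invisible(c(rgb_path, dem_path))
}
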