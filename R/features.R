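#' Descriptions of the 14 latent growth-curve phenotypes
#'
#' Feature codes used throughout the package, in their conventional order:
#' f1 value at the inflection point; f2/f3 DAP at 50%/80% of that value;
#' f4 DAP at inflection; f5 maximum value over the observed window;
#' f6 DAP at maximum growth rate; f7 maximum growth rate; f8/f9 DAP at
#' the first/last half-maximum growth rate; f10 days between them;
#' f11 area under the growth-rate curve over the window; f12 mean growth
#' rate; f13/f14 rate of growth-rate increase/decrease (slopes between the
#' half-maximum crossings and the peak of the rate curve).
#'
#' @return Data frame with columns \code{code} and \code{description}.
#' @export
latent_feature_codes <- function() {
  data.frame(
    code = paste0("f", 1:14),
    description = c(
      "value of the inflection point",
      "DAP at 50% of inflection-point value",
      "DAP at 80% of inflection-point value",
      "DAP at inflection point",
      "maximum value over observed window",
      "DAP at maximum growth rate",
      "maximum growth rate",
      "DAP at first half-maximum growth rate",
      "DAP at last half-maximum growth rate",
      "DAP between half-maximum growth rates",
      "area under growth-rate curve",
      "mean growth rate",
      "rate of growth-rate increase",
      "rate of growth-rate decrease"),
    stringsAsFactors = FALSE)
}

#' Extract the 14 latent phenotypes from a fitted growth curve
#'
#' Inflection point and maximum growth rate come from closed forms
#' (logistic: value \eqn{K/2}, rate \eqn{rK/4} at
#' \eqn{t^* = \ln((K-N_0)/N_0)/r}; gompertz: value \eqn{N_0/e}, rate
#' \eqn{N_0\alpha/e} at \eqn{t^* = \ln\beta/\alpha}). Curve and rate-curve
#' crossings (f2, f3, f8, f9) are found by root bisection on the analytic
#' curves to 1e-8 days, so both families share one code path. f5 is the
#' fitted value at the last observed DAP (the asymptote may be unreachable
#' within the season). f11 is the net trait gain over the window (the
#' exact integral of the rate curve) and f12 = f11 / window length.
#' Crossings falling outside the observed window are clipped to the window
#' bound and recorded in the \code{clipped} attribute.
#'
#' @param fit A converged [fit_sigmoid()] result, or any list with
#'   \code{family}, \code{params} and \code{window}.
#' @return Named numeric vector \code{f1..f14} with attribute
#'   \code{clipped} (character vector of clipped feature codes).
#' @export
extract_features <- function(fit) {
  stopifnot(!is.null(fit$family), !is.null(fit$params),
            length(fit$window) == 2)
  p <- fit$params; fam <- fit$family
  w <- as.numeric(fit$window)
  curve <- function(t) evaluate_curve(p, fam, t)
  rate <- function(t) growth_rate(p, fam, t)

  t_star <- inflection_time(p, fam)
  f1 <- curve(t_star)
  f4 <- f6 <- t_star
  f7 <- rate(t_star)
  f5 <- curve(w[2])

  clipped <- character(0)
  clip <- function(t, code) {
    if (t < w[1]) { clipped <<- c(clipped, code); return(w[1]) }
    if (t > w[2]) { clipped <<- c(clipped, code); return(w[2]) }
    t
  }

  f2r <- rising_crossing(curve, 0.5 * f1, t_star)
  f3r <- rising_crossing(curve, 0.8 * f1, t_star)
  f8r <- half_rate_crossing(rate, f7, t_star, "left")
  f9r <- half_rate_crossing(rate, f7, t_star, "right")
  f2 <- clip(f2r, "f2"); f3 <- clip(f3r, "f3")
  f8 <- clip(f8r, "f8"); f9 <- clip(f9r, "f9")
  f10 <- f9 - f8

  f11 <- curve(w[2]) - curve(w[1])
  f12 <- f11 / (w[2] - w[1])
  f13 <- f7 / (2 * (f6 - f8))
  f14 <- -f7 / (2 * (f9 - f6))

  structure(c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6,
              f7 = f7, f8 = f8, f9 = f9, f10 = f10, f11 = f11, f12 = f12,
              f13 = f13, f14 = f14),
            clipped = clipped)
}

# t where an increasing sigmoid reaches `target`, searching left of t_star.
rising_crossing <- function(curve, target, t_star, tol = 1e-8) {
  lo <- t_star - 1
  while (curve(lo) > target && t_star - lo < 1e6) lo <- t_star - 2 * (t_star - lo)
  stats::uniroot(function(t) curve(t) - target, c(lo, t_star),
                 tol = tol)$root
}

# t where the unimodal rate curve falls to half its peak, on either side.
half_rate_crossing <- function(rate, peak, t_star, side, tol = 1e-8) {
  target <- peak / 2
  step <- 1
  if (side == "left") {
    lo <- t_star - step
    while (rate(lo) > target && t_star - lo < 1e6) lo <- t_star - (step <- 2 * step)
    iv <- c(lo, t_star)
  } else {
    hi <- t_star + step
    while (rate(hi) > target && hi - t_star < 1e6) hi <- t_star + (step <- 2 * step)
    iv <- c(t_star, hi)
  }
  stats::uniroot(function(t) rate(t) - target, iv, tol = tol)$root
}

#' Pool latent phenotypes into a plot-by-feature matrix
#'
#' One row per plot, one column per trait x family x feature combination
#' named \code{trait_family_feature} (e.g. \code{CC_gompertz_f9}). Plots
#' lacking a converged fit for any requested trait/family combination are
#' dropped with a message.
#'
#' @param fits Output of [fit_trait_curves()].
#' @return Data frame: \code{plot_id}, \code{genotype}, \code{year}, then
#'   feature columns.
#' @export
feature_pool <- function(fits) {
  stopifnot(all(c("plot_id", "trait", "family", "fit") %in% names(fits)))
  combos <- unique(fits[c("trait", "family")])
  plots <- unique(fits$plot_id)
  keep <- logical(length(plots)); names(keep) <- plots
  rows <- vector("list", length(plots))
  for (i in seq_along(plots)) {
    sub <- fits[fits$plot_id == plots[i], , drop = FALSE]
    if (nrow(sub) < nrow(combos) || !all(sub$converged)) {
      message("dropping plot ", plots[i], ": missing or non-converged fit")
      next
    }
    vals <- unlist(lapply(seq_len(nrow(sub)), function(j) {
      fs <- extract_features(sub$fit[[j]])
      names(fs) <- paste(sub$trait[j], sub$family[j], names(fs), sep = "_")
      fs
    }))
    rows[[i]] <- data.frame(plot_id = plots[i], genotype = sub$genotype[1],
                            year = sub$year[1], t(vals),
                            stringsAsFactors = FALSE)
    keep[i] <- TRUE
  }
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out
}
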