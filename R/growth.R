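#' Sigmoidal growth curves and their analytic growth rates
#'
#' Two classical three-parameter sigmoids describe a trait's trajectory
#' against days after planting (DAP):
#' \describe{
#'   \item{logistic}{\eqn{N(t) = K / (1 + A e^{-rt})} with
#'     \eqn{A = (K - N_0)/N_0}; \code{K} is the asymptote, \code{N0} the
#'     value at \eqn{t = 0}, \code{r} the intrinsic growth rate (per day).}
#'   \item{gompertz}{\eqn{N(t) = N_0 \exp(-\beta e^{-\alpha t})}; here
#'     \code{N0} is the upper asymptote, \code{beta} the displacement and
#'     \code{alpha} the growth-rate parameter (per day).}
#' }
#'
#' @param params Named numeric vector: \code{c(K, N0, r)} for logistic,
#'   \code{c(N0, beta, alpha)} for gompertz.
#' @param family \code{"logistic"} or \code{"gompertz"}.
#' @param t Days after planting (vectorized).
#' @return Trait value(s) at \code{t}.
#' @export
evaluate_curve <- function(params, family = c("logistic", "gompertz"), t) {
  family <- match.arg(family)
  check_sigmoid_params(params, family)
  if (family == "logistic") {
    A <- (params[["K"]] - params[["N0"]]) / params[["N0"]]
    params[["K"]] / (1 + A * exp(-params[["r"]] * t))
  } else {
    params[["N0"]] * exp(-params[["beta"]] * exp(-params[["alpha"]] * t))
  }
}

#' @rdname evaluate_curve
#' @details \code{growth_rate} is the analytic first derivative
#'   \eqn{N'(t)}: logistic \eqn{rN(1 - N/K)}, gompertz
#'   \eqn{N_0 \alpha \beta e^{-\alpha t} \exp(-\beta e^{-\alpha t})}.
#' @export
growth_rate <- function(params, family = c("logistic", "gompertz"), t) {
  family <- match.arg(family)
  check_sigmoid_params(params, family)
  if (family == "logistic") {
    N <- evaluate_curve(params, family, t)
    params[["r"]] * N * (1 - N / params[["K"]])
  } else {
    u <- params[["beta"]] * exp(-params[["alpha"]] * t)
    params[["N0"]] * params[["alpha"]] * u * exp(-u)
  }
}

# DAP of the inflection point (where the growth rate peaks).
inflection_time <- function(params, family) {
  if (family == "logistic") {
    log((params[["K"]] - params[["N0"]]) / params[["N0"]]) / params[["r"]]
  } else {
    log(params[["beta"]]) / params[["alpha"]]
  }
}

check_sigmoid_params <- function(params, family) {
  need <- if (family == "logistic") c("K", "N0", "r") else c("N0", "beta", "alpha")
  if (!all(need %in% names(params)))
    stop("params must contain ", paste(need, collapse = ", "), " for ", family)
  if (any(params[need] <= 0))
    stop("all ", family, " parameters must be positive")
  if (family == "logistic" && params[["N0"]] >= params[["K"]])
    stop("logistic requires 0 < N0 < K")
  invisible(TRUE)
}

#' Fit a sigmoidal growth curve to one plot's trait series
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded) with a
#' deterministic multi-start: a linearization-based initial guess, then a
#' fixed grid of rescaled restarts only if the first fit fails or fits
#' poorly. The asymptote is bounded by \code{2 * max(value)} (and by
#' \code{asymptote_max} if given, e.g. 1 for canopy cover), rates by
#' \eqn{[10^{-4}, 1]} per day, and the Gompertz displacement by
#' \eqn{[10^{-3}, 10^3]}.
#'
#' @param dap,value Numeric vectors: days after planting and the observed
#'   trait. At least 4 points; values must be non-negative.
#' @param family \code{"logistic"} or \code{"gompertz"}.
#' @param asymptote_max Optional hard cap on the fitted asymptote.
#' @return A \code{sigmoid_fit}: list with \code{family}, \code{params}
#'   (named vector), \code{rss}, \code{r2_fit}, \code{converged} and
#'   \code{window = c(first DAP, last DAP)}.
#' @export
fit_sigmoid <- function(dap, value, family = c("logistic", "gompertz"),
                        asymptote_max = Inf) {
  family <- match.arg(family)
  stopifnot(length(dap) == length(value))
  if (length(dap) < 4) stop("need at least 4 points to fit 3 parameters")
  if (any(value < 0)) stop("trait values must be non-negative")
  ord <- order(dap)
  dap <- dap[ord]; value <- value[ord]

  vmax <- max(value)
  if (vmax <= 0) stop("all-zero series cannot be fitted")
  asym_hi <- min(2 * vmax, asymptote_max)
  asym0 <- min(1.05 * vmax, asym_hi)

  starts <- sigmoid_starts(dap, value, family, asym0, asym_hi)
  lower <- if (family == "logistic") c(K = 1e-8, N0 = 1e-10, r = 1e-4)
           else c(N0 = 1e-8, beta = 1e-3, alpha = 1e-4)
  upper <- if (family == "logistic") c(K = asym_hi, N0 = asym_hi, r = 1)
           else c(N0 = asym_hi, beta = 1e3, alpha = 1)

  tss <- sum((value - mean(value))^2)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-12), upper - 1e-12)
    if ("N0" %in% names(st) && "K" %in% names(st))
      st[["N0"]] <- min(st[["N0"]], st[["K"]] * 0.99)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ sigmoid_rhs(dap, p1, p2, p3, family),
        start = list(p1 = st[[1]], p2 = st[[2]], p3 = st[[3]]),
        lower = unname(lower), upper = unname(upper),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      p <- stats::coef(fit)
      names(p) <- names(lower)
      best <- list(params = p, rss = rss)
    }
    # good enough: stop restarting (keeps noiseless fits cheap and exact)
    if (!is.null(best) && tss > 0 && best$rss / tss < 1e-10) break
  }

  if (is.null(best)) {
    st <- starts[[1]]
    p <- stats::setNames(pmin(pmax(st, lower), upper), names(lower))
    pred <- sigmoid_rhs(dap, p[[1]], p[[2]], p[[3]], family)
    best <- list(params = p, rss = sum((value - pred)^2))
    converged <- FALSE
  } else converged <- TRUE

  structure(list(
    family = family,
    params = best$params,
    rss = best$rss,
    r2_fit = if (tss > 0) 1 - best$rss / tss else NA_real_,
    converged = converged,
    window = c(dap[1], dap[length(dap)])
  ), class = "sigmoid_fit")
}

sigmoid_rhs <- function(t, p1, p2, p3, family) {
  if (family == "logistic") p1 / (1 + ((p1 - p2) / p2) * exp(-p3 * t))
  else p1 * exp(-p2 * exp(-p3 * t))
}

# Deterministic start list: linearized estimate first, then fixed
# rate/displacement rescalings (no RNG involved).
sigmoid_starts <- function(dap, value, family, asym0, asym_hi) {
  eps <- 1e-9
  v <- pmin(pmax(value, eps), asym0 * (1 - 1e-6))
  if (family == "logistic") {
    # log((K/N) - 1) = log A - r t
    y <- log(asym0 / v - 1)
    sl <- stats::coef(stats::lm(y ~ dap))
    r0 <- max(min(-sl[[2]], 0.9), 1e-3)
    A0 <- max(exp(sl[[1]]), 1e-6)
    base <- c(K = asym0, N0 = asym0 / (1 + A0), r = r0)
    alt <- lapply(c(0.4, 1, 2.5), function(m)
      c(K = min(1.3 * asym0, asym_hi), N0 = max(value[1], eps), r = min(r0 * m, 0.9)))
  } else {
    # log(-log(N/N0)) = log beta - alpha t
    y <- log(-log(v / asym0))
    sl <- stats::coef(stats::lm(y ~ dap))
    a0 <- max(min(-sl[[2]], 0.9), 1e-3)
    b0 <- max(min(exp(sl[[1]]), 999), 1e-2)
    base <- c(N0 = asym0, beta = b0, alpha = a0)
    alt <- lapply(c(0.4, 1, 2.5), function(m)
      c(N0 = min(1.3 * asym0, asym_hi), beta = min(b0 * 2, 999),
        alpha = min(a0 * m, 0.9)))
  }
  c(list(base), alt)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> %s  r2_fit=%.4f  converged=%s\n",
              x$family, x$r2_fit, x$converged))
  print(signif(x$params, 6))
  invisible(x)
}

#' Fill rare missing plot-by-date trait observations
#'
#' A plot missing from a flight date is filled, trait by trait, with the
#' mean of that trait over the plots observed on the same date in the same
#' year, so every plot carries a complete series for curve fitting.
#' Filled rows are flagged in an \code{imputed} column.
#'
#' @param traits Trait table: \code{plot_id}, \code{genotype}, \code{rep},
#'   \code{year}, \code{dap} plus numeric trait columns.
#' @param trait_cols Trait columns to fill; defaults to the standard six.
#' @return The completed table, ordered by year, plot and DAP.
#' @export
impute_missing <- function(traits, trait_cols = c("CC", "CH", "CH90",
                                                  "CV", "CV90", "ExG")) {
  trait_cols <- intersect(trait_cols, names(traits))
  stopifnot(length(trait_cols) > 0,
            all(c("plot_id", "year", "dap") %in% names(traits)))
  traits$imputed <- FALSE
  out <- lapply(split(traits, traits$year), function(yr) {
    plots <- unique(yr[c("plot_id", "genotype", "rep", "year")])
    daps <- sort(unique(yr$dap))
    full <- merge(plots, data.frame(dap = daps), by = NULL)
    m <- merge(full, yr, all.x = TRUE,
               by = intersect(names(full), names(yr)))
    for (dp in daps) {
      idx <- m$dap == dp
      for (tc in trait_cols) {
        miss <- idx & is.na(m[[tc]])
        if (!any(miss)) next
        obs <- m[[tc]][idx & !is.na(m[[tc]])]
        if (length(obs) == 0)
          stop("no observed ", tc, " values on DAP ", dp, " to impute from")
        m[[tc]][miss] <- mean(obs)
        m$imputed[miss] <- TRUE
      }
    }
    m$imputed[is.na(m$imputed)] <- TRUE
    m
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$year, out$plot_id, out$dap), , drop = FALSE]
}

#' Fit growth curves for every plot, trait and curve family
#'
#' @param traits Completed trait table (see [impute_missing()]).
#' @param trait_cols Traits to fit.
#' @param families Curve families to fit.
#' @return Data frame with one row per plot x trait x family and a
#'   \code{fit} list-column of \code{sigmoid_fit} objects.
#' @export
fit_trait_curves <- function(traits,
                             trait_cols = c("CC", "CH", "CH90", "CV", "CV90", "ExG"),
                             families = c("logistic", "gompertz")) {
  trait_cols <- intersect(trait_cols, names(traits))
  rows <- list()
  for (pid in unique(traits$plot_id)) {
    sub <- traits[traits$plot_id == pid, , drop = FALSE]
    sub <- sub[order(sub$dap), , drop = FALSE]
    for (tc in trait_cols) {
      ok <- !is.na(sub[[tc]])
      for (fam in families) {
        fit <- tryCatch(
          fit_sigmoid(sub$dap[ok], sub[[tc]][ok], fam,
                      asymptote_max = if (tc == "CC") 1 else Inf),
          error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          plot_id = pid, genotype = sub$genotype[1], year = sub$year[1],
          trait = tc, family = fam, r2_fit = fit$r2_fit,
          converged = fit$converged, stringsAsFactors = FALSE,
          fit = I(list(fit)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
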