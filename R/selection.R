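#' Iterative variance-inflation-factor pruning
#'
#' Each feature is regressed on all the others; its VIF is
#' \eqn{1/(1 - R^2_{aux})}. The feature with the highest VIF is removed
#' and the factors recomputed, until every survivor's VIF is at or below
#' the threshold. One-at-a-time removal avoids over-pruning mutually
#' collinear groups. Constant columns (undefined VIF) are removed first
#' with a warning; an auxiliary R-squared that rounds to 1 is recorded as
#' infinite VIF.
#'
#' @param x Numeric feature data frame or matrix (plots x features).
#' @param threshold Removal threshold (default 5).
#' @return List: \code{features} (pruned data frame), \code{report}
#'   (data frame of every feature with final or at-removal VIF,
#'   \code{r2_aux}, \code{removed} flag and removal \code{order}).
#' @export
vif_filter <- function(x, threshold = 5) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2, all(vapply(x, is.numeric, TRUE)))
  removed <- character(0)
  report <- list()
  const <- vapply(x, function(v) stats::var(v) == 0, TRUE)
  if (any(const)) {
    warning("removing constant column(s): ",
            paste(names(x)[const], collapse = ", "))
    for (nm in names(x)[const])
      report[[nm]] <- data.frame(feature = nm, vif = NA_real_,
                                 r2_aux = NA_real_, removed = TRUE)
    removed <- names(x)[const]
    x <- x[!const]
  }
  repeat {
    if (ncol(x) < 2) break
    vifs <- vapply(seq_along(x), function(j) {
      aux_r2(as.matrix(x[-j]), x[[j]])
    }, 0)
    vifs_v <- ifelse(vifs >= 1 - 1e-12, Inf, 1 / (1 - vifs))
    if (max(vifs_v) <= threshold) {
      for (j in seq_along(x))
        report[[names(x)[j]]] <- data.frame(feature = names(x)[j],
                                            vif = vifs_v[j], r2_aux = vifs[j],
                                            removed = FALSE)
      break
    }
    worst <- which.max(vifs_v)
    nm <- names(x)[worst]
    report[[nm]] <- data.frame(feature = nm, vif = vifs_v[worst],
                               r2_aux = vifs[worst], removed = TRUE)
    removed <- c(removed, nm)
    x <- x[-worst]
  }
  for (nm in setdiff(names(x), names(report)))  # lone survivor edge case
    report[[nm]] <- data.frame(feature = nm, vif = 1, r2_aux = 0,
                               removed = FALSE)
  rep_df <- do.call(rbind, report)
  rep_df$order <- NA_integer_
  rep_df$order[match(removed, rep_df$feature)] <- seq_along(removed)
  rownames(rep_df) <- NULL
  list(features = x, report = rep_df)
}

# R-squared of y regressed on the columns of X (with intercept); fast path
# via least squares on the centered system. Rank-deficient systems (more
# features than rows) resolve via the minimum-norm solution and report the
# achieved fit, which is what VIF pruning needs.
aux_r2 <- function(X, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sst
}

#' Recursive feature elimination sweep over feature-count limits
#'
#' For each Monte-Carlo iteration the data are split into train and test
#' sets; a single backward-elimination path is computed on the training
#' set (fit the learner, drop the least important feature, repeat), and
#' every requested limit is read off that path: the model is refitted on
#' the top-\code{limit} survivors and scored with adjusted R-squared on
#' both sets. Means across iterations give the sweep curve; the chosen
#' limit is the smallest one whose mean test adjusted R-squared is within
#' \code{tolerance} of the curve's peak.
#'
#' @param x Pruned feature data frame (from [vif_filter()]).
#' @param y Yield vector, tons/ha.
#' @param spec A [model_spec()] (random forest or gradient boosting).
#' @param limits Feature-count limits to evaluate (default 1:30; capped at
#'   the number of available features).
#' @param iterations Monte-Carlo iterations (train/test re-splits).
#' @param train_frac Training fraction per split (default 0.7).
#' @param tolerance Peak-selection tolerance in adjusted R-squared.
#' @param seed Integer seed.
#' @return List: \code{curve} (limit, mean_train_adj_r2, mean_test_adj_r2),
#'   \code{chosen_limit}, \code{selected} (feature names selected at the
#'   chosen limit on the full data), \code{per_iteration}.
#' @export
rfe_sweep <- function(x, y, spec, limits = 1:30, iterations = 25,
                      train_frac = 0.7, tolerance = 0.005, seed = 1) {
  x <- as.data.frame(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, iterations >= 1)
  limits <- sort(unique(pmin(limits, p)))
  seeds <- derive_seeds(seed, iterations)
  per_iter <- list()
  for (it in seq_len(iterations)) {
    idx <- with_seed(seeds[it], sample.int(n, round(train_frac * n)))
    xtr <- x[idx, , drop = FALSE]; ytr <- y[idx]
    xte <- x[-idx, , drop = FALSE]; yte <- y[-idx]
    path <- rfe_path(xtr, ytr, spec, seed = seeds[it])
    for (lim in limits) {
      sel <- utils::head(path, lim)
      fit <- fit_learner(spec, xtr[sel], ytr, seed = seeds[it])
      tr_r2 <- prediction_r2(ytr, predict_learner(fit, xtr[sel]))
      te_r2 <- prediction_r2(yte, predict_learner(fit, xte[sel]))
      per_iter[[length(per_iter) + 1L]] <- data.frame(
        iteration = it, limit = lim,
        train_adj_r2 = adjusted_r2(tr_r2, length(ytr), lim),
        test_adj_r2 = adjusted_r2(te_r2, length(yte), lim))
    }
  }
  per_iter <- do.call(rbind, per_iter)
  curve <- do.call(rbind, lapply(split(per_iter, per_iter$limit), function(d)
    data.frame(limit = d$limit[1],
               mean_train_adj_r2 = mean(d$train_adj_r2),
               mean_test_adj_r2 = mean(d$test_adj_r2))))
  curve <- curve[order(curve$limit), ]
  rownames(curve) <- NULL
  peak <- max(curve$mean_test_adj_r2)
  chosen <- min(curve$limit[curve$mean_test_adj_r2 >= peak - tolerance])
  full_path <- rfe_path(x, y, spec, seed = seed)
  list(curve = curve, chosen_limit = chosen,
       selected = utils::head(full_path, chosen), per_iteration = per_iter)
}

# Backward-elimination order: returns feature names ranked from kept
# longest (most important) to dropped first. Importance ties are broken
# by dropping the later column, which is deterministic.
rfe_path <- function(x, y, spec, seed = 1) {
  remaining <- names(x)
  dropped <- character(0)
  while (length(remaining) > 1) {
    fit <- fit_learner(spec, x[remaining], y, seed = seed)
    imp <- importance_learner(fit, remaining)
    worst <- remaining[max(which(imp == min(imp)))]
    dropped <- c(worst, dropped)
    remaining <- setdiff(remaining, worst)
  }
  c(remaining, dropped)
}
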