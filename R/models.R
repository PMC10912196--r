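#' Specify an ensemble yield-prediction learner
#'
#' Two tree ensembles are supported, with defaults at the grid-search
#' optima used throughout the package: a random forest with 400 trees of
#' maximum depth 10, and gradient boosting with learning rate 0.06,
#' maximum depth 3 and minimum child weight 5 (100 boosting rounds).
#' The forest considers all features at each split (\code{mtry = p}),
#' mirroring the regression default of the implementation this protocol
#' models; pass \code{mtry} to change it.
#'
#' @param kind \code{"random_forest"} or \code{"gradient_boosting"}.
#' @param max_depth Maximum tree depth (0 = unlimited for the forest).
#' @param n_trees Number of trees (forest) or boosting rounds.
#' @param learning_rate Boosting shrinkage (ignored for the forest).
#' @param min_child_weight Boosting minimum child weight.
#' @param mtry Forest features-per-split; \code{NULL} = all features.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(kind = c("random_forest", "gradient_boosting"),
                       max_depth = NULL, n_trees = NULL,
                       learning_rate = 0.06, min_child_weight = 5,
                       mtry = NULL) {
  kind <- match.arg(kind)
  if (kind == "random_forest") {
    if (is.null(max_depth)) max_depth <- 10
    if (is.null(n_trees)) n_trees <- 400
  } else {
    if (is.null(max_depth)) max_depth <- 3
    if (is.null(n_trees)) n_trees <- 100
    stopifnot(learning_rate > 0, min_child_weight >= 0)
  }
  stopifnot(max_depth >= 0, n_trees >= 1)
  structure(list(kind = kind, max_depth = max_depth, n_trees = n_trees,
                 learning_rate = learning_rate,
                 min_child_weight = min_child_weight, mtry = mtry),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
rf_spec <- function(max_depth = 10, n_trees = 400, mtry = NULL)
  model_spec("random_forest", max_depth = max_depth, n_trees = n_trees,
             mtry = mtry)

#' @rdname model_spec
#' @export
xgb_spec <- function(learning_rate = 0.06, max_depth = 3,
                     min_child_weight = 5, n_trees = 100)
  model_spec("gradient_boosting", max_depth = max_depth, n_trees = n_trees,
             learning_rate = learning_rate,
             min_child_weight = min_child_weight)

#' Fit / predict / rank with a specified learner
#'
#' Thin deterministic wrappers (single-threaded, seeded) around the two
#' ensemble back-ends, so cross-validation code is learner-agnostic.
#'
#' @param spec A [model_spec()].
#' @param x Feature data frame; @param y response vector.
#' @param seed Integer seed.
#' @return \code{fit_learner}: a \code{yield_model} (model handle plus the
#'   training feature-column manifest).
#' @export
fit_learner <- function(spec, x, y, seed = 1) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y), ncol(x) >= 1)
  if (spec$kind == "random_forest") {
    m <- ranger::ranger(
      x = x, y = y, num.trees = spec$n_trees, max.depth = spec$max_depth,
      mtry = if (is.null(spec$mtry)) ncol(x) else min(spec$mtry, ncol(x)),
      importance = "impurity", seed = seed, num.threads = 1)
  } else {
    m <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    eta = spec$learning_rate, max_depth = spec$max_depth,
                    min_child_weight = spec$min_child_weight,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
      nrounds = spec$n_trees)
  }
  structure(list(spec = spec, model = m, feature_names = names(x)),
            class = "yield_model")
}

#' @rdname fit_learner
#' @param fit A \code{yield_model} from [fit_learner()].
#' @export
predict_learner <- function(fit, x) {
  x <- as.data.frame(x)
  if (!identical(names(x)[match(fit$feature_names, names(x))],
                 fit$feature_names))
    stop("feature columns do not match the training manifest")
  x <- x[fit$feature_names]
  if (fit$spec$kind == "random_forest")
    stats::predict(fit$model, data = x, num.threads = 1)$predictions
  else
    stats::predict(fit$model, newdata = as.matrix(x))
}

#' @rdname fit_learner
#' @param feature_names Names to report importance for, in order.
#' @export
importance_learner <- function(fit, feature_names = fit$feature_names) {
  if (fit$spec$kind == "random_forest") {
    imp <- ranger::importance(fit$model)
  } else {
    tab <- xgboost::xgb.importance(model = fit$model)
    imp <- stats::setNames(rep(0, length(fit$feature_names)),
                           fit$feature_names)
    imp[tab$Feature] <- tab$Gain
  }
  imp[feature_names]
}

#' Exhaustive hyperparameter grid search by k-fold cross-validation
#'
#' Every grid point is scored by mean k-fold test adjusted R-squared on a
#' shared fold assignment; ties go to the simpler model (fewer trees,
#' then shallower depth).
#'
#' @param spec Base [model_spec()] (sets the learner kind).
#' @param x,y Features and yield.
#' @param grid Data frame of hyperparameter columns to override on
#'   \code{spec}; defaults to the package grids (forest: depth
#'   \{5, 10, 15, 0\} x trees \{100, 200, 400, 800\}; boosting:
#'   learning rate \{0.03, 0.06, 0.1\} x depth \{3, 5, 7\} x minimum
#'   child weight \{1, 3, 5\}).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List: \code{best} (a \code{model_spec}), \code{scores} (the
#'   grid with mean test adjusted R-squared per point).
#' @export
grid_search <- function(spec, x, y, grid = NULL, folds = 5, seed = 1) {
  if (is.null(grid)) grid <- default_grid(spec$kind)
  stopifnot(nrow(grid) >= 1)
  # simple-first ordering makes the tie-break "first max wins";
  # max_depth 0 means unlimited, i.e. most complex, so it sorts last
  key <- grid
  if ("max_depth" %in% names(key))
    key$max_depth[key$max_depth == 0] <- .Machine$integer.max
  ord_cols <- intersect(c("n_trees", "max_depth", "learning_rate",
                          "min_child_weight"), names(key))
  grid <- grid[do.call(order, key[ord_cols]), , drop = FALSE]
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    sp <- spec
    for (nm in names(grid)) sp[[nm]] <- grid[[nm]][i]
    kfold(sp, x, y, k = folds, seed = seed)$mean_test_adj_r2
  }, 0)
  best_i <- which.max(scores)
  best <- spec
  for (nm in names(grid)) best[[nm]] <- grid[[nm]][best_i]
  g <- grid; g$mean_test_adj_r2 <- scores
  list(best = best, scores = g)
}

default_grid <- function(kind) {
  if (kind == "random_forest")
    expand.grid(max_depth = c(5, 10, 15, 0), n_trees = c(100, 200, 400, 800))
  else
    expand.grid(learning_rate = c(0.03, 0.06, 0.1), max_depth = c(3, 5, 7),
                min_child_weight = c(1, 3, 5))
}

#' Monte-Carlo cross-validation of a yield model
#'
#' Each iteration draws a fresh random train/test partition (fixed
#' \code{train_frac}, or per-iteration fractions drawn from
#' \{0.5, 0.6, 0.7, 0.8, 0.9\} in variable mode), fits the learner on the
#' training set and scores both sets with adjusted R-squared computed on
#' each set's own size. Iterations whose test set is too small for the
#' adjusted-R-squared denominator are skipped and logged. The best
#' iteration is the one with the highest test adjusted R-squared (ties
#' broken by training score); its fitted model is retained.
#'
#' @param spec A [model_spec()].
#' @param x,y Features and yield.
#' @param iterations Number of random states (default 1000).
#' @param train_frac Training fraction, or \code{"variable"}.
#' @param seed Integer seed.
#' @return A \code{cv_result}: \code{scores} (per-iteration data frame),
#'   \code{summary} (means/SDs), \code{best_iteration}, \code{best_model},
#'   \code{best_split} (row indices of the best training set),
#'   \code{skipped}.
#' @export
mccv <- function(spec, x, y, iterations = 1000, train_frac = 0.7, seed = 1) {
  x <- as.data.frame(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(iterations >= 1, length(y) == n)
  variable <- identical(train_frac, "variable")
  seeds <- derive_seeds(seed, iterations)
  scores <- vector("list", iterations)
  best <- NULL; skipped <- integer(0)
  for (it in seq_len(iterations)) {
    split <- with_seed(seeds[it], {
      fr <- if (variable) sample(c(0.5, 0.6, 0.7, 0.8, 0.9), 1) else train_frac
      sample.int(n, round(fr * n))
    })
    n_tr <- length(split); n_te <- n - n_tr
    if (n_te <= p + 1 || n_tr <= p + 1) {
      skipped <- c(skipped, it)
      next
    }
    fit <- fit_learner(spec, x[split, , drop = FALSE], y[split],
                       seed = seeds[it])
    tr <- adjusted_r2(prediction_r2(y[split],
                                    predict_learner(fit, x[split, , drop = FALSE])),
                      n_tr, p)
    te <- adjusted_r2(prediction_r2(y[-split],
                                    predict_learner(fit, x[-split, , drop = FALSE])),
                      n_te, p)
    scores[[it]] <- data.frame(iteration = it, n_train = n_tr, n_test = n_te,
                               train_adj_r2 = tr, test_adj_r2 = te)
    if (is.null(best) || te > best$te ||
        (te == best$te && tr > best$tr)) {
      best <- list(it = it, tr = tr, te = te, model = fit, split = split)
    }
  }
  scores <- do.call(rbind, scores)
  if (is.null(scores)) stop("every iteration was skipped; test sets too small")
  structure(list(
    scores = scores,
    summary = data.frame(
      mean_train_adj_r2 = mean(scores$train_adj_r2),
      mean_test_adj_r2 = mean(scores$test_adj_r2),
      sd_train_adj_r2 = stats::sd(scores$train_adj_r2),
      sd_test_adj_r2 = stats::sd(scores$test_adj_r2)),
    best_iteration = best$it, best_model = best$model,
    best_split = best$split, skipped = skipped, seed = seed),
    class = "cv_result")
}

#' k-fold cross-validation of a yield model
#'
#' @inheritParams mccv
#' @param k Number of folds (default 10).
#' @return List with per-fold scores and \code{mean_test_adj_r2}.
#' @export
kfold <- function(spec, x, y, k = 10, seed = 1) {
  x <- as.data.frame(x)
  n <- nrow(x); p <- ncol(x)
  if (k > n) stop("more folds than observations")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  if (min(table(fold)) <= p + 1)
    stop("fold test sets too small for adjusted R-squared (n_test <= p + 1)")
  per_fold <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_learner(spec, x[tr, , drop = FALSE], y[tr], seed = seed + f)
    adjusted_r2(prediction_r2(y[!tr],
                              predict_learner(fit, x[!tr, , drop = FALSE])),
                sum(!tr), p)
  }, 0)
  list(fold_test_adj_r2 = per_fold, mean_test_adj_r2 = mean(per_fold))
}

#' Plot-level yield predictions from the best cross-validation state
#'
#' Predicts every plot (training and test alike) with the retained
#' best-iteration model, labelling each plot's membership in that
#' iteration's split for downstream plotting and regression.
#'
#' @param cv A \code{cv_result} from [mccv()].
#' @param x Feature data frame for all plots (same columns as training).
#' @param plot_ids Optional plot identifiers (default row order).
#' @return Data frame: \code{plot_id}, \code{estimated_yield},
#'   \code{set_label} ("train"/"test").
#' @export
predict_all <- function(cv, x, plot_ids = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  x <- as.data.frame(x)
  if (is.null(plot_ids)) plot_ids <- seq_len(nrow(x))
  lab <- rep("test", nrow(x))
  lab[cv$best_split] <- "train"
  data.frame(plot_id = plot_ids,
             estimated_yield = predict_learner(cv$best_model, x),
             set_label = lab, stringsAsFactors = FALSE)
}
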