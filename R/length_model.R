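# Voting-ensemble regressor for LV length from mask shape features, plus the
# model-comparison harness (seeded k-fold CV, per-fold R^2, one-way ANOVA
# across models). The ensemble averages four base learners: extremely
# randomised trees, AdaBoost.R2 over shallow regression trees, the lasso and
# a stack of ridge + k-nearest-neighbours + gradient-boosted trees combined
# by an L2-regularised linear meta-learner.

#' Ensemble specification for the LV-length model
#'
#' @param n_trees trees for the tree ensembles (extra trees, GBDT) and
#'   boosting rounds for AdaBoost.
#' @param knn_k neighbours for the stacked KNN regressor.
#' @param lambda regularisation strength of the lasso/ridge members and the
#'   stack's linear meta-learner.
#' @param max_depth tree depth for the boosted learners.
#' @param seed integer RNG seed controlling every stochastic learner and the
#'   internal out-of-fold split.
#' @return An `EnsembleSpec`. The four base learners are fixed by design and
#'   combined by an unweighted mean vote.
#' @export
ensemble_spec <- function(n_trees = 100L, knn_k = 5L, lambda = 1.0,
                          max_depth = 3L, seed = 1L) {
  structure(list(base_learners = c("extra_trees", "adaboost", "lasso", "stack"),
                 n_trees = as.integer(n_trees), knn_k = as.integer(knn_k),
                 lambda = lambda, max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "EnsembleSpec")
}

check_training_set <- function(data) {
  stop_if(!is.data.frame(data) || !"length" %in% names(data),
          "training data must be a data.frame with a 'length' column")
  stop_if(nrow(data) < 2, "need at least 2 rows to fit")
  stop_if(any(!is.finite(as.matrix(data))), "non-finite features or targets")
  stop_if(any(data$length <= 0), "target lengths must be positive")
  if (nrow(data) < 10) warning("fewer than 10 rows; fit may be unstable")
  invisible(data)
}

feat_matrix <- function(data) as.matrix(data[, setdiff(names(data), "length"),
                                             drop = FALSE])

# AdaBoost.R2 (linear loss) over shallow rpart regression trees
fit_adaboost_r2 <- function(x, y, n_rounds, max_depth, seed) {
  df <- data.frame(x, y = y)
  w <- rep(1 / length(y), length(y))
  models <- list(); alphas <- numeric(0)
  with_seed(seed, for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w * length(y),
                        control = rpart::rpart.control(maxdepth = max_depth,
                                                       cp = 0, xval = 0,
                                                       minsplit = 5))
    pred <- predict(fit, df)
    err <- abs(y - pred)
    D <- max(err)
    if (D == 0) {  # perfect member; it decides alone
      models <- c(models, list(fit)); alphas <- c(alphas, 1)
      break
    }
    L <- err / D
    ebar <- sum(w * L)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    models <- c(models, list(fit)); alphas <- c(alphas, log(1 / beta))
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  })
  if (length(models) == 0) {  # fall back to a single stump
    models <- list(rpart::rpart(y ~ ., data = df,
                                control = rpart::rpart.control(maxdepth = max_depth,
                                                               cp = 0, xval = 0)))
    alphas <- 1
  }
  structure(list(models = models, alphas = alphas), class = "adaboost_r2")
}

# weighted-median combination, the AdaBoost.R2 prediction rule
predict_adaboost_r2 <- function(fit, newx) {
  newdf <- as.data.frame(newx)
  preds <- vapply(fit$models, function(m) as.numeric(predict(m, newdf)),
                  numeric(nrow(newdf)))
  preds <- matrix(preds, nrow = nrow(newdf))
  apply_weighted_median <- function(row) {
    o <- order(row)
    cw <- cumsum(fit$alphas[o])
    row[o][which(cw >= cw[length(cw)] / 2)[1]]
  }
  apply(preds, 1, apply_weighted_median)
}

make_folds <- function(n, k, seed) {
  stop_if(k < 2, "k must be >= 2")
  stop_if(k > n, "k must not exceed the number of rows")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

fit_single <- function(learner, data, spec) {
  x <- feat_matrix(data); y <- data$length
  # a constant target defeats glmnet's standardisation; the exact fit is the mean
  if (learner %in% c("lasso", "ridge") && sd(y) == 0)
    return(structure(list(value = y[1]), class = "mean_model"))
  switch(learner,
    extra_trees = ranger::ranger(length ~ ., data = data,
                                 num.trees = spec$n_trees,
                                 splitrule = "extratrees",
                                 num.random.splits = 1, replace = FALSE,
                                 sample.fraction = 1, seed = spec$seed,
                                 num.threads = 1),
    adaboost = fit_adaboost_r2(x, y, spec$n_trees, spec$max_depth, spec$seed),
    lasso = glmnet::glmnet(x, y, alpha = 1, lambda = spec$lambda),
    ridge = glmnet::glmnet(x, y, alpha = 0, lambda = spec$lambda),
    knn = caret::knnreg(x, y, k = min(spec$knn_k, nrow(x))),
    gbdt = xgboost::xgboost(x = x, y = y, nrounds = spec$n_trees,
                            max_depth = spec$max_depth, learning_rate = 0.3,
                            objective = "reg:squarederror",
                            nthreads = 1, seed = spec$seed, verbosity = 0),
    mean = structure(list(value = mean(y)), class = "mean_model"),
    stop(sprintf("unknown learner '%s'", learner))
  )
}

predict_single <- function(fit, newx) {
  newx <- matrix(as.numeric(newx), ncol = ncol(newx),
                 dimnames = list(NULL, colnames(newx)))
  if (inherits(fit, "ranger"))
    as.numeric(predict(fit, data = as.data.frame(newx), num.threads = 1)$predictions)
  else if (inherits(fit, "adaboost_r2")) predict_adaboost_r2(fit, newx)
  else if (inherits(fit, "glmnet")) as.numeric(predict(fit, newx))
  else if (inherits(fit, "xgb.Booster")) as.numeric(predict(fit, newx))
  else if (inherits(fit, "mean_model")) rep(fit$value, nrow(newx))
  else as.numeric(predict(fit, newx))  # knnreg and friends
}

# stack: ridge + knn + gbdt, meta-learner fitted on out-of-fold predictions
fit_stack <- function(data, spec) {
  members <- c("ridge", "knn", "gbdt")
  n <- nrow(data)
  folds <- make_folds(n, min(5L, n), spec$seed)
  oof <- matrix(NA_real_, n, length(members),
                dimnames = list(NULL, members))
  for (f in sort(unique(folds))) {
    tr <- data[folds != f, , drop = FALSE]
    te_x <- feat_matrix(data[folds == f, , drop = FALSE])
    for (m in members) {
      fit <- fit_single(m, tr, spec)
      oof[folds == f, m] <- predict_single(fit, te_x)
    }
  }
  meta <- if (sd(data$length) == 0)
    structure(list(value = data$length[1]), class = "mean_model")
  else glmnet::glmnet(oof, data$length, alpha = 0, lambda = spec$lambda)
  full <- lapply(stats::setNames(members, members), fit_single,
                 data = data, spec = spec)
  structure(list(members = full, meta = meta, member_names = members),
            class = "stack_model")
}

predict_stack <- function(fit, newx) {
  z <- vapply(fit$member_names,
              function(m) predict_single(fit$members[[m]], newx),
              numeric(nrow(newx)))
  z <- matrix(z, nrow = nrow(newx), dimnames = list(NULL, fit$member_names))
  if (inherits(fit$meta, "mean_model")) return(rep(fit$meta$value, nrow(newx)))
  as.numeric(predict(fit$meta, z))
}

#' Fit the voting-ensemble LV-length model
#'
#' Fits all four base learners (extra trees, AdaBoost.R2, lasso, stack) on
#' `(features, length)` rows. Deterministic for a fixed spec seed.
#'
#' @param data data.frame with feature columns (`area, height, w1..w5` as
#'   produced by [features_row()]) and a positive `length` target column.
#' @param spec an [ensemble_spec()].
#' @return A `LengthModel`.
#' @export
fit_length_model <- function(data, spec = ensemble_spec()) {
  check_training_set(data)
  fits <- list(
    extra_trees = fit_single("extra_trees", data, spec),
    adaboost    = fit_single("adaboost", data, spec),
    lasso       = fit_single("lasso", data, spec),
    stack       = fit_stack(data, spec)
  )
  structure(list(fits = fits, spec = spec,
                 feature_names = setdiff(names(data), "length"),
                 cv_scores = NULL),
            class = "LengthModel")
}

#' Predict LV length from shape features
#'
#' The vote is the unweighted mean of the four base-learner predictions.
#'
#' @param model a fitted `LengthModel`.
#' @param features a `ShapeFeatures` object, a named numeric vector, or a
#'   matrix/data.frame of feature rows.
#' @return predicted length(s) in px.
#' @export
predict_length <- function(model, features) {
  stop_if(!inherits(model, "LengthModel"), "model must be a fitted LengthModel")
  if (inherits(features, "ShapeFeatures")) features <- features_row(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  features <- as.matrix(features)[, model$feature_names, drop = FALSE]
  base <- cbind(
    predict_single(model$fits$extra_trees, features),
    predict_single(model$fits$adaboost, features),
    predict_single(model$fits$lasso, features),
    predict_stack(model$fits$stack, features)
  )
  rowMeans(base)
}

#' Seeded k-fold cross-validated R^2 of the ensemble
#'
#' The fold partition depends only on `(n, k, seed)`. Per-fold R^2 is
#' `1 - SSres/SStot` with SStot taken about the held-out fold's mean.
#'
#' @param data as in [fit_length_model()].
#' @param spec an [ensemble_spec()].
#' @param k number of folds (default 5).
#' @param seed partition seed.
#' @return numeric vector of per-fold R^2 values.
#' @export
crossval_r2 <- function(data, spec = ensemble_spec(), k = 5L, seed = 1L) {
  check_training_set(data)
  folds <- make_folds(nrow(data), k, seed)
  vapply(sort(unique(folds)), function(f) {
    fit <- fit_length_model(data[folds != f, , drop = FALSE], spec)
    te <- data[folds == f, , drop = FALSE]
    pred <- predict_length(fit, feat_matrix(te))
    1 - sum((te$length - pred)^2) / sum((te$length - mean(te$length))^2)
  }, numeric(1))
}

#' One-way ANOVA across groups of per-fold scores
#'
#' @param groups named list of numeric score vectors (one per model).
#' @return list with `f` and `p`; a zero within-group mean square (perfect
#'   separation) reports `f = Inf`, `p = 0`.
#' @export
score_anova <- function(groups) {
  df <- data.frame(score = unlist(groups),
                   model = factor(rep(names(groups), lengths(groups))))
  msw <- sum(tapply(df$score, df$model, function(v) sum((v - mean(v))^2))) /
    (nrow(df) - nlevels(df$model))
  if (msw == 0) {
    grand <- mean(df$score)
    msb <- sum(tapply(df$score, df$model,
                      function(v) length(v) * (mean(v) - grand)^2)) /
      (nlevels(df$model) - 1)
    return(list(f = if (msb > 0) Inf else 0, p = if (msb > 0) 0 else 1))
  }
  tab <- anova(lm(score ~ model, data = df))
  list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1])
}

#' Compare length-model specs by cross-validated R^2 plus ANOVA
#'
#' All specs are evaluated on the *same* seeded fold partition; a one-way
#' ANOVA across the per-fold R^2 groups tests whether the models differ.
#'
#' @param data as in [fit_length_model()].
#' @param specs named list; each element is an [ensemble_spec()] or a single
#'   learner name (`"extra_trees"`, `"adaboost"`, `"lasso"`, `"ridge"`,
#'   `"knn"`, `"gbdt"`, `"mean"`).
#' @param k folds; @param seed partition seed.
#' @return list with `scores` (data.frame `model`, `fold`, `r2`) and `anova`
#'   (`f`, `p`). Specs that fail to fit are dropped with a warning.
#' @export
compare_models <- function(data, specs, k = 5L, seed = 1L) {
  stop_if(length(specs) < 2, "need at least 2 specs to compare")
  if (is.null(names(specs))) names(specs) <- paste0("model", seq_along(specs))
  check_training_set(data)
  folds <- make_folds(nrow(data), k, seed)
  fit_one <- function(sp, tr) {
    if (inherits(sp, "EnsembleSpec")) fit_length_model(tr, sp)
    else fit_single(sp, tr, ensemble_spec(seed = seed))
  }
  pred_one <- function(sp, fit, newx) {
    if (inherits(sp, "EnsembleSpec")) predict_length(fit, newx)
    else predict_single(fit, newx)
  }
  rows <- NULL
  groups <- list()
  for (nm in names(specs)) {
    r2 <- tryCatch(
      vapply(sort(unique(folds)), function(f) {
        fit <- fit_one(specs[[nm]], data[folds != f, , drop = FALSE])
        te <- data[folds == f, , drop = FALSE]
        pred <- pred_one(specs[[nm]], fit, feat_matrix(te))
        1 - sum((te$length - pred)^2) / sum((te$length - mean(te$length))^2)
      }, numeric(1)),
      error = function(e) {
        warning(sprintf("spec '%s' failed to fit (%s); dropped from ANOVA",
                        nm, conditionMessage(e)))
        NULL
      })
    if (!is.null(r2)) {
      groups[[nm]] <- r2
      rows <- rbind(rows, data.frame(model = nm, fold = seq_along(r2), r2 = r2))
    }
  }
  list(scores = rows, anova = score_anova(groups))
}
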