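# Listwise deletion, univariate constant imputation and multivariate
# round-robin iterative imputation.

#' Listwise deletion of training records
#'
#' Drops every record with at least one missing value among the model's
#' features; missingness outside the model features is ignored.
#'
#' @param table a [rating_table].
#' @param model_features feature names the classifier consumes.
#' @return The surviving records as a [rating_table].
#' @export
listwise_delete_train <- function(table, model_features) {
  stopifnot(all(model_features %in% table$features$names))
  keep <- stats::complete.cases(table$values[, model_features, drop = FALSE])
  if (!any(keep)) stop("degenerate training set: listwise deletion drops every record")
  table[keep]
}

#' Which test subjects can the baseline still predict?
#'
#' Under listwise deletion a rating is unusable if any model feature is
#' missing; a subject becomes unpredictable when all of its ratings are
#' unusable (e.g., all 3 raters left the same feature blank).
#'
#' @param test a rater-grouped [rating_table].
#' @param model_features feature names the classifier consumes.
#' @return Named logical vector over subjects: `TRUE` if at least one
#'   complete rating survives.
#' @export
listwise_predictability <- function(test, model_features) {
  ok <- stats::complete.cases(test$values[, model_features, drop = FALSE])
  subs <- unique(test$subject_id)
  out <- vapply(subs, function(s) any(ok[test$subject_id == s]), logical(1))
  stats::setNames(out, subs)
}

#' Fit a univariate imputer
#'
#' Stores, per feature, a fill constant equal to the chosen statistic
#' over the observed training values of that same feature.
#'
#' @param train a [rating_table].
#' @param statistic `"mean"`, `"median"` or `"mode"` (most frequent
#'   value; ties toward the smallest).
#' @param features features to fit; default: the table's model features.
#' @return An object of class `univariate_imputer`.
#' @examples
#' fs <- feature_set("a", 4)
#' rt <- rating_table(matrix(c(0, 2, NA, 4), 4, 1,
#'                           dimnames = list(NULL, "a")), fs)
#' fit_univariate(rt, "mean", "a")$constants
#' @export
fit_univariate <- function(train, statistic = c("mean", "median", "mode"),
                           features = NULL) {
  statistic <- match.arg(statistic)
  features <- features %||% train$features$model_features
  stopifnot(all(features %in% train$features$names))
  fun <- switch(statistic, mean = function(v) mean(v, na.rm = TRUE),
                median = function(v) stats::median(v, na.rm = TRUE),
                mode = stat_mode)
  constants <- vapply(features, function(f) fun(train$values[, f]), numeric(1))
  if (anyNA(constants)) {
    stop("unfittable feature (no observed training values): ",
         paste(features[is.na(constants)], collapse = ", "))
  }
  structure(list(statistic = statistic, constants = constants,
                 features = features),
            class = "univariate_imputer")
}

#' Impute missing values in a rating table
#'
#' Fills every missing entry of the imputer's features; observed entries
#' are never changed. Output values may be non-integer.
#'
#' @param imputer a fitted `univariate_imputer` or `iterative_imputer`.
#' @param table a [rating_table] whose features include the imputer's.
#' @param ... passed to methods.
#' @return The completed [rating_table].
#' @export
impute <- function(imputer, table, ...) UseMethod("impute")

#' @export
impute.univariate_imputer <- function(imputer, table, ...) {
  miss_f <- setdiff(imputer$features, table$features$names)
  if (length(miss_f)) stop("table lacks features seen at fit: ",
                           paste(miss_f, collapse = ", "))
  vals <- table$values
  for (f in imputer$features) {
    v <- vals[, f]
    v[is.na(v)] <- imputer$constants[[f]]
    vals[, f] <- v
  }
  set_values(table, vals)
}

# --- per-feature estimators for the round-robin imputer ------------------

.fit_estimator <- function(type, X, y) {
  switch(type,
    ridge = {
      # closed-form ridge with fixed penalty 1 (imputer hyperparameters
      # are not part of the classifier's grid search)
      xm <- colMeans(X); ym <- mean(y)
      Xc <- sweep(X, 2, xm)
      beta <- solve(crossprod(Xc) + diag(1, ncol(X)), crossprod(Xc, y - ym))
      list(type = "ridge", beta = drop(beta), xmean = xm, ymean = ym)
    },
    dtree = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                          control = rpart::rpart.control(
                            maxdepth = 5, xval = 0, cp = 1e-4, minsplit = 10))
      list(type = "dtree", fit = fit)
    },
    gm_em = .fit_gm(X, y),
    stop("unknown estimator '", type, "'")
  )
}

.fit_gm <- function(X, y) {
  dat <- cbind(X, .y = y)
  fit <- tryCatch(
    mclust::Mclust(dat, G = 2, modelNames = c("VVV", "EEE", "EII"),
                   control = mclust::emControl(tol = 1e-4, itmax = 200),
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate mixture: a single Gaussian's conditional mean is linear
    return(.fit_estimator("ridge", X, y))
  }
  list(type = "gm_em", pro = fit$parameters$pro,
       mean = fit$parameters$mean, sigma = fit$parameters$variance$sigma,
       p = ncol(X))
}

.log_dmvnorm <- function(X, mu, S) {
  p <- length(mu)
  ch <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-8, p)))
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

.predict_estimator <- function(est, X) {
  X <- as.matrix(X)
  switch(est$type,
    ridge = drop(sweep(X, 2, est$xmean) %*% est$beta) + est$ymean,
    dtree = unname(stats::predict(est$fit,
                                  newdata = data.frame(X, check.names = FALSE))),
    gm_em = {
      p <- est$p
      G <- length(est$pro)
      logw <- matrix(NA_real_, nrow(X), G)
      cond <- matrix(NA_real_, nrow(X), G)
      for (g in seq_len(G)) {
        mu <- est$mean[, g]
        S <- est$sigma[, , g]
        Sxx <- S[seq_len(p), seq_len(p), drop = FALSE]
        Syx <- S[p + 1L, seq_len(p), drop = FALSE]
        coef <- Syx %*% solve(Sxx + diag(1e-10, p))
        cond[, g] <- mu[p + 1L] + drop(sweep(X, 2, mu[seq_len(p)]) %*% t(coef))
        logw[, g] <- log(est$pro[g]) + .log_dmvnorm(X, mu[seq_len(p)], Sxx)
      }
      w <- exp(logw - apply(logw, 1, max))
      rowSums(w * cond) / rowSums(w)
    }
  )
}

#' Fit an iterative round-robin multivariate imputer
#'
#' Predicts the missing values of each model feature from all the other
#' model features. Missing entries are initialized with the per-feature
#' median; features are then visited round-robin in ascending-missingness
#' order, each visit refitting the per-feature predictor on the records
#' where the target was observed (using current values of the other
#' features) and re-predicting the missing entries. Sweeps stop when the
#' largest absolute change across imputed entries falls below `tolerance`
#' or after `max_iterations` sweeps.
#'
#' @param train a [rating_table]; every model feature needs at least one
#'   observed value.
#' @param estimator `"ridge"` (closed-form, penalty 1), `"dtree"`
#'   (regression tree, depth <= 5) or `"gm_em"` (2-component Gaussian
#'   mixture fitted by EM; imputation uses the conditional mean).
#' @param model_features the features to complete (>= 2).
#' @param max_iterations,tolerance stopping rule (defaults 10 and 1e-3).
#' @return An object of class `iterative_imputer` holding the fitted
#'   per-feature predictors of the final sweep.
#' @export
fit_iterative <- function(train, estimator = c("ridge", "dtree", "gm_em"),
                          model_features = NULL, max_iterations = 10,
                          tolerance = 1e-3) {
  estimator <- match.arg(estimator)
  model_features <- model_features %||% train$features$model_features
  if (length(model_features) < 2) stop("need >= 2 model features")
  stopifnot(all(model_features %in% train$features$names))
  M <- train$values[, model_features, drop = FALSE]
  obs <- !is.na(M)
  if (any(colSums(obs) == 0)) {
    stop("unfittable feature (no observed training values): ",
         paste(model_features[colSums(obs) == 0], collapse = ", "))
  }
  init <- vapply(model_features,
                 function(f) stats::median(M[, f], na.rm = TRUE), numeric(1))
  X <- M
  for (f in model_features) X[is.na(X[, f]), f] <- init[[f]]
  visit <- model_features[order(colSums(!obs))]  # ascending missingness, stable
  models <- stats::setNames(vector("list", length(model_features)),
                            model_features)
  n_sweeps <- 0L
  for (it in seq_len(max_iterations)) {
    n_sweeps <- it
    max_change <- 0
    for (f in visit) {
      others <- setdiff(model_features, f)
      est <- .fit_estimator(estimator, X[obs[, f], others, drop = FALSE],
                            M[obs[, f], f])
      models[[f]] <- est
      hole <- !obs[, f]
      if (any(hole)) {
        pred <- .predict_estimator(est, X[hole, others, drop = FALSE])
        max_change <- max(max_change, max(abs(pred - X[hole, f])))
        X[hole, f] <- pred
      }
    }
    if (max_change < tolerance) break
  }
  structure(
    list(estimator = estimator, models = models, visit = visit,
         init = init, features = model_features,
         max_iterations = as.integer(max_iterations), tolerance = tolerance,
         n_sweeps = n_sweeps),
    class = "iterative_imputer"
  )
}

#' @export
impute.iterative_imputer <- function(imputer, table, ...) {
  miss_f <- setdiff(imputer$features, table$features$names)
  if (length(miss_f)) stop("table lacks features seen at fit: ",
                           paste(miss_f, collapse = ", "))
  mf <- imputer$features
  M <- table$values[, mf, drop = FALSE]
  obs <- !is.na(M)
  if (all(obs)) return(table)
  X <- M
  for (f in mf) X[is.na(X[, f]), f] <- imputer$init[[f]]
  for (it in seq_len(imputer$max_iterations)) {
    max_change <- 0
    for (f in imputer$visit) {
      hole <- !obs[, f]
      if (!any(hole)) next
      others <- setdiff(mf, f)
      pred <- .predict_estimator(imputer$models[[f]],
                                 X[hole, others, drop = FALSE])
      max_change <- max(max_change, max(abs(pred - X[hole, f])))
      X[hole, f] <- pred
    }
    if (max_change < imputer$tolerance) break
  }
  vals <- table$values
  vals[, mf] <- X
  set_values(table, vals)
}
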