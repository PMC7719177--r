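# End-to-end evaluation harness: train the missing-value method and the
# classifier with a UAR-optimised stratified grid search, aggregate the
# repeated ratings of each test subject by mode, repeat with re-drawn
# folds, and compare every method to the listwise-deletion baseline with
# Welch t-tests and Bonferroni correction.

.metric_names <- c("sensitivity", "specificity", "uar", "auc_roc", "auc_pr")

#' Aggregate repeated ratings of each subject by mode
#'
#' Per feature, the consensus is the most frequent value over the
#' non-missing rater values (ties toward the smallest); the consensus is
#' missing only if every rater left the feature blank.
#'
#' @param table a rater-grouped [rating_table] (>= 1 rating per subject).
#' @return A [rating_table] with one consensus record per subject
#'   (`rater_id = "consensus"`), subjects in first-appearance order.
#' @examples
#' fs <- feature_set("a", 4)
#' rt <- rating_table(matrix(c(2, 2, 3), 3, 1, dimnames = list(NULL, "a")),
#'                    fs, subject_id = "S1", rater_id = c("R1", "R2", "R3"))
#' aggregate_raters(rt)$values
#' @export
aggregate_raters <- function(table) {
  subs <- unique(table$subject_id)
  fs <- table$features
  vals <- matrix(NA_real_, length(subs), length(fs$names),
                 dimnames = list(NULL, fs$names))
  first <- match(subs, table$subject_id)
  for (i in seq_along(subs)) {
    rows <- table$values[table$subject_id == subs[i], , drop = FALSE]
    vals[i, ] <- apply(rows, 2, stat_mode)
  }
  rating_table(vals, features = fs, label = table$label[first],
               subject_id = subs, rater_id = "consensus",
               age_group = table$age_group[first],
               gender = table$gender[first])
}

#' Welch two-sample t-test p-value
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate samples follow a documented convention: when both
#' samples are constant, `p = 1` if their means agree and `p = 0`
#' otherwise.
#'
#' @param x,y numeric samples of size >= 2.
#' @return The p-value.
#' @examples
#' welch_compare(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
#' @export
welch_compare <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Bonferroni significance flags
#'
#' @param p p-values.
#' @param alpha significance level (default 0.05).
#' @param m family size; defaults to `length(p)` but may be larger when
#'   the family spans several vectors (e.g., all method-by-metric
#'   comparisons of one report).
#' @return A list with logical vectors `raw` (`p < alpha`) and
#'   `corrected` (`p < alpha / m`).
#' @examples
#' bonferroni_flags(0.04, m = 15)
#' @export
bonferroni_flags <- function(p, alpha = 0.05, m = length(p)) {
  stopifnot(m >= 1)
  list(raw = p < alpha, corrected = pmin(p * m, 1) < alpha)
}

# stratified fold labels; caller controls the RNG seed
make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

.model_features_for <- function(config) {
  config$model_features %||%
    switch(config$model, logistic = lr9_features(), adtree = adtree7_features())
}

.round_to_grid <- function(table, model_features) {
  vals <- table$values
  for (f in model_features) {
    vals[, f] <- clip(round(vals[, f]), 0, table$features$domain_max[[f]])
  }
  set_values(table, vals)
}

# Fit the configured missing-value method on a training table. Training
# completion for dynamic replacement uses the general map; per-record
# dynamic maps are a test-time device.
fit_missing_handler <- function(train, method, model_features, config) {
  h <- list(method = method, model_features = model_features)
  if (method == "listwise") {
    h$train_out <- listwise_delete_train(train, model_features)
    h$dropped_train <- n_records(train) - n_records(h$train_out)
  } else if (method %in% c("mean", "median", "mode")) {
    h$imputer <- fit_univariate(train, method, model_features)
    h$train_out <- impute(h$imputer, train)
  } else if (method %in% c("gm_em", "ridge", "dtree")) {
    h$imputer <- fit_iterative(train, method, model_features,
                               config$max_iterations, config$tolerance)
    h$train_out <- impute(h$imputer, train)
  } else {
    score <- sub("^(repl|dyn)_", "", method)
    h$score <- score
    h$fallback <- fit_univariate(train, "mode", model_features)
    h$map <- build_general_map(train, model_features, .score_method(score),
                               min_overlap = config$min_overlap)
    h$train_out <- apply_replacement_table(train, h$map, model_features,
                                           h$fallback)
    if (startsWith(method, "dyn_")) h$train_ref <- train
  }
  if (config$round_imputed && method != "listwise") {
    h$train_out <- .round_to_grid(h$train_out, model_features)
  }
  h
}

# Complete a table of ratings with a fitted handler. For the baseline the
# incomplete ratings are dropped instead (returned kept index tells which
# survived).
fill_records <- function(h, table, config) {
  mf <- h$model_features
  if (h$method == "listwise") {
    ok <- stats::complete.cases(table$values[, mf, drop = FALSE])
    return(list(table = table[ok], kept = ok))
  }
  out <- if (h$method %in% c("mean", "median", "mode", "gm_em", "ridge",
                             "dtree")) {
    impute(h$imputer, table)
  } else if (startsWith(h$method, "repl_")) {
    apply_replacement_table(table, h$map, mf, h$fallback)
  } else {
    dynamic_replace_table(table, h$train_ref, mf, .score_method(h$score),
                          k = config$dynamic_k,
                          min_overlap = config$min_overlap,
                          fallback = h$fallback)
  }
  if (config$round_imputed) out <- .round_to_grid(out, mf)
  list(table = out, kept = rep(TRUE, n_records(table)))
}

.fit_model <- function(model, X, y, hyper) {
  switch(model,
    logistic = fit_logistic(X, y, C = hyper),
    adtree = fit_adtree(X, y, n_rounds = hyper))
}

# mean CV UAR per grid value; NA folds (degenerate validation splits)
# are dropped from the mean
.grid_search <- function(train, method, model_features, config, grid) {
  y_all <- label_to_binary(train$label)
  folds <- make_stratified_folds(y_all, config$cv_folds)
  scores <- matrix(NA_real_, config$cv_folds, length(grid))
  for (k in seq_len(config$cv_folds)) {
    tr <- train[folds != k]
    va <- train[folds == k]
    h <- fit_missing_handler(tr, method, model_features, config)
    filled <- fill_records(h, va, config)
    Xv <- filled$table$values[, model_features, drop = FALSE]
    yv <- label_to_binary(filled$table$label)
    if (length(unique(yv)) < 2) next
    Xt <- h$train_out$values[, model_features, drop = FALSE]
    yt <- label_to_binary(h$train_out$label)
    if (length(unique(yt)) < 2) next
    for (gi in seq_along(grid)) {
      fit <- .fit_model(config$model, Xt, yt, grid[gi])
      pred <- predict_label(fit, Xv)
      sens <- sum(pred == 1 & yv == 1) / sum(yv == 1)
      spec <- sum(pred == 0 & yv == 0) / sum(yv == 0)
      scores[k, gi] <- (sens + spec) / 2
    }
  }
  colMeans(scores, na.rm = TRUE)
}

.residual_fill <- function(h, cons) {
  if (!missing_count(cons, h$model_features)) return(cons)
  fb <- h$fallback %||% h$imputer
  if (inherits(fb, "univariate_imputer")) impute(fb, cons)
  else impute(h$imputer, cons)
}

#' Run the full train/test pipeline for one missing-value method
#'
#' Per repeat `r` (seed `config$seed + r - 1`): (a) fit the configured
#' missing-value method on the training table (the baseline applies
#' listwise deletion instead); (b) if the hyperparameter grid has more
#' than one value, grid-search it by stratified `cv_folds`-fold cross
#' validation scored by UAR, refitting the missing-value method inside
#' each fold's training split only; (c) refit the best model on the full
#' training table; (d) on the test table, fill missingness per rating
#' (dynamic methods build a per-record map), aggregate each subject's
#' raters by mode, fill any residual consensus missingness with the
#' univariate fallback, and score -- the baseline instead drops ratings
#' containing a missing model feature and excludes subjects with no
#' surviving rating from the metric denominators, reporting their count;
#' (e) compute the metric set. Means and SDs are taken over repeats.
#'
#' @param train a single-rater training [rating_table].
#' @param test a rater-grouped test [rating_table].
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: per-repeat `metrics`
#'   matrix, `mean`, `sd`, `dropped_ratings` / `dropped_subjects`
#'   (baseline accounting), and the selected hyperparameter per repeat.
#' @export
run_pipeline <- function(train, test, config) {
  stopifnot(inherits(train, "rating_table"), inherits(test, "rating_table"),
            inherits(config, "pipeline_config"))
  mf <- .model_features_for(config)
  stopifnot(all(mf %in% train$features$names),
            all(mf %in% test$features$names))
  method <- config$imputation_method
  grid <- if (config$model == "logistic") config$logistic_grid else
    config$adtree_grid
  R <- config$n_repeats
  metrics <- matrix(NA_real_, R, length(.metric_names),
                    dimnames = list(NULL, .metric_names))
  best_hyper <- numeric(R)
  dropped_ratings <- integer(R)
  dropped_subjects <- integer(R)
  for (r in seq_len(R)) {
    set.seed(config$seed + r - 1L)
    best <- if (length(grid) > 1) {
      cv <- .grid_search(train, method, mf, config, grid)
      grid[which.max(cv)]
    } else grid[1]
    best_hyper[r] <- best
    h <- fit_missing_handler(train, method, mf, config)
    fit <- .fit_model(config$model,
                      h$train_out$values[, mf, drop = FALSE],
                      label_to_binary(h$train_out$label), best)
    if (method == "listwise") {
      predictable <- listwise_predictability(test, mf)
      dropped_subjects[r] <- sum(!predictable)
      if (!any(predictable)) {
        stop("every test subject is unpredictable under the baseline")
      }
      filled <- fill_records(h, test, config)
      dropped_ratings[r] <- sum(!filled$kept)
      cons <- aggregate_raters(filled$table)
    } else if (config$impute_after_aggregation) {
      cons <- aggregate_raters(test)
      cons <- fill_records(h, cons, config)$table
    } else {
      filled <- fill_records(h, test, config)
      cons <- aggregate_raters(filled$table)
    }
    cons <- .residual_fill(h, cons)
    Xc <- cons$values[, mf, drop = FALSE]
    ms <- compute_metrics(cons$label, predict_label(fit, Xc),
                          predict_score(fit, Xc))
    metrics[r, ] <- unlist(ms)[.metric_names]
  }
  structure(
    list(method = method, model = config$model, metrics = metrics,
         mean = colMeans(metrics), sd = apply(metrics, 2, stats::sd),
         dropped_ratings = dropped_ratings,
         dropped_subjects = dropped_subjects, best_hyper = best_hyper,
         n_test_subjects = length(unique(test$subject_id))),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s / %s over %d repeats\n",
              x$model, x$method, nrow(x$metrics)))
  cat(sprintf("  UAR %.4f (%.4f)", x$mean[["uar"]], x$sd[["uar"]]))
  if (x$method == "listwise") {
    cat(sprintf("  [dropped: %d ratings, %d subjects]",
                x$dropped_ratings[1], x$dropped_subjects[1]))
  }
  cat("\n")
  invisible(x)
}

#' Compare missing-value methods against the listwise baseline
#'
#' Runs [run_pipeline()] for each method (the `listwise` baseline is
#' always included) and tests every method-by-metric mean against the
#' baseline with [welch_compare()]; Bonferroni flags use the whole
#' report as the family (non-baseline methods x 5 metrics).
#'
#' @param train,test [rating_table]s as in [run_pipeline()].
#' @param config a [pipeline_config()]; its `imputation_method` is
#'   ignored in favour of `methods`.
#' @param methods method names to compare (default: all 13).
#' @return An object of class `evaluation_report`.
#' @export
compare_methods <- function(train, test, config,
                            methods = imputation_methods()) {
  methods <- union("listwise", methods)
  results <- lapply(methods, function(m) {
    cfg <- config
    cfg$imputation_method <- m
    run_pipeline(train, test, cfg)
  })
  names(results) <- methods
  others <- setdiff(methods, "listwise")
  base <- results[["listwise"]]$metrics
  p <- matrix(NA_real_, length(others), length(.metric_names),
              dimnames = list(others, .metric_names))
  for (m in others) {
    for (j in .metric_names) {
      p[m, j] <- if (nrow(base) >= 2) {
        welch_compare(base[, j], results[[m]]$metrics[, j])
      } else NA_real_
    }
  }
  m_family <- length(others) * length(.metric_names)
  flags <- if (length(others)) {
    bonferroni_flags(p, alpha = config$alpha, m = m_family)
  } else list(raw = p, corrected = p)
  structure(
    list(results = results, methods = methods,
         mean = t(vapply(results, `[[`, numeric(5), "mean")),
         sd = t(vapply(results, `[[`, numeric(5), "sd")),
         p_values = p, raw = flags$raw, corrected = flags$corrected,
         alpha = config$alpha, m_family = m_family,
         dropped_ratings = results[["listwise"]]$dropped_ratings[1],
         dropped_subjects = results[["listwise"]]$dropped_subjects[1],
         model = config$model),
    class = "evaluation_report"
  )
}

#' Report as a data frame (one row per method)
#'
#' Cells show `mean (SD)` per metric with `*` for raw significance
#' against the baseline at level alpha and `*B` when the difference
#' stands after Bonferroni correction.
#'
#' @param x an `evaluation_report`.
#' @param row.names,optional,... ignored.
#' @return A data frame.
#' @export
as.data.frame.evaluation_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  star <- function(m, j) {
    if (m == "listwise") return("")
    if (isTRUE(x$corrected[m, j])) "*B" else if (isTRUE(x$raw[m, j])) "*" else ""
  }
  out <- data.frame(method = x$methods, stringsAsFactors = FALSE)
  for (j in .metric_names) {
    out[[j]] <- vapply(x$methods, function(m) {
      sprintf("%.4f (%.4f)%s", x$mean[m, j], x$sd[m, j], star(m, j))
    }, character(1))
  }
  out$dropped <- ifelse(out$method == "listwise",
                        sprintf("%d ratings, %d subjects",
                                x$dropped_ratings, x$dropped_subjects), "")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s model, %d methods, alpha = %g (family %d)\n",
              x$model, length(x$methods), x$alpha, x$m_family))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the formatted table as CSV and/or the raw per-repeat values as
#' JSON.
#'
#' @param report an `evaluation_report`.
#' @param csv,json destination paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
export_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    raw <- lapply(report$results, function(r) {
      list(metrics = as.data.frame(r$metrics), best_hyper = r$best_hyper,
           dropped_ratings = r$dropped_ratings,
           dropped_subjects = r$dropped_subjects)
    })
    jsonlite::write_json(
      list(model = report$model, alpha = report$alpha,
           p_values = as.data.frame(report$p_values), per_method = raw),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv, json))
}

#' Per-feature missingness comparison between subject groups
#'
#' For each feature, counts the missing entries per subject (across that
#' subject's ratings) and compares the two groups with Welch t-tests; the
#' per-subject totals over all features are compared the same way
#' (`.overall` row). The Bonferroni family is the number of features
#' plus one for the overall test. Groups with fewer than two subjects
#' are skipped with a warning.
#'
#' @param table a rater-grouped [rating_table].
#' @param grouping `"label"`, `"gender"` or `"age_group"`.
#' @param alpha significance level.
#' @param features features to analyse (default: all).
#' @return A data frame with per-group mean missing counts, Welch
#'   p-values and raw/Bonferroni flags; group names in
#'   `attr(, "groups")`.
#' @export
missingness_analysis <- function(table, grouping = c("label", "gender",
                                                     "age_group"),
                                 alpha = 0.05, features = NULL) {
  grouping <- match.arg(grouping)
  features <- features %||% table$features$names
  subs <- unique(table$subject_id)
  first <- match(subs, table$subject_id)
  grp <- table[[grouping]][first]
  counts <- matrix(0L, length(subs), length(features),
                   dimnames = list(NULL, features))
  for (i in seq_along(subs)) {
    rows <- table$values[table$subject_id == subs[i], features, drop = FALSE]
    counts[i, ] <- colSums(is.na(rows))
  }
  tab <- table(grp)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("skipping group(s) with < 2 subjects: ",
            paste(small, collapse = ", "))
  }
  groups <- setdiff(names(tab), small)
  if (length(groups) < 2) stop("need at least two groups of >= 2 subjects")
  if (length(groups) > 2) stop("only two-group comparisons are supported")
  g1 <- which(grp == groups[1])
  g2 <- which(grp == groups[2])
  p <- vapply(features, function(f) welch_compare(counts[g1, f],
                                                  counts[g2, f]), numeric(1))
  p_overall <- welch_compare(rowSums(counts)[g1], rowSums(counts)[g2])
  m <- length(features) + 1L
  pv <- c(p, .overall = p_overall)
  flags <- bonferroni_flags(pv, alpha = alpha, m = m)
  out <- data.frame(
    feature = c(features, ".overall"),
    mean_group1 = c(colMeans(counts[g1, , drop = FALSE]),
                    mean(rowSums(counts)[g1])),
    mean_group2 = c(colMeans(counts[g2, , drop = FALSE]),
                    mean(rowSums(counts)[g2])),
    p_value = unname(pv),
    significant = unname(flags$raw),
    bonferroni = unname(flags$corrected),
    stringsAsFactors = FALSE
  )
  attr(out, "groups") <- groups
  attr(out, "alpha") <- alpha
  out
}
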