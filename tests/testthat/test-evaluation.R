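test_that("mode aggregation of raters follows the majority/missing rules", {
  vals <- rbind(c(2, 1, NA), c(2, NA, NA), c(3, 1, NA))
  colnames(vals) <- c("a", "b", "c")
  tab <- make_table(vals, subject_id = "S1", rater_id = c("R1", "R2", "R3"),
                    label = "ASD")
  cons <- aggregate_raters(tab)
  expect_equal(n_records(cons), 1)
  expect_equal(unname(cons$values[1, ]), c(2, 1, NA))
  expect_identical(cons$label, "ASD")
  # ties go to the smallest value
  tie <- make_table(matrix(c(1, 3, NA), 3, 1, dimnames = list(NULL, "a")),
                    subject_id = "S1")
  expect_equal(aggregate_raters(tie)$values[1, "a"], c(a = 1))
})

test_that("welch_compare matches its conventions and the integration oracle", {
  expect_equal(welch_compare(c(1, 2, 3), c(3, 2, 1)), 1)  # t = 0
  expect_equal(welch_compare(rep(2, 5), rep(2, 5)), 1)
  expect_equal(welch_compare(rep(0, 5), rep(1, 5)), 0)
  set.seed(12)
  p <- welch_compare(rep(0, 5), rep(1, 5) + rnorm(5, 0, 1e-6))
  expect_lt(p, 1e-6)
  for (i in 1:50) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = runif(1))
    expect_equal(welch_compare(x, y), oracle_welch_p(x, y), tolerance = 1e-8)
  }
})

test_that("Bonferroni flags divide the level by the family size", {
  f <- bonferroni_flags(0.04, m = 1)
  expect_true(f$raw); expect_true(f$corrected)
  f <- bonferroni_flags(0.04, m = 15)
  expect_true(f$raw); expect_false(f$corrected)
  f <- bonferroni_flags(0, m = 1000)
  expect_true(f$raw); expect_true(f$corrected)
  expect_true(all(bonferroni_flags(c(0.001, 0.04), alpha = 0.05)$raw))
})

study <- simulate_rating_study(seed = 42, n_train = 500, n_test_subjects = 50)
cfg <- pipeline_config(model = "adtree", imputation_method = "mean",
                       n_repeats = 2, adtree_grid = c(3L, 5L), cv_folds = 5,
                       seed = 7)

test_that("the pipeline is deterministic given config and seed", {
  r1 <- run_pipeline(study$train, study$test, cfg)
  r2 <- run_pipeline(study$train, study$test, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$best_hyper, r2$best_hyper)
  expect_equal(nrow(r1$metrics), 2)
  expect_true(all(r1$sd >= 0))
  # report means/SDs recompute from the stored per-repeat values
  expect_equal(r1$mean, colMeans(r1$metrics))
  expect_equal(r1$sd, apply(r1$metrics, 2, sd))
})

test_that("with a complete test set every method scores identically", {
  # nothing to fill anywhere: train and test both complete
  fs <- default_feature_set("adtree")
  train <- generate_cohort(cohort_spec(300, fs, seed = 5))
  complete_test <- generate_cohort(cohort_spec(40, fs, n_raters = 3,
                                               rater_noise = 0.2, seed = 6))
  cfg1 <- cfg; cfg1$adtree_grid <- 5L; cfg1$n_repeats <- 1L
  metrics <- sapply(c("listwise", "mean", "mode", "repl_corr", "dyn_nn"),
                    function(m) {
    cfg1$imputation_method <- m
    run_pipeline(train, complete_test, cfg1)$metrics[1, ]
  })
  expect_true(all(metrics == metrics[, 1]))
})

test_that("baseline accounting: dropped + surviving = total, subjects flagged", {
  cfgb <- cfg; cfgb$imputation_method <- "listwise"; cfgb$adtree_grid <- 5L
  cfgb$n_repeats <- 1L
  res <- run_pipeline(study$train, study$test, cfgb)
  mf <- adtree7_features()
  ok <- complete.cases(study$test$values[, mf])
  expect_equal(res$dropped_ratings[1], sum(!ok))
  expect_equal(res$dropped_ratings[1] + sum(ok), n_records(study$test))
  expect_equal(res$dropped_subjects[1],
               sum(!listwise_predictability(study$test, mf)))
})

test_that("fold-internal imputer fitting cannot leak held-out labels", {
  tr <- study$train[1:200]
  va <- study$train[201:260]
  for (m in c("mean", "ridge", "repl_mi")) {
    h <- featrepl:::fit_missing_handler(tr, m, adtree7_features(), cfg)
    filled <- featrepl:::fill_records(h, va, cfg)$table
    va_flip <- va
    va_flip$label <- rev(va$label)
    va_flip$subject_id <- paste0("X", seq_len(n_records(va)))  # keep labels consistent
    filled_flip <- featrepl:::fill_records(h, va_flip, cfg)$table
    expect_identical(filled$values, filled_flip$values)
  }
})

test_that("method comparison reports p-values and flags against the baseline", {
  cfgc <- cfg; cfgc$adtree_grid <- 4L; cfgc$n_repeats <- 3L
  rep_methods <- c("listwise", "mean", "repl_corr")
  report <- compare_methods(study$train, study$test, cfgc,
                            methods = rep_methods)
  expect_setequal(report$methods, rep_methods)
  expect_equal(dim(report$p_values), c(2L, 5L))
  expect_equal(report$m_family, 10L)
  # Bonferroni flag implies the raw flag
  expect_true(all(report$raw[report$corrected]))
  df <- as.data.frame(report)
  expect_equal(nrow(df), 3)
  expect_match(df$dropped[df$method == "listwise"], "subjects")
  paths <- export_report(report,
                         csv = withr::local_tempfile(fileext = ".csv"),
                         json = withr::local_tempfile(fileext = ".json"))
  expect_true(all(file.exists(paths)))
})

test_that("missingness analysis compares groups per feature plus overall", {
  tb <- simulate_rating_study(seed = 11, n_train = 50)
  res <- missingness_analysis(tb$test, "label")
  expect_equal(nrow(res), 31)  # 30 features + .overall
  expect_setequal(attr(res, "groups"), c("ASD", "NT"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$significant[res$bonferroni]))
  # the label-driven heavy feature shows the ASD excess
  hv <- res[res$feature == tb$heavy_feature, ]
  asd_col <- paste0("mean_group", which(attr(res, "groups") == "ASD"))
  nt_col <- paste0("mean_group", which(attr(res, "groups") == "NT"))
  expect_gt(hv[[asd_col]], hv[[nt_col]])
  expect_error(missingness_analysis(tb$test, "nope"))
})
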