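mf2 <- c("a", "b")

test_that("listwise deletion drops exactly the records missing a model feature", {
  vals <- rbind(c(1, 2, NA), c(NA, 1, 1), c(0, 0, 0))
  colnames(vals) <- c("a", "b", "c")
  tab <- make_table(vals, model_features = mf2)
  kept <- listwise_delete_train(tab, mf2)
  expect_equal(n_records(kept), 2)      # record 2 lost (model feature a)
  expect_equal(n_records(listwise_delete_train(tab, c("a", "b", "c"))), 1)
  complete <- make_table(vals[3, , drop = FALSE])
  expect_equal(n_records(listwise_delete_train(complete, mf2)), 1)
  all_bad <- make_table(matrix(c(NA, 1, 1), 1, 3,
                               dimnames = list(NULL, c("a", "b", "c"))))
  expect_error(listwise_delete_train(all_bad, mf2), "degenerate")
})

test_that("a subject is unpredictable only when no complete rating survives", {
  vals <- rbind(c(NA, 1), c(1, NA), c(NA, 1),   # S1: every rating broken
                c(1, 1), c(NA, 0), c(0, NA))    # S2: one complete rating
  colnames(vals) <- mf2
  tab <- make_table(vals, subject_id = rep(c("S1", "S2"), each = 3),
                    rater_id = rep(c("R1", "R2", "R3"), 2))
  flags <- listwise_predictability(tab, mf2)
  expect_identical(unname(flags), c(FALSE, TRUE))
})

test_that("univariate fill constants match the column statistic", {
  col <- function(v) make_table(matrix(v, ncol = 1,
                                       dimnames = list(NULL, "a")))
  expect_equal(fit_univariate(col(c(0, 2, NA, 4)), "mean", "a")$constants[["a"]], 2)
  expect_equal(fit_univariate(col(c(0, 1, 3, NA)), "median", "a")$constants[["a"]], 1)
  expect_equal(fit_univariate(col(c(2, 2, 3, NA)), "mode", "a")$constants[["a"]], 2)
  expect_error(fit_univariate(col(c(NA, NA)), "mean", "a"), "unfittable")
})

test_that("univariate constants equal brute-force column statistics on random tables", {
  brute_mode <- function(v) {
    v <- v[!is.na(v)]
    cnt <- table(v)
    as.numeric(names(cnt)[cnt == max(cnt)][1])  # names sorted ascending
  }
  for (seed in 1:100) {
    tab <- rand_table(12, 3, miss = 0.3, seed = seed)
    ok <- colSums(!is.na(tab$values)) > 0
    feats <- colnames(tab$values)[ok]
    for (stat in c("mean", "median", "mode")) {
      imp <- fit_univariate(tab, stat, feats)
      for (f in feats) {
        v <- tab$values[, f]
        expected <- switch(stat, mean = mean(v, na.rm = TRUE),
                           median = median(v, na.rm = TRUE),
                           mode = brute_mode(v))
        expect_equal(imp$constants[[f]], expected)
      }
    }
  }
})

test_that("imputation fills every hole and never touches observed entries", {
  tab <- rand_table(60, 5, miss = 0.25, seed = 7)
  obs <- !is.na(tab$values)
  imp <- fit_univariate(tab, "mean", colnames(tab$values))
  out <- impute(imp, tab)
  expect_equal(missing_count(out), 0)
  expect_identical(out$values[obs], tab$values[obs])
  it <- fit_iterative(tab, "ridge", colnames(tab$values))
  out2 <- impute(it, tab)
  expect_equal(missing_count(out2), 0)
  expect_identical(out2$values[obs], tab$values[obs])
  # no missing -> identity
  expect_identical(impute(imp, out)$values, out$values)
  expect_error(impute(imp, make_table(matrix(1, 1, 1,
                                             dimnames = list(NULL, "zz")))),
               "lacks features")
})

test_that("perfectly collinear features are recovered by the ridge imputer", {
  set.seed(21)
  a <- sample(0:4, 200, replace = TRUE)
  vals <- cbind(a = a, b = a, c = sample(0:4, 200, replace = TRUE))
  vals <- matrix(as.numeric(vals), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  truth <- vals
  vals[runif(200) < 0.2, "b"] <- NA
  tab <- make_table(vals)
  it <- fit_iterative(tab, "ridge", c("a", "b", "c"))
  out <- impute(it, tab)
  holes <- is.na(vals[, "b"])
  expect_lt(max(abs(out$values[holes, "b"] - truth[holes, "a"])), 0.05)
})

test_that("the round-robin loop honours its stopping rule", {
  tab <- rand_table(80, 4, miss = 0.2, seed = 3)
  complete <- impute(fit_univariate(tab, "mode", colnames(tab$values)), tab)
  it0 <- fit_iterative(complete, "ridge", colnames(tab$values))
  expect_equal(it0$n_sweeps, 1L)          # nothing to change
  it1 <- fit_iterative(tab, "ridge", colnames(tab$values), tolerance = Inf)
  expect_equal(it1$n_sweeps, 1L)          # tolerance = Inf: one sweep
  itN <- fit_iterative(tab, "ridge", colnames(tab$values),
                       max_iterations = 4, tolerance = 0)
  expect_lte(itN$n_sweeps, 4L)            # always terminates within the cap
  expect_error(fit_iterative(tab, "krige", colnames(tab$values)))
})

test_that("decision-tree and Gaussian-mixture estimators complete tables too", {
  tab <- rand_table(120, 4, miss = 0.15, seed = 12)
  for (est in c("dtree", "gm_em")) {
    out <- impute(fit_iterative(tab, est, colnames(tab$values)), tab)
    expect_equal(missing_count(out), 0)
    obs <- !is.na(tab$values)
    expect_identical(out$values[obs], tab$values[obs])
  }
})

test_that("under MCAR with strong correlation, iterative beats mean imputation", {
  fs <- feature_set(paste0("f", 1:5), 4)
  wins <- 0L
  for (seed in 1:20) {
    truth <- generate_cohort(cohort_spec(400, fs, loading = 0.9, seed = seed))
    holed <- apply_missingness(truth, missingness_spec(
      "MCAR", rates = setNames(rep(0.2, 5), fs$names), seed = seed + 1000L))
    holes <- is.na(holed$values)
    rmse <- function(out) sqrt(mean((out$values[holes] - truth$values[holes])^2))
    r_iter <- rmse(impute(fit_iterative(holed, "ridge", fs$names), holed))
    r_mean <- rmse(impute(fit_univariate(holed, "mean", fs$names), holed))
    if (r_iter < r_mean) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
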