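# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

# quick rating table from a values matrix (features inferred, domain 4
# unless given)
make_table <- function(values, dmax = 4, model_features = NULL, ...) {
  values <- as.matrix(values)
  fs <- feature_set(colnames(values), dmax,
                    model_features = model_features %||% colnames(values))
  rating_table(values, features = fs, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random ordinal table with MCAR holes, for property tests
rand_table <- function(n, p, dmax = 4, miss = 0.2, seed = 1) {
  set.seed(seed)
  vals <- matrix(sample(0:dmax, n * p, replace = TRUE), n, p,
                 dimnames = list(NULL, paste0("f", seq_len(p))))
  vals[matrix(runif(n * p) < miss, n, p)] <- NA_real_
  make_table(vals, dmax = dmax)
}

# Cohort in which every model feature has an exact duplicate in the
# expanded set; missingness hits only the model features, so replacement
# can reconstruct the complete data exactly.
make_dup_study <- function(seed, n_train = 400, n_test_subjects = 40,
                           heavy_rate = 0.4) {
  mf <- adtree7_features()
  base_fs <- default_feature_set("adtree")
  dmax <- base_fs$domain_max[mf]
  fs7 <- feature_set(mf, dmax, mf)
  dup_names <- paste0(mf, "_dup")
  fs_exp <- feature_set(c(mf, dup_names), c(dmax, setNames(dmax, dup_names)),
                        model_features = mf)
  expand <- function(tab) {
    vals <- cbind(tab$values, structure(tab$values,
                                        dimnames = list(NULL, dup_names)))
    rating_table(vals, features = fs_exp, label = tab$label,
                 subject_id = tab$subject_id, rater_id = tab$rater_id,
                 age_group = tab$age_group, gender = tab$gender)
  }
  train <- expand(generate_cohort(cohort_spec(
    n_train, fs7, effect = 2.5, loading = 0.7, n_raters = 1, seed = seed)))
  test_complete <- expand(generate_cohort(cohort_spec(
    n_test_subjects, fs7, effect = 2.5, loading = 0.7, n_raters = 3,
    rater_noise = 0.2, seed = seed + 50L)))
  rates <- setNames(rep(0.15, length(mf)), mf)
  rates[["pretend_play"]] <- heavy_rate
  test_missing <- apply_missingness(
    test_complete, missingness_spec("MCAR", rates, seed = seed + 99L))
  list(train = train, test_complete = test_complete,
       test_missing = test_missing, model_features = mf, features = fs_exp)
}

# brute-force ADTree margin: walk the precondition chain recursively
oracle_adtree_margin <- function(model, X) {
  rules <- model$rules
  holds <- function(i, pid) {
    if (pid == 1L) return(TRUE)
    r <- pid %/% 2L
    want_true <- pid %% 2L == 0L
    rule <- rules[r, ]
    cond <- X[i, rule$feature] <= rule$threshold
    holds(i, rule$precondition) && (cond == want_true)
  }
  vapply(seq_len(nrow(X)), function(i) {
    m <- model$root_score
    if (nrow(rules)) {
      for (r in seq_len(nrow(rules))) {
        pid <- 2L * r  # rule r introduced preconditions 2r / 2r+1
        rule <- rules[r, ]
        if (holds(i, rule$precondition)) {
          cond <- X[i, rule$feature] <= rule$threshold
          m <- m + if (cond) rule$score_true else rule$score_false
        }
      }
    }
    m
  }, numeric(1))
}

# Welch p-value by explicit statistic + numerical integration of the t
# density (independent of stats::t.test)
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * integrate(function(u) dt(u, df), lower = abs(t_stat), upper = Inf,
                rel.tol = 1e-12, abs.tol = 1e-14)$value
}
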