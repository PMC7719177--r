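# Synthetic scoresheet simulator: class-correlated ordinal features from a
# one-factor latent-severity model, repeated noisy raters per subject, and
# parameterized MCAR/MAR/MNAR missingness. Stands in for the instrument
# archives and the video-rating test set that the evaluation harness was
# designed around.

#' Specify a synthetic cohort
#'
#' Each subject carries a latent severity `z ~ N(effect * 1[ASD], 1)`.
#' Feature `f` with loading `l_f` observes `u = l_f z + sqrt(1 - l_f^2) e`
#' (`e` standard normal), discretized into `[0, domain_max]` at fixed
#' quantile cut-points of the noise-free marginal so that domain usage is
#' roughly uniform. Each of `n_raters` records per subject independently
#' perturbs every value by +/-1 with probability `rater_noise` (clipped to
#' the domain).
#'
#' @param n_subjects number of subjects.
#' @param features a [feature_set].
#' @param prevalence fraction of ASD subjects, in (0, 1).
#' @param effect latent class-separation in SD units (>= 0).
#' @param loading per-feature latent loading in `[0, 1]`; scalar recycled.
#' @param n_raters ratings per subject.
#' @param rater_noise probability a rater perturbs a value by +/-1.
#' @param seed integer RNG seed; generation is deterministic given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, features, prevalence = 0.5, effect = 2.5,
                        loading = 0.7, n_raters = 1, rater_noise = 0,
                        seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1,
            rater_noise >= 0, rater_noise <= 1,
            effect >= 0, all(loading >= 0), all(loading <= 1))
  if (length(loading) == 1L) {
    loading <- stats::setNames(rep(loading, length(features$names)),
                               features$names)
  }
  stopifnot(all(features$names %in% names(loading)))
  structure(
    list(n_subjects = as.integer(n_subjects), features = features,
         prevalence = prevalence, effect = effect,
         loading = loading[features$names],
         n_raters = as.integer(n_raters), rater_noise = rater_noise,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# quantile cut-points of the class-mixture marginal of the latent score u
.mixture_cuts <- function(domain_max, loading, effect, prevalence) {
  d <- as.integer(domain_max)
  shift <- loading * effect
  cdf <- function(t) (1 - prevalence) * stats::pnorm(t) +
    prevalence * stats::pnorm(t, mean = shift)
  vapply((1:d) / (d + 1), function(p) {
    stats::uniroot(function(t) cdf(t) - p, lower = -10, upper = 10 + shift,
                   tol = 1e-9)$root
  }, numeric(1))
}

#' Generate a complete synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A complete (no missing values) [rating_table] with
#'   `n_subjects * n_raters` records, balanced age-group and gender
#'   metadata assigned independently of the label.
#' @examples
#' fs <- feature_set(c("a", "b"), 3)
#' tab <- generate_cohort(cohort_spec(20, fs, seed = 7))
#' n_records(tab)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (n * spec$n_raters == 0L) stop("empty table: n_subjects * n_raters is 0")
  set.seed(spec$seed)
  fs <- spec$features
  n_asd <- max(1L, min(n - 1L, round(spec$prevalence * n)))
  label <- rep(c("ASD", "NT"), c(n_asd, n - n_asd))
  # balanced metadata, independent of label: cycle within each class
  age_group <- character(n); gender <- character(n)
  for (cl in c("ASD", "NT")) {
    idx <- which(label == cl)
    age_group[idx] <- rep(c("1-3", "4-6"), length.out = length(idx))
    gender[idx] <- rep(c("F", "M", "M", "F"), length.out = length(idx))
  }
  z <- stats::rnorm(n) + ifelse(label == "ASD", spec$effect, 0)
  base <- matrix(NA_real_, n, length(fs$names),
                 dimnames = list(NULL, fs$names))
  for (f in fs$names) {
    l <- spec$loading[[f]]
    u <- l * z + sqrt(1 - l^2) * stats::rnorm(n)
    cuts <- .mixture_cuts(fs$domain_max[[f]], l, spec$effect, spec$prevalence)
    base[, f] <- rowSums(outer(u, cuts, `>`))
  }
  idx <- rep(seq_len(n), each = spec$n_raters)
  vals <- base[idx, , drop = FALSE]
  if (spec$rater_noise > 0) {
    m <- length(vals)
    flip <- stats::runif(m) < spec$rater_noise
    delta <- sample(c(-1, 1), m, replace = TRUE)
    vals[flip] <- vals[flip] + delta[flip]
    for (f in fs$names) {
      vals[, f] <- clip(vals[, f], 0, fs$domain_max[[f]])
    }
  }
  rating_table(
    vals, features = fs, label = label[idx],
    subject_id = sprintf("S%04d", idx),
    rater_id = sprintf("R%d", rep(seq_len(spec$n_raters), n)),
    age_group = age_group[idx], gender = gender[idx]
  )
}

#' Specify a missingness mechanism
#'
#' Entries of the targeted features are independently set missing with a
#' per-entry probability `clip(rate * (1 + slope * d), 0, 1)` where the
#' dependence `d` in `[0, 1]` is mechanism-specific: 0 for MCAR (the rate
#' applies uniformly); the scaled value of an *observed* driver column for
#' MAR; the entry's own scaled value for MNAR_value; and the class
#' indicator (ASD = 1) for MNAR_label, which emulates missingness driven
#' by the diagnosis itself.
#'
#' @param mechanism one of `"MCAR"`, `"MAR"`, `"MNAR_value"`,
#'   `"MNAR_label"`.
#' @param rates named per-feature base rates in `[0, 1]`; only named
#'   features are targeted.
#' @param driver for MAR: the observed feature or metadata column
#'   (`"age_group"`, `"gender"`) whose value scales missingness.
#' @param slope dependence strength (0 reduces every mechanism to MCAR).
#' @param seed integer RNG seed.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR_value",
                                           "MNAR_label"),
                             rates, driver = NULL, slope = 0, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(rates), !is.null(names(rates)),
            all(rates >= 0), all(rates <= 1))
  if (mechanism == "MAR" && is.null(driver)) {
    stop("MAR requires a driver column")
  }
  structure(
    list(mechanism = mechanism, rates = rates, driver = driver,
         slope = slope, seed = as.integer(seed)),
    class = "missingness_spec"
  )
}

#' Apply a missingness mechanism to a rating table
#'
#' Already-missing entries stay missing; realized per-entry probabilities
#' are clipped to `[0, 1]`. Deterministic given the spec seed.
#'
#' @param table a [rating_table].
#' @param spec a [missingness_spec()].
#' @return The table with entries knocked out.
#' @examples
#' fs <- feature_set(c("a", "b"), 3)
#' tab <- generate_cohort(cohort_spec(50, fs, seed = 1))
#' ms <- missingness_spec("MCAR", rates = c(a = 0.5), seed = 2)
#' missing_count(apply_missingness(tab, ms))
#' @export
apply_missingness <- function(table, spec) {
  stopifnot(inherits(table, "rating_table"),
            inherits(spec, "missingness_spec"))
  fs <- table$features
  targets <- names(spec$rates)
  unknown <- setdiff(targets, fs$names)
  if (length(unknown)) stop("rates name unknown features: ",
                            paste(unknown, collapse = ", "))
  if (spec$mechanism == "MAR") {
    drv <- spec$driver
    if (!drv %in% c(fs$names, "age_group", "gender")) {
      stop("MAR driver '", drv, "' is not an observed column")
    }
  }
  set.seed(spec$seed)
  n <- n_records(table)
  vals <- table$values
  for (f in targets) {
    d <- switch(spec$mechanism,
      MCAR = rep(0, n),
      MAR = {
        drv <- spec$driver
        if (drv %in% fs$names) {
          x <- vals[, drv] / fs$domain_max[[drv]]
          x[is.na(x)] <- mean(x, na.rm = TRUE)  # driver gaps get the average pull
          x
        } else if (drv == "age_group") {
          as.numeric(table$age_group == "1-3")
        } else {
          as.numeric(table$gender == "M")
        }
      },
      MNAR_value = {
        x <- vals[, f] / fs$domain_max[[f]]
        x[is.na(x)] <- 0
        x
      },
      MNAR_label = as.numeric(table$label == "ASD")
    )
    d[is.na(d)] <- 0
    p <- clip(spec$rates[[f]] * (1 + spec$slope * d), 0, 1)
    knock <- stats::runif(n) < p
    vals[knock, f] <- NA_real_
  }
  set_values(table, vals)
}

# deterministic per-feature base rates used by the study simulator
.study_rates <- function(features, lo, hi) {
  stats::setNames(rep(seq(lo, hi, length.out = 6),
                      length.out = length(features)), features)
}

#' Simulate a complete rating study (training archive + video test set)
#'
#' Convenience testbed mirroring the shape of the study the harness was
#' designed for: a large single-rater training archive and a test set of
#' 140 subjects, each scored on 30 behavioral features by 3 independent
#' noisy raters, class-balanced and balanced for age and gender. Training
#' missingness is MCAR with per-feature rates cycling through 0.02-0.18
#' (0.30 for the heavy feature `pretend_play`). Test missingness is, by
#' default, label-driven (MNAR) for five speech/play-related features --
#' `pretend_play` at base rate 0.33 and slope 0.5 (realized rate about
#' 0.41) and four more at base 0.10, slope 0.8 -- with MCAR background
#' rates cycling through 0.02-0.12 elsewhere. `mechanism = "MCAR"` keeps
#' the same expected rates but removes the label dependence (the null
#' configuration for missingness analyses).
#'
#' @param seed integer seed driving every random draw.
#' @param n_train training records (single-rater).
#' @param n_test_subjects test subjects (3 raters each).
#' @param mechanism `"MNAR_label"` (default) or `"MCAR"`.
#' @return A list with `train` and `test` [rating_table]s, the
#'   `features` set, the label-`driven` feature names and the
#'   `heavy_feature`.
#' @examples
#' tb <- simulate_rating_study(seed = 1, n_train = 200, n_test_subjects = 30)
#' n_records(tb$test)
#' @export
simulate_rating_study <- function(seed = 1, n_train = 2000,
                                  n_test_subjects = 140,
                                  mechanism = c("MNAR_label", "MCAR")) {
  mechanism <- match.arg(mechanism)
  fs <- default_feature_set("all")
  loading <- stats::setNames(rep(seq(0.55, 0.85, length.out = 6),
                                 length.out = length(fs$names)), fs$names)
  heavy <- "pretend_play"
  driven <- c("pretend_play", "speech_patterns", "communicative_engagement",
              "understands_language", "stereotyped_speech")

  train <- generate_cohort(cohort_spec(
    n_subjects = n_train, features = fs, loading = loading,
    effect = 2.5, n_raters = 1, rater_noise = 0.25, seed = seed
  ))
  train_rates <- .study_rates(fs$names, 0.02, 0.18)
  train_rates[[heavy]] <- 0.30
  train <- apply_missingness(train, missingness_spec(
    "MCAR", rates = train_rates, seed = seed + 101L))

  test <- generate_cohort(cohort_spec(
    n_subjects = n_test_subjects, features = fs, loading = loading,
    effect = 2.5, n_raters = 3, rater_noise = 0.25, seed = seed + 202L
  ))
  driven_rates <- stats::setNames(rep(0.10, length(driven)), driven)
  driven_rates[[heavy]] <- 0.33
  bg <- .study_rates(setdiff(fs$names, driven), 0.02, 0.12)
  if (mechanism == "MNAR_label") {
    test <- apply_missingness(test, missingness_spec(
      "MNAR_label", rates = driven_rates["pretend_play"], slope = 0.5,
      seed = seed + 303L))
    test <- apply_missingness(test, missingness_spec(
      "MNAR_label", rates = driven_rates[setdiff(driven, heavy)], slope = 0.8,
      seed = seed + 404L))
  } else {
    # same expected realized rates, no label dependence
    flat <- driven_rates
    flat[[heavy]] <- driven_rates[[heavy]] * (1 + 0.5 * 0.5)
    flat[setdiff(driven, heavy)] <-
      driven_rates[setdiff(driven, heavy)] * (1 + 0.8 * 0.5)
    test <- apply_missingness(test, missingness_spec(
      "MCAR", rates = flat, seed = seed + 303L))
  }
  test <- apply_missingness(test, missingness_spec(
    "MCAR", rates = bg, seed = seed + 505L))

  list(train = train, test = test, features = fs,
       driven = driven, heavy_feature = heavy)
}
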