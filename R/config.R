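# Pipeline run configuration.

.valid_methods <- c(
  "listwise", "mean", "median", "mode", "gm_em", "ridge", "dtree",
  "repl_corr", "repl_nn", "repl_mi", "dyn_corr", "dyn_nn", "dyn_mi"
)

#' Names of the supported missing-value methods
#'
#' `listwise` is the deletion baseline; `mean`/`median`/`mode` are
#' univariate imputers; `gm_em`/`ridge`/`dtree` are iterative round-robin
#' multivariate imputers; `repl_*` are general feature replacement and
#' `dyn_*` dynamic feature replacement, scored by Spearman correlation
#' (`corr`), Euclidean proximity (`nn`) or mutual information (`mi`).
#'
#' @return Character vector of the 13 method names.
#' @export
imputation_methods <- function() .valid_methods

#' Construct a pipeline configuration
#'
#' @param model downstream classifier: `"logistic"` (LR9-style,
#'   L2-penalised logistic regression) or `"adtree"` (ADTree7-style
#'   boosted alternating decision tree).
#' @param imputation_method one of [imputation_methods()].
#' @param cv_folds folds of the stratified grid-search cross validation
#'   (default 10).
#' @param n_repeats number of times the whole train/test process is
#'   repeated with re-drawn folds (default 5).
#' @param seed base RNG seed; repeat `r` uses `seed + r - 1`.
#' @param model_features explicit model feature names; default `NULL`
#'   selects [lr9_features()] or [adtree7_features()] to match `model`.
#' @param dynamic_k neighborhood size for dynamic replacement; default
#'   `NULL` means `max(50, 5%` of training records`)`.
#' @param logistic_grid inverse-regularization grid for the logistic
#'   model; the lower bound 0.01 guards against degenerate regularization.
#' @param adtree_grid boosting-round grid for the alternating decision
#'   tree.
#' @param max_iterations,tolerance stopping rule of the iterative
#'   imputers.
#' @param min_overlap minimum pairwise-complete overlap for replacement
#'   scoring.
#' @param round_imputed round imputed values back to the ordinal grid
#'   (default `FALSE`: both classifiers accept reals, and rounding
#'   discards information).
#' @param impute_after_aggregation fill test missingness after, rather
#'   than before, mode aggregation of raters.
#' @param alpha significance level for method comparisons.
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(model = "adtree", imputation_method = "repl_corr")
#' cfg$cv_folds
#' @export
pipeline_config <- function(model = c("logistic", "adtree"),
                            imputation_method = "listwise",
                            cv_folds = 10, n_repeats = 5, seed = 1,
                            model_features = NULL, dynamic_k = NULL,
                            logistic_grid = c(0.01, 0.1, 1),
                            adtree_grid = c(3L, 5L, 7L, 10L),
                            max_iterations = 10, tolerance = 1e-3,
                            min_overlap = 30,
                            round_imputed = FALSE,
                            impute_after_aggregation = FALSE,
                            alpha = 0.05) {
  model <- match.arg(model)
  if (!imputation_method %in% .valid_methods) {
    stop("unknown imputation_method '", imputation_method, "'; valid names: ",
         paste(.valid_methods, collapse = ", "))
  }
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (any(logistic_grid < 0.01)) {
    stop("logistic_grid values must respect the lower bound 0.01")
  }
  structure(
    list(model = model, imputation_method = imputation_method,
         cv_folds = as.integer(cv_folds), n_repeats = as.integer(n_repeats),
         seed = as.integer(seed), model_features = model_features,
         dynamic_k = dynamic_k, logistic_grid = logistic_grid,
         adtree_grid = as.integer(adtree_grid),
         max_iterations = as.integer(max_iterations), tolerance = tolerance,
         min_overlap = as.integer(min_overlap),
         round_imputed = isTRUE(round_imputed),
         impute_after_aggregation = isTRUE(impute_after_aggregation),
         alpha = alpha),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys match the arguments of [pipeline_config()]; unstated keys take
#' their defaults and unknown keys are rejected.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  keys <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  if (is.null(keys)) keys <- list()
  known <- setdiff(names(formals(pipeline_config)), "...")
  unknown <- setdiff(names(keys), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, keys)
}
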