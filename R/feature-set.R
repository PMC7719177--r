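# Feature catalogues for the 30-item behavioral rating questionnaire and
# the two published minimal-feature classifiers built on top of it.

.lr9_names <- c(
  "expressive_language", "eye_contact", "joint_attention_pointing",
  "stereotyped_speech", "spontaneous_gestures", "indicates_pleasure",
  "social_overtures", "complex_mannerisms", "stereotyped_interests"
)

.adtree7_names <- c(
  "expressive_language", "understands_language", "eye_contact",
  "developmental_delay", "social_participation", "pretend_play",
  "indicates_pleasure"
)

.extra_names <- c(
  "social_smile", "pointing", "showing", "imitates_actions", "echolalia",
  "speech_patterns", "communicative_engagement", "calls_attention_to_objects",
  "amount_social_overtures", "descriptive_gestures", "response_to_name",
  "shared_enjoyment", "facial_expressions", "unusual_sensory_interests",
  "repetitive_behaviors", "frustration_tolerance", "attention_span"
)

.reserved_columns <- c("subject_id", "rater_id", "label", "age_group", "gender")

#' Construct a feature set
#'
#' A feature set names the ordinal features of a scoresheet, the maximum
#' ordinal value of each (items are scored from 0, typical behavior, to 3
#' or 4, severely atypical), and which subset a classifier consumes
#' (its *model features*, size `n`, drawn from the expanded set of size
#' `n*`).
#'
#' @param names character vector of feature identifiers (no duplicates).
#' @param domain_max per-feature maximum ordinal value; a scalar is
#'   recycled, a named vector is matched by feature name.
#' @param model_features subset of `names` used by a classifier.
#' @return An object of class `feature_set`.
#' @examples
#' fs <- feature_set(c("a", "b", "c"), domain_max = 3, model_features = c("a", "b"))
#' fs$domain_max
#' @export
feature_set <- function(names, domain_max = 4, model_features = names) {
  if (anyDuplicated(names)) stop("duplicate feature names")
  if (length(domain_max) == 1L) {
    domain_max <- stats::setNames(rep(as.numeric(domain_max), length(names)), names)
  }
  if (is.null(names(domain_max)) || !all(names %in% names(domain_max))) {
    stop("domain_max must be a scalar or a named vector covering every feature")
  }
  domain_max <- domain_max[names]
  if (any(domain_max < 1) || any(domain_max != round(domain_max))) {
    stop("domain_max values must be positive integers")
  }
  if (!all(model_features %in% names)) {
    stop("model_features must be a subset of names")
  }
  if (any(names %in% .reserved_columns)) {
    stop("feature names may not collide with reserved columns: ",
         paste(intersect(names, .reserved_columns), collapse = ", "))
  }
  structure(
    list(names = names, domain_max = domain_max,
         model_features = model_features),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features (%d model features)\n",
              length(x$names), length(x$model_features)))
  invisible(x)
}

#' The nine LR9 model features
#'
#' Feature names of the published 9-feature logistic-regression autism
#' classifier (ADOS-derived items, scored 0-3).
#' @return Character vector of length 9.
#' @export
lr9_features <- function() .lr9_names

#' The seven ADTree7 model features
#'
#' Feature names of the published 7-feature alternating-decision-tree
#' autism classifier (ADI-R-derived items, scored 0-4; the three features
#' shared with LR9 keep their 0-3 scale here).
#' @return Character vector of length 7.
#' @export
adtree7_features <- function() .adtree7_names

#' Default 30-feature questionnaire
#'
#' The full behavioral questionnaire scored by raters: the union of the
#' LR9 and ADTree7 model features (13 items) plus 17 further behavioral
#' items that serve as replacement candidates. LR9 items use a 0-3 scale,
#' all others 0-4.
#'
#' @param model which classifier's features to mark as model features:
#'   `"adtree"` (7), `"logistic"` (9) or `"all"`.
#' @return A [feature_set] with 30 features.
#' @examples
#' fs <- default_feature_set("logistic")
#' length(fs$names)
#' fs$model_features
#' @export
default_feature_set <- function(model = c("adtree", "logistic", "all")) {
  model <- match.arg(model)
  all_names <- unique(c(.lr9_names, .adtree7_names, .extra_names))
  dmax <- stats::setNames(ifelse(all_names %in% .lr9_names, 3, 4), all_names)
  mf <- switch(model,
    adtree = .adtree7_names,
    logistic = .lr9_names,
    all = all_names
  )
  feature_set(all_names, dmax, mf)
}
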