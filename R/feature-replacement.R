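# Feature replacement: fill a missing model feature by copying the value
# of its "closest" feature from the expanded feature set. The map from
# model feature to ranked substitutes is either computed once on the whole
# training table (general) or rebuilt per record on the training records
# most similar to it (dynamic). This substitutes -- rather than adds -- a
# question a rater could not answer.

#' Closeness score between two feature columns
#'
#' Computed over pairwise-complete records only. All three scores orient
#' so that larger means a better substitute: `"correlation"` is the
#' Spearman rank correlation; `"nearest_neighbor"` is the negative
#' root-mean-square difference (Euclidean distance scaled to be
#' comparable across overlaps); `"mutual_information"` is the plugin
#' (maximum-likelihood) mutual information of the joint ordinal
#' histogram, in nats.
#'
#' @param x,y numeric feature columns of equal length; `NA` = missing.
#' @param method `"correlation"`, `"nearest_neighbor"` or
#'   `"mutual_information"`.
#' @param min_overlap minimum number of pairwise-complete records; below
#'   it (or when the score is undefined, e.g. Spearman with a constant
#'   column) `NA` is returned and the candidate is skipped.
#' @return A single score, or `NA`.
#' @examples
#' pair_score(c(0, 1, 2, 3), c(3, 2, 1, 0), "correlation", min_overlap = 2)
#' @export
pair_score <- function(x, y,
                       method = c("correlation", "nearest_neighbor",
                                  "mutual_information"),
                       min_overlap = 30) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  switch(method,
    correlation = suppressWarnings(stats::cor(x, y, method = "spearman")),
    nearest_neighbor = -sqrt(mean((x - y)^2)),
    mutual_information = {
      joint <- table(x, y)
      pxy <- joint / sum(joint)
      px <- rowSums(pxy); py <- colSums(pxy)
      terms <- pxy * log(pxy / outer(px, py))
      sum(terms[pxy > 0])
    }
  )
}

.score_method <- function(method) {
  switch(method,
    corr = "correlation", nn = "nearest_neighbor", mi = "mutual_information",
    method)
}

#' Build a general replacement map
#'
#' For each model feature, every other feature of the expanded training
#' table is scored with [pair_score()] and ranked by descending score
#' (ties keep the table's column order). The map is deterministic given
#' the training table.
#'
#' @param train the expanded [rating_table] (model features plus
#'   candidates).
#' @param model_features features the classifier consumes.
#' @param method `"correlation"`, `"nearest_neighbor"` or
#'   `"mutual_information"` (short forms `"corr"`, `"nn"`, `"mi"` also
#'   accepted).
#' @param min_overlap minimum pairwise-complete overlap for scoring.
#' @param exclude_model if `TRUE`, other model features are excluded from
#'   the candidate pool (by default they are allowed: the pool is every
#'   expanded feature except the target itself).
#' @return An object of class `replacement_map`: per model feature, a
#'   data frame of candidates and scores, sorted by descending score.
#' @export
build_general_map <- function(train, model_features,
                              method = c("correlation", "nearest_neighbor",
                                         "mutual_information"),
                              min_overlap = 30, exclude_model = FALSE) {
  method <- .score_method(match.arg(method, c("correlation",
                                              "nearest_neighbor",
                                              "mutual_information",
                                              "corr", "nn", "mi")))
  fs <- train$features
  stopifnot(all(model_features %in% fs$names))
  if (length(fs$names) <= length(model_features) && !exclude_model &&
      length(fs$names) < 2) {
    stop("expanded table must contain at least one candidate feature")
  }
  targets <- stats::setNames(vector("list", length(model_features)),
                             model_features)
  for (f in model_features) {
    pool <- setdiff(fs$names, f)
    if (exclude_model) pool <- setdiff(pool, model_features)
    if (!length(pool)) stop("no candidate features for '", f, "'")
    s <- vapply(pool, function(g) {
      pair_score(train$values[, f], train$values[, g], method, min_overlap)
    }, numeric(1))
    keep <- !is.na(s)
    if (!any(keep)) {
      stop("unmappable feature '", f,
           "': no candidate reaches the minimum overlap")
    }
    ord <- order(-s[keep])  # stable: ties keep column order
    targets[[f]] <- data.frame(candidate = pool[keep][ord],
                               score = unname(s[keep][ord]),
                               stringsAsFactors = FALSE)
  }
  structure(
    list(method = method, targets = targets,
         provenance = list(type = "general"), min_overlap = min_overlap),
    class = "replacement_map"
  )
}

#' @export
print.replacement_map <- function(x, ...) {
  cat(sprintf("<replacement_map> method=%s (%s), %d model features\n",
              x$method, x$provenance$type, length(x$targets)))
  for (f in names(x$targets)) {
    top <- x$targets[[f]][1, ]
    cat(sprintf("  %s -> %s (s = %.3f)\n", f, top$candidate, top$score))
  }
  invisible(x)
}

#' Export a replacement map as a data frame
#'
#' One row per (model feature, candidate) pair with rank and score --
#' the question-substitution audit trail.
#'
#' @param x a `replacement_map`.
#' @param row.names,optional,... ignored.
#' @return A data frame with columns `feature`, `rank`, `candidate`,
#'   `score`.
#' @export
as.data.frame.replacement_map <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  do.call(rbind, lapply(names(x$targets), function(f) {
    d <- x$targets[[f]]
    data.frame(feature = f, rank = seq_len(nrow(d)), candidate = d$candidate,
               score = d$score, stringsAsFactors = FALSE)
  }))
}

#' Fill one record's missing model features from a replacement map
#'
#' Each missing model feature takes the record's own value of the
#' highest-ranked candidate that is observed in the record, clipped to
#' the target feature's domain when domains differ; if no ranked
#' candidate is observed, the fallback fill constant is used. Observed
#' entries are never touched, and the number of filled features equals
#' the number of missing model features (replacement substitutes, it
#' never adds).
#'
#' @param record named numeric vector of the record's feature values
#'   (`NA` = missing).
#' @param map a `replacement_map` covering the model features.
#' @param features the [feature_set] (for domain clipping).
#' @param model_features features the classifier consumes.
#' @param fallback a `univariate_imputer` used when every candidate is
#'   missing too; omit only if that case cannot arise.
#' @return The record with no missing value among the model features.
#' @export
apply_replacement <- function(record, map, features, model_features,
                              fallback = NULL) {
  stopifnot(all(model_features %in% names(map$targets)))
  for (f in model_features) {
    if (!is.na(record[[f]])) next
    filled <- NA_real_
    for (cand in map$targets[[f]]$candidate) {
      v <- record[[cand]]
      if (!is.na(v)) { filled <- v; break }
    }
    if (is.na(filled)) {
      if (is.null(fallback)) {
        stop("no observed candidate for '", f, "' and no fallback imputer")
      }
      filled <- fallback$constants[[f]]
    }
    record[[f]] <- clip(filled, 0, features$domain_max[[f]])
  }
  record
}

#' Apply a general replacement map to every record of a table
#'
#' @param table a [rating_table].
#' @param map a `replacement_map`.
#' @param model_features features the classifier consumes.
#' @param fallback a `univariate_imputer` (see [apply_replacement()]).
#' @return The completed [rating_table].
#' @export
apply_replacement_table <- function(table, map, model_features,
                                    fallback = NULL) {
  vals <- table$values
  mf_missing <- which(rowSums(is.na(vals[, model_features, drop = FALSE])) > 0)
  for (i in mf_missing) {
    vals[i, ] <- apply_replacement(vals[i, ], map, table$features,
                                   model_features, fallback)
  }
  set_values(table, vals)
}

#' Build a dynamic (per-record) replacement map
#'
#' Selects the `k` training records nearest to the test record --
#' Euclidean distance over the test record's observed features, averaged
#' over the features also observed in each training record -- and builds
#' the general map on that subset, so the substitute question adapts to
#' the record at hand. With `k` equal to the full training size the
#' result is identical to [build_general_map()].
#'
#' @param record named numeric vector with at least one observed feature
#'   shared with the training table.
#' @param train the expanded training [rating_table].
#' @param model_features features the classifier consumes.
#' @param method replacement score, as in [build_general_map()].
#' @param k neighborhood size; default `max(50, 5%` of training
#'   records`)`. If fewer training records exist, all are used with a
#'   warning.
#' @param min_overlap minimum pairwise-complete overlap for scoring,
#'   capped at `k / 2` so small neighborhoods degrade instead of
#'   failing.
#' @param targets model features to map; default all. (Filling a record
#'   only needs maps for its missing features.)
#' @param subject_id optional provenance tag.
#' @return A `replacement_map` with dynamic provenance.
#' @export
build_dynamic_map <- function(record, train, model_features,
                              method = c("correlation", "nearest_neighbor",
                                         "mutual_information"),
                              k = NULL, min_overlap = 30, targets = NULL,
                              subject_id = NULL) {
  fs <- train$features
  n <- n_records(train)
  k <- as.integer(k %||% max(50, ceiling(0.05 * n)))
  if (k < 2) stop("k must be >= 2")
  if (k > n) {
    warning("fewer than k training records; using all ", n)
    k <- n
  }
  obs_f <- intersect(fs$names, names(record)[!is.na(record)])
  if (!length(obs_f)) stop("record shares no observed feature with train")
  R <- train$values[, obs_f, drop = FALSE]
  diff2 <- sweep(R, 2, record[obs_f])^2
  cnt <- rowSums(!is.na(diff2))
  d <- rowSums(diff2, na.rm = TRUE) / cnt
  d[cnt == 0] <- Inf
  sel <- sort(order(d)[seq_len(k)])  # sorted so k = n reproduces general
  sub <- train[sel]
  # small neighborhoods cannot honour the global overlap floor; cap it at
  # half the subset so dynamic maps degrade instead of failing
  eff_overlap <- max(2L, min(min_overlap, k %/% 2L))
  map <- build_general_map(sub, targets %||% model_features, method,
                           min_overlap = eff_overlap)
  map$provenance <- list(type = "dynamic", subject_id = subject_id, k = k)
  map
}

#' Dynamically fill every record of a table
#'
#' Builds, for each record with missing model features, a per-record map
#' via [build_dynamic_map()] (targeting just its missing features) and
#' applies it. Identical records get identical maps.
#'
#' @inheritParams build_dynamic_map
#' @param table the [rating_table] to complete.
#' @param fallback a `univariate_imputer` (see [apply_replacement()]).
#' @return The completed [rating_table].
#' @export
dynamic_replace_table <- function(table, train, model_features,
                                  method = c("correlation",
                                             "nearest_neighbor",
                                             "mutual_information"),
                                  k = NULL, min_overlap = 30,
                                  fallback = NULL) {
  vals <- table$values
  mf_missing <- which(rowSums(is.na(vals[, model_features, drop = FALSE])) > 0)
  for (i in mf_missing) {
    rec <- vals[i, ]
    miss <- model_features[is.na(rec[model_features])]
    map <- tryCatch(
      build_dynamic_map(rec, train, model_features, method, k = k,
                        min_overlap = min_overlap, targets = miss,
                        subject_id = table$subject_id[i]),
      error = function(e) NULL)
    if (is.null(map)) {
      # no scorable candidate even in the neighborhood: univariate fallback
      if (is.null(fallback)) stop("unmappable record and no fallback imputer")
      for (f in miss) {
        rec[[f]] <- clip(fallback$constants[[f]], 0,
                         table$features$domain_max[[f]])
      }
      vals[i, ] <- rec
    } else {
      vals[i, ] <- apply_replacement(rec, map, table$features, miss, fallback)
    }
  }
  set_values(table, vals)
}
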