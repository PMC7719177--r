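# The rating table: records x ordinal features with explicit missing
# entries (NA), class labels and per-record metadata. This is the
# universal exchange object between the simulator, the imputers, the
# replacement methods and the evaluation harness.

#' Construct a rating table
#'
#' @param values numeric matrix or data frame, records x features; `NA`
#'   marks a missing entry. Column names must match `features$names`
#'   (column order is taken from the feature set).
#' @param features a [feature_set]; if `NULL`, one is inferred from the
#'   column names with `domain_max` set to the largest observed value
#'   per feature (at least 1).
#' @param label per-record class, `"ASD"` or `"NT"` (may be `NA` at
#'   prediction time).
#' @param subject_id,rater_id per-record identifiers; records sharing a
#'   `subject_id` are repeated ratings of the same subject and must carry
#'   identical label and metadata.
#' @param age_group,gender per-record metadata (`"1-3"`/`"4-6"`,
#'   `"F"`/`"M"`); defaults to `NA`.
#' @return An object of class `rating_table`.
#' @examples
#' fs <- feature_set(c("a", "b"), 3)
#' rt <- rating_table(matrix(c(0, 1, NA, 2), 2, 2,
#'                           dimnames = list(NULL, c("a", "b"))),
#'                    features = fs, label = c("ASD", "NT"))
#' missing_count(rt)
#' @export
rating_table <- function(values, features = NULL, label = NULL,
                         subject_id = NULL, rater_id = NULL,
                         age_group = NULL, gender = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("values must have feature column names")
  n <- nrow(values)
  if (is.null(features)) {
    dmax <- apply(values, 2, function(v) {
      if (all(is.na(v))) 4 else max(1, max(v, na.rm = TRUE))
    })
    features <- feature_set(colnames(values), dmax)
  }
  if (!setequal(colnames(values), features$names)) {
    stop("value columns do not match the feature set")
  }
  values <- values[, features$names, drop = FALSE]
  fill <- function(x, default) {
    if (is.null(x)) {
      if (length(default) == 1L) rep(default, n) else default
    } else {
      if (length(x) == 1L) x <- rep(x, n)
      stopifnot(length(x) == n)
      as.character(x)
    }
  }
  tab <- structure(
    list(
      features = features,
      values = values,
      label = fill(label, NA_character_),
      subject_id = fill(subject_id, as.character(seq_len(max(n, 1)))[seq_len(n)]),
      rater_id = fill(rater_id, "R1"),
      age_group = fill(age_group, NA_character_),
      gender = fill(gender, NA_character_)
    ),
    class = "rating_table"
  )
  validate_rating_table(tab)
  tab
}

#' Validate a rating table
#'
#' Checks that every non-missing value lies within its feature's ordinal
#' domain (and, optionally, on the integer grid -- imputed tables carry
#' reals) and that repeated ratings of a subject agree on label and
#' metadata.
#'
#' @param x a [rating_table].
#' @param require_integer if `TRUE`, non-integer values are rejected.
#' @return `x`, invisibly; errors describe the offending feature/record.
#' @export
validate_rating_table <- function(x, require_integer = FALSE) {
  stopifnot(inherits(x, "rating_table"))
  n <- nrow(x$values)
  for (col in c("label", "subject_id", "rater_id", "age_group", "gender")) {
    if (length(x[[col]]) != n) {
      stop(sprintf("%s has length %d, expected %d", col, length(x[[col]]), n))
    }
  }
  dmax <- x$features$domain_max
  for (f in x$features$names) {
    v <- x$values[, f]
    bad <- which(!is.na(v) & (v < 0 | v > dmax[[f]]))
    if (length(bad)) {
      stop(sprintf("value %g outside [0, %d] for feature '%s' at record %d",
                   v[bad[1]], as.integer(dmax[[f]]), f, bad[1]))
    }
    if (require_integer) {
      nonint <- which(!is.na(v) & v != round(v))
      if (length(nonint)) {
        stop(sprintf("non-integer value %g for feature '%s' at record %d",
                     v[nonint[1]], f, nonint[1]))
      }
    }
  }
  for (s in unique(x$subject_id)) {
    idx <- which(x$subject_id == s)
    for (col in c("label", "age_group", "gender")) {
      u <- unique(x[[col]][idx])
      if (length(u) > 1L) {
        stop(sprintf("subject '%s' has inconsistent %s", s, col))
      }
    }
  }
  invisible(x)
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf(
    "<rating_table> %d records, %d subjects, %d features, %d missing entries\n",
    n_records(x), length(unique(x$subject_id)), length(x$features$names),
    missing_count(x)))
  invisible(x)
}

#' Number of records in a rating table
#' @param x a [rating_table].
#' @return integer record count.
#' @export
n_records <- function(x) nrow(x$values)

#' Count of missing entries in a rating table
#' @param x a [rating_table].
#' @param features optional subset of features to count over.
#' @return integer number of `NA` cells.
#' @export
missing_count <- function(x, features = NULL) {
  v <- if (is.null(features)) x$values else x$values[, features, drop = FALSE]
  sum(is.na(v))
}

#' Subset records of a rating table
#' @param x a [rating_table].
#' @param i record indices (integer or logical).
#' @param ... unused.
#' @return A [rating_table] with the selected records.
#' @export
`[.rating_table` <- function(x, i, ...) {
  out <- x
  out$values <- x$values[i, , drop = FALSE]
  for (col in c("label", "subject_id", "rater_id", "age_group", "gender")) {
    out[[col]] <- x[[col]][i]
  }
  out
}

#' @export
as.data.frame.rating_table <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id, rater_id = x$rater_id, label = x$label,
    age_group = x$age_group, gender = x$gender,
    as.data.frame(x$values, optional = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

# replace the value grid, keeping metadata
set_values <- function(x, values) {
  stopifnot(identical(dim(values), dim(x$values)))
  x$values <- values
  x
}

#' Read a rating table from a scoresheet CSV
#'
#' The header names the features plus any of the reserved columns
#' `subject_id`, `rater_id`, `label`, `age_group`, `gender`. An empty
#' cell or the token `NA` (case-insensitive) marks a missing entry;
#' nothing else is silently coerced.
#'
#' @param path CSV file path.
#' @param features a [feature_set] giving the schema, or `NULL` to infer
#'   one from the file (domains from the observed maxima).
#' @param require_integer reject non-integer values (default `TRUE`;
#'   set `FALSE` to read back imputed tables).
#' @return A [rating_table].
#' @examples
#' fs <- feature_set(c("a", "b"), 3)
#' rt <- rating_table(matrix(c(0, 1, NA, 2), 2, 2,
#'                           dimnames = list(NULL, c("a", "b"))), fs)
#' p <- tempfile(fileext = ".csv")
#' write_rating_table(rt, p)
#' rt2 <- read_rating_table(p, fs)
#' missing_count(rt2)
#' @export
read_rating_table <- function(path, features = NULL, require_integer = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  cols <- names(raw)
  feat_cols <- setdiff(cols, .reserved_columns)
  if (!is.null(features)) {
    missing_feats <- setdiff(features$names, cols)
    if (length(missing_feats)) {
      stop("file lacks features: ", paste(missing_feats, collapse = ", "))
    }
    feat_cols <- features$names
  }
  if (!length(feat_cols)) stop("no feature columns found in ", path)
  n <- nrow(raw)
  vals <- matrix(NA_real_, n, length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (f in feat_cols) {
    cell <- trimws(raw[[f]])
    is_miss <- cell == "" | tolower(cell) == "na"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error at line %d, feature '%s': cannot read '%s'",
                   bad[1] + 1L, f, cell[bad[1]]))
    }
    num[is_miss] <- NA_real_
    vals[, f] <- num
  }
  get_col <- function(nm) if (nm %in% cols) {
    v <- trimws(raw[[nm]])
    v[v == "" | tolower(v) == "na"] <- NA_character_
    v
  } else NULL
  tab <- rating_table(
    vals, features = features,
    label = get_col("label"), subject_id = get_col("subject_id"),
    rater_id = get_col("rater_id"), age_group = get_col("age_group"),
    gender = get_col("gender")
  )
  validate_rating_table(tab, require_integer = require_integer)
  tab
}

#' Write a rating table to a scoresheet CSV
#'
#' Missing entries are written as empty cells; columns follow the feature
#' set order, preceded by the reserved metadata columns. `write` then
#' `read` is the identity on valid tables.
#'
#' @param table a [rating_table].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_rating_table <- function(table, path) {
  validate_rating_table(table)
  df <- as.data.frame(table)
  # keep integers unadorned so round-trips are exact
  for (f in table$features$names) {
    v <- df[[f]]
    if (all(is.na(v) | v == round(v))) df[[f]] <- as.integer(round(v))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
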