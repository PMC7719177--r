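# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Most frequent value
#'
#' Mode of a vector after dropping `NA`s; ties are broken toward the
#' smallest value so the statistic is deterministic.
#'
#' @param x numeric vector.
#' @return The most frequent value, or `NA` if nothing is observed.
#' @examples
#' stat_mode(c(2, 2, 3, NA))
#' stat_mode(c(0, 1))  # tie -> 0
#' @export
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Map class labels to the 0/1 coding used everywhere downstream:
# ASD (the screening-positive class) = 1, NT = 0.
label_to_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1 (ASD = 1, NT = 0)")
    }
    return(as.integer(labels))
  }
  out <- ifelse(labels == "ASD", 1L, ifelse(labels == "NT", 0L, NA_integer_))
  if (anyNA(out)) stop("labels must be 'ASD' or 'NT'")
  out
}
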