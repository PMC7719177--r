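# Alternating decision tree trained by boosting (ADTree7-style non-linear
# classifier): a root prediction plus precondition-gated splitter rules
# whose scores sum to a margin; sign of the margin is the class.

#' Fit an alternating decision tree
#'
#' Standard boosting induction. With uniform initial example weights the
#' root score is `0.5 * ln(W+ / W-)`. Each round adds one rule at the
#' (precondition, feature, threshold) triple minimising the boosting
#' impurity `Z = 2 * (sqrt(W+(p,c) W-(p,c)) + sqrt(W+(p,!c) W-(p,!c))) +
#' W(!p)` over candidate thresholds (midpoints of sorted observed
#' values); rule scores are `0.5 * ln` of the weight ratios with +1
#' smoothing, and example weights update multiplicatively. Ties in the
#' greedy search break by (precondition, feature, threshold) order, so
#' the fit is deterministic.
#'
#' @param X numeric feature matrix (no missing values).
#' @param y labels (`"ASD"`/`"NT"` or 0/1); both classes must be present.
#' @param n_rounds number of boosting rounds (>= 0); with 0 rounds the
#'   model predicts the root sign everywhere.
#' @param smoothing additive smoothing of the score weight ratios.
#' @return An object of class `adtree_model`: `root_score`, a `rules`
#'   data frame (`precondition`, `feature`, `threshold`, `score_true`,
#'   `score_false`) and the feature names. Precondition 1 is the root;
#'   rule `r` contributes preconditions `2r` (condition true) and
#'   `2r + 1` (condition false).
#' @examples
#' X <- matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
#' m <- fit_adtree(X, c(0, 0, 1, 1), n_rounds = 1)
#' predict_score(m, X)
#' @export
fit_adtree <- function(X, y, n_rounds = 5, smoothing = 1) {
  X <- as.matrix(X)
  y <- label_to_binary(y)
  if (length(unique(y)) < 2) stop("single-class y: cannot fit")
  if (anyNA(X)) stop("X contains missing values; impute or replace first")
  stopifnot(n_rounds >= 0)
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  w <- rep(1, n)
  root <- 0.5 * log(sum(w[yy > 0]) / sum(w[yy < 0]))
  if (n_rounds == 0 && abs(root) < 1e-12) {
    warning("n_rounds = 0 with balanced classes: margin is 0 everywhere")
  }
  w <- w * exp(-yy * root)
  thresholds <- lapply(seq_len(ncol(X)), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) numeric(0) else (u[-1] + u[-length(u)]) / 2
  })
  pre <- matrix(TRUE, n, 1)  # column 1 = root precondition
  rules <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    best <- NULL; bestZ <- Inf
    Wtot <- sum(w)
    for (pi in seq_len(ncol(pre))) {
      p <- pre[, pi]
      if (!any(p)) next
      wp <- w[p]; yp <- yy[p]
      Wnotp <- Wtot - sum(wp)
      for (j in seq_len(ncol(X))) {
        xj <- X[p, j]
        for (t in thresholds[[j]]) {
          cc <- xj <= t
          Wcp <- sum(wp[cc & yp > 0]); Wcn <- sum(wp[cc & yp < 0])
          Wnp <- sum(wp[!cc & yp > 0]); Wnn <- sum(wp[!cc & yp < 0])
          Z <- 2 * (sqrt(Wcp * Wcn) + sqrt(Wnp * Wnn)) + Wnotp
          if (Z < bestZ - 1e-12) {
            bestZ <- Z
            best <- list(pi = pi, j = j, t = t,
                         s_t = 0.5 * log((Wcp + smoothing) / (Wcn + smoothing)),
                         s_f = 0.5 * log((Wnp + smoothing) / (Wnn + smoothing)))
          }
        }
      }
    }
    if (is.null(best)) { rules <- rules[seq_len(r - 1)]; break }
    p <- pre[, best$pi]
    cond <- X[, best$j] <= best$t
    contrib <- ifelse(cond, best$s_t, best$s_f)
    w[p] <- w[p] * exp(-yy[p] * contrib[p])
    pre <- cbind(pre, p & cond, p & !cond)
    rules[[r]] <- data.frame(
      precondition = best$pi, feature = colnames(X)[best$j],
      threshold = best$t, score_true = best$s_t, score_false = best$s_f,
      stringsAsFactors = FALSE)
  }
  rules <- if (length(rules)) do.call(rbind, rules) else
    data.frame(precondition = integer(0), feature = character(0),
               threshold = numeric(0), score_true = numeric(0),
               score_false = numeric(0))
  structure(
    list(root_score = root, rules = rules, n_rounds = nrow(rules),
         features = colnames(X)),
    class = "adtree_model"
  )
}

#' @export
print.adtree_model <- function(x, ...) {
  cat(sprintf("<adtree_model> root %.4f, %d rules over %d features\n",
              x$root_score, nrow(x$rules), length(x$features)))
  invisible(x)
}

#' @export
predict_score.adtree_model <- function(model, X, ...) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  if (anyNA(X)) stop("X contains missing values; impute or replace first")
  m <- nrow(X)
  margin <- rep(model$root_score, m)
  pre <- matrix(TRUE, m, 1)
  if (nrow(model$rules)) {
    for (r in seq_len(nrow(model$rules))) {
      rule <- model$rules[r, ]
      p <- pre[, rule$precondition]
      cond <- X[, rule$feature] <= rule$threshold
      margin[p] <- margin[p] +
        ifelse(cond[p], rule$score_true, rule$score_false)
      pre <- cbind(pre, p & cond, p & !cond)
    }
  }
  margin
}

#' Serialize a fitted model to JSON
#'
#' Writes the documented JSON schema: logistic models store intercept,
#' weights and `C`; ADTrees store the root score and the rule list.
#'
#' @param model a `logistic_model` or `adtree_model`.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "logistic_model")) {
    list(type = "logistic", intercept = model$intercept,
         weights = as.list(model$weights), C = model$C)
  } else if (inherits(model, "adtree_model")) {
    list(type = "adtree", root_score = model$root_score,
         rules = model$rules, features = model$features)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a serialized model
#'
#' @param path a `.json` file written by [write_model()].
#' @return The model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "logistic") {
    structure(list(intercept = obj$intercept,
                   weights = unlist(obj$weights), C = obj$C),
              class = "logistic_model")
  } else if (obj$type == "adtree") {
    rules <- as.data.frame(obj$rules, stringsAsFactors = FALSE)
    structure(list(root_score = obj$root_score, rules = rules,
                   n_rounds = nrow(rules), features = obj$features),
              class = "adtree_model")
  } else stop("unknown model type: ", obj$type)
}
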