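# L2-penalised logistic regression (LR9-style linear classifier).

#' Fit an L2-penalised logistic regression
#'
#' Maximises the binomial log-likelihood minus `||w||^2 / (2C)` (the
#' intercept is not penalised) by Newton iterations; deterministic given
#' the inputs. `C` is the inverse regularization strength; small `C`
#' shrinks the weights toward 0 and the score toward the class-prior
#' logit.
#'
#' @param X numeric feature matrix (no missing values).
#' @param y labels (`"ASD"`/`"NT"` or 0/1); both classes must be present.
#' @param C inverse regularization strength (> 0).
#' @param tol convergence tolerance on the max absolute gradient.
#' @param max_iter Newton iteration cap.
#' @return An object of class `logistic_model` with `weights`,
#'   `intercept` and `C`.
#' @examples
#' X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
#' m <- fit_logistic(X, c(0, 0, 1, 1), C = 100)
#' predict_score(m, X)
#' @export
fit_logistic <- function(X, y, C = 1, tol = 1e-6, max_iter = 100) {
  X <- as.matrix(X)
  y <- label_to_binary(y)
  if (length(unique(y)) < 2) stop("single-class y: cannot fit")
  stopifnot(C > 0)
  if (anyNA(X)) stop("X contains missing values; impute or replace first")
  n <- nrow(X); p <- ncol(X)
  Xt <- cbind(`(Intercept)` = 1, X)
  lambda <- 1 / C
  beta <- numeric(p + 1)
  pen <- c(0, rep(lambda, p))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xt %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Xt, mu - y)) + pen * beta
    if (max(abs(g)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xt * w, Xt) + diag(pen, p + 1)
    beta <- beta - solve(H + diag(1e-10, p + 1), g)
  }
  structure(
    list(intercept = unname(beta[1]),
         weights = stats::setNames(beta[-1], colnames(X)), C = C),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %d features, C = %g\n",
              length(x$weights), x$C))
  invisible(x)
}

#' Continuous classifier score
#'
#' Logistic models return the class probability in (0, 1); alternating
#' decision trees return the additive margin. Both are monotone in the
#' decision function. `X` must be complete on the model features:
#' imputation or replacement must run first.
#'
#' @param model a fitted `logistic_model` or `adtree_model`.
#' @param X numeric feature matrix with the model's feature columns.
#' @param ... unused.
#' @return Numeric score vector.
#' @export
predict_score <- function(model, X, ...) UseMethod("predict_score")

#' @export
predict_score.logistic_model <- function(model, X, ...) {
  X <- as.matrix(X)[, names(model$weights), drop = FALSE]
  if (anyNA(X)) stop("X contains missing values; impute or replace first")
  stats::plogis(model$intercept + drop(X %*% model$weights))
}

#' Binary class prediction
#'
#' @param model a fitted `logistic_model` or `adtree_model`.
#' @param X numeric feature matrix.
#' @param threshold decision threshold on the score; defaults to 0.5
#'   (probability) for logistic models and 0 (margin) for ADTrees.
#' @return Integer vector, 1 = ASD, 0 = NT.
#' @export
predict_label <- function(model, X, threshold = NULL) {
  s <- predict_score(model, X)
  thr <- threshold %||% if (inherits(model, "logistic_model")) 0.5 else 0
  as.integer(s >= thr)
}
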