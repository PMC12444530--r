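# Linear QSPR models: fixed-coefficient multilinear predictor, ordinary
# least squares, ridge (intercept unpenalized) and Huber robust regression.

.EQ13 <- c(estrada = 90, wiener = -1.0789, gutman = 0.2822)
.EQ13_INTERCEPT <- -417.6882

new_qspr_linear <- function(coefficients, intercept, kind, extra = list()) {
  structure(c(list(coefficients = coefficients, intercept = intercept,
                   kind = kind), extra),
            class = "qspr_linear")
}

#' @export
print.qspr_linear <- function(x, ...) {
  cat(sprintf("QSPR linear model (%s)\n", x$kind))
  cat(sprintf("  intercept: %.6g\n", x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-12s %.6g\n", nm, x$coefficients[[nm]]))
  invisible(x)
}

#' @export
coef.qspr_linear <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

.model_matrix <- function(newdata, feature_names) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, feature_names))
  x <- as.matrix(as.data.frame(newdata))
  missing <- setdiff(feature_names, colnames(x))
  if (length(missing) > 0L)
    stop(sprintf("missing feature column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  x[, feature_names, drop = FALSE]
}

#' @export
predict.qspr_linear <- function(object, newdata, ...) {
  x <- .model_matrix(newdata, names(object$coefficients))
  as.numeric(object$intercept + x %*% object$coefficients)
}

#' Fixed-coefficient multilinear enthalpy predictor
#'
#' The three-index multiple linear regression combining the Estrada,
#' Wiener and Gutman indices:
#' \deqn{-\Delta_c H^\circ = 90\,EE - 1.0789\,W + 0.2822\,Gut - 417.6882}
#' (kJ/mol).  Coefficients are fixed constants, not refit.
#'
#' @param v a named vector / list / data.frame with \code{estrada},
#'   \code{wiener}, \code{gutman} columns
#' @return predicted \eqn{-\Delta_c H^\circ} in kJ/mol.
#' @examples
#' eq13_predict(c(estrada = 0, wiener = 0, gutman = 0))  # the intercept
#' @export
eq13_predict <- function(v) {
  predict(eq13_model(), v)
}

#' @rdname eq13_predict
#' @return \code{eq13_model()} returns the same predictor as a
#'   \code{qspr_linear} object with \code{kind = "fixed"}.
#' @export
eq13_model <- function() {
  new_qspr_linear(.EQ13, .EQ13_INTERCEPT, "fixed")
}

.as_xy <- function(X, y) {
  x <- as.matrix(as.data.frame(X))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (nrow(x) != length(y))
    stop("X and y dimensions disagree", call. = FALSE)
  list(x = x, y = as.numeric(y))
}

#' Ordinary least squares fit
#'
#' @param X numeric matrix or data.frame of predictors
#' @param y numeric response (positive enthalpy magnitudes, kJ/mol)
#' @return a \code{qspr_linear} model of kind \code{"ols"}.
#' @export
ols_fit <- function(X, y) {
  d <- .as_xy(X, y)
  if (nrow(d$x) < ncol(d$x) + 1L)
    stop("OLS needs at least p + 1 rows", call. = FALSE)
  xa <- cbind(`(Intercept)` = 1, d$x)
  fit <- lm.fit(xa, d$y)
  if (fit$rank < ncol(xa))
    stop("rank-deficient design: singular normal equations", call. = FALSE)
  new_qspr_linear(fit$coefficients[-1L], unname(fit$coefficients[1L]), "ols")
}

#' Ridge regression fit (intercept unpenalized)
#'
#' Minimizes \eqn{\|y - b_0 - Xb\|^2 + \alpha \|b\|^2}.  Predictors are
#' used on their given scale (z-score them first for comparable
#' penalization across features).
#'
#' @inheritParams ols_fit
#' @param alpha nonnegative L2 penalty weight (default 1)
#' @return a \code{qspr_linear} model of kind \code{"ridge"}.
#' @export
ridge_fit <- function(X, y, alpha = 1) {
  stopifnot(alpha >= 0)
  d <- .as_xy(X, y)
  xm <- colMeans(d$x); ym <- mean(d$y)
  xc <- sweep(d$x, 2L, xm)
  p <- ncol(xc)
  beta <- tryCatch(
    solve(crossprod(xc) + diag(alpha, p), crossprod(xc, d$y - ym)),
    error = function(e)
      stop("rank-deficient design: singular penalized normal equations",
           call. = FALSE))
  beta <- as.numeric(beta)
  names(beta) <- colnames(d$x)
  new_qspr_linear(beta, ym - sum(xm * beta), "ridge",
                  extra = list(alpha = alpha))
}

#' Huber robust regression fit
#'
#' Minimizes the Huber loss -- quadratic for standardized residuals below
#' the switch point \code{epsilon}, linear beyond it -- plus an L2 penalty
#' \code{alpha} on the coefficients (intercept unpenalized).  Solved by
#' iteratively reweighted least squares; the residual scale is
#' re-estimated each iteration as MAD/0.6745, so \code{epsilon} acts on
#' the studentized-residual scale.
#'
#' @inheritParams ols_fit
#' @param epsilon residual-scale switch point (>= 1; default 1.35)
#' @param alpha L2 penalty weight (default 0.0001)
#' @param tol coefficient-change convergence tolerance
#' @param max_iter iteration cap
#' @return a \code{qspr_linear} model of kind \code{"huber"}.
#' @export
huber_fit <- function(X, y, epsilon = 1.35, alpha = 1e-4,
                      tol = 1e-6, max_iter = 1000L) {
  stopifnot(epsilon >= 1, alpha >= 0)
  d <- .as_xy(X, y)
  p <- ncol(d$x)
  xa <- cbind(1, d$x)
  pen <- diag(c(0, rep(alpha, p)))
  # start from the (possibly ridge-stabilized) LS solution
  beta <- tryCatch(as.numeric(solve(crossprod(xa) + pen, crossprod(xa, d$y))),
                   error = function(e)
                     stop("singular design in Huber fit", call. = FALSE))
  for (it in seq_len(max_iter)) {
    r <- d$y - as.numeric(xa %*% beta)
    s <- stats::mad(r)
    if (s == 0) s <- max(stats::sd(r), .Machine$double.eps)
    u <- abs(r) / s
    w <- ifelse(u <= epsilon, 1, epsilon / u)
    xw <- xa * w
    beta_new <- tryCatch(
      as.numeric(solve(crossprod(xw, xa) + pen, crossprod(xw, d$y))),
      error = function(e)
        stop("singular weighted system in Huber fit", call. = FALSE))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      cf <- beta[-1L]; names(cf) <- colnames(d$x)
      return(new_qspr_linear(cf, beta[1L], "huber",
                             extra = list(epsilon = epsilon, alpha = alpha,
                                          iterations = it, scale = s)))
    }
    beta <- beta_new
  }
  r <- d$y - as.numeric(xa %*% beta)
  stop(sprintf(
    "Huber IRLS did not converge in %d iterations (residual norm %.3g)",
    max_iter, sqrt(sum(r^2))), call. = FALSE)
}

#' @export
residuals.qspr_linear <- function(object, X, y, ...) {
  y - predict(object, X)
}
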