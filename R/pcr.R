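#' Principal component regression
#'
#' Regresses a centred response on the leading principal directions of the
#' centred, normalized predictor matrix, the standard remedy for the
#' multicollinearity of socio-economic data. The procedure is: (1) centre and
#' normalize the columns of X (unit sample standard deviation) and centre y;
#' (2) eigendecompose \eqn{X'X = V \Lambda V'}; (3) form the component
#' scores \eqn{W_k = [Xv_1, \ldots, Xv_k]}; (4) compute
#' \eqn{\gamma_k = (W_k'W_k)^{-1} W_k' y}; (5) map back to coefficients on
#' the original (standardized) predictors, \eqn{\beta_k = V_k \gamma_k}.
#' With \eqn{k = m} (all components) the result equals ordinary least
#' squares on the standardized predictors.
#'
#' Eigenvector signs are fixed so that each column's largest-magnitude
#' loading is positive; \eqn{\beta_k} is invariant to this convention.
#'
#' @param X Numeric matrix or data frame of predictors (n rows, m columns),
#'   no missing values, n > m.
#' @param y Numeric response of length n.
#' @param k Number of retained components, 1 <= k <= m.
#' @return Object of class \code{"pcr_fit"}: \code{beta} (coefficients on
#'   standardized predictors), \code{gamma} (component-space coefficients),
#'   \code{V}, \code{lambda}, \code{k}, \code{r2}, \code{adj_r2}, centring
#'   and scaling constants, fitted values and residuals.
#' @examples
#' tt <- gen_turnout_table(turnout_spec(n = 40), seed = 2)
#' pcr_fit(tt$X, tt$y, k = 3)
#' @export
pcr_fit <- function(X, y, k) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); m <- ncol(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= m) stop("need more observations (", n, ") than predictors (", m, ")")
  if (k < 1 || k > m) stop("'k' must lie in 1..", m, ", got ", k)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  if (any(scale_ == 0)) stop("constant predictor column: ",
                             paste(colnames(X)[scale_ == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  ybar <- mean(y)
  yc <- y - ybar

  eg <- eigen(crossprod(Xs), symmetric = TRUE)
  V <- eg$vectors
  lambda <- pmax(eg$values, 0)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)

  W <- Xs %*% V[, seq_len(k), drop = FALSE]
  WtW <- crossprod(W)
  if (kappa(WtW) > 1e12)
    stop("rank-deficient component scores: reduce 'k'")
  gamma <- drop(solve(WtW, crossprod(W, yc)))
  beta <- drop(V[, seq_len(k), drop = FALSE] %*% gamma)
  names(beta) <- colnames(X)
  fitted <- drop(W %*% gamma) + ybar
  res <- y - fitted
  sst <- sum(yc^2)
  r2 <- 1 - sum(res^2) / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  structure(list(beta = beta, gamma = gamma, V = V, lambda = lambda,
                 k = k, m = m, n = n, r2 = r2, adj_r2 = adj_r2,
                 center = center, scale = scale_, ybar = ybar,
                 fitted = fitted, residuals = res),
            class = "pcr_fit")
}

#' Select the number of components by adjusted R-squared
#'
#' Fits all models with k = 1, ..., m components and returns the one
#' maximizing the adjusted coefficient of determination; ties are broken
#' toward the smaller k.
#'
#' @inheritParams pcr_fit
#' @return The selected \code{pcr_fit}, with the full adjusted-R-squared
#'   profile in \code{$adj_r2_profile} and the choice in \code{$selected_k}.
#' @export
pcr_select <- function(X, y) {
  m <- ncol(as.matrix(X))
  fits <- lapply(seq_len(m), function(k) pcr_fit(X, y, k))
  prof <- vapply(fits, `[[`, numeric(1), "adj_r2")
  sel <- which.max(prof)   # first maximum = smallest k on ties
  out <- fits[[sel]]
  out$adj_r2_profile <- prof
  out$selected_k <- sel
  out
}

#' @export
coef.pcr_fit <- function(object, ...) object$beta

#' @export
fitted.pcr_fit <- function(object, ...) object$fitted

#' @export
residuals.pcr_fit <- function(object, ...) object$residuals

#' @export
predict.pcr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  drop(Xs %*% object$beta) + object$ybar
}

#' @export
print.pcr_fit <- function(x, digits = 4, ...) {
  cat("Principal component regression: k =", x$k, "of", x$m,
      "components\n")
  if (!is.null(x$selected_k))
    cat("  selected by adjusted R^2; profile:",
        paste(round(x$adj_r2_profile, 3), collapse = ", "), "\n")
  cat("  R^2 =", round(x$r2, digits), " adjusted R^2 =",
      round(x$adj_r2, digits), "\n")
  cat("  coefficients (standardized predictors):\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
summary.pcr_fit <- function(object, ...) {
  structure(list(k = object$k, m = object$m, n = object$n,
                 beta = object$beta, gamma = object$gamma,
                 lambda = object$lambda, r2 = object$r2,
                 adj_r2 = object$adj_r2,
                 adj_r2_profile = object$adj_r2_profile,
                 selected_k = object$selected_k),
            class = "summary.pcr_fit")
}

#' @export
print.summary.pcr_fit <- function(x, ...) {
  cat("Principal component regression (n =", x$n, ")\n")
  cat("Eigenvalues:", paste(round(x$lambda, 3), collapse = ", "), "\n")
  if (!is.null(x$adj_r2_profile)) {
    cat("Adjusted R^2 by k:\n")
    print(round(stats::setNames(x$adj_r2_profile, seq_along(x$adj_r2_profile)), 4))
    cat("Selected k =", x$selected_k, "\n")
  } else {
    cat("k =", x$k, "; R^2 =", round(x$r2, 4), "; adj R^2 =",
        round(x$adj_r2, 4), "\n")
  }
  cat("Coefficients (standardized predictors):\n")
  print(round(x$beta, 4))
  invisible(x)
}
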