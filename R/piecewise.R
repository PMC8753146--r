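#' Continuous piecewise-linear (changepoint) regression
#'
#' Fits the continuous two-segment model
#' \deqn{y = a_1 x + b \quad (x < x_c), \qquad
#'       y = a_2 (x - x_c) + a_1 x_c + b \quad (x \ge x_c)}
#' by least squares: a multistart profile over a grid of candidate
#' changepoints (each profile is an exact linear fit given \eqn{x_c}),
#' followed by Levenberg-Marquardt refinement of all four coefficients.
#' 95\% confidence intervals for the slopes and intercept come from the
#' asymptotic covariance \eqn{\hat\sigma^2 (J'J)^{-1}} with a t quantile on
#' \eqn{n - 4} degrees of freedom; the changepoint interval defaults to a
#' profile interval because the mean function is not differentiable in
#' \eqn{x_c} and the Wald interval undercovers there. A percentile bootstrap
#' is available as a sensitivity option.
#'
#' The changepoint is constrained to the interior of the observed x range
#' with at least 3 points on each side; an optimum on the boundary is
#' flagged and warned about.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped
#'   (listwise) with a message. At least 5 finite pairs are required and x
#'   must not be constant.
#' @param ci \code{"wald"} (default) or \code{"bootstrap"}.
#' @param xc_ci Interval method for the changepoint itself:
#'   \code{"profile"} (default; inverts the F test on the profiled residual
#'   sum of squares, which stays calibrated despite the kink's
#'   non-smoothness) or \code{"wald"}. Ignored when \code{ci = "bootstrap"}.
#' @param n_boot Bootstrap resamples when \code{ci = "bootstrap"}.
#' @param grid Candidate changepoints for the multistart profile; defaults
#'   to the interior deciles of x.
#' @return Object of class \code{"piecewise_fit"} with coefficients
#'   \code{a1} (gentle slope), \code{a2} (steep slope), \code{b}
#'   (intercept), \code{xc} (changepoint), covariance matrix, \code{ci95},
#'   residual variance \code{sigma2}, \code{n}, and fit diagnostics.
#' @examples
#' d <- gen_piecewise_data(piecewise_spec(1, 2, 0, 5, n = 80, noise_sd = 0.5))
#' fit <- fit_piecewise(d$x, d$y)
#' coef(fit)
#' @export
fit_piecewise <- function(x, y, ci = c("wald", "bootstrap"),
                          xc_ci = c("profile", "wald"), n_boot = 2000,
                          grid = NULL) {
  ci <- match.arg(ci)
  xc_ci <- match.arg(xc_ci)
  ok <- is.finite(x) & is.finite(y)
  if (sum(!ok) > 0)
    message("dropping ", sum(!ok), " pair(s) with missing values")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 finite (x, y) pairs, got ", n)
  if (diff(range(x)) == 0) stop("x must not be constant")
  xs <- sort(x)
  lo <- xs[3]; hi <- xs[n - 2]       # >= 3 points per side
  if (lo >= hi) { lo <- xs[2]; hi <- xs[n - 1] }
  if (is.null(grid)) {
    grid <- stats::quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE)
    grid <- grid[grid > lo & grid < hi]
    if (!length(grid)) grid <- (lo + hi) / 2
  }

  profile_fit <- function(xc) {
    h <- pmax(x - xc, 0)
    fit <- stats::lm(y ~ x + h)
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    list(b = cf[[1]], a1 = cf[[2]], a2 = cf[[2]] + cf[[3]],
         sse = sum(stats::resid(fit)^2))
  }
  prof <- lapply(grid, profile_fit)
  best <- which.min(vapply(prof, `[[`, numeric(1), "sse"))
  start <- c(a1 = prof[[best]]$a1, a2 = prof[[best]]$a2,
             b = prof[[best]]$b, xc = grid[best])

  residual_fun <- function(par)
    y - piecewise_mean(x, par[1], par[2], par[3], par[4])
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = residual_fun,
                       lower = c(-Inf, -Inf, -Inf, lo),
                       upper = c(Inf, Inf, Inf, hi),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  grid_sse <- prof[[best]]$sse
  if (!is.null(lm_fit) && sum(residual_fun(lm_fit$par)^2) <= grid_sse) {
    par <- lm_fit$par
  } else {
    # LM failed or did not improve: profile on a fine grid instead
    fine <- seq(lo, hi, length.out = 512)
    pf <- lapply(fine, profile_fit)
    i <- which.min(vapply(pf, `[[`, numeric(1), "sse"))
    par <- c(a1 = pf[[i]]$a1, a2 = pf[[i]]$a2, b = pf[[i]]$b, xc = fine[i])
  }
  names(par) <- c("a1", "a2", "b", "xc")
  res <- residual_fun(par)
  sse <- sum(res^2)
  sigma2 <- sse / (n - 4)

  # analytic Jacobian of the mean function
  left <- x < par["xc"]
  J <- cbind(a1 = ifelse(left, x, par["xc"]),
             a2 = ifelse(left, 0, x - par["xc"]),
             b = 1,
             xc = ifelse(left, 0, par["a1"] - par["a2"]))
  JtJ <- crossprod(J)
  vcov <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    warning("singular Jacobian: covariance from pseudo-inverse")
    sigma2 * MASS_ginv(JtJ)
  })
  dimnames(vcov) <- list(names(par), names(par))
  boundary <- par["xc"] <= lo + 1e-10 || par["xc"] >= hi - 1e-10 ||
    sum(x < par["xc"]) < 3 || sum(x >= par["xc"]) < 3
  if (boundary)
    warning("changepoint at the boundary of its admissible range")

  tq <- stats::qt(0.975, n - 4)
  se <- sqrt(pmax(diag(vcov), 0))
  ci95 <- cbind(lower = par - tq * se, upper = par + tq * se)
  if (ci == "wald" && xc_ci == "profile") {
    # invert the F test on the profiled SSE: robust to the kink
    Xmat <- cbind(1, x, 0)
    sse_at <- function(xc) {
      Xmat[, 3] <- pmax(x - xc, 0)
      sum(stats::lm.fit(Xmat, y)$residuals^2)
    }
    thr <- sse * (1 + stats::qf(0.95, 1, n - 4) / (n - 4))
    pg <- seq(lo, hi, length.out = 400)
    prof_sse <- vapply(pg, sse_at, numeric(1))
    inside <- pg[prof_sse <= thr]
    if (length(inside))
      ci95["xc", ] <- c(min(inside), max(inside))
  }

  fit <- structure(list(coefficients = par, vcov = vcov, ci95 = ci95,
                        se = se, sigma2 = sigma2, n = n, sse = sse,
                        df = n - 4, boundary = boundary, ci_method = ci,
                        x = x, y = y, fitted = y - res, residuals = res,
                        grid = grid),
                   class = "piecewise_fit")
  if (ci == "bootstrap") {
    bs <- matrix(NA_real_, n_boot, 4)
    for (bidx in seq_len(n_boot)) {
      take <- sample.int(n, n, replace = TRUE)
      bfit <- tryCatch(
        suppressWarnings(suppressMessages(
          fit_piecewise(x[take], y[take], ci = "wald", xc_ci = "wald"))),
        error = function(e) NULL)
      if (!is.null(bfit)) bs[bidx, ] <- bfit$coefficients
    }
    qs <- apply(bs, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    fit$ci95 <- cbind(lower = qs[1, ], upper = qs[2, ])
    rownames(fit$ci95) <- names(par)
    fit$boot <- bs
  }
  fit
}

# minimal Moore-Penrose inverse (symmetric case) for degenerate designs
MASS_ginv <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Evaluate a fitted piecewise model
#'
#' @param object A \code{piecewise_fit}.
#' @param newdata Numeric vector of x values (or data frame with column x);
#'   defaults to the training x.
#' @param ... Unused.
#' @return Predicted y values; the curve is continuous at the changepoint.
#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
  else if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  unname(piecewise_mean(x, cf[["a1"]], cf[["a2"]], cf[["b"]], cf[["xc"]]))
}

#' @rdname predict.piecewise_fit
#' @param fit A \code{piecewise_fit}.
#' @param x Numeric vector of evaluation points.
#' @export
predict_piecewise <- function(fit, x) predict(fit, x)

#' @export
coef.piecewise_fit <- function(object, ...) object$coefficients

#' @export
vcov.piecewise_fit <- function(object, ...) object$vcov

#' @export
residuals.piecewise_fit <- function(object, ...) object$residuals

#' @export
fitted.piecewise_fit <- function(object, ...) object$fitted

#' @export
confint.piecewise_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) {
    tq <- stats::qt(1 - (1 - level) / 2, object$df)
    ci <- cbind(object$coefficients - tq * object$se,
                object$coefficients + tq * object$se)
  } else ci <- object$ci95
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.piecewise_fit <- function(x, digits = 4, ...) {
  cat("Continuous piecewise-linear fit (n =", x$n, ")\n")
  cf <- x$coefficients
  cat(sprintf("  intercept b  = %.*g\n  gentle a1    = %.*g\n  changepoint xc = %.*g\n  steep a2     = %.*g\n",
              digits, cf["b"], digits, cf["a1"], digits, cf["xc"],
              digits, cf["a2"]))
  invisible(x)
}

#' @export
summary.piecewise_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, std.error = object$se,
               object$ci95)
  structure(list(coefficients = tab, sigma2 = object$sigma2, n = object$n,
                 df = object$df, sse = object$sse,
                 boundary = object$boundary, ci_method = object$ci_method),
            class = "summary.piecewise_fit")
}

#' @export
print.summary.piecewise_fit <- function(x, ...) {
  cat("Continuous piecewise-linear regression\n")
  cat("n =", x$n, "; residual variance =", format(x$sigma2, digits = 4),
      "; 95% CI:", x$ci_method, "\n")
  print(round(x$coefficients, 4))
  if (x$boundary) cat("NOTE: changepoint at boundary of admissible range\n")
  invisible(x)
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "x", ylab = "y", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = 2, lwd = 2)
  graphics::abline(v = x$coefficients["xc"], lty = 2, col = "grey50")
  invisible(x)
}

#' @export
simulate.piecewise_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- predict(object)
  out <- replicate(nsim, m + stats::rnorm(object$n, 0, sqrt(object$sigma2)),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}
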