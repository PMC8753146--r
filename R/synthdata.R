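#' Specification of a synthetic piecewise-linear dataset
#'
#' Truth coefficients of the continuous two-segment model
#' \eqn{y = a_1 x + b} for \eqn{x < x_c} and
#' \eqn{y = a_2 (x - x_c) + a_1 x_c + b} for \eqn{x \ge x_c}, emulating the
#' kinked index-versus-index relationships the changepoint estimator targets.
#'
#' @param a1,a2 Gentle and steep slopes.
#' @param b Intercept.
#' @param xc Changepoint; must lie strictly inside \code{x_range}.
#' @param x_range Length-2 range from which x is drawn uniformly.
#' @param n Number of points (>= 8).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @return An object of class \code{"piecewise_spec"}.
#' @export
piecewise_spec <- function(a1, a2, b, xc, x_range = c(0, 10), n = 160,
                           noise_sd = 0) {
  if (length(x_range) != 2 || x_range[1] >= x_range[2])
    stop("'x_range' must be an increasing length-2 range")
  if (xc <= x_range[1] || xc >= x_range[2])
    stop("'xc' must lie strictly inside 'x_range'")
  if (n < 8) stop("'n' must be >= 8")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(a1 = a1, a2 = a2, b = b, xc = xc, x_range = x_range,
                 n = n, noise_sd = noise_sd),
            class = "piecewise_spec")
}

# the two-branch mean function shared by the generator and the estimator
piecewise_mean <- function(x, a1, a2, b, xc) {
  ifelse(x < xc, a1 * x + b, a2 * (x - xc) + a1 * xc + b)
}

#' Generate a synthetic piecewise-linear dataset
#'
#' @param spec A \code{\link{piecewise_spec}}.
#' @param seed Integer seed; the dataset is deterministic given
#'   \code{(spec, seed)}.
#' @return Data frame with columns \code{x} and \code{y}.
#' @examples
#' d <- gen_piecewise_data(piecewise_spec(1, 2, 0, 5, n = 50), seed = 1)
#' @export
gen_piecewise_data <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "piecewise_spec"))
  set.seed(seed)
  x <- stats::runif(spec$n, spec$x_range[1], spec$x_range[2])
  y <- piecewise_mean(x, spec$a1, spec$a2, spec$b, spec$xc) +
    stats::rnorm(spec$n, 0, spec$noise_sd)
  data.frame(x = x, y = y)
}

#' Specification of a synthetic multicollinear turnout table
#'
#' Emulates the multicollinearity of socio-economic country data: five
#' correlated predictors (cpi, democracy, gdp, eu, population) with the
#' response built from the top three principal directions of the realized
#' predictor matrix, so that principal component regression with
#' adjusted-R-squared selection should retain three components.
#'
#' @param n Number of countries (> 5).
#' @param corr 5x5 positive semi-definite predictor correlation matrix.
#' @param beta Length-3 coefficients on the leading principal directions.
#' @param noise_sd Standard deviation of response noise (>= 0).
#' @return An object of class \code{"turnout_spec"}.
#' @export
turnout_spec <- function(n = 50, corr = default_turnout_corr(),
                         beta = c(6, 3, 2), noise_sd = 1) {
  corr <- as.matrix(corr)
  if (!all(dim(corr) == c(5, 5))) stop("'corr' must be 5x5")
  if (is.null(colnames(corr)))
    dimnames(corr) <- rep(list(c("cpi", "democracy", "gdp", "eu",
                                 "population")), 2)
  if (max(abs(corr - t(corr))) > 1e-12) stop("'corr' must be symmetric")
  if (n <= 5) stop("'n' must exceed the number of predictors (5)")
  if (length(beta) != 3) stop("'beta' must have length 3")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(n = n, corr = corr, beta = beta, noise_sd = noise_sd),
            class = "turnout_spec")
}

#' @rdname turnout_spec
#' @export
default_turnout_corr <- function() {
  nm <- c("cpi", "democracy", "gdp", "eu", "population")
  corr <- diag(5)
  dimnames(corr) <- list(nm, nm)
  # wealthy, democratic, clean-government countries cluster together
  corr["cpi", "democracy"] <- corr["democracy", "cpi"] <- 0.7
  corr["cpi", "gdp"] <- corr["gdp", "cpi"] <- 0.6
  corr["democracy", "gdp"] <- corr["gdp", "democracy"] <- 0.5
  corr["eu", "cpi"] <- corr["cpi", "eu"] <- 0.4
  corr["eu", "democracy"] <- corr["democracy", "eu"] <- 0.4
  corr["eu", "gdp"] <- corr["gdp", "eu"] <- 0.3
  corr["population", "gdp"] <- corr["gdp", "population"] <- -0.2
  corr
}

#' Generate a synthetic multicollinear turnout table
#'
#' @param spec A \code{\link{turnout_spec}}.
#' @param seed Integer seed.
#' @return List with \code{X} (data frame of 5 predictors, \code{eu} binary)
#'   and numeric response \code{y} (synthetic turnout).
#' @export
gen_turnout_table <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "turnout_spec"))
  ch <- tryCatch(chol(spec$corr), error = function(e)
    stop("'corr' is not positive definite: ", conditionMessage(e)))
  set.seed(seed)
  Z <- matrix(stats::rnorm(spec$n * 5), spec$n, 5) %*% ch
  colnames(Z) <- colnames(spec$corr)
  X <- as.data.frame(Z)
  X$eu <- as.numeric(X$eu > 0)
  # response lives in the span of the top-3 principal directions of the
  # realized (centred, normalized) predictors
  Xs <- scale(as.matrix(X))
  eg <- eigen(crossprod(Xs), symmetric = TRUE)
  W <- Xs %*% eg$vectors[, 1:3]
  y <- drop(W %*% spec$beta) + stats::rnorm(spec$n, 0, spec$noise_sd)
  list(X = X, y = y)
}

#' Generate a synthetic country-index table
#'
#' Emits a table in the schema accepted by \code{\link{read_country_table}},
#' with correlated indicators mapped into their documented ranges and a
#' turnout response carried by the leading principal directions. Purely
#' synthetic: the rows are labelled SYN001, SYN002, ... and do not attempt
#' to match any real country's indicators.
#'
#' @param n Number of synthetic countries (> 5).
#' @param seed Integer seed.
#' @param noise_sd Turnout noise standard deviation (percentage points).
#' @return A \code{country_table} data frame.
#' @export
gen_synthetic_country_table <- function(n = 50, seed = 1, noise_sd = 4) {
  tt <- gen_turnout_table(turnout_spec(n = n, noise_sd = 0), seed = seed)
  set.seed(seed + 1L)
  X <- tt$X
  df <- data.frame(
    country = sprintf("Synthetic country %03d", seq_len(n)),
    iso3 = sprintf("S%02d", seq_len(n) %% 100),
    democracy_index = round(stats::pnorm(X$democracy) * 10, 2),
    cpi = round(stats::pnorm(X$cpi) * 100),
    freedom_score = round(stats::pnorm(0.8 * X$democracy +
                                         0.2 * stats::rnorm(n)) * 100),
    control_of_corruption = round(pmax(pmin(0.9 * X$cpi +
                                              0.3 * stats::rnorm(n), 2.5),
                                       -2.5), 2),
    turnout_avg = NA_real_,
    gdp_pc = round(exp(9 + 1.2 * X$gdp)),
    eu_member = X$eu,
    population = round(exp(15 + 1.5 * X$population)),
    stringsAsFactors = FALSE)
  y <- tt$y + stats::rnorm(n, 0, noise_sd)
  df$turnout_avg <- round(pmax(pmin(65 + 3 * scale(y)[, 1] * 4, 99), 20), 1)
  validate_country_table(df, "synthetic country table")
}

#' Draw heterogeneous society parameters for an ensemble
#'
#' Independent uniform draws of the per-society initial rates
#' \code{(pa, pv, p, r, f0)}. The default ranges define the reference
#' ensemble conditions used by \code{\link{simulate_ensemble}}: recruitment
#' slow enough that the parochial pool grows on the same timescale as the
#' drift of intrinsic altruism, apathy rates spanning enthusiastic to
#' disheartened electorates, and peer-pressure strengths straddling the
#' bistable regime.
#'
#' @param n Number of societies (>= 2).
#' @param ranges Named list of c(min, max) for any of \code{pa}, \code{pv},
#'   \code{p}, \code{r}, \code{f0}; unspecified entries use the defaults.
#' @param seed Integer seed.
#' @return Data frame with columns pa, pv, p, r, f0.
#' @examples
#' gen_country_params(5, seed = 1)
#' @export
gen_country_params <- function(n, ranges = NULL, seed = 1) {
  if (n < 2) stop("'n' must be >= 2")
  defaults <- list(pa = c(5e-5, 1e-3), pv = c(0.005, 0.06),
                   p = c(0.002, 0.08), r = c(0.08, 0.35),
                   f0 = c(0.02, 0.15))
  if (is.null(ranges)) ranges <- list()
  for (nm in names(ranges)) {
    if (!nm %in% names(defaults))
      stop("unknown parameter range '", nm, "'")
    rg <- ranges[[nm]]
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 0 || rg[2] > 1)
      stop("range for '", nm, "' must be c(min, max) inside [0, 1]")
    defaults[[nm]] <- rg
  }
  set.seed(seed)
  out <- lapply(defaults, function(rg) stats::runif(n, rg[1], rg[2]))
  as.data.frame(out)
}
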