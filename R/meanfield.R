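#' Degree distributions for the mean-field theory
#'
#' A degree distribution assigns a probability mass \code{zdf(k)} to each
#' friendship count \code{k}. The mean-field neighbourhood term averages the
#' eligibility probability over this distribution.
#'
#' @param support Integer vector of degrees (k >= 0), no duplicates.
#' @param mass Numeric vector of fractions, same length as \code{support};
#'   must be non-negative and sum to 1 within 1e-12.
#' @return An object of class \code{"degree_distribution"}.
#' @examples
#' delta_degree(10)
#' degree_distribution(c(4, 8), c(0.5, 0.5))
#' @export
degree_distribution <- function(support, mass) {
  support <- as.integer(support)
  mass <- as.numeric(mass)
  if (length(support) != length(mass) || length(support) == 0L)
    stop("'support' and 'mass' must be non-empty and of equal length")
  if (anyDuplicated(support)) stop("duplicate degrees in 'support'")
  if (any(support < 0L)) stop("degrees must be non-negative")
  if (any(mass < 0)) stop("degree masses must be non-negative")
  if (abs(sum(mass) - 1) > 1e-12)
    stop("degree masses must sum to 1 (within 1e-12), got ", sum(mass))
  ord <- order(support)
  structure(list(support = support[ord], mass = mass[ord]),
            class = "degree_distribution")
}

#' @rdname degree_distribution
#' @param k Single degree at which all mass concentrates.
#' @export
delta_degree <- function(k) degree_distribution(k, 1)

#' @rdname degree_distribution
#' @param mean_degree Mean of the (truncated) Poisson degree distribution;
#'   this is the degree law of the Erdős–Rényi friendship baseline.
#' @param kmax Truncation degree; defaults to the 1 - 1e-9 Poisson quantile.
#' @export
poisson_degree <- function(mean_degree, kmax = NULL) {
  if (mean_degree <= 0) stop("'mean_degree' must be positive")
  if (is.null(kmax)) kmax <- stats::qpois(1 - 1e-9, mean_degree)
  ks <- 0:kmax
  mass <- stats::dpois(ks, mean_degree)
  degree_distribution(ks, mass / sum(mass))
}

#' @rdname degree_distribution
#' @param graph A \code{society_graph} whose realized degree sequence is
#'   tabulated into an empirical distribution.
#' @export
empirical_degree_distribution <- function(graph) {
  stopifnot(inherits(graph, "society_graph"))
  tab <- table(graph$degree)
  degree_distribution(as.integer(names(tab)), as.numeric(tab) / graph$N)
}

#' @rdname degree_distribution
#' @param path CSV path with two columns, degree \code{k} and \code{mass}.
#' @export
read_degree_distribution <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected two columns (k, mass) in ", path)
  degree_distribution(df[[1]], df[[2]])
}

#' @rdname degree_distribution
#' @param dd A \code{degree_distribution} to write.
#' @export
write_degree_distribution <- function(dd, path) {
  stopifnot(inherits(dd, "degree_distribution"))
  utils::write.csv(data.frame(k = dd$support, mass = dd$mass), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("Degree distribution on", length(x$support), "degree(s); mean degree",
      format(sum(x$support * x$mass), digits = 4), "\n")
  invisible(x)
}

#' Window-aggregated flip probability
#'
#' A spin raised with per-step probability \code{rate} stays up for
#' \code{window} steps after a successful trial, so the probability of
#' observing it up is the probability of at least one success in the trailing
#' window: \eqn{1 - (1 - rate)^{window}}. The widely used exponential
#' approximation \eqn{1 - e^{-rate \cdot window}} is available via
#' \code{form = "exponential"}.
#'
#' @param rate Per-step success probability in [0, 1].
#' @param window Persistence window length in steps (>= 1).
#' @param form \code{"exact"} (default) or \code{"exponential"}.
#' @return Effective probability in [0, 1].
#' @examples
#' effective_probability(0.01, 10)                  # 1 - 0.99^10
#' effective_probability(0.01, 10, "exponential")   # 1 - exp(-0.1)
#' @export
effective_probability <- function(rate, window, form = c("exact", "exponential")) {
  form <- match.arg(form)
  if (any(rate < 0 | rate > 1)) stop("'rate' must lie in [0, 1]")
  if (any(window < 1)) stop("'window' must be >= 1")
  switch(form,
         exact = 1 - (1 - rate)^window,
         exponential = 1 - exp(-rate * window))
}

#' Mean-field parameter set
#'
#' Bundles the effective probabilities, parochial fraction, the altruist
#' neighbourhood threshold and a degree distribution into the parameter set of
#' the mean-field self-consistency equation.
#'
#' The threshold can be read in two conventions that differ whenever
#' \code{k != 2 * mu}: under \code{"printed"} an agent is eligible for induced
#' altruism iff its neighbourhood contains at most \code{mu} non-altruists;
#' under \code{"textual"} iff it contains at least \code{mu} altruists. A
#' degree-0 agent is always eligible under \code{"printed"} and (for
#' \code{mu > 0}) never under \code{"textual"}.
#'
#' @param p_star Effective intrinsic flip probability in [0, 1].
#' @param r_star Effective induced flip probability in [0, 1].
#' @param f Parochialist fraction in [0, 1).
#' @param mu Neighbourhood threshold (integer >= 0).
#' @param degree_dist A \code{degree_distribution}.
#' @param convention \code{"printed"} (default) or \code{"textual"}.
#' @return An object of class \code{"meanfield_params"}.
#' @export
meanfield_params <- function(p_star, r_star, f, mu, degree_dist,
                             convention = c("printed", "textual")) {
  convention <- match.arg(convention)
  stopifnot(inherits(degree_dist, "degree_distribution"))
  if (p_star < 0 || p_star > 1) stop("'p_star' must lie in [0, 1]")
  if (r_star < 0 || r_star > 1) stop("'r_star' must lie in [0, 1]")
  if (f < 0 || f >= 1) stop("'f' must lie in [0, 1)")
  if (mu < 0 || mu != round(mu)) stop("'mu' must be a non-negative integer")
  structure(list(p_star = p_star, r_star = r_star, f = f, mu = as.integer(mu),
                 degree_dist = degree_dist, convention = convention),
            class = "meanfield_params")
}

#' Neighbourhood eligibility term E(z)
#'
#' Probability that a randomly chosen agent's neighbourhood satisfies the
#' altruist-count condition for induced altruism, averaged over the degree
#' distribution, when each neighbour is independently altruistic with
#' probability \code{z}. Under the \code{"printed"} convention this is
#' \eqn{E(z) = \sum_k zdf(k)\, P(\mathrm{Bin}(k, 1-z) \le \mu)}; under
#' \code{"textual"} it is \eqn{\sum_k zdf(k)\, P(\mathrm{Bin}(k, z) \ge \mu)}.
#' E is non-decreasing in z and maps [0, 1] into [0, 1].
#'
#' @param z Altruist fraction(s) in [0, 1]; vectorized.
#' @param params A \code{meanfield_params} object.
#' @return E(z), same length as \code{z}.
#' @examples
#' mfp <- meanfield_params(0.5, 0.5, 0, 1, delta_degree(4))
#' neighborhood_term(0.5, mfp)  # 5/16
#' @export
neighborhood_term <- function(z, params) {
  stopifnot(inherits(params, "meanfield_params"))
  if (any(z < 0 | z > 1)) stop("'z' must lie in [0, 1]")
  dd <- params$degree_dist
  mu <- params$mu
  n <- length(z)
  ns <- length(dd$support)
  # one vectorized pbinom call over the (z, k) grid
  if (params$convention == "printed") {
    m <- matrix(stats::pbinom(mu, rep(dd$support, each = n), 1 - z), n, ns)
  } else if (mu == 0L) {
    m <- matrix(1, n, ns)
  } else {
    m <- matrix(1 - stats::pbinom(mu - 1L, rep(dd$support, each = n), z),
                n, ns)
  }
  pmin(pmax(drop(m %*% dd$mass), 0), 1)
}

# dE/dz, analytic: d/dq P(Bin(n,q) <= m) = -n * dbinom(m, n-1, q)
neighborhood_term_deriv <- function(z, params) {
  dd <- params$degree_dist
  mu <- params$mu
  n <- length(z)
  pos <- dd$support >= 1L
  if (!any(pos)) return(numeric(n))
  ks <- dd$support[pos]
  w <- dd$mass[pos] * ks
  ns <- length(ks)
  if (params$convention == "printed") {
    m <- matrix(stats::dbinom(mu, rep(ks - 1L, each = n), 1 - z), n, ns)
  } else if (mu == 0L) {
    return(numeric(n))
  } else {
    m <- matrix(stats::dbinom(mu - 1L, rep(ks - 1L, each = n), z), n, ns)
  }
  drop(m %*% w)
}

# right-hand side of the self-consistency map z -> (1-f) p* r* E(z)
meanfield_rhs <- function(z, params) {
  (1 - params$f) * params$p_star * params$r_star * neighborhood_term(z, params)
}

#' Fixed points of the mean-field self-consistency equation
#'
#' Finds all roots of \eqn{g(z) = z - (1-f)\,p^* r^* E(z)} on
#' \eqn{[0, 1-f]} by a dense sign-change scan followed by bisection, labels
#' each root stable or unstable by the discrete-map criterion (derivative of
#' the right-hand side < 1 at the root), and attaches the implied population
#' shares \eqn{(z, d, f)} with \eqn{d = 1 - f - z}.
#'
#' @param params A \code{meanfield_params} object.
#' @param n_grid Number of scan points (default 1e4).
#' @param tol Residual tolerance for accepted roots (default 1e-10).
#' @return An object of class \code{"meanfield_solution"} with components
#'   \code{roots} (ascending), \code{stable} (logical), \code{degenerate}
#'   (logical, near-tangency), \code{shares} (data frame with z, d, f),
#'   \code{region} and the input \code{params}.
#' @export
fixed_points <- function(params, n_grid = 1e4, tol = 1e-10) {
  stopifnot(inherits(params, "meanfield_params"))
  hi <- 1 - params$f
  g <- function(z) z - meanfield_rhs(z, params)
  zs <- seq(0, hi, length.out = n_grid)
  gs <- g(zs)
  roots <- numeric(0)
  # endpoint / on-grid exact roots
  roots <- c(roots, zs[abs(gs) < tol])
  # sign changes between grid points
  sgn <- sign(gs)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(g, lower = zs[i], upper = zs[i + 1],
                        tol = 1e-14)$root
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (length(roots) > 1) {        # dedupe near-identical roots
    keep <- c(TRUE, diff(roots) > 1e-8)
    roots <- roots[keep]
  }
  # polish: one Newton step each, then keep residual check honest
  slope <- (1 - params$f) * params$p_star * params$r_star *
    neighborhood_term_deriv(roots, params)
  gp <- 1 - slope
  newton_ok <- abs(gp) > 1e-8
  roots[newton_ok] <- roots[newton_ok] - g(roots[newton_ok]) / gp[newton_ok]
  roots <- pmin(pmax(roots, 0), hi)
  roots <- roots[abs(g(roots)) < tol]
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-8)
    roots <- roots[keep]
  }
  slope <- (1 - params$f) * params$p_star * params$r_star *
    neighborhood_term_deriv(roots, params)
  stable <- slope < 1
  degenerate <- abs(slope - 1) < 1e-6
  shares <- data.frame(z = roots, d = 1 - params$f - roots, f = params$f)
  region <- classify_region(roots, stable, params$f)
  structure(list(roots = roots, stable = stable, degenerate = degenerate,
                 slope = slope, shares = shares, region = region,
                 params = params),
            class = "meanfield_solution")
}

classify_region <- function(roots, stable, f) {
  ns <- sum(stable)
  if (ns >= 2) return("bistable")
  z <- if (ns == 1) roots[stable][1] else roots[which.min(abs(roots))]
  if (z < (1 - f) / 2) "few-altruists" else "many-altruists"
}

#' @export
print.meanfield_solution <- function(x, digits = 6, ...) {
  cat("Mean-field fixed points (region: ", x$region, ")\n", sep = "")
  df <- cbind(round(x$shares, digits),
              stable = x$stable, degenerate = x$degenerate)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Classify the mean-field phase region
#'
#' A parameter point is \code{"bistable"} when the self-consistency equation
#' has at least two stable roots; otherwise the single stable root is called
#' \code{"few-altruists"} when it lies below \eqn{(1-f)/2} and
#' \code{"many-altruists"} above.
#'
#' @inheritParams fixed_points
#' @return Character region label.
#' @export
phase_classify <- function(params, n_grid = 1e4, tol = 1e-10) {
  fixed_points(params, n_grid = n_grid, tol = tol)$region
}

#' Sweep the (p*, r*) plane into a phase diagram
#'
#' @param p_star_grid,r_star_grid Numeric grids of effective probabilities.
#' @param f,mu,degree_dist,convention As in \code{\link{meanfield_params}}.
#' @param n_grid Scan resolution passed to \code{\link{fixed_points}}.
#' @return Data frame with columns \code{p_star}, \code{r_star},
#'   \code{region}, \code{n_roots}, \code{z_low}, \code{z_high}.
#' @export
phase_diagram <- function(p_star_grid, r_star_grid, f, mu, degree_dist,
                          convention = "printed", n_grid = 2000) {
  grid <- expand.grid(p_star = p_star_grid, r_star = r_star_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mfp <- meanfield_params(grid$p_star[i], grid$r_star[i], f, mu,
                            degree_dist, convention)
    sol <- fixed_points(mfp, n_grid = n_grid)
    st <- sol$roots[sol$stable]
    data.frame(region = sol$region, n_roots = length(sol$roots),
               z_low = if (length(st)) min(st) else NA_real_,
               z_high = if (length(st)) max(st) else NA_real_)
  })
  cbind(grid, do.call(rbind, res))
}

#' Critical intrinsic-altruism threshold (saddle-node in p*)
#'
#' Locates the smallest effective intrinsic probability \eqn{p^*} at which
#' the low-altruism stable branch disappears, i.e. the fold at which altruist
#' abundance explodes along an upward sweep of \eqn{p^*}. Found by bisection
#' on the root count of the self-consistency equation.
#'
#' @param r_star Effective induced probability.
#' @param f Parochialist fraction.
#' @param mu Neighbourhood threshold.
#' @param degree_dist A \code{degree_distribution}.
#' @param convention Eligibility convention.
#' @param tol Bisection tolerance on p* (default 1e-6).
#' @param n_scan Number of p* scan points used to bracket the fold.
#' @param n_grid Root-scan resolution.
#' @return The fold location as a single number, or \code{NA} when no
#'   bistable window exists at these settings.
#' @export
critical_threshold <- function(r_star, f, mu, degree_dist,
                               convention = "printed", tol = 1e-6,
                               n_scan = 200, n_grid = 4000) {
  nroots <- function(p_star) {
    mfp <- meanfield_params(p_star, r_star, f, mu, degree_dist, convention)
    length(fixed_points(mfp, n_grid = n_grid)$roots)
  }
  ps <- seq(0, 1, length.out = n_scan)
  counts <- vapply(ps, nroots, integer(1))
  bist <- which(counts >= 3)
  if (!length(bist)) return(NA_real_)
  i <- max(bist)                       # last bistable scan point
  if (i == length(ps)) return(NA_real_)  # fold beyond p* = 1
  lo <- ps[i]; hi <- ps[i + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nroots(mid) >= 3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
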