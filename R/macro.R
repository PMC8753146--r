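#' Enthusiastic-voter fraction
#'
#' A non-parochial agent is apathetic for \code{T} steps after an apathy flip
#' that occurs with per-step probability \code{pv}; the stationary enthusiastic
#' fraction is therefore \eqn{(1-p_v)^T}, commonly approximated by
#' \eqn{e^{-p_v T}}. The exponential form is the default used throughout the
#' voting arithmetic; the exact form is available via \code{form = "exact"}.
#'
#' @param pv Per-step apathy flip probability in [0, 1].
#' @param T Apathy persistence in steps (>= 1).
#' @param form \code{"exponential"} (default) or \code{"exact"}.
#' @return Enthusiastic fraction in [0, 1].
#' @examples
#' enthusiastic_fraction(0.01, 20, "exact")  # 0.99^20
#' enthusiastic_fraction(0.01, 20)           # exp(-0.2)
#' @export
enthusiastic_fraction <- function(pv, T, form = c("exponential", "exact")) {
  form <- match.arg(form)
  if (any(pv < 0 | pv > 1)) stop("'pv' must lie in [0, 1]")
  if (any(T < 1)) stop("'T' must be >= 1")
  switch(form,
         exact = (1 - pv)^T,
         exponential = exp(-pv * T))
}

#' Election vote shares
#'
#' Altruists and opportunists vote only when enthusiastic; parochialists
#' always vote to preserve influence. The altruist share of the electorate is
#' \eqn{z \cdot e} and the parochialist-opportunist bloc share is
#' \eqn{f + d \cdot e}, where \eqn{e} is the enthusiastic fraction. Altruists
#' win strictly, i.e. iff \eqn{(z - d) e - f > 0}.
#'
#' @param z,d,f Altruist, opportunist and parochialist population fractions;
#'   must sum to 1 within 1e-9.
#' @param enthusiasm Enthusiastic-voter fraction in [0, 1].
#' @return List with \code{altruist_share}, \code{bloc_share} and logical
#'   \code{altruists_win}.
#' @examples
#' vote_shares(0.5, 0.35, 0.15, 0.8)  # 40% vs 43%: altruists lose
#' @export
vote_shares <- function(z, d, f, enthusiasm) {
  if (abs(z + d + f - 1) > 1e-9)
    stop("population shares must sum to 1 within 1e-9, got ", z + d + f)
  if (enthusiasm < 0 || enthusiasm > 1) stop("'enthusiasm' must lie in [0, 1]")
  alt <- z * enthusiasm
  bloc <- f + d * enthusiasm
  list(altruist_share = alt, bloc_share = bloc,
       altruists_win = (z - d) * enthusiasm - f > 0)
}

#' One reform step
#'
#' When enthusiastic altruists strictly outvote the parochialist-opportunist
#' bloc (Heaviside convention H(0) = 0), reforms decay the recruitment and
#' apathy rates multiplicatively, \eqn{p_a \leftarrow p_a (1 - \zeta_a)} and
#' \eqn{p_v \leftarrow p_v (1 - \zeta_v)}, which keeps both non-negative.
#'
#' @param state List with at least \code{z}, \code{d}, \code{f}, \code{pa},
#'   \code{pv}.
#' @param zeta_a,zeta_v Reform rates in [0, 1].
#' @param enthusiasm Enthusiastic-voter fraction used in the election test.
#' @return The updated state.
#' @export
reform_step <- function(state, zeta_a, zeta_v, enthusiasm) {
  condition <- (state$z - state$d) * enthusiasm - state$f
  if (condition > 0) {
    state$pa <- state$pa * (1 - zeta_a)
    state$pv <- state$pv * (1 - zeta_v)
    state$reformed <- TRUE
  }
  state
}

#' One slow-drift step
#'
#' The parochialist pool grows by recruiting opportunists,
#' \eqn{\Delta f = p_a (1 - z - f)}, and the intrinsic altruism rate drifts
#' upward, \eqn{\Delta p = \epsilon (1 - p)}. Both updates respect [0, 1]
#' bounds for unit step size and rates at most 1.
#'
#' @param state List with at least \code{z}, \code{f}, \code{p}.
#' @param epsilon Drift rate of \code{p} (>= 0).
#' @param pa Recruitment rate used for the f update.
#' @return The updated state.
#' @export
drift_step <- function(state, epsilon, pa) {
  state$f <- state$f + pa * (1 - state$z - state$f)
  state$p <- state$p + epsilon * (1 - state$p)
  state
}

# Warm-started branch continuation for z = c * E(z).
# Damped fixed-point iteration tracks the stable branch the previous z sat
# on; a Newton polish handles the critical slowing down near folds; when the
# branch has vanished (saddle-node) the fallback snaps to the nearest
# remaining stable root, producing the explosive jump.
solve_branch <- function(z0, params, tol = 1e-12) {
  dd <- params$degree_dist
  cfac <- (1 - params$f) * params$p_star * params$r_star
  mu <- params$mu
  printed <- params$convention == "printed"
  support <- dd$support
  mass <- dd$mass
  pos <- support >= 1L
  ksd <- support[pos] - 1L
  wd <- mass[pos] * support[pos]
  Efun <- if (printed) {
    function(z) sum(mass * stats::pbinom(mu, support, 1 - z))
  } else if (mu == 0L) {
    function(z) 1
  } else {
    function(z) sum(mass * (1 - stats::pbinom(mu - 1L, support, z)))
  }
  Eder <- if (printed) {
    function(z) sum(wd * stats::dbinom(mu, ksd, 1 - z))
  } else if (mu == 0L) {
    function(z) 0
  } else {
    function(z) sum(wd * stats::dbinom(mu - 1L, ksd, z))
  }
  hi <- 1 - params$f
  z <- min(max(z0, 0), hi)
  # damped iteration: converges fast away from folds
  for (i in 1:60) {
    znew <- 0.5 * z + 0.5 * min(cfac * Efun(z), hi)
    if (abs(znew - z) < tol) return(znew)
    z <- znew
  }
  # Newton polish on g(z) = z - c E(z); accept only stable roots
  zn <- z
  for (i in 1:50) {
    g <- zn - cfac * Efun(zn)
    gp <- 1 - cfac * Eder(zn)
    if (abs(gp) < 1e-12) break
    step <- g / gp
    zn <- zn - step
    if (zn < 0 || zn > hi) { zn <- NA_real_; break }
    if (abs(step) < tol) break
  }
  if (!is.na(zn) && abs(zn - cfac * Efun(zn)) < 1e-10 &&
      cfac * Eder(zn) < 1) return(zn)
  # branch vanished (or polish failed): nearest stable root wins
  sol <- fixed_points(params, n_grid = 2000)
  st <- sol$roots[sol$stable]
  if (!length(st)) return(z)
  st[which.min(abs(st - z))]
}

#' Run the slow society-scale dynamics
#'
#' Tracks a society along the mean-field branch while the slow variables
#' evolve: each step computes the effective probabilities from the current
#' rates, solves the self-consistency equation for the altruist share by
#' warm-started damped fixed-point continuation (which reproduces the
#' explosive jump at the fold and hysteresis), then applies the drift of
#' \code{p} and \code{f} and the election-triggered reform of \code{pa} and
#' \code{pv}.
#'
#' @param initial List with starting values \code{f}, \code{p}, \code{pa},
#'   \code{pv} and optionally \code{z0} (default: converged from z = 0).
#' @param params List of slow-dynamics parameters: \code{r} and \code{tau2}
#'   (or directly \code{r_star}), \code{tau1}, \code{T}, \code{epsilon},
#'   \code{zeta_a}, \code{zeta_v}, \code{mu}, \code{degree_dist},
#'   \code{convention} (default "printed"), \code{enthusiasm_form} (default
#'   "exponential"), \code{election_every} (cadence in steps, default 1).
#' @param horizon Number of steps (>= 1).
#' @return Object of class \code{"macro_trajectory"}: a data frame with one
#'   row per step (step, z, d, f, p, p_star, pa, pv, enthusiasm,
#'   altruist_share, bloc_share, reformed).
#' @export
run_macro <- function(initial, params, horizon) {
  stopifnot(horizon >= 1)
  p <- initial$p; f <- initial$f; pa <- initial$pa; pv <- initial$pv
  if (is.null(params$r_star) && is.null(params$r))
    stop("provide 'r_star' or ('r', 'tau2') in params")
  r_star <- if (!is.null(params$r_star)) params$r_star else
    effective_probability(params$r, params$tau2)
  tau1 <- params$tau1
  T <- params$T
  epsilon <- if (is.null(params$epsilon)) 0 else params$epsilon
  zeta_a <- if (is.null(params$zeta_a)) 0 else params$zeta_a
  zeta_v <- if (is.null(params$zeta_v)) 0 else params$zeta_v
  convention <- if (is.null(params$convention)) "printed" else params$convention
  eform <- if (is.null(params$enthusiasm_form)) "exponential" else
    params$enthusiasm_form
  cadence <- if (is.null(params$election_every)) 1L else
    as.integer(params$election_every)
  dd <- params$degree_dist
  mu <- params$mu

  z <- if (is.null(initial$z0)) 0 else initial$z0
  out <- matrix(NA_real_, horizon, 12)
  colnames(out) <- c("step", "z", "d", "f", "p", "p_star", "pa", "pv",
                     "enthusiasm", "altruist_share", "bloc_share", "reformed")
  for (t in seq_len(horizon)) {
    p_star <- effective_probability(p, tau1)
    mfp <- meanfield_params(p_star, r_star, f, mu, dd, convention)
    z <- solve_branch(z, mfp)
    d <- 1 - f - z
    e <- enthusiastic_fraction(pv, T, eform)
    vs <- vote_shares(z, d, f, e)
    state <- list(z = z, d = d, f = f, p = p, pa = pa, pv = pv,
                  reformed = FALSE)
    state <- drift_step(state, epsilon, pa)
    if (t %% cadence == 0L)
      state <- reform_step(state, zeta_a, zeta_v, e)
    out[t, ] <- c(t, z, d, f, p, p_star, pa, pv, e,
                  vs$altruist_share, vs$bloc_share, as.numeric(state$reformed))
    f <- state$f; p <- state$p; pa <- state$pa; pv <- state$pv
  }
  traj <- as.data.frame(out)
  traj$reformed <- traj$reformed > 0
  class(traj) <- c("macro_trajectory", "data.frame")
  traj
}

#' @export
print.macro_trajectory <- function(x, ...) {
  cat("Macro trajectory:", nrow(x), "steps; final z =",
      format(x$z[nrow(x)], digits = 4),
      "f =", format(x$f[nrow(x)], digits = 4),
      if (any(x$reformed)) sprintf("(reforms from step %d)",
                                   min(x$step[x$reformed])) else
        "(no reforms)", "\n")
  invisible(x)
}

#' @export
plot.macro_trajectory <- function(x, ...) {
  graphics::matplot(x$step, cbind(x$z, x$f, x$p_star), type = "l",
                    lty = 1, xlab = "step", ylab = "fraction", ...)
  graphics::legend("topleft", c("z", "f", "p*"), lty = 1, col = 1:3,
                   bty = "n")
  invisible(x)
}

#' Democracy and corruption-suppression indices for one society
#'
#' The democracy index combines intrinsic altruism and voting enthusiasm,
#' \eqn{DI = p^* + e^{-p_v T} - p^* e^{-p_v T}}
#' (equivalently \eqn{1 - (1 - p^*)(1 - e^{-p_v T})}); the
#' corruption-suppression index measures how much recruitment into the
#' parochial group has been curbed relative to the pre-reform ensemble
#' average, \eqn{CSI = 1 - p_a / \langle p_a \rangle}.
#'
#' @param p,pv,tau1,T Current rates and windows.
#' @param pa Current recruitment rate; \code{pa_mean} the pre-reform ensemble
#'   average it is compared against.
#' @param pa_mean Ensemble average of pre-reform recruitment rates.
#' @param p_star_form \code{"exact"} (default) or \code{"exponential"} form
#'   of p*.
#' @return List with \code{DI_raw} and \code{CSI_raw}.
#' @export
society_indices <- function(p, pv, tau1, T, pa, pa_mean,
                            p_star_form = c("exact", "exponential")) {
  p_star_form <- match.arg(p_star_form)
  p_star <- effective_probability(p, tau1, p_star_form)
  e <- exp(-pv * T)
  list(DI_raw = p_star + e - p_star * e,
       CSI_raw = 1 - pa / pa_mean)
}

#' Simulate an ensemble of societies and their indices
#'
#' Draws per-society initial rates uniformly from configured ranges, runs the
#' slow dynamics for each, and converts the end states into model-generated
#' democracy (DI) and corruption-suppression (CSI) indices, min-max rescaled
#' to [0, 1] over the ensemble. Societies whose altruists came to outvote the
#' parochialist-opportunist bloc have had their recruitment and apathy rates
#' reformed away, so they populate the steep high-democracy arm of the
#' DI-CSI scatter.
#'
#' @param n_countries Number of simulated societies (>= 2).
#' @param ranges Named list of c(min, max) ranges for \code{pa}, \code{pv},
#'   \code{p}, \code{r}, \code{f0}; see \code{\link{gen_country_params}} for
#'   the defaults.
#' @param horizon Steps of slow dynamics per society.
#' @param seed Integer seed; the ensemble is deterministic given the seed.
#' @param params Shared slow-dynamics parameters as in \code{\link{run_macro}}
#'   (defaults: tau1 = 10, tau2 = 10, T = 20, epsilon = 3e-4,
#'   zeta_a = zeta_v = 0.05, mu = 6, and the reference overdispersed degree
#'   distribution with 20\% of agents at degree 2 and 80\% at degree 10 --
#'   the sparsely connected minority is unconditionally receptive to induced
#'   altruism and seeds the explosive transition).
#' @return Object of class \code{"index_ensemble"}: a data frame with one row
#'   per society (draws, final rates, DI/CSI raw and rescaled, reform flag).
#'   A degenerate CSI (all pre-reform pa equal) is flagged via the
#'   \code{"csi_degenerate"} attribute.
#' @export
simulate_ensemble <- function(n_countries = 200, ranges = NULL,
                              horizon = 600, seed = 1, params = NULL) {
  if (n_countries < 2) stop("'n_countries' must be >= 2")
  if (is.null(params)) params <- list()
  defaults <- list(tau1 = 10, tau2 = 10, T = 20, epsilon = 3e-4,
                   zeta_a = 0.05, zeta_v = 0.05, mu = 6,
                   degree_dist = degree_distribution(c(2, 10), c(0.2, 0.8)),
                   convention = "printed", enthusiasm_form = "exponential")
  for (nm in names(defaults))
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  draws <- gen_country_params(n_countries, ranges, seed)
  res <- vector("list", n_countries)
  for (i in seq_len(n_countries)) {
    pars_i <- params
    pars_i$r <- draws$r[i]
    traj <- run_macro(list(f = draws$f0[i], p = draws$p[i],
                           pa = draws$pa[i], pv = draws$pv[i]),
                      pars_i, horizon)
    last <- traj[nrow(traj), ]
    res[[i]] <- data.frame(country_id = i, pa0 = draws$pa[i],
                           pv0 = draws$pv[i], p0 = draws$p[i],
                           r = draws$r[i], f0 = draws$f0[i],
                           z_final = last$z, f_final = last$f,
                           p_final = last$p, pa_final = last$pa,
                           pv_final = last$pv,
                           reformed = any(traj$reformed))
  }
  ens <- do.call(rbind, res)
  pa_mean <- mean(ens$pa0)   # pre-reform ensemble average
  idx <- society_indices(ens$p_final, ens$pv_final, params$tau1, params$T,
                         ens$pa_final, pa_mean)
  ens$DI_raw <- idx$DI_raw
  ens$CSI_raw <- idx$CSI_raw
  rescale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(0.5, length(x)))
    (x - rng[1]) / diff(rng)
  }
  ens$DI <- rescale01(ens$DI_raw)
  ens$CSI <- rescale01(ens$CSI_raw)
  attr(ens, "csi_degenerate") <- diff(range(ens$CSI_raw)) == 0
  if (attr(ens, "csi_degenerate"))
    warning("all pre-reform pa equal: CSI is degenerate")
  class(ens) <- c("index_ensemble", "data.frame")
  ens
}

#' @export
print.index_ensemble <- function(x, ...) {
  cat("Index ensemble:", nrow(x), "simulated societies;",
      sum(x$reformed), "reformed\n")
  cat("DI range [", format(min(x$DI_raw), digits = 3), ",",
      format(max(x$DI_raw), digits = 3), "] raw; CSI raw range [",
      format(min(x$CSI_raw), digits = 3), ",",
      format(max(x$CSI_raw), digits = 3), "]\n")
  invisible(x)
}

#' @export
plot.index_ensemble <- function(x, ...) {
  graphics::plot(x$DI, x$CSI, xlab = "Democracy index (rescaled)",
                 ylab = "Corruption-suppression index (rescaled)",
                 col = ifelse(x$reformed, 2, 1), ...)
  invisible(x)
}

#' Sweep p* up and down along the mean-field branch
#'
#' Warm-started continuation of the altruist share along an increasing then
#' decreasing grid of \eqn{p^*}; inside the bistable wedge the two sweeps
#' trace different branches (hysteresis), outside they coincide.
#'
#' @param p_star_grid Increasing grid of p* values.
#' @param r_star,f,mu,degree_dist,convention Mean-field settings.
#' @return Data frame with columns p_star, z_up, z_down.
#' @export
hysteresis_sweep <- function(p_star_grid, r_star, f, mu, degree_dist,
                             convention = "printed") {
  up <- numeric(length(p_star_grid))
  z <- 0
  for (i in seq_along(p_star_grid)) {
    mfp <- meanfield_params(p_star_grid[i], r_star, f, mu, degree_dist,
                            convention)
    z <- solve_branch(z, mfp)
    up[i] <- z
  }
  down <- numeric(length(p_star_grid))
  z <- up[length(up)]
  for (i in rev(seq_along(p_star_grid))) {
    mfp <- meanfield_params(p_star_grid[i], r_star, f, mu, degree_dist,
                            convention)
    z <- solve_branch(z, mfp)
    down[i] <- z
  }
  data.frame(p_star = p_star_grid, z_up = up, z_down = down)
}
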