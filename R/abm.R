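#' Society-level parameter set for the agent-based model
#'
#' Collects every micro- and macro-scale rate of the spin model. Agents carry
#' an intrinsic-preference spin s1 (flips up with probability \code{p} per
#' step, persists \code{tau1} steps), an induced-preference spin s2 (flips up
#' with probability \code{r} while the neighbourhood eligibility condition
#' holds, persists \code{tau2} steps) and a voting spin sD (apathy flips with
#' probability \code{pv}, persists \code{T} steps). Opportunists are accepted
#' into the parochial group with probability \code{pa} per step; membership
#' is absorbing and members densify to mean total degree \code{kp}.
#'
#' @param N Agent count (>= 2).
#' @param k0 Baseline mean degree (> 0, < N).
#' @param kp Parochial mean total degree (> k0, < N).
#' @param mu Altruist-neighbourhood threshold (integer >= 0).
#' @param p Per-step intrinsic flip probability.
#' @param r Per-step induced flip probability.
#' @param tau1,tau2 Persistence windows (steps, >= 1).
#' @param pa Per-step acceptance probability into the parochial group.
#' @param pv Per-step apathy flip probability.
#' @param T Apathy persistence (steps, >= 1).
#' @param epsilon Drift rate of p (>= 0).
#' @param zeta_a,zeta_v Reform rates (>= 0).
#' @param f0 Initial parochial fraction in [0, 1).
#' @param convention Eligibility convention, \code{"printed"} (eligible iff
#'   at most \code{mu} non-altruist neighbours) or \code{"textual"} (at least
#'   \code{mu} altruist neighbours).
#' @return An object of class \code{"society_params"}.
#' @examples
#' society_params(N = 500, k0 = 8, kp = 20, mu = 6, p = 0.01, r = 0.2)
#' @export
society_params <- function(N, k0, kp = 3 * k0, mu = 6, p = 0.01, r = 0.1,
                           tau1 = 10, tau2 = 10, pa = 0, pv = 0, T = 20,
                           epsilon = 0, zeta_a = 0, zeta_v = 0, f0 = 0,
                           convention = c("printed", "textual")) {
  convention <- match.arg(convention)
  N <- as.integer(N)
  if (N < 2) stop("'N' must be >= 2")
  if (k0 <= 0 || k0 >= N) stop("'k0' must lie in (0, N)")
  if (kp >= N) stop("'kp' >= N: impossible edge density")
  if (kp <= k0) stop("'kp' must exceed 'k0'")
  for (nm in c("p", "r", "pa", "pv")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop("'", nm, "' must lie in [0, 1]")
  }
  if (f0 < 0 || f0 >= 1) stop("'f0' must lie in [0, 1)")
  if (tau1 < 1 || tau2 < 1 || T < 1) stop("persistence windows must be >= 1")
  if (epsilon < 0 || zeta_a < 0 || zeta_v < 0)
    stop("drift/reform rates must be >= 0")
  if (mu < 0 || mu != round(mu)) stop("'mu' must be a non-negative integer")
  structure(list(N = N, k0 = k0, kp = kp, mu = as.integer(mu), p = p, r = r,
                 tau1 = as.integer(tau1), tau2 = as.integer(tau2), pa = pa,
                 pv = pv, T = as.integer(T), epsilon = epsilon,
                 zeta_a = zeta_a, zeta_v = zeta_v, f0 = f0,
                 convention = convention),
            class = "society_params")
}

#' @export
print.society_params <- function(x, ...) {
  cat("Society parameters: N =", x$N, ", k0 =", x$k0, ", kp =", x$kp,
      ", mu =", x$mu, "(", x$convention, ")\n")
  cat("  spins: p =", x$p, "tau1 =", x$tau1, "| r =", x$r, "tau2 =", x$tau2,
      "| pv =", x$pv, "T =", x$T, "\n")
  cat("  slow: pa =", x$pa, "epsilon =", x$epsilon, "zeta_a =", x$zeta_a,
      "zeta_v =", x$zeta_v, "f0 =", x$f0, "\n")
  invisible(x)
}

#' Build the social network
#'
#' Friendships form indiscriminately as an Erdős–Rényi graph with edge
#' probability \code{k0 / (N - 1)}. A fraction \code{f0} of agents, chosen
#' uniformly, starts as parochial-group members; members gain additional
#' in-group (member-member) edges so that their mean total degree is
#' approximately \code{kp}.
#'
#' @param params A \code{\link{society_params}} object.
#' @param seed Integer seed; the graph is deterministic given
#'   \code{(params, seed)}.
#' @return Object of class \code{"society_graph"}: list with \code{N},
#'   \code{edges} (2-column matrix), \code{adj} (adjacency list),
#'   \code{degree}, logical \code{member}.
#' @export
build_society <- function(params, seed = 1) {
  stopifnot(inherits(params, "society_params"))
  set.seed(seed)
  N <- params$N
  g <- igraph::sample_gnp(N, params$k0 / (N - 1))
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  member <- rep(FALSE, N)
  n_m <- round(params$f0 * N)
  if (n_m > 0) {
    member[sample.int(N, n_m)] <- TRUE
    if (n_m > 1) {
      extra <- params$kp - params$k0
      q <- extra / (n_m - 1)
      if (q > 1)
        stop("too few members to reach mean degree kp: ",
             "need kp - k0 <= ", n_m - 1)
      ids <- which(member)
      pairs <- utils::combn(n_m, 2)
      keep <- stats::runif(ncol(pairs)) < q
      if (any(keep)) {
        new_edges <- cbind(ids[pairs[1, keep]], ids[pairs[2, keep]])
        edges <- rbind(edges, new_edges)
        edges <- unique(edges)   # ER layer may already hold a member pair
      }
    }
  }
  graph_from_edges(N, edges, member)
}

# assemble the society_graph object from an integer edge matrix
graph_from_edges <- function(N, edges, member) {
  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = N)
  adj <- vector("list", N)
  if (nrow(edges)) {
    ends <- c(edges[, 1], edges[, 2])
    other <- c(edges[, 2], edges[, 1])
    ord <- order(ends)
    adj <- split(other[ord], factor(ends[ord], levels = seq_len(N)))
    adj <- unname(adj)
  }
  structure(list(N = N, edges = edges, adj = adj, degree = degree,
                 member = member),
            class = "society_graph")
}

#' @export
print.society_graph <- function(x, ...) {
  cat("Society graph:", x$N, "agents,", nrow(x$edges), "friendships; ",
      sum(x$member), "parochial members\n")
  cat("  mean degree", format(mean(x$degree), digits = 4))
  if (any(x$member))
    cat("; member mean degree", format(mean(x$degree[x$member]), digits = 4))
  cat("\n")
  invisible(x)
}

# sparse adjacency of the initial (non-member-relevant) friendship layer;
# altruist-neighbour counts are A %*% indicator
society_adjacency <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(graph$N, graph$N))
}

# fresh spin-state collection: spins down, sD up (baseline), clocks "never"
init_states <- function(N, member) {
  list(last_s1 = rep(NA_integer_, N), last_s2 = rep(NA_integer_, N),
       last_sD = rep(NA_integer_, N), member = member)
}

# spin values implied by the trial clocks at 'step'
spin_values <- function(states, params, step) {
  s1 <- !is.na(states$last_s1) & (step - states$last_s1 < params$tau1)
  s2 <- !is.na(states$last_s2) & (step - states$last_s2 < params$tau2)
  sD <- is.na(states$last_sD) | (step - states$last_sD >= params$T)
  sD[states$member] <- TRUE
  list(s1 = s1, s2 = s2, sD = sD)
}

# eligibility of each agent given altruist flags of the previous step
eligibility <- function(alt_count, degree, mu, convention) {
  if (convention == "printed") (degree - alt_count) <= mu
  else alt_count >= mu
}

#' One synchronous spin-update step
#'
#' Every non-member agent runs an independent Bernoulli(p) trial for the
#' intrinsic spin (s1 = 1 iff a success occurred within the trailing
#' \code{tau1} steps), a Bernoulli(r) trial for the induced spin while the
#' eligibility condition on the previous step's altruist labels holds (s2 = 1
#' iff eligible now and a success occurred within \code{tau2} steps), and a
#' Bernoulli(pv) apathy trial (sD = 0 iff a success occurred within \code{T}
#' steps). Members are pinned: permanently parochial and always enthusiastic.
#'
#' @param graph A \code{society_graph}.
#' @param states State collection as produced by \code{\link{run_abm}}
#'   internals: trial clocks \code{last_s1}, \code{last_s2}, \code{last_sD}
#'   and the membership flag.
#' @param params A \code{society_params}.
#' @param step Current step index (>= 1).
#' @param prev_altruist Logical vector of the previous step's altruist
#'   labels, used for neighbour counting.
#' @param adjacency Optional precomputed sparse adjacency.
#' @return Updated state collection, with the realized spins and the
#'   eligibility flags attached as attributes.
#' @export
step_spins <- function(graph, states, params, step, prev_altruist = NULL,
                       adjacency = NULL) {
  N <- graph$N
  if (length(states$last_s1) != N) stop("state collection size mismatch")
  if (is.null(prev_altruist)) prev_altruist <- rep(FALSE, N)
  if (is.null(adjacency)) adjacency <- society_adjacency(graph)
  non <- !states$member
  # s1: intrinsic trials every step, state-independent
  hit1 <- stats::runif(N) < params$p
  states$last_s1[hit1 & non] <- step
  # s2: trials only while eligible (previous step's altruist labels)
  alt_count <- as.numeric(adjacency %*% prev_altruist)
  elig <- eligibility(alt_count, graph$degree, params$mu, params$convention)
  hit2 <- stats::runif(N) < params$r
  states$last_s2[hit2 & elig & non] <- step
  # sD: apathy trials every step
  hitv <- stats::runif(N) < params$pv
  states$last_sD[hitv & non] <- step
  spins <- spin_values(states, params, step)
  spins$s2 <- spins$s2 & elig          # s2 requires eligibility *now*
  attr(states, "spins") <- spins
  attr(states, "eligible") <- elig
  states
}

#' Classify agents into altruists, opportunists and parochialists
#'
#' Altruists are non-members in spin state |1,1>; parochialists are members
#' regardless of spins; the rest are opportunists.
#'
#' @param spins List with logical vectors \code{s1} and \code{s2}.
#' @param member Logical membership vector.
#' @return Object of class \code{"type_counts"}: list with fractions
#'   \code{z}, \code{d}, \code{f} summing to 1 exactly, plus the logical
#'   \code{altruist} labels.
#' @export
classify_agents <- function(spins, member) {
  N <- length(member)
  altruist <- spins$s1 & spins$s2 & !member
  nz <- sum(altruist); nf <- sum(member)
  structure(list(z = nz / N, d = (N - nz - nf) / N, f = nf / N,
                 altruist = altruist),
            class = "type_counts")
}

#' @export
print.type_counts <- function(x, ...) {
  cat(sprintf("z = %.4f (altruists), d = %.4f (opportunists), f = %.4f (parochialists)\n",
              x$z, x$d, x$f))
  invisible(x)
}

#' Recruit opportunists into the parochial group
#'
#' Each current opportunist independently joins with probability \code{pa};
#' a new member draws Poisson(max(kp - degree, 0)) extra in-group edges to
#' uniformly sampled existing members. Membership is absorbing.
#'
#' @param graph A \code{society_graph}.
#' @param opportunist Logical vector of current opportunist labels.
#' @param params A \code{society_params}.
#' @return List with the updated \code{graph} and the indices of the
#'   \code{new_members}.
#' @export
recruit_parochialists <- function(graph, opportunist, params) {
  if (params$pa <= 0) return(list(graph = graph, new_members = integer(0)))
  cand <- which(opportunist & !graph$member)
  joins <- cand[stats::runif(length(cand)) < params$pa]
  if (!length(joins)) return(list(graph = graph, new_members = integer(0)))
  if (!any(graph$member))
    warning("recruitment with no existing members: no in-group edges attached")
  new_edges <- list()
  for (i in joins) {
    graph$member[i] <- TRUE
    pool <- setdiff(which(graph$member), i)
    if (!length(pool)) next
    want <- stats::rpois(1, max(params$kp - graph$degree[i], 0))
    want <- min(want, length(pool))
    if (want > 0) {
      tgt <- pool[sample.int(length(pool), want)]
      tgt <- setdiff(tgt, graph$adj[[i]])   # simple graph: no multi-edges
      if (length(tgt)) {
        new_edges[[length(new_edges) + 1L]] <- cbind(i, tgt)
        graph$degree[i] <- graph$degree[i] + length(tgt)
        graph$degree[tgt] <- graph$degree[tgt] + 1L
        graph$adj[[i]] <- c(graph$adj[[i]], tgt)
        for (j in tgt) graph$adj[[j]] <- c(graph$adj[[j]], i)
      }
    }
  }
  if (length(new_edges)) {
    ne <- do.call(rbind, new_edges)
    storage.mode(ne) <- "integer"
    colnames(ne) <- NULL
    graph$edges <- rbind(graph$edges, ne)
  }
  list(graph = graph, new_members = joins)
}

#' Run the stochastic agent-based model
#'
#' Assembles the full microdynamics: per step, synchronous spin updates,
#' classification into types, recruitment into the (absorbing) parochial
#' group, the slow upward drift of the intrinsic rate p, and the
#' election-triggered reform of pa and pv.
#'
#' In-group edges gained by members never affect non-member eligibility
#' (altruists are never members), so the spin dynamics use the fixed initial
#' friendship layer while member degrees are tracked for bookkeeping.
#'
#' @param params A \code{\link{society_params}}.
#' @param horizon Number of steps (>= 1).
#' @param seed Integer seed; output is identical for identical
#'   \code{(params, horizon, seed)}.
#' @return Object of class \code{"abm_trajectory"}: data frame with per-step
#'   columns (step, z, d, f, p, pa, pv, s1_frac, eligible_frac, enth_non,
#'   altruist_share, bloc_share, reformed), with the final
#'   \code{society_graph} attached as attribute \code{"graph"} and the seed
#'   as attribute \code{"seed"}.
#' @export
run_abm <- function(params, horizon, seed = 1) {
  stopifnot(inherits(params, "society_params"), horizon >= 1)
  graph <- build_society(params, seed)
  adjacency <- society_adjacency(graph)
  states <- init_states(params$N, graph$member)
  prev_alt <- rep(FALSE, params$N)
  p <- params$p; pa <- params$pa; pv <- params$pv
  out <- matrix(NA_real_, horizon, 13)
  colnames(out) <- c("step", "z", "d", "f", "p", "pa", "pv", "s1_frac",
                     "eligible_frac", "enth_non", "altruist_share",
                     "bloc_share", "reformed")
  pars_t <- params
  for (t in seq_len(horizon)) {
    pars_t$p <- p; pars_t$pa <- pa; pars_t$pv <- pv
    states <- step_spins(graph, states, pars_t, t, prev_alt, adjacency)
    spins <- attr(states, "spins")
    tc <- classify_agents(spins, graph$member)
    rec <- recruit_parochialists(graph, !tc$altruist & !graph$member, pars_t)
    graph <- rec$graph
    states$member <- graph$member
    # slow couplings: drift of p, election check, reforms
    p <- p + params$epsilon * (1 - p)
    non <- !graph$member
    f_now <- mean(graph$member)
    d_now <- 1 - tc$z - f_now
    enth_non <- if (any(non)) mean(spins$sD[non]) else 0
    e_formula <- exp(-pv * params$T)
    vs <- vote_shares(tc$z, d_now, f_now, e_formula)
    reformed <- FALSE
    if ((tc$z - d_now) * e_formula - f_now > 0 &&
        (params$zeta_a > 0 || params$zeta_v > 0)) {
      pa <- pa * (1 - params$zeta_a)
      pv <- pv * (1 - params$zeta_v)
      reformed <- TRUE
    }
    out[t, ] <- c(t, tc$z, d_now, f_now, pars_t$p, pars_t$pa, pars_t$pv,
                  mean(spins$s1[non]), mean(attr(states, "eligible")[non]),
                  enth_non, vs$altruist_share, vs$bloc_share,
                  as.numeric(reformed))
    prev_alt <- tc$altruist
  }
  traj <- as.data.frame(out)
  traj$reformed <- traj$reformed > 0
  attr(traj, "graph") <- graph
  attr(traj, "seed") <- seed
  class(traj) <- c("abm_trajectory", "data.frame")
  traj
}

#' @export
print.abm_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat("ABM trajectory:", n, "steps; final (z, d, f) = (",
      sprintf("%.4f, %.4f, %.4f", x$z[n], x$d[n], x$f[n]), ")\n")
  invisible(x)
}

#' @export
plot.abm_trajectory <- function(x, ...) {
  graphics::matplot(x$step, cbind(x$z, x$d, x$f), type = "l", lty = 1,
                    xlab = "step", ylab = "fraction", ...)
  graphics::legend("right", c("z", "d", "f"), lty = 1, col = 1:3, bty = "n")
  invisible(x)
}
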