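# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: enumeration, brute-force scanning and
# single-agent renewal simulation.

# Exact neighbourhood eligibility probability by enumeration over all 2^k
# neighbour configurations (k small).
enumerate_neighborhood <- function(k, mu, z, convention = "printed") {
  if (k == 0) {
    if (convention == "printed") return(1)
    return(as.numeric(mu == 0))
  }
  configs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  n_alt <- rowSums(configs)
  probs <- z^n_alt * (1 - z)^(k - n_alt)
  ok <- if (convention == "printed") (k - n_alt) <= mu else n_alt >= mu
  sum(probs[ok])
}

# Brute-force root scan of g(z) = z - (1-f) p* r* E(z) with linear
# interpolation at sign changes.
brute_roots <- function(params, n = 1e6) {
  hi <- 1 - params$f
  zs <- seq(0, hi, length.out = n)
  gs <- zs - demotip::neighborhood_term(zs, params) *
    (1 - params$f) * params$p_star * params$r_star
  roots <- zs[abs(gs) < 1e-12]
  sgn <- sign(gs)
  idx <- which(sgn[-1] * sgn[-n] < 0)
  if (length(idx)) {
    z1 <- zs[idx]; z2 <- zs[idx + 1]
    g1 <- gs[idx]; g2 <- gs[idx + 1]
    roots <- c(roots, z1 - g1 * (z2 - z1) / (g2 - g1))
  }
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-7)]
  roots
}

# Single-agent renewal simulation: long-run fraction of steps on which at
# least one success occurred within the trailing window.
renewal_fraction <- function(rate, window, steps = 1e5, seed = 99) {
  set.seed(seed)
  hits <- runif(steps) < rate
  within <- stats::filter(hits, rep(1, window), sides = 1)
  mean(within > 0, na.rm = TRUE)
}

# Tiny deterministic society for unit tests.
tiny_params <- function(...) {
  args <- list(...)
  defaults <- list(N = 200, k0 = 6, kp = 18, mu = 4, p = 0.02, r = 0.2,
                   tau1 = 5, tau2 = 5, pa = 0, pv = 0.02, T = 10,
                   epsilon = 0, zeta_a = 0, zeta_v = 0, f0 = 0)
  defaults[names(args)] <- args
  do.call(demotip::society_params, defaults)
}

# Reference fold scenario: overdispersed degrees with an unconditionally
# receptive minority; has a genuine saddle-node along p*.
fold_degree_dist <- function() demotip::degree_distribution(c(2, 10), c(0.2, 0.8))

fold_macro_params <- function(...) {
  args <- list(...)
  defaults <- list(r_star = 0.9, tau1 = 10, T = 20, epsilon = 3e-4,
                   zeta_a = 0, zeta_v = 0, mu = 6,
                   degree_dist = fold_degree_dist())
  defaults[names(args)] <- args
  defaults
}
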