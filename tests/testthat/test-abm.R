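test_that("society graphs hit their target densities", {
  sp <- tiny_params(N = 1000, k0 = 10, kp = 30, f0 = 0)
  g <- build_society(sp, seed = 1)
  expect_equal(sum(g$member), 0)
  # ER mean degree k0 within 3 s.e. (degree variance ~ k0)
  expect_lt(abs(mean(g$degree) - 10), 3 * sqrt(10 / 1000))
  sp2 <- tiny_params(N = 1000, k0 = 10, kp = 30, f0 = 0.1)
  g2 <- build_society(sp2, seed = 2)
  expect_equal(sum(g2$member), 100)
  mdeg <- mean(g2$degree[g2$member])
  expect_lt(abs(mdeg - 30), 3 * sqrt(30 / 100))
  expect_gt(mean(g2$degree[g2$member]), mean(g2$degree[!g2$member]))
  # determinism: identical seed, identical edge set
  g3 <- build_society(sp2, seed = 2)
  expect_identical(g2$edges, g3$edges)
  expect_identical(g2$member, g3$member)
})

test_that("impossible configurations are rejected", {
  expect_error(society_params(N = 100, k0 = 10, kp = 120), "impossible")
  expect_error(society_params(N = 100, k0 = 10, kp = 30, f0 = 1), "f0")
  expect_error(society_params(N = 100, k0 = 10, kp = 30, p = 1.5), "p")
})

test_that("spin trials respect their zero- and certain-rate limits", {
  sp <- tiny_params(N = 50, p = 0, r = 0, pv = 0)
  g <- build_society(sp, seed = 3)
  st <- demotip:::init_states(sp$N, g$member)
  adjacency <- demotip:::society_adjacency(g)
  for (t in 1:5)
    st <- step_spins(g, st, sp, t, adjacency = adjacency)
  spins <- attr(st, "spins")
  expect_true(all(!spins$s1))       # p = 0: nothing ever flips
  expect_true(all(!spins$s2))
  expect_true(all(spins$sD))        # pv = 0: everyone enthusiastic
  sp1 <- tiny_params(N = 50, p = 1, tau1 = 1)
  st1 <- demotip:::init_states(sp1$N, g$member)
  st1 <- step_spins(g, st1, sp1, 1, adjacency = adjacency)
  expect_true(all(attr(st1, "spins")$s1))   # certain flip
})

test_that("agent classification counts types exactly", {
  member <- rep(c(TRUE, FALSE), c(150, 850))
  s1 <- s2 <- rep(FALSE, 1000)
  s1[151:450] <- TRUE; s2[151:450] <- TRUE    # 300 non-members at |1,1>
  s1[451:700] <- TRUE                          # |1,0> opportunists
  tc <- classify_agents(list(s1 = s1, s2 = s2), member)
  expect_equal(c(tc$z, tc$d, tc$f), c(0.30, 0.55, 0.15))
  expect_equal(tc$z + tc$d + tc$f, 1)
  # all members
  tc2 <- classify_agents(list(s1 = s1, s2 = s2), rep(TRUE, 1000))
  expect_equal(tc2$f, 1)
  # all non-members at |1,1>
  tc3 <- classify_agents(list(s1 = rep(TRUE, 10), s2 = rep(TRUE, 10)),
                         rep(FALSE, 10))
  expect_equal(c(tc3$z, tc3$d, tc3$f), c(1, 0, 0))
})

test_that("recruitment is absorbing and matches its binomial rate", {
  sp <- tiny_params(N = 1000, f0 = 0.1, pa = 0)
  g <- build_society(sp, seed = 4)
  out <- recruit_parochialists(g, rep(TRUE, 1000), sp)
  expect_identical(out$graph$member, g$member)   # pa = 0: no change
  # members never revert, and are never re-recruited
  sp2 <- tiny_params(N = 1000, f0 = 0.1, pa = 1)
  out2 <- recruit_parochialists(g, rep(TRUE, 1000), sp2)
  expect_true(all(out2$graph$member[g$member]))
  expect_false(any(out2$new_members %in% which(g$member)))
  # expected recruit count pa * d * N, checked over replicates
  sp3 <- tiny_params(N = 1000, f0 = 0.1, pa = 0.1)
  opportunist <- !g$member & (seq_len(1000) %% 2 == 0)  # d ~ 0.45
  d <- mean(opportunist & !g$member)
  set.seed(11)
  recruits <- replicate(60, length(
    recruit_parochialists(g, opportunist, sp3)$new_members))
  expected <- 0.1 * sum(opportunist & !g$member)
  se <- sqrt(expected * 0.9 / 60)
  expect_lt(abs(mean(recruits) - expected), 3 * se)
})

test_that("trajectories conserve shares, absorb membership and are reproducible", {
  sp <- tiny_params(N = 400, f0 = 0.05, pa = 0.002, pv = 0.02, epsilon = 1e-3,
                    zeta_a = 0.05, zeta_v = 0.05)
  tr <- run_abm(sp, 60, seed = 9)
  expect_equal(tr$z + tr$d + tr$f, rep(1, 60))
  expect_true(all(diff(tr$f) >= 0))
  expect_true(all(diff(tr$p) >= 0))
  expect_true(all(diff(tr$pa) <= 0) && all(tr$pa >= 0))
  tr2 <- run_abm(sp, 60, seed = 9)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("stationary spin fractions match their closed forms", {
  # moderate size here; the large-N check lives in the acceptance suite
  sp <- tiny_params(N = 4000, k0 = 8, kp = 24, p = 0.02, r = 0, tau1 = 8,
                    pv = 0.02, T = 15)
  tr <- run_abm(sp, 100, seed = 21)
  p_star <- 1 - 0.98^8
  enth <- 0.98^15
  s1_obs <- mean(tr$s1_frac[41:100])
  enth_obs <- mean(tr$enth_non[41:100])
  expect_lt(abs(s1_obs - p_star), 3 * sqrt(p_star * (1 - p_star) / 4000))
  expect_lt(abs(enth_obs - enth), 3 * sqrt(enth * (1 - enth) / 4000))
})

test_that("frozen-f equilibrium altruism matches the mean-field prediction", {
  # epsilon = pa = 0: f constant; z fluctuates about (1-f) p* r* E-hat
  sp <- tiny_params(N = 4000, k0 = 10, kp = 30, mu = 6, p = 0.05, r = 0.3,
                    tau1 = 10, tau2 = 10, pv = 0, f0 = 0.1)
  tr <- run_abm(sp, 120, seed = 31)
  expect_equal(var(tr$f), 0)
  p_star <- 1 - 0.95^10
  r_star <- 1 - 0.7^10
  ehat <- mean(tr$eligible_frac[61:120])
  target <- (1 - 0.1) * p_star * r_star * ehat
  z_obs <- mean(tr$z[61:120])
  se <- sqrt(target * (1 - target) / 4000)
  expect_lt(abs(z_obs - target), 4 * se)
})
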