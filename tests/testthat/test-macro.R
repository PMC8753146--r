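test_that("enthusiastic fraction: exact form, approximation and limits", {
  expect_equal(enthusiastic_fraction(0, 20), 1)
  expect_equal(enthusiastic_fraction(1, 5, "exact"), 0)
  expect_equal(enthusiastic_fraction(0.01, 20, "exact"), 0.99^20)
  expect_equal(enthusiastic_fraction(0.01, 20), exp(-0.2))
  expect_equal(round(enthusiastic_fraction(0.01, 20, "exact"), 6), 0.817907)
  expect_equal(round(enthusiastic_fraction(0.01, 20), 6), 0.818731)
})

test_that("the worked election example and vote-share limits come out exactly", {
  vs <- vote_shares(0.5, 0.35, 0.15, 0.8)
  expect_equal(vs$altruist_share, 0.40)
  expect_equal(vs$bloc_share, 0.43)
  expect_false(vs$altruists_win)
  expect_equal(vote_shares(1, 0, 0, 1)$altruist_share, 1)
  expect_equal(vote_shares(1, 0, 0, 1)$bloc_share, 0)
  vs0 <- vote_shares(0.5, 0.35, 0.15, 0)
  expect_equal(vs0$altruist_share, 0)
  expect_equal(vs0$bloc_share, 0.15)
  expect_error(vote_shares(0.5, 0.5, 0.5, 1), "sum to 1")
})

test_that("reforms decay rates multiplicatively and only on strict wins", {
  st <- list(z = 0.5, d = 0.2, f = 0.3, pa = 0.1, pv = 0.05)
  # condition = (0.3) * e - 0.3 <= 0 for any e <= 1: no reform
  unchanged <- reform_step(st, 0.05, 0.05, enthusiasm = 1)  # H(0) = 0
  expect_equal(unchanged$pa, 0.1)
  st2 <- list(z = 0.6, d = 0.2, f = 0.2, pa = 0.1, pv = 0.05)
  reformed <- reform_step(st2, 0.05, 0.1, enthusiasm = 0.9)
  expect_equal(reformed$pa, 0.095)
  expect_equal(reformed$pv, 0.045)
  for (i in 1:200) st2 <- reform_step(st2, 0.1, 0.1, enthusiasm = 0.9)
  expect_true(st2$pa >= 0 && st2$pa < 1e-8)
})

test_that("drift updates f and p at their stated rates and respect bounds", {
  st <- list(z = 0.3, f = 0.2, p = 0.4)
  out <- drift_step(st, epsilon = 0.01, pa = 0.1)
  expect_equal(out$f, 0.2 + 0.1 * (1 - 0.3 - 0.2))  # Delta f = 0.05
  expect_equal(out$p, 0.4 + 0.01 * 0.6)
  # saturated cases
  expect_equal(drift_step(list(z = 0.8, f = 0.2, p = 0.5), 0.01, 0.3)$f, 0.2)
  expect_equal(drift_step(list(z = 0, f = 0, p = 1), 0.05, 0)$p, 1)
})

test_that("slow dynamics conserve shares and freeze rates without reforms", {
  pars <- fold_macro_params(zeta_a = 0, zeta_v = 0)
  tr <- run_macro(list(f = 0.1, p = 0.01, pa = 1e-4, pv = 0.02), pars, 100)
  expect_equal(tr$z + tr$d + tr$f, rep(1, 100))
  expect_true(all(diff(tr$p) >= 0))
  expect_equal(var(tr$pa), 0)   # zeta_a = 0
  expect_equal(var(tr$pv), 0)
  expect_true(all(diff(tr$f) >= 0))
})

test_that("continuation through the fold produces an explosive jump", {
  pars <- fold_macro_params()
  tr <- run_macro(list(f = 0.1, p = 0.005, pa = 0, pv = 0.02), pars, 600)
  dz <- diff(tr$z)
  j <- which.max(dz)
  expect_gt(j, 2)
  expect_gt(dz[j], 10 * dz[j - 1])
  expect_gt(tr$z[j + 1], 0.5)    # lands on the high-altruism branch
})

test_that("up and down sweeps differ only inside the bistable window", {
  dd <- fold_degree_dist()
  ps <- seq(0.4, 1, by = 0.01)
  hs <- hysteresis_sweep(ps, r_star = 0.9, f = 0.1, mu = 6, dd)
  differs <- abs(hs$z_up - hs$z_down) > 1e-6
  nroots <- vapply(ps, function(p) length(fixed_points(
    meanfield_params(p, 0.9, 0.1, 6, dd))$roots), integer(1))
  bistable <- nroots >= 3
  expect_true(any(differs))
  expect_true(any(!differs))
  expect_identical(differs, bistable)
})

test_that("final altruism falls as the initial parochial pool grows", {
  pars <- fold_macro_params()
  finals <- vapply(c(0, 0.08, 0.16, 0.24), function(f0) {
    tr <- run_macro(list(f = f0, p = 0.005, pa = 0, pv = 0.02), pars, 400)
    tr$z[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-9))
})

test_that("society indices follow their defining formulas", {
  idx <- society_indices(p = 1, pv = 0.5, tau1 = 5, T = 20, pa = 0.05,
                         pa_mean = 0.05)
  expect_equal(idx$DI_raw, 1)      # p* = 1 makes DI 1 regardless of pv
  expect_equal(idx$CSI_raw, 0)     # pa at the ensemble average
  # DI = 1 - (1 - p*)(1 - e^(-pv T)): monotone up in p*, down in pv
  di <- function(p, pv) society_indices(p, pv, 10, 20, 1, 1)$DI_raw
  expect_gt(di(0.05, 0.02), di(0.02, 0.02))
  expect_gt(di(0.02, 0.01), di(0.02, 0.05))
  expect_equal(di(0.03, 0.02),
               1 - (1 - (1 - 0.97^10)) * (1 - exp(-0.4)))
})

test_that("small ensembles are reproducible and properly rescaled", {
  ens <- simulate_ensemble(12, horizon = 150, seed = 5)
  ens2 <- simulate_ensemble(12, horizon = 150, seed = 5)
  expect_identical(as.data.frame(ens), as.data.frame(ens2))
  expect_true(all(ens$DI >= 0 & ens$DI <= 1))
  expect_true(all(ens$CSI >= 0 & ens$CSI <= 1))
  expect_equal(nrow(ens), 12)
  expect_false(attr(ens, "csi_degenerate"))
  # degenerate pre-reform pa is flagged
  expect_warning(
    simulate_ensemble(5, ranges = list(pa = c(2e-4, 2e-4), pv = c(0.03, 0.03),
                                       p = c(0.01, 0.01), r = c(0.1, 0.1),
                                       f0 = c(0.1, 0.1)),
                      horizon = 30, seed = 2),
    "degenerate")
})
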