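test_that("effective probability matches the window closed form and its oracle", {
  expect_equal(effective_probability(0, 7), 0)
  expect_equal(effective_probability(1, 3), 1)
  expect_equal(effective_probability(0.01, 10), 1 - 0.99^10)
  expect_equal(effective_probability(0.01, 10, "exponential"), 1 - exp(-0.1))
  # independent single-agent renewal simulation
  mc <- renewal_fraction(0.01, 10, steps = 2e5)
  se <- sqrt(0.0956 * (1 - 0.0956) / 2e5) * sqrt(2 * 10)  # window correlation
  expect_lt(abs(mc - effective_probability(0.01, 10)), 3 * se)
  expect_error(effective_probability(1.2, 5), "rate")
})

test_that("neighbourhood term matches exhaustive enumeration under both conventions", {
  dd4 <- delta_degree(4)
  mfp <- meanfield_params(0.5, 0.5, 0, 1, dd4)
  expect_equal(neighborhood_term(0.5, mfp), 5 / 16)
  expect_equal(neighborhood_term(0, mfp), 0)  # all terms carry z^(k-j), k-j>0
  # mu >= max degree: every configuration eligible
  mfp_all <- meanfield_params(0.5, 0.5, 0, 4, dd4)
  expect_equal(neighborhood_term(c(0, 0.3, 1), mfp_all), c(1, 1, 1))
  set.seed(42)
  for (i in 1:10) {
    k <- sample(0:6, 1); mu <- sample(0:6, 1); z <- runif(1)
    conv <- sample(c("printed", "textual"), 1)
    mfp_i <- meanfield_params(0.5, 0.5, 0, mu, delta_degree(k), conv)
    expect_equal(neighborhood_term(z, mfp_i),
                 enumerate_neighborhood(k, mu, z, conv), tolerance = 1e-12)
  }
  # mixtures average the per-degree terms
  dd <- degree_distribution(c(2, 5), c(0.3, 0.7))
  mfp_m <- meanfield_params(0.5, 0.5, 0, 2, dd, "textual")
  expect_equal(neighborhood_term(0.4, mfp_m),
               0.3 * enumerate_neighborhood(2, 2, 0.4, "textual") +
                 0.7 * enumerate_neighborhood(5, 2, 0.4, "textual"))
})

test_that("neighbourhood term is a non-decreasing map into [0, 1]", {
  set.seed(7)
  zs <- seq(0, 1, length.out = 101)
  for (i in 1:8) {
    supp <- sort(sample(0:12, sample(1:4, 1)))
    mass <- rexp(length(supp)); mass <- mass / sum(mass)
    mu <- sample(0:8, 1)
    conv <- sample(c("printed", "textual"), 1)
    mfp <- meanfield_params(0.5, 0.5, 0, mu,
                            degree_distribution(supp, mass), conv)
    E <- neighborhood_term(zs, mfp)
    expect_true(all(E >= 0 & E <= 1))
    expect_true(all(diff(E) >= -1e-12))
    # all-altruist limit: every neighbourhood passes the printed test;
    # under the textual reading only degrees >= mu can
    if (conv == "printed") expect_equal(E[101], 1)
    else expect_equal(E[101], sum(mass[supp >= mu]))
  }
})

test_that("degree distributions round-trip through two-column CSV", {
  dd <- degree_distribution(c(2, 10), c(0.2, 0.8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_degree_distribution(dd, path)
  back <- read_degree_distribution(path)
  expect_equal(back$support, dd$support)
  expect_equal(back$mass, dd$mass)
  expect_error(degree_distribution(c(2, 2), c(0.5, 0.5)), "duplicate")
  expect_error(degree_distribution(c(1, 2), c(0.6, 0.5)), "sum to 1")
})

test_that("fixed points solve the self-consistency equation exactly", {
  # linear case E = 1: unique root at p* r*
  mfp <- meanfield_params(0.3, 0.5, 0, 10, delta_degree(4))
  sol <- fixed_points(mfp)
  expect_equal(sol$roots, 0.15, tolerance = 1e-9)
  expect_true(all(sol$stable))
  # absorbing zero state for delta degrees above the threshold
  mfp0 <- meanfield_params(0.9, 0.9, 0, 1, delta_degree(4))
  expect_true(any(abs(fixed_points(mfp0)$roots) < 1e-12))
  # residuals, shares, ordering, stability alternation
  mfp2 <- meanfield_params(0.9, 0.9, 0.05, 2, delta_degree(10))
  sol2 <- fixed_points(mfp2)
  g <- sol2$roots - (1 - 0.05) * 0.81 * neighborhood_term(sol2$roots, mfp2)
  expect_true(all(abs(g) < 1e-10))
  expect_equal(sol2$shares$z + sol2$shares$d + sol2$shares$f,
               rep(1, nrow(sol2$shares)))
  expect_true(!is.unsorted(sol2$roots))
})

test_that("root sets agree with a dense brute-force scan on randomized draws", {
  set.seed(1234)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    mfp <- meanfield_params(runif(1, 0.2, 1), runif(1, 0.2, 1),
                            runif(1, 0, 0.3), sample(0:k, 1),
                            delta_degree(k))
    ours <- fixed_points(mfp)$roots
    brute <- brute_roots(mfp, n = 1e5)
    expect_equal(length(ours), length(brute),
                 info = sprintf("draw %d: root count", i))
    if (length(ours) == length(brute))
      expect_lt(max(abs(ours - brute)), 1e-6)
  }
})

test_that("phase classification distinguishes the three regions", {
  # E = 1 (threshold above max degree) is linear: never bistable
  for (ps in c(0.1, 0.5, 0.9))
    expect_false(phase_classify(
      meanfield_params(ps, 0.9, 0, 5, delta_degree(3))) == "bistable")
  # low and high single-root regions
  dd <- fold_degree_dist()
  expect_equal(phase_classify(meanfield_params(0.2, 0.9, 0.1, 6, dd)),
               "few-altruists")
  expect_equal(phase_classify(meanfield_params(0.95, 0.95, 0.1, 6, dd)),
               "many-altruists")
  # three roots => bistable by definition
  mfp_b <- meanfield_params(0.78, 0.9, 0.1, 6, dd)
  if (length(fixed_points(mfp_b)$roots) >= 3)
    expect_equal(phase_classify(mfp_b), "bistable")
})

test_that("critical threshold brackets the saddle-node and grows with f", {
  # linear case has no fold
  expect_true(is.na(critical_threshold(0.9, 0, 5, delta_degree(3))))
  dd <- fold_degree_dist()
  pc <- critical_threshold(0.9, 0.1, 6, dd)
  expect_false(is.na(pc))
  n_at <- function(ps) length(fixed_points(
    meanfield_params(ps, 0.9, 0.1, 6, dd))$roots)
  expect_gte(n_at(pc - 1e-4), 3)
  expect_equal(n_at(pc + 1e-4), 1)
  # the border shifts as the parochial pool expands
  pcs <- vapply(c(0.05, 0.1, 0.15), function(f)
    critical_threshold(0.9, f, 6, dd, n_scan = 100), numeric(1))
  expect_true(all(diff(pcs) >= -1e-5))
})
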