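test_that("stage means honour the initial condition and the N = 1 limit", {
  ch <- stage_chain(4, 0.3, 0.05, 250)
  expect_equal(ms_mean_stages(ch, 0), c(250, 0, 0, 0),
               ignore_attr = TRUE)
  # N = 1: plain linear birth-death process
  bd <- stage_chain(1, 0.4, 0.1, 50)
  for (t in c(0, 2, 10)) {
    expect_equal(ms_mean_stages(bd, t), 50 * exp((0.4 - 0.1) * t),
                 ignore_attr = TRUE)
    expect_equal(ms_mean_total(bd, t), 50 * exp((0.4 - 0.1) * t))
  }
})

test_that("N = 2 stage means reduce to the cosh/sinh forms", {
  lam <- 0.25; mu <- 0.04; C0 <- 80
  ch <- stage_chain(2, lam, mu, C0)
  for (t in c(0.5, 3, 12)) {
    m <- ms_mean_stages(ch, t)
    expect_equal(m[[1]], C0 * exp(-(lam + mu) * t) * cosh(sqrt(2) * lam * t))
    expect_equal(m[[2]],
                 C0 / sqrt(2) * exp(-(lam + mu) * t) * sinh(sqrt(2) * lam * t))
  }
})

test_that("total equals stage sum and satisfies dM/dt = lambda M_N - mu M", {
  ch <- stage_chain(5, 0.8, 0.1, 100)
  for (t in c(1, 10, 60)) {
    expect_equal(ms_mean_total(ch, t), sum(ms_mean_stages(ch, t)))
    lhs <- fd_deriv(function(u) ms_mean_total(ch, u), t)
    m <- ms_mean_stages(ch, t)
    rhs <- 0.8 * m[[5]] - 0.1 * sum(m)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("late-time stage ratio approaches 2^((N-1)/N)", {
  ch <- stage_chain(5, 0.8, 0.1, 100)
  m <- ms_mean_stages(ch, 100)
  expect_equal(m[[1]] / m[[5]], 2^(4 / 5), tolerance = 1e-4)
})

test_that("growth exponent is 2^(1/N) - 1 with N * sigma_N -> log 2", {
  expect_equal(growth_exponent(1), 1)
  expect_equal(growth_exponent(2), sqrt(2) - 1)
  expect_equal(1e6 * growth_exponent(1e6), log(2), tolerance = 1e-5)
  expect_error(growth_exponent(0), ">= 1")
})

test_that("extinction probabilities match the printed N = 1, 2 formulas", {
  set.seed(41)
  for (i in 1:5) {
    lam <- runif(1, 0.2, 2); mu <- runif(1, 0, 0.8)
    e1 <- extinction_probabilities(stage_chain(1, lam, mu))
    expect_equal(e1$p[1], min(mu / lam, 1))
    e2 <- extinction_probabilities(stage_chain(2, lam, mu))
    expect_equal(e2$p[1], min((mu^2 + 2 * mu * lam) / lam^2, 1))
  }
})

test_that("extinction is certain iff mu >= (2^(1/N) - 1) lambda", {
  e <- extinction_probabilities(stage_chain(5, 0.5, 0.1))
  expect_identical(e$regime, "certain")
  expect_equal(e$p, rep(1, 5))
  crit <- growth_exponent(5) * 0.5
  esup <- extinction_probabilities(stage_chain(5, 0.5, crit * 0.999))
  expect_identical(esup$regime, "supercritical")
  expect_lt(esup$p[1], 1)
  eat <- extinction_probabilities(stage_chain(5, 0.5, crit))
  expect_equal(eat$p[1], 1)
})

test_that("closed-form and fixed-point extinction routes agree", {
  for (pars in list(c(3, 1, 0.1), c(5, 0.5, 0.1), c(4, 0.7, 0.25))) {
    ch <- stage_chain(pars[1], pars[2], pars[3])
    a <- extinction_probabilities(ch, method = "closed_form")
    b <- extinction_probabilities(ch, method = "fixed_point")
    expect_equal(a$p, b$p, tolerance = 1e-10)
  }
})

test_that("stationary stage fractions are geometric, sum to 1, decrease", {
  expect_equal(stationary_stage_fractions(1), 1)
  expect_equal(stationary_stage_fractions(2),
               c(2 - sqrt(2), sqrt(2) - 1))
  for (N in c(3, 5, 8)) {
    p <- stationary_stage_fractions(N)
    expect_equal(sum(p), 1)
    expect_true(all(diff(p) < 0))
  }
})

test_that("uniform generation-resolved means collapse to the stage means", {
  N <- 3; lam <- 0.2; mu <- 0.05; C0 <- 50
  for (t in c(6, 24, 60)) {
    m <- msg_uniform_mean(N, lam, mu, C0, t)
    # generation 0, stage 1 is the no-event survival term
    expect_equal(m[1, 1], C0 * exp(-(lam + mu) * t))
    # summing over generations at fixed stage reproduces the Erlang chain
    stage_sum <- colSums(m)
    ref <- ms_mean_stages(stage_chain(N, lam, mu, C0), t)
    expect_equal(stage_sum, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(msg_uniform_mean(N, lam, mu, C0, 0)[1, 1], C0)
})

test_that("uniform closed form agrees with the matrix-exponential solver", {
  N <- 3; lam <- 0.2; mu <- 0.05; C0 <- 50; t <- 24
  m <- msg_uniform_mean(N, lam, mu, C0, t)
  g_cut <- nrow(m) - 1L
  sched <- uniform_schedule(C0, N, lam, mu, g_cut)
  traj <- solve_mean(sched, times = t)
  expect_equal(as.vector(t(m)), as.vector(traj$values),
               tolerance = 1e-6)
})

test_that("single-stage generation means match their closed form", {
  lam <- 0.1 + 0.01 * (0:3); mu <- 0.01 * (0:3); C0 <- 100
  m <- msg_exponential_mean(lam, mu, C0, c(0, 48))
  expect_equal(m[1, 1], C0, ignore_attr = TRUE)   # M^0(0) = C0
  expect_equal(m[2:4, 1], rep(0, 3), ignore_attr = TRUE)
  expect_equal(m[1, 2], C0 * exp(-(lam[1] + mu[1]) * 48),
               ignore_attr = TRUE)
  sched <- generation_schedule(rep(1L, 4), lam, mu, C0)
  traj <- solve_mean(sched, times = 48)
  expect_equal(m[, 2], traj$values[, 1], tolerance = 1e-8,
               ignore_attr = TRUE)
  # coincident rate sums must raise the degenerate-rates condition
  expect_error(msg_exponential_mean(c(0.1, 0.2), c(0.1, 0), 10, 5),
               class = "multistage_degenerate_rates")
})

test_that("critical-regime stage means level out to 2^((1-j)/N) C0 / N", {
  N <- 5; lam <- 0.6; C0 <- 100
  ch <- stage_chain(N, lam, growth_exponent(N) * lam, C0)
  m <- ms_mean_stages(ch, 50 / lam)
  expect_equal(m, 2^((1 - (1:N)) / N) * C0 / N, tolerance = 0.01,
               ignore_attr = TRUE)
})
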