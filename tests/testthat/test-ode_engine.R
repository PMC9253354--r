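test_that("generator matrix has the documented block structure", {
  # single compartment
  s1 <- generation_schedule(1L, 0.3, 0.1, 10)
  A1 <- build_generator(s1)
  expect_equal(unclass(A1), matrix(-0.4), ignore_attr = TRUE)

  # two single-stage generations: explicit 2 x 2 block form
  s2 <- generation_schedule(c(1L, 1L), c(0.3, 0.5), c(0.1, 0.2), 10)
  A2 <- unclass(build_generator(s2))
  expect_equal(A2, matrix(c(-0.4, 0.6, 0, -0.7), 2, 2),
               ignore_attr = TRUE)

  # dimension is the total stage count
  s3 <- generation_schedule(c(2L, 3L, 4L), c(0.1, 0.2, 0.3),
                            c(0, 0.1, 0.2), 5)
  A3 <- build_generator(s3)
  expect_equal(dim(unclass(A3)), c(9L, 9L))

  # structural invariants on a mixed schedule
  s4 <- build_schedule(100, 2, 0.15, 3, 0.25, alpha = 0.01, G_max = 4)
  A4 <- unclass(build_generator(s4))
  gen <- attr(build_generator(s4), "generation")
  expect_equal(diag(A4), -(s4$lambda_g[gen + 1] + s4$mu_g[gen + 1]),
               ignore_attr = TRUE)
  expect_equal(sum(A4 != 0),
               sum(s4$N_g) + (sum(s4$N_g) - 1))  # diag + sub/couplings
})

test_that("solve_mean reproduces n0 at t = 0 and is linear in n0", {
  s <- build_schedule(100, 2, 0.15, 3, 0.25, alpha = 0.01, G_max = 6)
  dim <- sum(s$N_g)
  n0 <- c(100, rep(0, dim - 1))
  tr <- solve_mean(s, n0, times = c(0, 10))
  expect_equal(tr$values[, 1], n0)
  tr3 <- solve_mean(s, 3 * n0, times = c(0, 10))
  expect_equal(tr3$values, 3 * tr$values, tolerance = 1e-12)
  expect_true(all(tr$values >= 0))
})

test_that("solver matches the dense matrix-exponential oracle", {
  set.seed(7)
  for (rep in 1:3) {
    s <- build_schedule(C0 = runif(1, 10, 200), N0 = sample(1:4, 1),
                        lambda0 = runif(1, 0.05, 0.4),
                        N = sample(1:5, 1), lambda = runif(1, 0.05, 0.4),
                        alpha = runif(1, 0, 0.01), G_max = 8)
    times <- c(5, 25, 80)
    tr <- solve_mean(s, times = times)
    ref <- expm_oracle(s, times = times)
    expect_equal(tr$values, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("arbitrary admissible initial vectors are accepted", {
  s <- uniform_schedule(0, 3, 0.2, 0.05, 6)
  dim <- sum(s$N_g)
  set.seed(11)
  n0 <- runif(dim, 0, 5)
  tr <- solve_mean(s, n0, times = c(0, 4, 12))
  ref <- expm_oracle(s, n0, times = c(0, 4, 12))
  expect_equal(tr$values, ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(solve_mean(s, c(-1, n0[-1]), times = 1), "nonnegative")
})

test_that("generation collapse conserves totals and is the identity for
           single-stage generations", {
  s <- generation_schedule(rep(1L, 4), c(0.1, 0.12, 0.14, 0.16),
                           c(0, 0.01, 0.02, 0.03), 60)
  tr <- solve_mean(s, times = c(3, 30))
  expect_equal(collapse_generations(tr), tr$values, ignore_attr = TRUE)

  s2 <- build_schedule(100, 2, 0.15, 3, 0.25, alpha = 0.005, G_max = 6)
  tr2 <- solve_mean(s2, times = c(3, 30))
  pg <- collapse_generations(tr2)
  expect_equal(colSums(pg), colSums(tr2$values))
  expect_equal(colSums(collapse_stages(tr2)), colSums(tr2$values))
})

test_that("generation totals obey the flux-balance ODEs", {
  s <- build_schedule(100, 2, 0.15, 3, 0.25, alpha = 0.005, G_max = 6)
  t0 <- 12
  Mg_at <- function(t) collapse_generations(solve_mean(s, times = t))[, 1]
  MgN_at <- function(t) {
    tr <- solve_mean(s, times = t)
    vapply(0:s$G_max, function(g) {
      idx <- tr$generation == g
      tr$values[idx, 1][sum(idx)]   # last stage of generation g
    }, numeric(1))
  }
  d <- (Mg_at(t0 + 1e-3) - Mg_at(t0 - 1e-3)) / 2e-3
  Mg <- Mg_at(t0); MgN <- MgN_at(t0)
  # dM0/dt = -lambda_0 M0_{N0} - mu_0 M0
  expect_equal(d[1], -s$lambda_g[1] * MgN[1] - s$mu_g[1] * Mg[1],
               tolerance = 1e-5)
  # dMg/dt = 2 lambda_{g-1} M^{g-1}_{N} - lambda_g M^g_{N} - mu_g M^g
  for (g in 2:5)
    expect_equal(d[g],
                 2 * s$lambda_g[g - 1] * MgN[g - 1] -
                   s$lambda_g[g] * MgN[g] - s$mu_g[g] * Mg[g],
                 tolerance = 1e-5)
})

test_that("tail merging preserves totals and validates the cutoff", {
  pg <- matrix(0, 9, 2, dimnames = list(0:8, NULL))
  pg["0", ] <- c(7, 5)
  m <- merge_tail_class(pg)
  expect_equal(m["5+", ], c(0, 0))
  pg2 <- matrix(0, 9, 1, dimnames = list(0:8, NULL))
  pg2["7", ] <- 11
  expect_equal(merge_tail_class(pg2)["5+", ], 11, ignore_attr = TRUE)
  set.seed(3)
  pg3 <- matrix(runif(18), 9, 2)
  expect_equal(colSums(merge_tail_class(pg3)), colSums(pg3))
  expect_equal(rownames(merge_tail_class(pg3)),
               c("0", "1", "2", "3", "4", "5+"))
  expect_error(merge_tail_class(pg3[1:4, , drop = FALSE]), "merged")
})

test_that("stage-occupancy fractions forget the initial distribution", {
  # three distinct initial vectors all converge to the stationary profile
  N <- 4; lam <- 0.5; mu <- 0.1
  s <- uniform_schedule(0, N, lam, mu, 45)
  dim <- sum(s$N_g)
  # arbitrary stage distributions, kept within the early generations so
  # the truncated tail stays negligible over the horizon
  inits <- list(c(100, rep(0, dim - 1)),
                c(rep(0, N - 1), 100, rep(0, dim - N)),
                c(rep(100 / (3 * N), 3 * N), rep(0, dim - 3 * N)))
  target <- stationary_stage_fractions(N)
  for (n0 in inits) {
    tr <- solve_mean(s, n0, times = 60 / lam)
    frac <- collapse_stages(tr)[, 1] / sum(tr$values[, 1])
    expect_equal(frac, target, tolerance = 1e-3, ignore_attr = TRUE)
  }
})
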