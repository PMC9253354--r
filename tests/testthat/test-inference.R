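# A small noiseless "dataset": summaries equal to a model prediction with
# unit standard deviations, so the distance has a known zero.
noiseless_summaries <- function(theta, days = c(3, 5, 7, 12)) {
  tt <- days * 24
  pc <- predict_classes(theta, tt)
  data.frame(
    time_h = rep(tt, each = nrow(pc)),
    generation_class = rep(rownames(pc), length(tt)),
    mean_count = as.vector(pc),
    sd_count = 1,
    n_replicates = 1L)
}

test_that("prior samples respect the stated supports and marginals", {
  set.seed(2)
  th <- sample_prior(10000, "ms")
  expect_true(all(th$log10C0 >= 4 & th$log10C0 <= 6))
  expect_true(all(th$N0 %in% 1:50 & th$N %in% 1:50))
  expect_true(all(th$log10lambda >= -3 & th$log10lambda <= 1))
  expect_true(all(th$log10alpha >= -5 & th$log10alpha <= -1))
  # exponents are uniform (Kolmogorov-Smirnov)
  ks1 <- suppressWarnings(ks.test(th$log10C0, "punif", 4, 6))
  ks2 <- suppressWarnings(ks.test(th$log10lambda, "punif", -3, 1))
  expect_gt(ks1$p.value, 0.001)
  expect_gt(ks2$p.value, 0.001)
  # stage counts are discrete uniform (chi-squared)
  chi <- chisq.test(table(factor(th$N, levels = 1:50)))
  expect_gt(chi$p.value, 0.001)
  # exponential variant pins the stage counts
  the <- sample_prior(100, "exp")
  expect_true(all(the$N0 == 1 & the$N == 1))
})

test_that("the distance is the root of the standardised squared error", {
  mc <- matrix(c(3, 1), 2, 1, dimnames = list(c("0", "1"), "24"))
  sm <- data.frame(time_h = 24, generation_class = c("0", "1"),
                   mean_count = c(3, 1), sd_count = c(2, 2),
                   n_replicates = 3L)
  expect_identical(distance_to_data(mc, sm), 0)
  sm$mean_count <- c(1, 1)   # one cell off by 2 with sd 2 -> 1
  expect_equal(distance_to_data(mc, sm), 1)
  # 3-4-5: residual/sd of 3 and 4
  mc2 <- matrix(c(3, 4), 2, 1, dimnames = list(c("0", "1"), "24"))
  sm2 <- data.frame(time_h = 24, generation_class = c("0", "1"),
                    mean_count = c(0, 0), sd_count = c(1, 1),
                    n_replicates = 3L)
  expect_equal(distance_to_data(mc2, sm2), 5)
  # missing (class, time) pairs are an alignment error
  sm3 <- sm2; sm3$time_h <- 48
  expect_error(distance_to_data(mc2, sm3), "missing")
})

test_that("predict_classes keeps mass where it belongs", {
  th <- list(C0 = 1e5, N0 = 3, N = 4, lambda0 = 0.05, lambda = 0.1,
             alpha = 0)
  pc <- predict_classes(th, c(0, 100))
  expect_equal(pc["0", "0"], 1e5)          # all mass undivided at t = 0
  expect_equal(sum(pc[, "0"]), 1e5)
  # conservation against the solver total
  sched <- build_schedule(1e5, 3, 0.05, 4, 0.1, 0,
                          G_max = attr(pc, "G_max_used"))
  tr <- solve_mean(sched, times = 100)
  expect_equal(sum(pc[, "100"]), sum(tr$values[, 1]), tolerance = 1e-10)
  # exponential reduction against the partial-fraction closed form.  The
  # closed form is only well conditioned for low generations (few
  # partial-fraction terms), so classes 0-4 are compared directly and the
  # merged class via conservation.
  the <- list(C0 = 5e4, N0 = 1, N = 1, lambda0 = 0.0217, lambda = 0.003,
              alpha = 1.3e-4)
  pce <- predict_classes(the, c(72, 168))
  G <- attr(pce, "G_max_used")
  ref <- msg_exponential_mean(c(0.0217, rep(0.003, G)), 1.3e-4 * (0:G),
                              5e4, c(72, 168))
  expect_equal(pce[1:5, ], ref[1:5, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  sched_e <- build_schedule(5e4, 1, 0.0217, 1, 0.003, 1.3e-4, G_max = G)
  tot <- colSums(solve_mean(sched_e, times = c(72, 168))$values)
  expect_equal(colSums(pce), tot, tolerance = 1e-10, ignore_attr = TRUE)
  # overflow screen: absurd growth returns NULL, not an error
  expect_null(predict_classes(list(C0 = 1e6, N0 = 1, N = 1, lambda0 = 10,
                                   lambda = 10, alpha = 1e-5), 432))
})

test_that("AICc follows the working-likelihood convention", {
  expect_equal(aicc(sqrt(10), 10, 1), 2.5)   # n ln(1) + 2 + 0.5
  expect_lt(aicc(5, 48, 6), aicc(10, 48, 6)) # better fit, lower score
  expect_error(aicc(1, 5, 4), "undefined")
})

test_that("ABC-SMC runs are seed-reproducible with decreasing thresholds", {
  th <- list(C0 = 3e4, N0 = 2, N = 2, lambda0 = 0.02, lambda = 0.02,
             alpha = 1e-3)
  sm <- noiseless_summaries(th)
  a <- run_abc_smc(sm, "exp", n_particles = 60, n_iterations = 4,
                   n_prior_draws = 300, seed = 5)
  b <- run_abc_smc(sm, "exp", n_particles = 60, n_iterations = 4,
                   n_prior_draws = 300, seed = 5)
  expect_equal(a$populations, b$populations)
  expect_equal(a$epsilon, b$epsilon)
  expect_true(all(diff(a$epsilon) < 0))
  final <- a$populations[[length(a$populations)]]
  expect_identical(nrow(final), 60L)
  expect_true(all(final$weight > 0))
  expect_equal(sum(final$weight), 1)
  expect_true(all(final$N0 == 1 & final$N == 1))
})

test_that("on noiseless data the best distance shrinks along iterations", {
  th <- list(C0 = 3e4, N0 = 3, N = 3, lambda0 = 0.03, lambda = 0.03,
             alpha = 1e-3)
  sm <- noiseless_summaries(th)
  post <- run_abc_smc(sm, "ms", n_particles = 80, n_iterations = 10,
                      n_prior_draws = 400, seed = 17)
  dmin <- vapply(post$populations, function(p) min(p$distance), numeric(1))
  expect_lt(dmin[length(dmin)], dmin[1] / 2)
  expect_lt(post$epsilon[length(post$epsilon)], post$epsilon[2] / 2)
  expect_true(all(diff(post$epsilon) < 0))
})

test_that("weighted quantiles invert the weighted CDF", {
  x <- c(1, 2, 3, 4)
  w <- c(0.1, 0.4, 0.4, 0.1)
  expect_equal(weighted_quantile(x, w, 0.5), 2)
  expect_equal(weighted_quantile(x, w, c(0.05, 0.95)), c(1, 4))
  # invariant under relabelling
  o <- c(3, 1, 4, 2)
  expect_equal(weighted_quantile(x[o], w[o], 0.5), 2)
})
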