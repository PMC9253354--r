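# Independent oracles and small utilities shared across tests.

# Dense matrix-exponential solve via Matrix::expm (independent of the
# package's own uniformization kernel).
expm_oracle <- function(schedule, n0 = NULL, times) {
  A <- unclass(build_generator(schedule))
  if (is.null(n0)) n0 <- c(schedule$initial_count, rep(0, nrow(A) - 1))
  sapply(times, function(t)
    as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% n0))
}

# Central finite difference of f at t
fd_deriv <- function(f, t, h = 1e-4) (f(t + h) - f(t - h)) / (2 * h)

# Uniform schedule (same N, lambda for every generation, constant death):
# the generation-collapsed system whose stage marginals reproduce the
# plain Erlang chain.
uniform_schedule <- function(C0, N, lambda, mu, G_max) {
  build_schedule(C0 = C0, N0 = N, lambda0 = lambda, N = N, lambda = lambda,
                 alpha = 0, G_max = G_max, mu_constant = mu)
}
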