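# Closed-form results for the Erlang chain: mean trajectories, extinction
# probabilities, late-time asymptotics, stationary stage fractions, and the
# generation-resolved closed forms for identical parameters across
# generations.

check_erlang <- function(chain) {
  if (!inherits(chain, "stage_chain"))
    stop("`chain` must be a stage_chain", call. = FALSE)
  if (!chain$is_erlang)
    stop("closed forms require equal per-stage rates; use solve_mean() ",
         "for stage-dependent rates", call. = FALSE)
  invisible(chain)
}

#' Closed-form mean number of cells in each stage of the Erlang chain
#'
#' Evaluates the root-of-unity representation of the stage means,
#' \deqn{M_j(t) = C_0 \frac{2^{(1-j)/N}}{N} e^{-\mu t}
#'   \sum_{k=0}^{N-1} z^{(1-j)k} e^{(2^{1/N} z^k - 1)\lambda t},}
#' with \eqn{z = e^{2\pi i/N}}, for all `C0` founder cells in stage 1 at
#' time 0.  The sum is provably real; the complex arithmetic is carried out
#' explicitly and the imaginary residue is checked against `1e-9 * C0`.
#'
#' @param chain A [stage_chain()] with equal advance rates (Erlang).
#' @param t Times in hours (vector allowed), all >= 0.
#' @return A matrix with `N` rows (stages) and `length(t)` columns; a vector
#'   when `t` is scalar.
#' @examples
#' ch <- stage_chain(5, 0.8, 0.1, 100)
#' ms_mean_stages(ch, c(0, 50, 100))
#' @export
ms_mean_stages <- function(chain, t) {
  check_erlang(chain)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  N <- chain$N
  lam <- chain$advance_rates[1]
  mu <- chain$death_rate
  C0 <- chain$initial_count
  z <- exp(2i * pi / N)
  k <- 0:(N - 1)
  zk <- z^k
  out <- matrix(NA_real_, N, length(t))
  for (ti in seq_along(t)) {
    ek <- exp((2^(1 / N) * zk - 1) * lam * t[ti])
    for (j in 1:N) {
      s <- sum(zk^(1 - j) * ek)
      val <- C0 * 2^((1 - j) / N) / N * exp(-mu * t[ti]) * s
      if (abs(Im(val)) > 1e-9 * max(C0, 1))
        stop("imaginary residue exceeds tolerance in stage-mean sum",
             call. = FALSE)
      out[j, ti] <- Re(val)
    }
  }
  rownames(out) <- paste0("stage", 1:N)
  if (length(t) == 1L) out[, 1] else out
}

#' Closed-form expected total population size of the Erlang chain
#'
#' \deqn{M(t) = C_0 \frac{2^{1/N}}{2N} e^{-\mu t} \sum_{k=0}^{N-1}
#'   \frac{z^k}{2^{1/N} z^k - 1} e^{(2^{1/N} z^k - 1)\lambda t}.}
#'
#' @inheritParams ms_mean_stages
#' @return Expected total cell count(s) at `t`.
#' @export
ms_mean_total <- function(chain, t) {
  check_erlang(chain)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  N <- chain$N
  lam <- chain$advance_rates[1]
  mu <- chain$death_rate
  C0 <- chain$initial_count
  zk <- exp(2i * pi / N)^(0:(N - 1))
  vapply(t, function(tt) {
    s <- sum(zk / (2^(1 / N) * zk - 1) * exp((2^(1 / N) * zk - 1) * lam * tt))
    val <- C0 * 2^(1 / N) / (2 * N) * exp(-mu * tt) * s
    if (abs(Im(val)) > 1e-9 * max(C0, 1))
      stop("imaginary residue exceeds tolerance in total-mean sum",
           call. = FALSE)
    Re(val)
  }, numeric(1))
}

#' Late-time growth exponent of the Erlang chain
#'
#' The dimensionless exponent \eqn{\sigma_N = 2^{1/N} - 1}: at late times the
#' population grows like \eqn{e^{(\sigma_N \lambda - \mu)t}}.  It is smaller
#' than `1/N`, so `N` stages at rate `lambda` are *not* equivalent to a single
#' step at rate `lambda/N`; `N * sigma_N` tends to `log 2` from above as the
#' number of stages grows.
#'
#' @param N Number of stages, integer >= 1 (vectorised).
#' @return The value of \eqn{2^{1/N} - 1}, computed via `expm1` for
#'   accuracy at large `N`.
#' @export
growth_exponent <- function(N) {
  if (any(!is.finite(N)) || any(N < 1) || any(N != floor(N)))
    stop("`N` must contain integers >= 1", call. = FALSE)
  expm1(log(2) / N)
}

#' Ultimate extinction probabilities of the Erlang chain
#'
#' For a population founded by a single cell in stage `j`, the probability
#' that the population eventually hits zero.  A first-step argument gives the
#' recursion \eqn{p_i = \frac{\mu}{\lambda+\mu} + \frac{\lambda}{\lambda+\mu}
#' p_{i+1}} for `i < N` and \eqn{p_N = \frac{\mu}{\lambda+\mu} +
#' \frac{\lambda}{\lambda+\mu} p_1^2}.  Its minimal solution is
#' \eqn{p_1 = (1-r)^{-N} - 1} with \eqn{r = \mu/(\mu+\lambda)} when
#' \eqn{\mu < (2^{1/N}-1)\lambda}, and 1 otherwise (extinction certain).
#' Founders in later stages follow from the recursion; with `m` independent
#' founders the probability is `p_j^m`.
#'
#' @param chain A [stage_chain()] with equal advance rates.
#' @param method `"closed_form"` evaluates the branch formula and back-fills
#'   `p_2..p_N` from the recursion; `"fixed_point"` iterates the first-step
#'   system from 0 until convergence (an independent route to the same
#'   minimal solution).
#' @return An object of class `extinction_result`: a list with per-stage
#'   probabilities `p` (length `N`), the ratio `r` (mu over mu + lambda),
#'   and `regime`
#'   (`"supercritical"` when extinction is uncertain, `"certain"` otherwise).
#' @examples
#' extinction_probabilities(stage_chain(5, 0.5, 0.1))$p[1] # 1: mu above
#' # the critical value (2^(1/5)-1) * lambda
#' @export
extinction_probabilities <- function(chain,
                                     method = c("closed_form",
                                                "fixed_point")) {
  check_erlang(chain)
  method <- match.arg(method)
  N <- chain$N
  lam <- chain$advance_rates[1]
  mu <- chain$death_rate
  q <- lam / (lam + mu)
  r <- mu / (lam + mu)
  certain <- mu >= growth_exponent(N) * lam
  if (method == "closed_form") {
    p1 <- if (certain) 1 else (1 - r)^(-N) - 1
    p1 <- min(max(p1, 0), 1)
    # p_j = 1 - q^(N-j) (1 - p_N), with p_N from the division branch
    pN <- r + q * p1^2
    p <- 1 - q^(N - (1:N)) * (1 - pN)
    p[N] <- pN
    p[1] <- p1
  } else {
    p <- rep(0, N)
    repeat {
      pnew <- c(r + q * p[-1L], r + q * p[1L]^2)
      if (N == 1L) pnew <- r + q * p[1L]^2
      if (max(abs(pnew - p)) < 1e-15) { p <- pnew; break }
      p <- pnew
    }
  }
  p <- pmin(pmax(p, 0), 1)
  res <- abs(p[-N] - (r + q * p[-1L]))
  resN <- abs(p[N] - (r + q * p[1L]^2))
  if (max(c(res, resN, 0)) > 1e-12)
    stop("extinction recursion residual exceeds 1e-12", call. = FALSE)
  structure(list(p = p, r = r,
                 regime = if (certain) "certain" else "supercritical",
                 N = N, lambda = lam, mu = mu),
            class = "extinction_result")
}

#' @export
print.extinction_result <- function(x, ...) {
  cat(sprintf("Extinction (%s regime, r = %.4g): p_1 = %.6g",
              x$regime, x$r, x$p[1]))
  if (x$N > 1) cat(sprintf(", p_%d = %.6g", x$N, x$p[x$N]))
  cat("\n")
  invisible(x)
}

#' Stationary fraction of cells in each stage
#'
#' At late times the fraction of cells in stage `j` converges, independently
#' of the initial distribution and of both rates, to
#' \deqn{P^*_j = (2^{1/N})^{N-j} (2^{1/N} - 1),}
#' a strictly decreasing geometric profile summing to 1: the population is
#' biased towards early stages, which is why the growth exponent is smaller
#' than the naive `lambda/N` rate would suggest.
#'
#' @param N Number of stages, integer >= 1.
#' @return Vector of length `N` with the stationary fractions.
#' @export
stationary_stage_fractions <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 1 ||
      N != floor(N))
    stop("`N` must be a single integer >= 1", call. = FALSE)
  j <- 1:N
  p <- 2^((N - j) / N) * (2^(1 / N) - 1)
  # steady-state system consistency: P1 = 2 PN / (1+PN), Pj = P(j-1)/(1+PN)
  pN <- p[N]
  resid <- c(abs(p[1] - 2 * pN / (1 + pN)),
             if (N > 1) abs(p[-1L] - p[-N] / (1 + pN)))
  if (max(resid) > 1e-12)
    stop("stationary fractions fail the fixed-point system", call. = FALSE)
  p
}

# Smallest generation cut such that generations > g_cut hold a negligible
# share of the series mass; from a Poisson tail bound on 2^(1/N) * lambda * t
# (the series terms are Poisson weights in the total stage index).
choose_generation_cut <- function(N, lambda, t, tail = 1e-12) {
  x <- 2^(1 / N) * lambda * max(t)
  nmax <- qpois(1 - min(tail, 1e-12), x) + 10
  max(1L, as.integer(ceiling((nmax + 1) / N)) + 2L)
}

#' Closed-form generation-resolved means, identical Erlang clocks
#'
#' When every generation has the same stage count `N`, birth rate `lambda`
#' and death rate `mu`, the mean number of cells in stage `j` of generation
#' `g` is
#' \deqn{M^g_j(t) = 2^g C_0 \frac{(\lambda t)^{Ng+j-1}}{(Ng+j-1)!}
#'   e^{-(\lambda+\mu)t},}
#' evaluated in log space (via `lgamma`) to avoid overflow of the factorial.
#' Generations are truncated at `g_cut`, chosen adaptively from a Poisson
#' tail bound so the omitted mass is below `1e-9` of the total.
#'
#' @param N,lambda,mu Shared stage count, birth and death rate.
#' @param C0 Founder cells in stage 1 of generation 0 at time 0.
#' @param t A single time in hours.
#' @param g_cut Optional explicit truncation generation.
#' @return Matrix `(g_cut+1) x N`; rows are generations `0..g_cut`, columns
#'   stages. Attribute `g_cut` records the truncation used.
#' @export
msg_uniform_mean <- function(N, lambda, mu, C0, t, g_cut = NULL) {
  if (length(t) != 1L || t < 0) stop("`t` must be a single time >= 0",
                                     call. = FALSE)
  if (N < 1 || N != floor(N) || lambda <= 0 || mu < 0 || C0 < 0)
    stop("invalid parameters", call. = FALSE)
  adaptive <- is.null(g_cut)
  if (adaptive) g_cut <- choose_generation_cut(N, lambda, t)
  gg <- 0:g_cut
  out <- matrix(0, g_cut + 1L, N,
                dimnames = list(paste0("gen", gg), paste0("stage", 1:N)))
  if (t == 0) {
    out[1, 1] <- C0
  } else {
    for (g in gg) {
      n <- N * g + (1:N) - 1          # total stage index
      out[g + 1L, ] <- exp(g * log(2) + log(C0) + n * log(lambda * t) -
                             (lambda + mu) * t - lgamma(n + 1))
    }
    tail_share <- sum(out[g_cut + 1L, ]) / max(sum(out), .Machine$double.xmin)
    if (adaptive && tail_share > 1e-9) {
      if (g_cut > 10000L)
        stop("generation truncation did not converge", call. = FALSE)
      return(msg_uniform_mean(N, lambda, mu, C0, t, g_cut = 2L * g_cut))
    }
  }
  attr(out, "g_cut") <- g_cut
  out
}

#' Closed-form generation means for single-stage (exponential) generations
#'
#' With one stage per generation (`N_g = 1`) and generation-dependent rates,
#' the model is a birth-and-death process tracking generations, with
#' \deqn{M^0(t) = C_0 e^{-(\lambda_0+\mu_0)t}, \qquad
#'   M^g(t) = 2^g C_0 \Big(\prod_{l=0}^{g-1}\lambda_l\Big) \sum_{i=0}^g
#'   e^{-(\lambda_i+\mu_i)t} \prod_{k \ne i}
#'   \frac{1}{\lambda_k+\mu_k-\lambda_i-\mu_i}.}
#' The partial-fraction form requires all rate sums `lambda_i + mu_i` to be
#' distinct; coincident sums raise an error of class
#' `multistage_degenerate_rates` (fall back to [solve_mean()]).
#'
#' @param lambda_g,mu_g Per-generation birth and death rates (`g = 0..G`).
#' @param C0 Founder cells in generation 0 at time 0.
#' @param t Times in hours (vector allowed).
#' @return Matrix `(G+1) x length(t)` of generation means.
#' @export
msg_exponential_mean <- function(lambda_g, mu_g, C0, t) {
  G1 <- length(lambda_g)
  if (length(mu_g) != G1) stop("rate vectors must have equal length",
                               call. = FALSE)
  s <- lambda_g + mu_g
  if (G1 > 1) {
    gaps <- abs(outer(s, s, "-"))
    diag(gaps) <- Inf
    if (min(gaps) < 1e-10 * max(s)) {
      cnd <- simpleError(
        "coincident rate sums lambda_i + mu_i: partial fractions degenerate; use solve_mean()")
      class(cnd) <- c("multistage_degenerate_rates", class(cnd))
      stop(cnd)
    }
  }
  out <- matrix(0, G1, length(t),
                dimnames = list(paste0("gen", 0:(G1 - 1)), NULL))
  out[1, ] <- C0 * exp(-s[1] * t)
  for (g in seq_len(G1 - 1)) {
    idx <- 1:(g + 1)
    coef <- vapply(idx, function(i) prod(1 / (s[idx[-i]] - s[i])), numeric(1))
    pre <- 2^g * C0 * prod(lambda_g[1:g])
    out[g + 1L, ] <- pre *
      colSums(coef * exp(-outer(s[idx], t)))
  }
  out
}
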