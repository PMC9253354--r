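# Exact continuous-time stochastic simulation (Gillespie) of the
# multi-stage process with generations.

# Deterministic substream seed for replicate r of a run seeded with `seed`;
# kept below 2^31.
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 1000003) * 2039 + r) %% 2147483647L
}

sim_ext_rule <- function(schedule) {
  r <- schedule$rule
  if (!is.null(r)) {
    list(N = as.integer(r$N), lambda = r$lambda,
         alpha = if (is.null(r$mu_constant)) r$alpha else -1,
         mu_const = if (is.null(r$mu_constant)) 0 else r$mu_constant)
  } else {
    gl <- schedule$G_max + 1L
    list(N = schedule$N_g[gl], lambda = schedule$lambda_g[gl],
         alpha = -1, mu_const = schedule$mu_g[gl])
  }
}

#' Exact stochastic simulation of the generation-resolved process
#'
#' Simulates the continuous-time Markov process exactly: a compartment
#' `(g, j)` holding `n` cells contributes hazard `n * lambda_g` for stage
#' advance (division from the last stage, placing two daughters in stage 1 of
#' generation `g + 1`) and `n * mu_g` for death.  Hazards are aggregated per
#' compartment -- cells in a compartment are exchangeable, so the sampled law
#' is identical to per-cell simulation.  Generations extend dynamically
#' during the run using the schedule's generating rule (there is no ceiling
#' on divisions in the process; only the dye saturates); the state is
#' recorded at `sample_times` by carrying the last event forward.
#'
#' @param schedule A [generation_schedule()].
#' @param C0 Founder cells in stage 1 of generation 0 (default: the
#'   schedule's `initial_count`).
#' @param sample_times Times (hours) at which to record the state.
#' @param seed Integer seed; replicate `r` uses a deterministically derived
#'   substream seed, so results are reproducible and independent of
#'   `replicates` batching.
#' @param replicates Number of independent realisations.
#' @param cell_cap Abort threshold on the total cell count; exceeding it
#'   raises an error of class `multistage_capped_run` rather than silently
#'   truncating.
#' @return A data.frame with columns `time_h, generation, stage, count,
#'   replicate` (class `msg_simulation`), containing every compartment that
#'   was ever occupied in a replicate.
#' @export
simulate_msg <- function(schedule, C0 = NULL, sample_times, seed,
                         replicates = 1L, cell_cap = 1e8) {
  stopifnot(inherits(schedule, "generation_schedule"))
  if (is.null(C0)) C0 <- schedule$initial_count
  if (C0 < 1) stop("`C0` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  sample_times <- sort(as.numeric(sample_times))
  ext <- sim_ext_rule(schedule)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(derive_seed(seed, r))
    sim <- cpp_msg_gillespie(schedule$N_g, schedule$lambda_g, schedule$mu_g,
                             ext$N, ext$lambda, ext$alpha, ext$mu_const,
                             C0, sample_times, cell_cap,
                             escape_threshold = -1)
    if (isTRUE(sim$capped)) {
      cnd <- simpleError(sprintf(
        "replicate %d exceeded the cell cap (%g cells) at t = %g h",
        r, cell_cap, sim$final_time))
      class(cnd) <- c("multistage_capped_run", class(cnd))
      stop(cnd)
    }
    out[[r]] <- data.frame(
      time_h = rep(sample_times, each = length(sim$generation)),
      generation = rep(sim$generation, length(sample_times)),
      stage = rep(sim$stage, length(sample_times)),
      count = as.vector(sim$counts),
      replicate = r)
  }
  res <- do.call(rbind, out)
  class(res) <- c("msg_simulation", "data.frame")
  attr(res, "seed") <- seed
  res
}

#' Ensemble mean counts per compartment from a simulation
#'
#' Averages replicate counts per `(generation, stage, time)` and attaches
#' the Monte-Carlo standard error of the mean.  Compartments never occupied
#' in a replicate count as zero.
#'
#' @param sim Output of [simulate_msg()].
#' @return data.frame `time_h, generation, stage, mean_count, se, n`.
#' @export
ensemble_mean <- function(sim) {
  stopifnot(inherits(sim, "msg_simulation"))
  R <- length(unique(sim$replicate))
  key <- paste(sim$time_h, sim$generation, sim$stage, sep = "|")
  # zero-fill: compartments absent from a replicate contribute 0
  sums <- tapply(sim$count, key, sum)
  sq <- tapply(sim$count^2, key, sum)
  info <- do.call(rbind, strsplit(names(sums), "|", fixed = TRUE))
  m <- sums / R
  v <- pmax(0, (sq - R * m^2) / max(1, R - 1))
  data.frame(time_h = as.numeric(info[, 1]),
             generation = as.integer(info[, 2]),
             stage = as.integer(info[, 3]),
             mean_count = as.vector(m),
             se = sqrt(as.vector(v) / R), n = R, row.names = NULL)
}

#' Monte-Carlo estimate of the ultimate extinction probability
#'
#' Runs `n_replicates` realisations of the chain from a single founder cell
#' in stage 1 and reports the fraction that went extinct.  Supercritical
#' runs are declared surviving as soon as the population reaches
#' `escape_threshold` cells (the probability of extinction from that size is
#' at most the single-cell probability to that power, far below Monte-Carlo
#' resolution); runs still alive at `t_end` also count as non-extinct.
#'
#' @param chain A [stage_chain()] (the daughters of a dividing cell re-enter
#'   stage 1 of the same chain).
#' @param n_replicates Number of independent founder cells.
#' @param t_end Time horizon in hours.
#' @param seed Integer seed.
#' @param escape_threshold Early-survival population size (default 1000).
#' @return List with `p_hat`, binomial `se`, `n_extinct`, `n`.
#' @export
estimate_extinction <- function(chain, n_replicates, t_end, seed,
                                escape_threshold = 1000) {
  stopifnot(inherits(chain, "stage_chain"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  # the chain is the uniform generation model with constant death, stage-
  # marginalised; extinction of the total population is identical
  sched <- generation_schedule(N_g = chain$N,
                               lambda_g = chain$advance_rates[1],
                               mu_g = chain$death_rate, initial_count = 1)
  next_rule <- list(N = chain$N, lambda = chain$advance_rates[1],
                    alpha = -1, mu_const = chain$death_rate)
  n_ext <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, r))
    sim <- cpp_msg_gillespie(sched$N_g, sched$lambda_g, sched$mu_g,
                             next_rule$N, next_rule$lambda, next_rule$alpha,
                             next_rule$mu_const, 1, t_end,
                             cell_cap = Inf,
                             escape_threshold = escape_threshold)
    if (isTRUE(sim$extinct)) n_ext <- n_ext + 1L
  }
  p <- n_ext / n_replicates
  list(p_hat = p, se = sqrt(p * (1 - p) / n_replicates),
       n_extinct = n_ext, n = n_replicates)
}
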