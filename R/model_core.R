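# Parameter containers and rate laws shared by all other modules.

#' Generation-dependent death rate, linear in the number of divisions
#'
#' The per-cell death rate of a generation-g cell is `alpha * g`: cells that
#' have divided more often are more likely to die, and undivided cells
#' (generation 0) do not die under this law.
#'
#' @param alpha Death-rate slope per division, in inverse hours. Must be >= 0.
#' @param g Generation (number of completed divisions), a non-negative
#'   integer; vectorised.
#' @return Death rate(s) `alpha * g` in inverse hours.
#' @examples
#' death_rate_at(0.01, 3) # 0.03
#' @export
death_rate_at <- function(alpha, g) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(g) || any(is.na(g)) || any(g < 0) || any(g != floor(g)))
    stop("`g` must contain non-negative integers", call. = FALSE)
  alpha * g
}

#' Multi-stage chain of a dividing and dying cell
#'
#' Container for the multi-stage (MS) model: a cell traverses `N` sequential
#' exponential stages with per-stage advance rates `advance_rates` before
#' dividing; at every stage it may instead die at rate `death_rate`.  When all
#' advance rates are equal the time to division is Erlang(lambda, N) and the
#' chain is flagged `is_erlang`, which unlocks the closed-form results.
#'
#' @param N Number of stages (integer >= 1).
#' @param advance_rates Per-stage advance rates in inverse hours; either a
#'   single rate (recycled to all stages) or a vector of length `N`. All > 0.
#' @param death_rate Per-cell death rate mu >= 0 (inverse hours).
#' @param initial_count Number of founder cells C0 >= 0, placed in stage 1 at
#'   time 0.
#' @return An object of class `stage_chain`.
#' @examples
#' stage_chain(N = 5, advance_rates = 0.8, death_rate = 0.1,
#'             initial_count = 100)
#' @export
stage_chain <- function(N, advance_rates, death_rate = 0, initial_count = 1) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N != floor(N))
    stop("`N` must be a single integer >= 1", call. = FALSE)
  N <- as.integer(N)
  if (length(advance_rates) == 1L) advance_rates <- rep(advance_rates, N)
  if (length(advance_rates) != N || any(!is.finite(advance_rates)) ||
      any(advance_rates <= 0))
    stop("`advance_rates` must be ", N, " finite positive rates",
         call. = FALSE)
  if (!is.numeric(death_rate) || length(death_rate) != 1L ||
      !is.finite(death_rate) || death_rate < 0)
    stop("`death_rate` must be a single rate >= 0", call. = FALSE)
  if (!is.numeric(initial_count) || length(initial_count) != 1L ||
      !is.finite(initial_count) || initial_count < 0)
    stop("`initial_count` must be >= 0", call. = FALSE)
  structure(
    list(N = N, advance_rates = as.numeric(advance_rates),
         death_rate = as.numeric(death_rate),
         initial_count = as.numeric(initial_count),
         is_erlang = isTRUE(diff(range(advance_rates)) == 0)),
    class = "stage_chain")
}

#' @export
print.stage_chain <- function(x, ...) {
  cat("Multi-stage chain: N =", x$N,
      if (x$is_erlang) sprintf("(Erlang, lambda = %g /h)", x$advance_rates[1])
      else "(stage-dependent rates)",
      sprintf("| mu = %g /h | C0 = %g\n", x$death_rate, x$initial_count))
  invisible(x)
}

#' Per-generation parameterisation of the multi-stage model with generations
#'
#' Container for the MS-G model: generation `g` (0-based) has `N_g` stages,
#' birth rate `lambda_g` and death rate `mu_g`.  Most users should construct
#' it through [build_schedule()]; this low-level constructor accepts arbitrary
#' per-generation vectors.
#'
#' @param N_g Integer vector of stage counts for generations `0..G_max`.
#' @param lambda_g Birth rates (inverse hours), one per generation, all > 0.
#' @param mu_g Death rates (inverse hours), one per generation, all >= 0.
#' @param initial_count Founder cells C0 >= 0 (stage 1 of generation 0 at
#'   time 0).
#' @param rule Optional named list recording how the schedule was generated
#'   (`N0`, `lambda0`, `N`, `lambda`, and either `alpha` or `mu_constant`);
#'   used to extend the schedule beyond `G_max` (e.g. by the simulator) and
#'   for config round-trips.  [build_schedule()] fills it in.
#' @return An object of class `generation_schedule` with fields `G_max`,
#'   `N_g`, `lambda_g`, `mu_g`, `initial_count`, `rule`, and `uniform` (TRUE
#'   iff stage count and both rates are identical across generations, the
#'   regime with closed-form solutions).
#' @export
generation_schedule <- function(N_g, lambda_g, mu_g, initial_count,
                                rule = NULL) {
  G1 <- length(N_g)
  if (G1 < 1L) stop("need at least generation 0", call. = FALSE)
  if (any(!is.finite(N_g)) || any(N_g < 1) || any(N_g != floor(N_g)))
    stop("all stage counts `N_g` must be integers >= 1", call. = FALSE)
  if (length(lambda_g) != G1 || any(!is.finite(lambda_g)) ||
      any(lambda_g <= 0))
    stop("`lambda_g` must be positive rates, one per generation",
         call. = FALSE)
  if (length(mu_g) != G1 || any(!is.finite(mu_g)) || any(mu_g < 0))
    stop("`mu_g` must be rates >= 0, one per generation", call. = FALSE)
  if (!is.numeric(initial_count) || length(initial_count) != 1L ||
      !is.finite(initial_count) || initial_count < 0)
    stop("`initial_count` must be >= 0", call. = FALSE)
  uniform <- diff(range(N_g)) == 0 && diff(range(lambda_g)) == 0 &&
    diff(range(mu_g)) == 0
  structure(
    list(G_max = G1 - 1L, N_g = as.integer(N_g),
         lambda_g = as.numeric(lambda_g), mu_g = as.numeric(mu_g),
         initial_count = as.numeric(initial_count), rule = rule,
         uniform = uniform),
    class = "generation_schedule")
}

#' Build the case-study generation schedule
#'
#' Generation 0 has `N0` stages and birth rate `lambda0` (activation and first
#' division are slower than later divisions); generations `1..G_max` share `N`
#' stages and birth rate `lambda`.  The death rate follows the linear law
#' `mu_g = alpha * g` (so `mu_0 = 0`), unless `mu_constant` is given, in which
#' case `mu_g` is the same for every generation (the regime required by the
#' stage-marginal closed forms).
#'
#' @param C0 Founder cells at time 0 (stage 1 of generation 0).
#' @param N0,lambda0 Stage count and birth rate of generation 0.
#' @param N,lambda Stage count and birth rate of generations >= 1.
#' @param alpha Death-rate slope of the linear law (see [death_rate_at()]).
#' @param G_max Largest explicitly tracked generation (default 15).
#' @param mu_constant Optional constant death rate overriding the linear law.
#' @param merged_tail Set TRUE when the schedule will feed the merged `"5+"`
#'   observation class; then `G_max < 5` is rejected because the class cannot
#'   be represented.
#' @return A [generation_schedule()].
#' @examples
#' sched <- build_schedule(C0 = 100, N0 = 2, lambda0 = 0.1, N = 3,
#'                         lambda = 0.2, alpha = 0.01, G_max = 8)
#' sched$mu_g[6] # mu_5 = 0.05
#' @export
build_schedule <- function(C0, N0, lambda0, N, lambda, alpha = 0,
                           G_max = 15L, mu_constant = NULL,
                           merged_tail = FALSE) {
  if (!is.numeric(G_max) || length(G_max) != 1L || G_max < 0 ||
      G_max != floor(G_max))
    stop("`G_max` must be a non-negative integer", call. = FALSE)
  if (isTRUE(merged_tail) && G_max < 5)
    stop("G_max < 5 cannot represent the merged \"5+\" class", call. = FALSE)
  gg <- 0:G_max
  if (is.null(mu_constant)) {
    mu_g <- death_rate_at(alpha, gg)
    rule <- list(N0 = N0, lambda0 = lambda0, N = N, lambda = lambda,
                 alpha = alpha)
  } else {
    if (!is.numeric(mu_constant) || mu_constant < 0)
      stop("`mu_constant` must be >= 0", call. = FALSE)
    mu_g <- rep(mu_constant, length(gg))
    rule <- list(N0 = N0, lambda0 = lambda0, N = N, lambda = lambda,
                 mu_constant = mu_constant)
  }
  generation_schedule(
    N_g = c(N0, rep(N, G_max)),
    lambda_g = c(lambda0, rep(lambda, G_max)),
    mu_g = mu_g, initial_count = C0, rule = rule)
}

#' @export
print.generation_schedule <- function(x, ...) {
  cat(sprintf(
    "Generation schedule: G_max = %d, C0 = %g%s\n", x$G_max,
    x$initial_count, if (x$uniform) " (uniform across generations)" else ""))
  cat(sprintf("  g = 0   : N = %d, lambda = %g /h, mu = %g /h\n",
              x$N_g[1], x$lambda_g[1], x$mu_g[1]))
  if (x$G_max >= 1)
    cat(sprintf("  g >= 1  : N in [%d,%d], lambda in [%g,%g], mu in [%g,%g]\n",
                min(x$N_g[-1]), max(x$N_g[-1]), min(x$lambda_g[-1]),
                max(x$lambda_g[-1]), min(x$mu_g[-1]), max(x$mu_g[-1])))
  invisible(x)
}

# Extend a schedule to a larger G_max using its generating rule; schedules
# without a rule repeat the terminal generation's parameters.
extend_schedule <- function(schedule, G_max) {
  stopifnot(inherits(schedule, "generation_schedule"))
  if (G_max <= schedule$G_max) return(schedule)
  r <- schedule$rule
  if (!is.null(r)) {
    build_schedule(C0 = schedule$initial_count, N0 = r$N0,
                   lambda0 = r$lambda0, N = r$N, lambda = r$lambda,
                   alpha = if (is.null(r$mu_constant)) r$alpha else 0,
                   G_max = G_max, mu_constant = r$mu_constant)
  } else {
    extra <- G_max - schedule$G_max
    tail_mu <- rep(schedule$mu_g[schedule$G_max + 1L], extra)
    generation_schedule(
      N_g = c(schedule$N_g, rep(schedule$N_g[schedule$G_max + 1L], extra)),
      lambda_g = c(schedule$lambda_g,
                   rep(schedule$lambda_g[schedule$G_max + 1L], extra)),
      mu_g = c(schedule$mu_g, tail_mu),
      initial_count = schedule$initial_count)
  }
}

#' Serialise a schedule to / from a config list
#'
#' `schedule_to_config()` renders a rule-built schedule as the `model` block
#' of the YAML configuration (`C0, N0, lambda0, N, lambda, alpha, G_max`,
#' optionally `mu_constant`); `schedule_from_config()` inverts it.  The
#' round-trip is lossless for schedules created by [build_schedule()].
#'
#' @param schedule A [generation_schedule()] carrying a generating rule.
#' @param config A named list as produced by `schedule_to_config()`.
#' @return A named list, or a `generation_schedule`, respectively.
#' @export
schedule_to_config <- function(schedule) {
  stopifnot(inherits(schedule, "generation_schedule"))
  r <- schedule$rule
  if (is.null(r))
    stop("schedule carries no generating rule; cannot serialise",
         call. = FALSE)
  out <- list(C0 = schedule$initial_count, N0 = r$N0, lambda0 = r$lambda0,
              N = r$N, lambda = r$lambda, G_max = schedule$G_max)
  if (is.null(r$mu_constant)) out$alpha <- r$alpha
  else out$mu_constant <- r$mu_constant
  out
}

#' @rdname schedule_to_config
#' @export
schedule_from_config <- function(config) {
  known <- c("C0", "N0", "lambda0", "N", "lambda", "alpha", "G_max",
             "mu_constant")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown model config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  need <- c("C0", "N0", "lambda0", "N", "lambda")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("model config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  build_schedule(C0 = config$C0, N0 = config$N0, lambda0 = config$lambda0,
                 N = config$N, lambda = config$lambda,
                 alpha = if (is.null(config$alpha)) 0 else config$alpha,
                 G_max = if (is.null(config$G_max)) 15L else config$G_max,
                 mu_constant = config$mu_constant)
}

#' Mean trajectory of the stage/generation compartments
#'
#' Expected counts `M^g_j(t)` on a time grid, as produced by [solve_mean()]
#' or the closed forms.  `values` is a matrix with one row per (generation,
#' stage) compartment (in generation-major order) and one column per time.
#'
#' @param times Strictly increasing time grid in hours.
#' @param values Numeric matrix, compartments x times.
#' @param generation,stage Integer vectors labelling the rows (generation is
#'   0-based, stage 1-based, matching the model's indexing).
#' @param provenance One of "closed-form", "matrix-exponential",
#'   "simulation-ensemble", "cyton".
#' @return An object of class `mean_trajectory`.
#' @export
mean_trajectory <- function(times, values, generation, stage,
                            provenance = c("matrix-exponential",
                                           "closed-form",
                                           "simulation-ensemble", "cyton")) {
  provenance <- match.arg(provenance)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  values <- as.matrix(values)
  if (ncol(values) != length(times))
    stop("`values` needs one column per time", call. = FALSE)
  if (length(generation) != nrow(values) || length(stage) != nrow(values))
    stop("row labels must match `values`", call. = FALSE)
  if (any(values < -1e-9 * max(1, max(abs(values)))))
    stop("negative mean counts beyond solver tolerance", call. = FALSE)
  structure(list(times = times, values = values,
                 generation = as.integer(generation),
                 stage = as.integer(stage), provenance = provenance),
            class = "mean_trajectory")
}

#' @export
print.mean_trajectory <- function(x, ...) {
  cat(sprintf(
    "Mean trajectory (%s): %d compartments (generations 0..%d) x %d times on [%g, %g] h\n",
    x$provenance, nrow(x$values), max(x$generation), length(x$times),
    min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.mean_trajectory <- function(x, ...) {
  data.frame(
    time_h = rep(x$times, each = nrow(x$values)),
    generation = rep(x$generation, length(x$times)),
    stage = rep(x$stage, length(x$times)),
    mean_count = as.vector(x$values))
}
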