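# Synthetic CFSE-style generation-count datasets: independent exact
# realisations per mouse, observed once, with generations >= 5 merged.

GENERATION_CLASSES <- c("0", "1", "2", "3", "4", "5+")

#' Default sampling design of the synthetic experiments
#'
#' Eight nominal time points (days 3, 4, 5, 6, 7, 10, 12 and 18 after
#' transfer) with between 3 and 7 mice each, mirroring adoptive-transfer
#' CFSE studies in lymphopenic hosts; later harvests use fewer animals.
#' Times are converted to hours on ingestion (the model works in hours).
#'
#' @return data.frame with columns `day` and `mice`.
#' @export
default_design <- function() {
  data.frame(day = c(3, 4, 5, 6, 7, 10, 12, 18),
             mice = c(5L, 5L, 5L, 5L, 5L, 4L, 4L, 3L))
}

#' Default ground-truth schedule for synthetic data
#'
#' A fast-clonotype-like parameterisation: `C0 = 4.5e4` transferred cells,
#' 3 stages at `0.05`/h for the first division (mean 60 h to first
#' division), 5 stages at `0.12`/h thereafter (mean 42 h per later
#' division), and a weak division-linked death slope `alpha = 2e-4`/h.
#'
#' @param G_max Tracked generations (default 15).
#' @return A [generation_schedule()].
#' @export
default_truth <- function(G_max = 15L) {
  build_schedule(C0 = 4.5e4, N0 = 3, lambda0 = 0.05, N = 5, lambda = 0.12,
                 alpha = 2e-4, G_max = G_max)
}

#' Generate a synthetic CFSE generation-count dataset
#'
#' Each mouse is one independent exact (Gillespie) realisation of the model
#' under `schedule`, started from the same `C0` founder cells and observed
#' once at its harvest time; generation totals at and beyond `cutoff` are
#' merged into the `"5+"` class.  The only noise is demographic
#' stochasticity -- no measurement-error overlay.
#'
#' @param schedule True [generation_schedule()].
#' @param design data.frame with columns `day` and `mice` (see
#'   [default_design()]).
#' @param seed Integer seed; the dataset is byte-identical on rerun.
#' @param cutoff First merged generation (default 5).
#' @param cell_cap Simulator abort threshold per mouse.
#' @return A data.frame of class `cfse_dataset` with columns
#'   `time_h, replicate_id, generation_class, cell_count`; every
#'   (time, replicate) carries all 6 classes (zeros included).
#' @export
generate_cfse_dataset <- function(schedule, design = default_design(), seed,
                                  cutoff = 5L, cell_cap = 1e9) {
  stopifnot(inherits(schedule, "generation_schedule"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!all(c("day", "mice") %in% names(design)))
    stop("`design` needs columns `day` and `mice`", call. = FALSE)
  if (any(design$mice < 1)) stop("need >= 1 replicate per time point",
                                 call. = FALSE)
  ext <- sim_ext_rule(schedule)
  rows <- list()
  rep_counter <- 0L
  for (i in seq_len(nrow(design))) {
    t_h <- design$day[i] * 24
    for (m in seq_len(design$mice[i])) {
      rep_counter <- rep_counter + 1L
      set.seed(derive_seed(seed, rep_counter))
      sim <- cpp_msg_gillespie(schedule$N_g, schedule$lambda_g,
                               schedule$mu_g, ext$N, ext$lambda, ext$alpha,
                               ext$mu_const, schedule$initial_count,
                               t_h, cell_cap, escape_threshold = -1)
      if (isTRUE(sim$capped))
        stop("simulated mouse exceeded the cell cap; raise `cell_cap`",
             call. = FALSE)
      per_gen <- tapply(sim$counts[, 1], sim$generation, sum)
      counts <- setNames(numeric(length(GENERATION_CLASSES)),
                         GENERATION_CLASSES)
      for (g in as.integer(names(per_gen))) {
        cls <- if (g >= cutoff) paste0(cutoff, "+") else as.character(g)
        counts[cls] <- counts[cls] + per_gen[as.character(g)]
      }
      rows[[rep_counter]] <- data.frame(
        time_h = t_h, replicate_id = sprintf("d%g_m%d", design$day[i], m),
        generation_class = GENERATION_CLASSES,
        cell_count = as.integer(counts))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cfse_dataset", "data.frame")
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  out
}

#' Replicate summaries of a generation-count dataset
#'
#' Per (generation class, time): the mean cell count across replicate mice
#' and its sample standard deviation.  The standard deviation enters the
#' calibration distance as a denominator, so it is floored at `sd_floor`
#' (default 1 cell), which also covers single-replicate time points and
#' identical replicates.
#'
#' @param dataset A `cfse_dataset` (from [generate_cfse_dataset()] or
#'   [read_counts()]).
#' @param sd_floor Lower bound on the standard deviation (cells).
#' @return data.frame `time_h, generation_class, mean_count, sd_count,
#'   n_replicates`, ordered by time then class.
#' @export
summarize_cfse <- function(dataset, sd_floor = 1) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0)
    stop("empty dataset", call. = FALSE)
  need <- c("time_h", "replicate_id", "generation_class", "cell_count")
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sp <- split(dataset, list(dataset$time_h, dataset$generation_class),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(time_h = d$time_h[1], generation_class = d$generation_class[1],
               mean_count = mean(d$cell_count),
               sd_count = max(if (nrow(d) > 1) sd(d$cell_count) else 0,
                              sd_floor),
               n_replicates = nrow(d))
  }))
  out <- out[order(out$time_h, match(out$generation_class,
                                     GENERATION_CLASSES)), ]
  rownames(out) <- NULL
  out
}
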