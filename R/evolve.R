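#' Evolutionary search configuration
#'
#' @param pop_size CMA-ES population size `NP` per generation.
#' @param max_generations Generation budget `NM`.
#' @param n_eval_reps Replicate rollouts `NE` averaged into each
#'   candidate's fitness.
#' @param sigma_init Initial CMA-ES step size on the (unbounded) flat
#'   genome; the phenotype is bounded by clipping instead of search-space
#'   bounds (states to the state limits at compile time, the competency
#'   gene inside [decode_competency()]).
#' @param sigma_genes Standard deviation of the random initial search mean
#'   (see [init_genome()]).
#' @param solve_threshold Averaged fitness at which the task counts as
#'   solved (the full-correctness level `Nj` of the 8x8 task is 64).
#' @param solve_metric What the threshold is compared against: the
#'   optimized averaged fitness `F` itself (`"fitness"`), or the averaged
#'   correctness term `2*nG - Nj` of the generation-best individual
#'   (`"correctness"`, the convention of the transfer experiments, where
#'   the full shaped fitness is optimized but solving means reaching the
#'   correctness level).
#' @param patience Extra generations to continue after the threshold is
#'   first crossed (0 stops at the crossing; `Inf` runs to
#'   `max_generations`).
#' @param seed Master seed of the run (drives CMA-ES sampling and all
#'   replicate seeds).
#' @param warm_sigma Initial step size used by [warm_start_evolve()].
#' @return An object of class `ea_config`.
#' @export
ea_config <- function(pop_size = 96L, max_generations = 2000L,
                      n_eval_reps = 8L, sigma_init = 0.5, sigma_genes = 0.1,
                      solve_threshold = 64,
                      solve_metric = c("fitness", "correctness"),
                      patience = 0L, seed = 1L, warm_sigma = 0.3) {
  stopifnot(pop_size >= 2L, max_generations >= 1L, n_eval_reps >= 1L,
            sigma_init > 0, warm_sigma > 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 n_eval_reps = as.integer(n_eval_reps),
                 sigma_init = sigma_init, sigma_genes = sigma_genes,
                 solve_threshold = solve_threshold,
                 solve_metric = match.arg(solve_metric),
                 patience = patience,
                 seed = as.integer(seed), warm_sigma = warm_sigma),
            class = "ea_config")
}

# Shared CMA-ES loop behind evolve() and warm_start_evolve().
evolve_loop <- function(target, arch, grid, env, weights, ea, mode,
                        start_mean, sigma0, log_file = NULL,
                        verbose = FALSE) {
  has_comp <- identical(mode, "evolvable_competency")
  n_struct <- grid$n_cells * grid$nc
  dim_total <- genome_length(arch, grid, has_comp)
  if (length(start_mean) != dim_total)
    stop("start mean has the wrong genome length")
  if (identical(mode, "direct")) env$actions_enabled <- FALSE
  if (has_comp) {
    env$pd <- NA_real_
    if (weights$l2_rate == 0) weights$l2_rate <- 0.01
  }

  set.seed(ea$seed)
  st <- cma_init(start_mean, sigma = sigma0, lambda = ea$pop_size)
  gen_log <- vector("list", ea$max_generations)
  best_ever <- -Inf
  best_corr <- -Inf
  best_genome <- NULL
  best_rep_seeds <- NULL
  solved_at <- NA_integer_
  n_gen <- 0L
  if (!is.null(log_file) && file.exists(log_file)) unlink(log_file)

  for (gen in seq_len(ea$max_generations)) {
    cand <- cma_ask(st)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, ea$n_eval_reps)
    scores <- numeric(ea$pop_size)
    ev_gb <- NULL
    for (j in seq_len(ea$pop_size)) {
      gj <- genome_unflatten(cand[j, ], arch, grid, has_comp)
      ev <- evaluate_genome(gj, target, env, weights, rep_seeds = rep_seeds)
      scores[j] <- ev$mean_score
      if (j == 1L || ev$mean_score > max(scores[seq_len(j - 1L)]))
        ev_gb <- ev
    }
    if (any(!is.finite(scores)))
      stop("non-finite fitness encountered at generation ", gen,
           "; first offending genome: ",
           paste(utils::head(cand[which(!is.finite(scores))[1], ], 8),
                 collapse = ", "), " ...")
    cma_tell(st, cand, -scores)
    gb <- which.max(scores)
    # averaged correctness term of the generation-best individual
    corr_gb <- mean(vapply(ev_gb$breakdowns, function(b)
      2 * b$n_correct - grid$n_cells, numeric(1)))
    if (corr_gb > best_corr) best_corr <- corr_gb
    if (scores[gb] > best_ever) {
      best_ever <- scores[gb]
      best_genome <- genome_unflatten(cand[gb, ], arch, grid, has_comp)
      best_rep_seeds <- rep_seeds
    }
    sf <- structural_fitness(genome_unflatten(cand[gb, ], arch, grid,
                                              has_comp),
                             target, env, weights,
                             rep_seeds = rep_seeds)$mean_score
    rec <- list(generation = gen, best_ever = best_ever,
                gen_best = scores[gb], pop_mean = mean(scores),
                pop_sd = stats::sd(scores), structural_best = sf,
                corr_best = corr_gb, best_ever_corr = best_corr,
                pd_best = if (has_comp)
                  decode_competency(cand[gb, dim_total]) else env$pd,
                sigma = st$sigma)
    gen_log[[gen]] <- rec
    if (!is.null(log_file))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = log_file, append = TRUE, sep = "")
    if (verbose && (gen %% 25L == 0L || gen == 1L))
      message(sprintf("gen %4d  best-ever %7.2f  mean %7.2f  sigma %.3g",
                      gen, best_ever, mean(scores), st$sigma))
    n_gen <- gen
    solve_level <- if (identical(ea$solve_metric, "correctness"))
      best_corr else best_ever
    if (is.na(solved_at) && solve_level >= ea$solve_threshold)
      solved_at <- gen
    if (!is.na(solved_at) && gen >= solved_at + ea$patience) break
  }

  recs <- gen_log[seq_len(n_gen)]
  generations <- data.frame(
    generation = vapply(recs, `[[`, numeric(1), "generation"),
    best_ever = vapply(recs, `[[`, numeric(1), "best_ever"),
    gen_best = vapply(recs, `[[`, numeric(1), "gen_best"),
    pop_mean = vapply(recs, `[[`, numeric(1), "pop_mean"),
    pop_sd = vapply(recs, `[[`, numeric(1), "pop_sd"),
    structural_best = vapply(recs, `[[`, numeric(1), "structural_best"),
    corr_best = vapply(recs, `[[`, numeric(1), "corr_best"),
    best_ever_corr = vapply(recs, `[[`, numeric(1), "best_ever_corr"),
    pd_best = vapply(recs, function(r)
      if (is.na(r$pd_best)) NA_real_ else r$pd_best, numeric(1)),
    sigma = vapply(recs, `[[`, numeric(1), "sigma"))
  structure(list(generations = generations, best_genome = best_genome,
                 best_fitness = best_ever, best_rep_seeds = best_rep_seeds,
                 solved_at = solved_at,
                 censored = is.na(solved_at), n_generations = n_gen,
                 mode = mode, env = env, weights = weights, ea = ea,
                 target_name = target$name),
            class = "run_log")
}

#' @export
print.run_log <- function(x, ...) {
  cat(sprintf("<run_log> '%s' (%s): %d generations, best F %.3f, %s\n",
              x$target_name, x$mode, x$n_generations, x$best_fitness,
              if (x$censored) "not solved (censored)"
              else sprintf("solved at generation %d", x$solved_at)))
  invisible(x)
}

#' Evolve an NCA genome with CMA-ES
#'
#' Runs a CMA-ES neuroevolution of the flat genome (structural initial
#' states, functional controller weights, and -- in
#' `"evolvable_competency"` mode -- the competency gene) against a target
#' pattern. Every candidate is scored by [evaluate_genome()] with a fresh
#' set of replicate seeds per generation (shared across the generation's
#' candidates). The run stops at the generation budget, or `patience`
#' generations after the averaged best-ever fitness first crosses
#' `solve_threshold`.
#'
#' Modes:
#' * `"multiscale"`: full agency; cells act with probability `env$pd`.
#' * `"direct"`: all actions disabled (direct encoding); the functional
#'   genes formally stay in the search vector so the search-space dimension
#'   is identical to the multiscale case.
#' * `"evolvable_competency"`: appends the competency gene (decoded to the
#'   decision probability at rollout time) and enables L2 regularization
#'   (`rL2 = 0.01`) unless a rate is already set.
#'
#' @param target A [target_pattern()].
#' @param arch A [controller_spec()].
#' @param grid A [grid_spec()] (defaults to the target's grid).
#' @param env An [env_config()].
#' @param weights A [fitness_weights()].
#' @param ea An [ea_config()].
#' @param mode Encoding mode, see above.
#' @param log_file Optional path; per-generation records are appended as
#'   JSON lines while the run progresses.
#' @param verbose Print progress every 25 generations.
#' @return A `run_log`: per-generation data frame (`generations`), the
#'   best genome and its fitness and replicate seeds, `solved_at` (first
#'   generation with best-ever fitness >= threshold; `NA` and
#'   `censored = TRUE` if never crossed), and the configuration.
#' @export
evolve <- function(target, arch = controller_spec("ff"),
                   grid = target$spec, env = env_config(),
                   weights = fitness_weights(), ea = ea_config(),
                   mode = c("multiscale", "direct", "evolvable_competency"),
                   log_file = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  has_comp <- mode == "evolvable_competency"
  start <- with_preserved_rng(ea$seed + 10^6, genome_flatten(
    init_genome(arch, grid, include_competency = has_comp,
                sigma_init = ea$sigma_genes)))
  evolve_loop(target, arch, grid, env, weights, ea, mode, start,
              sigma0 = ea$sigma_init, log_file = log_file,
              verbose = verbose)
}

#' Warm-started evolution from a pre-evolved genome
#'
#' Transfers an existing solution to a new target: the CMA-ES mean is
#' initialized at the seed genome, with a reduced initial step size
#' (`ea$warm_sigma`, default 0.3), and both the structural and functional
#' genes remain mutable. Everything else matches [evolve()]. The step size
#' must be large enough for the search to traverse structural-gene
#' distances (a cell-type flip moves an initial state across most of the
#' `[-3, 3]` range) within a few generations -- far smaller values freeze
#' the warm start near its origin.
#'
#' @param seed_genome The pre-evolved [genome()] to adapt.
#' @param new_target The new [target_pattern()] (same grid).
#' @inheritParams evolve
#' @return A `run_log`.
#' @export
warm_start_evolve <- function(seed_genome, new_target,
                              env = env_config(),
                              weights = fitness_weights(),
                              ea = ea_config(), log_file = NULL,
                              verbose = FALSE) {
  grid <- seed_genome$grid
  if (grid$nx != new_target$spec$nx || grid$ny != new_target$spec$ny ||
      grid$ng != new_target$spec$ng)
    stop("seed genome and new target live on different grids")
  has_comp <- !is.null(seed_genome$competency)
  mode <- if (has_comp) "evolvable_competency" else "multiscale"
  evolve_loop(new_target, seed_genome$arch, grid, env, weights, ea, mode,
              genome_flatten(seed_genome), sigma0 = ea$warm_sigma,
              log_file = log_file, verbose = verbose)
}

#' First generation at which a fitness threshold is crossed
#'
#' @param log A `run_log` from [evolve()].
#' @param threshold Fitness threshold (defaults to the run's solve
#'   threshold).
#' @return A list with `generations` (1-based generation number of the
#'   first crossing of the best-ever solve metric -- the averaged fitness,
#'   or the averaged correctness term for `solve_metric = "correctness"`
#'   runs; the generation budget `NM` when never crossed) and `censored`
#'   (`TRUE` if never crossed). Aggregations over censored runs must
#'   report the censoring fraction.
#' @export
generations_to_threshold <- function(log, threshold = log$ea$solve_threshold) {
  metric <- if (identical(log$ea$solve_metric, "correctness") &&
                !is.null(log$generations$best_ever_corr))
    log$generations$best_ever_corr else log$generations$best_ever
  hit <- which(metric >= threshold)
  if (length(hit) == 0L)
    list(generations = log$ea$max_generations, censored = TRUE)
  else
    list(generations = log$generations$generation[hit[1L]], censored = FALSE)
}

#' Plot the fitness trajectory of a run
#'
#' @param x A `run_log`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.run_log <- function(x, ...) {
  g <- x$generations
  graphics::plot(g$generation, g$best_ever, type = "l", lwd = 2,
                 xlab = "generation", ylab = "fitness",
                 ylim = range(c(g$pop_mean - g$pop_sd, g$best_ever),
                              finite = TRUE), ...)
  graphics::lines(g$generation, g$gen_best, col = "steelblue")
  graphics::lines(g$generation, g$pop_mean, col = "grey40")
  graphics::lines(g$generation, g$structural_best, col = "purple")
  graphics::abline(h = x$ea$solve_threshold, lty = 2, col = "darkgreen")
  graphics::legend("bottomright", bty = "n", lwd = c(2, 1, 1, 1),
                   col = c("black", "steelblue", "grey40", "purple"),
                   legend = c("best ever", "generation best",
                              "population mean", "structural (best)"))
  invisible(x)
}
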