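#' Plan a competency/noise/redundancy sweep
#'
#' Defines the experimental grid over the decision-making probability, the
#' developmental noise level, the controller redundancy number and the
#' controller architecture, with a number of statistically independent
#' evolutionary runs per cell. The defaults are the full study grid
#' (5 decision probabilities x 5 noise levels x 5 redundancy numbers,
#' 15 runs per combination); `profile = "desk"` selects a scaled-down
#' profile (small population/budget) suitable for interactive use and
#' testing.
#'
#' @param pd_values Decision probabilities to sweep.
#' @param noise_values Developmental noise levels to sweep.
#' @param redundancy_values Redundancy numbers R.
#' @param archs Character vector of controller architectures
#'   (`"ff"`, `"rgrn"`).
#' @param replicates Independent evolutionary runs per
#'   (pd, noise, R, arch) cell.
#' @param profile `"full"` (NP=96, NM=2000, NE=8) or `"desk"`
#'   (NP=16, NM=300, NE=4).
#' @param pop_size,max_generations,n_eval_reps Explicit budget overrides of
#'   the profile.
#' @param seed Master seed; every run of the sweep receives a unique seed
#'   derived from it.
#' @return An object of class `sweep_plan`.
#' @export
sweep_plan <- function(pd_values = c(0, 0.125, 0.25, 0.5, 1),
                       noise_values = c(0, 0.125, 0.25, 0.375, 0.5),
                       redundancy_values = c(1L, 2L, 4L, 8L, 16L),
                       archs = c("ff", "rgrn"), replicates = 15L,
                       profile = c("full", "desk"),
                       pop_size = NULL, max_generations = NULL,
                       n_eval_reps = NULL, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") c(96L, 2000L, 8L) else c(16L, 300L, 4L)
  structure(list(pd_values = pd_values, noise_values = noise_values,
                 redundancy_values = as.integer(redundancy_values),
                 archs = archs, replicates = as.integer(replicates),
                 profile = profile,
                 pop_size = as.integer(pop_size %||% defaults[1]),
                 max_generations = as.integer(max_generations %||% defaults[2]),
                 n_eval_reps = as.integer(n_eval_reps %||% defaults[3]),
                 seed = as.integer(seed)),
            class = "sweep_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sweep_plan <- function(x, ...) {
  n <- length(x$pd_values) * length(x$noise_values) *
    length(x$redundancy_values) * length(x$archs) * x$replicates
  cat(sprintf("<sweep_plan> %d runs (%d pd x %d noise x %d R x %d arch x %d reps), %s profile\n",
              n, length(x$pd_values), length(x$noise_values),
              length(x$redundancy_values), length(x$archs), x$replicates,
              x$profile))
  invisible(x)
}

sweep_run_table <- function(plan) {
  runs <- expand.grid(replicate = seq_len(plan$replicates),
                      redundancy = plan$redundancy_values,
                      arch = plan$archs, noise = plan$noise_values,
                      pd = plan$pd_values,
                      stringsAsFactors = FALSE)
  # content-addressed run id: condition + replicate, independent of order
  runs$run_id <- sprintf("pd%s_noise%s_%s_R%d_rep%02d",
                         format(runs$pd), format(runs$noise), runs$arch,
                         runs$redundancy, runs$replicate)
  runs$seed <- derive_seeds(plan$seed, nrow(runs))
  runs
}

#' Run a competency/noise/redundancy sweep
#'
#' Executes one [evolve()] per run of the plan and aggregates generations
#' to the solve threshold. The sweep is resumable: each completed run is
#' serialized under `out_dir` keyed by its run id, and re-running a
#' completed run is a no-op. Failed runs are recorded and never abort the
#' sweep.
#'
#' @param plan A [sweep_plan()].
#' @param target A [target_pattern()].
#' @param env Base [env_config()] (its `pd` and `noise_sigma` are
#'   overridden per cell).
#' @param weights A [fitness_weights()].
#' @param mode Encoding mode passed to [evolve()]; with the conventional
#'   `"multiscale"` mode, cells with `pd = 0` are the direct-encoding
#'   limit.
#' @param out_dir Optional directory for per-run JSON results (enables
#'   resuming).
#' @param verbose Print one line per completed run.
#' @return A list of class `sweep_result`: `runs` (per-run data frame with
#'   generations-to-threshold and censoring), `summary` (per (pd, noise)
#'   cell: mean/sd generations with censored runs entered at the generation
#'   budget, censoring fraction, n) and `summary_by_arch` (additionally
#'   partitioned by architecture).
#' @export
run_sweep <- function(plan, target, env = env_config(),
                      weights = fitness_weights(), mode = "multiscale",
                      out_dir = NULL, verbose = FALSE) {
  runs <- sweep_run_table(plan)
  runs$generations <- NA_real_
  runs$censored <- NA
  runs$best_fitness <- NA_real_
  runs$failed <- FALSE
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(nrow(runs))) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, paste0(runs$run_id[i], ".json")) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      rec <- jsonlite::fromJSON(cache)
    } else {
      rec <- tryCatch({
        arch <- controller_spec(runs$arch[i],
                                redundancy = runs$redundancy[i])
        env_i <- env
        env_i$pd <- runs$pd[i]
        env_i$noise_sigma <- runs$noise[i]
        ea <- ea_config(pop_size = plan$pop_size,
                        max_generations = plan$max_generations,
                        n_eval_reps = plan$n_eval_reps,
                        solve_threshold = target$spec$n_cells,
                        seed = runs$seed[i])
        log <- evolve(target, arch, target$spec, env_i, weights, ea,
                      mode = mode)
        gt <- generations_to_threshold(log)
        list(generations = gt$generations, censored = gt$censored,
             best_fitness = log$best_fitness, failed = FALSE)
      }, error = function(e)
        list(generations = NA, censored = NA, best_fitness = NA,
             failed = TRUE, error = conditionMessage(e)))
      if (!is.null(cache))
        jsonlite::write_json(rec, cache, auto_unbox = TRUE, digits = NA)
    }
    runs$generations[i] <- as.numeric(rec$generations)
    runs$censored[i] <- isTRUE(rec$censored)
    runs$best_fitness[i] <- as.numeric(rec$best_fitness)
    runs$failed[i] <- isTRUE(rec$failed)
    if (verbose)
      message(sprintf("[%d/%d] %s: %s", i, nrow(runs), runs$run_id[i],
                      if (runs$failed[i]) "FAILED"
                      else sprintf("%s gens%s", runs$generations[i],
                                   if (runs$censored[i]) " (censored)" else "")))
  }
  structure(list(runs = runs,
                 summary = summarize_sweep(runs, by_arch = FALSE),
                 summary_by_arch = summarize_sweep(runs, by_arch = TRUE),
                 plan = plan),
            class = "sweep_result")
}

# Aggregation is a pure function of the per-run table, so summaries are
# recomputable from raw logs alone.
summarize_sweep <- function(runs, by_arch = FALSE) {
  ok <- !runs$failed
  keys <- if (by_arch) c("pd", "noise", "arch") else c("pd", "noise")
  split_idx <- interaction(runs[ok, keys, drop = FALSE], drop = TRUE)
  parts <- split(runs[ok, , drop = FALSE], split_idx)
  out <- do.call(rbind, lapply(parts, function(d) {
    cell <- d[1, keys, drop = FALSE]
    cbind(cell,
          data.frame(mean_generations = mean(d$generations),
                     sd_generations = stats::sd(d$generations),
                     censoring_fraction = mean(d$censored),
                     n_runs = nrow(d)))
  }))
  rownames(out) <- NULL
  out[order(out$pd, out$noise), , drop = FALSE]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d runs (%d failed)\n", nrow(x$runs),
              sum(x$runs$failed)))
  print(x$summary)
  invisible(x)
}

#' Generalization rollouts of a fixed genome
#'
#' Deploys an already-evolved genome -- without any further optimization --
#' under conditions it was not evolved for: for each value of the varied
#' parameter (`noise_sigma` or `pd`) it runs `reps` independent rollouts of
#' `lifetime` steps (typically far beyond the developmental budget) and
#' records the correctness-only score `2*nG(t) - Nj` at every step.
#'
#' @param genome An [genome()].
#' @param target The [target_pattern()] the score is taken against.
#' @param vary `"noise"` or `"pd"`.
#' @param values Parameter values to deploy under.
#' @param env Base [env_config()]; the varied field is overridden, and
#'   `dev_steps` is set to `lifetime`.
#' @param lifetime Steps per rollout.
#' @param reps Independent rollouts per value.
#' @param seed Master seed.
#' @return A data frame of class `generalization_curves`: one row per
#'   (value, step) with the mean and standard deviation over replicates of
#'   the per-step correctness score, plus `reps`.
#' @export
generalization_eval <- function(genome, target, vary = c("noise", "pd"),
                                values, env = env_config(), lifetime = 100L,
                                reps = 100L, seed = 1L) {
  vary <- match.arg(vary)
  env$dev_steps <- as.integer(lifetime)
  nj <- genome$grid$n_cells
  seeds <- derive_seeds(seed, reps * length(values))
  out <- vector("list", length(values))
  for (v in seq_along(values)) {
    env_v <- env
    if (vary == "noise") env_v$noise_sigma <- values[v]
    else env_v$pd <- values[v]
    correct <- vapply(seq_len(reps), function(r) {
      tr <- rollout(genome, env_v, seed = seeds[(v - 1L) * reps + r])
      2 * trajectory_correct_cells(tr, target) - nj
    }, numeric(lifetime + 1L))
    out[[v]] <- data.frame(value = values[v], step = 0:lifetime,
                           mean_score = rowMeans(correct),
                           sd_score = apply(correct, 1L, stats::sd),
                           reps = reps)
  }
  res <- do.call(rbind, out)
  names(res)[1] <- vary
  class(res) <- c("generalization_curves", "data.frame")
  res
}

#' Transfer matrix: warm-started adaptation to new targets
#'
#' For each pre-evolved seed genome and each (new target, noise level)
#' combination, runs `replicates` warm-started evolutionary adaptations
#' ([warm_start_evolve()]) and reports the mean and minimum number of
#' generations until the averaged correctness term reaches `Nj` (the
#' full-pattern level). The adaptation optimizes the ordinary shaped
#' fitness (`weights`); only the solve detection is correctness-based,
#' matching the correctness-score convention of transfer experiments.
#'
#' @param seed_genomes Named list of pre-evolved [genome()] objects (names
#'   label the rows, e.g. by the competency level they were evolved at).
#' @param targets List of [target_pattern()] objects.
#' @param noise_values Noise levels to adapt under.
#' @param env Base [env_config()].
#' @param ea An [ea_config()] (its `max_generations` bounds each
#'   adaptation; censored runs enter at that bound).
#' @param weights The [fitness_weights()] optimized during adaptation.
#' @param replicates Warm-started runs per cell.
#' @param seed Master seed.
#' @return Data frame with one row per (seed genome, target, noise):
#'   mean/min/max generations-to-solve, censoring fraction, n.
#' @export
transfer_matrix <- function(seed_genomes, targets, noise_values = 0.25,
                            env = env_config(), ea = ea_config(),
                            weights = fitness_weights(),
                            replicates = 3L, seed = 1L) {
  if (length(targets) == 0L) {
    return(data.frame(seed_genome = character(), target = character(),
                      noise = numeric(), mean_generations = numeric(),
                      min_generations = numeric(), max_generations = numeric(),
                      censoring_fraction = numeric(), n_runs = integer()))
  }
  if (is.null(names(seed_genomes)))
    names(seed_genomes) <- sprintf("seed%d", seq_along(seed_genomes))
  grid_cells <- expand.grid(sg = names(seed_genomes),
                            tg = seq_along(targets), noise = noise_values,
                            stringsAsFactors = FALSE)
  run_seeds <- derive_seeds(seed, nrow(grid_cells) * replicates)
  rows <- vector("list", nrow(grid_cells))
  for (i in seq_len(nrow(grid_cells))) {
    target <- targets[[grid_cells$tg[i]]]
    env_i <- env
    env_i$noise_sigma <- grid_cells$noise[i]
    gens <- numeric(replicates)
    cens <- logical(replicates)
    for (r in seq_len(replicates)) {
      ea_r <- ea
      ea_r$seed <- run_seeds[(i - 1L) * replicates + r]
      ea_r$solve_threshold <- target$spec$n_cells
      ea_r$solve_metric <- "correctness"
      log <- warm_start_evolve(seed_genomes[[grid_cells$sg[i]]], target,
                               env_i, weights, ea_r)
      gt <- generations_to_threshold(log)
      gens[r] <- gt$generations
      cens[r] <- gt$censored
    }
    rows[[i]] <- data.frame(seed_genome = grid_cells$sg[i],
                            target = target$name,
                            noise = grid_cells$noise[i],
                            mean_generations = mean(gens),
                            min_generations = min(gens),
                            max_generations = max(gens),
                            censoring_fraction = mean(cens),
                            n_runs = replicates)
  }
  do.call(rbind, rows)
}
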