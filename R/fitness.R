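#' Fitness weights
#'
#' The phenotype-based fitness of a developmental trajectory is
#' `score = (2*nG - Nj) + rT*nT - rS*nS - l2`, where `nG` counts the cells
#' whose final type matches the target, `nT` counts post-update steps at
#' which the entire type map equals the target (rewarding maintenance of
#' the pattern), `nS` counts successive step pairs at which all cell types
#' stagnate while the pattern differs from the target (penalizing frozen
#' suboptimal patterns -- persistence of the correct pattern is never
#' penalized), and `l2` is an optional L2 penalty on the genome.
#'
#' @param maintain_reward Per-step reward `rT` for holding the full target
#'   pattern.
#' @param stagnation_penalty Per-step-pair penalty `rS` for suboptimal
#'   stagnation.
#' @param l2_rate L2 regularization rate `rL2` applied to the full flat
#'   genome (0 disables; 0.01 is used when the competency gene is evolved).
#' @param correctness_only If `TRUE`, forces `rT = rS = 0` so only the
#'   final-pattern correctness term `2*nG - Nj` remains.
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(maintain_reward = 0.25, stagnation_penalty = 0.5,
                            l2_rate = 0, correctness_only = FALSE) {
  if (correctness_only) {
    maintain_reward <- 0
    stagnation_penalty <- 0
  }
  stopifnot(l2_rate >= 0)
  structure(list(maintain_reward = maintain_reward,
                 stagnation_penalty = stagnation_penalty,
                 l2_rate = l2_rate, correctness_only = correctness_only),
            class = "fitness_weights")
}

#' L2 penalty on a flat genome
#'
#' @param flat Numeric vector (the full flat genome: structural, functional
#'   and competency genes alike).
#' @param l2_rate Penalty per squared parameter unit.
#' @return `l2_rate * sum(flat^2)`.
#' @export
l2_penalty <- function(flat, l2_rate) {
  l2_rate * sum(flat^2)
}

#' Score a developmental trajectory against a target pattern
#'
#' @param trajectory An [rollout()] result (states t0 .. tD).
#' @param target A [target_pattern()] on the same grid.
#' @param weights A [fitness_weights()].
#' @param genome_flat Optional flat genome vector; required when
#'   `weights$l2_rate > 0`.
#' @return An object of class `fitness_breakdown`: list with `n_correct`
#'   (nG), `n_target_steps` (nT, counted over the post-update states
#'   k = 1..tD), `n_stagnant` (nS, counted over the state pairs
#'   (k, k+1), k = 0..tD-1), `l2`, and `score`.
#' @examples
#' czech <- make_flag_pattern("czech")
#' g <- make_saturated_genome(czech)
#' tr <- rollout(g, env_config(actions_enabled = FALSE))
#' fitness(tr, czech)$score   # 70.25 = 64 + 0.25 * 25
#' @export
fitness <- function(trajectory, target, weights = fitness_weights(),
                    genome_flat = NULL) {
  grid <- trajectory$grid
  if (grid$nx != target$spec$nx || grid$ny != target$spec$ny ||
      grid$ng != target$spec$ng)
    stop("trajectory and target live on different grids")
  maps <- trajectory$type_maps
  td <- length(maps) - 1L
  nj <- grid$n_cells
  matches_target <- vapply(maps, function(tm) all(tm == target$types),
                           logical(1))
  n_correct <- sum(maps[[td + 1L]] == target$types)
  n_target_steps <- sum(matches_target[-1L])
  stagnant <- vapply(seq_len(td), function(k)
    all(maps[[k]] == maps[[k + 1L]]) && !matches_target[k], logical(1))
  n_stagnant <- sum(stagnant)
  l2 <- if (weights$l2_rate > 0) {
    if (is.null(genome_flat))
      stop("l2_rate > 0 requires the flat genome vector")
    l2_penalty(genome_flat, weights$l2_rate)
  } else 0
  score <- (2 * n_correct - nj) + weights$maintain_reward * n_target_steps -
    weights$stagnation_penalty * n_stagnant - l2
  structure(list(n_correct = n_correct, n_target_steps = n_target_steps,
                 n_stagnant = n_stagnant, l2 = l2, score = score,
                 n_cells = nj, dev_steps = td),
            class = "fitness_breakdown")
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat(sprintf("<fitness_breakdown> score %.4g (nG %d/%d, nT %d, nS %d, l2 %.4g)\n",
              x$score, x$n_correct, x$n_cells, x$n_target_steps,
              x$n_stagnant, x$l2))
  invisible(x)
}

derive_seeds <- function(master_seed, n) {
  with_preserved_rng(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Replicate-averaged genome fitness
#'
#' The selection criterion of the evolutionary search: the mean of `n_reps`
#' fitness scores from statistically independent developmental rollouts of
#' the same genome (development is stochastic under noise and partial
#' decision execution). Deterministic for a fixed seed set.
#'
#' @param genome An [genome()].
#' @param target A [target_pattern()].
#' @param env An [env_config()].
#' @param weights A [fitness_weights()].
#' @param n_reps Number of replicate rollouts `NE`.
#' @param seed Master seed from which the replicate seeds are derived, or
#'   `NULL` to pass `rep_seeds` explicitly.
#' @param rep_seeds Optional explicit integer vector of replicate seeds
#'   (overrides `seed`/`n_reps`); logged seeds allow exact re-scoring.
#' @param actions_enabled Override of `env$actions_enabled` (used by
#'   [structural_fitness()]).
#' @return Object of class `genome_fitness`: list with `mean_score` (F),
#'   `scores`, `rep_seeds`, `breakdowns`.
#' @export
evaluate_genome <- function(genome, target, env = env_config(),
                            weights = fitness_weights(), n_reps = 8L,
                            seed = NULL, rep_seeds = NULL,
                            actions_enabled = env$actions_enabled) {
  if (is.null(rep_seeds)) {
    if (is.null(seed))
      stop("provide either a master seed or explicit rep_seeds")
    rep_seeds <- derive_seeds(seed, n_reps)
  }
  env$actions_enabled <- actions_enabled
  flat <- if (weights$l2_rate > 0) genome_flatten(genome) else NULL
  breakdowns <- lapply(rep_seeds, function(s)
    fitness(rollout(genome, env, seed = s), target, weights, flat))
  scores <- vapply(breakdowns, `[[`, numeric(1), "score")
  structure(list(mean_score = mean(scores), scores = scores,
                 rep_seeds = rep_seeds, breakdowns = breakdowns),
            class = "genome_fitness")
}

#' @export
print.genome_fitness <- function(x, ...) {
  cat(sprintf("<genome_fitness> F = %.4g over %d replicates (sd %.3g)\n",
              x$mean_score, length(x$scores), stats::sd(x$scores)))
  invisible(x)
}

#' Structural (genotypic) fitness
#'
#' The fitness a genome's structural genes achieve on their own: the same
#' replicate-evaluation protocol as [evaluate_genome()] (same noise level,
#' same number of replicates) but with all agency disabled
#' (`actions_enabled = FALSE`), so only the initial cell states -- drifting
#' under developmental noise -- determine the phenotype. The functional
#' genes cannot act but still count toward the L2 term when enabled.
#'
#' @inheritParams evaluate_genome
#' @return A `genome_fitness` object.
#' @export
structural_fitness <- function(genome, target, env = env_config(),
                               weights = fitness_weights(), n_reps = 8L,
                               seed = NULL, rep_seeds = NULL) {
  evaluate_genome(genome, target, env, weights, n_reps, seed, rep_seeds,
                  actions_enabled = FALSE)
}
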