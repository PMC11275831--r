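test_that("fitness components match an exhaustive recount on random small trajectories", {
  set.seed(41)
  gs <- grid_spec(2, 2, ng = 3, nh = 0)
  target <- target_pattern(matrix(sample(0:2, 4, TRUE), 2, 2), gs)
  for (i in 1:50) {
    maps <- lapply(1:4, function(k)
      matrix(sample(0:2, 4, TRUE, prob = c(4, 1, 1)), 2, 2))
    # occasionally force repeats / target hits so all branches are exercised
    if (i %% 3 == 0) maps[[3]] <- maps[[2]]
    if (i %% 5 == 0) maps[[4]] <- target$types
    tr <- fake_trajectory(maps, gs)
    fb <- fitness(tr, target)
    oracle <- recount_fitness(maps, target$types, 0.25, 0.5, 4)
    expect_identical(fb$n_correct, oracle$ng)
    expect_identical(fb$n_target_steps, oracle$nt)
    expect_identical(fb$n_stagnant, oracle$ns)
    expect_equal(fb$score, oracle$score)
  }
})

test_that("maintenance is rewarded but holding the correct pattern is never penalized", {
  gs <- grid_spec(2, 2, ng = 2, nh = 0)
  tgt <- target_pattern(matrix(0L, 2, 2), gs)
  right <- matrix(0L, 2, 2)
  wrong <- matrix(1L, 2, 2)
  # correct and frozen throughout: full maintenance reward, zero stagnation
  fb <- fitness(fake_trajectory(rep(list(right), 6), gs), tgt)
  expect_identical(fb$n_target_steps, 5L)
  expect_identical(fb$n_stagnant, 0L)
  expect_equal(fb$score, 4 + 0.25 * 5)
  # wrong and frozen throughout: full stagnation penalty
  fb2 <- fitness(fake_trajectory(rep(list(wrong), 6), gs), tgt)
  expect_identical(fb2$n_stagnant, 5L)
  expect_equal(fb2$score, -4 - 0.5 * 5)
  # one extra correct final cell raises the first term by exactly 2
  part <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  part2 <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  d <- fitness(fake_trajectory(list(right, part2), gs), tgt)$score -
    fitness(fake_trajectory(list(right, part), gs), tgt)$score
  expect_equal(d, 2)
})

test_that("correctness-only weighting keeps just the final-pattern term", {
  gs <- grid_spec(2, 2, ng = 2, nh = 0)
  tgt <- target_pattern(matrix(0L, 2, 2), gs)
  maps <- list(matrix(1L, 2, 2), matrix(1L, 2, 2), matrix(0L, 2, 2))
  w <- fitness_weights(correctness_only = TRUE)
  expect_identical(w$maintain_reward, 0)
  expect_identical(w$stagnation_penalty, 0)
  expect_equal(fitness(fake_trajectory(maps, gs), tgt, w)$score, 4)
})

test_that("fitness ignores hidden channels and respects its analytic bounds", {
  czech <- make_flag_pattern("czech")
  g <- make_saturated_genome(czech)
  g$structural[, 4] <- runif(64, -3, 3)   # arbitrary hidden channel values
  tr <- rollout(g, env_config(actions_enabled = FALSE), seed = 1)
  expect_equal(fitness(tr, czech)$score, 70.25)
  # bounds: -Nj - rS tD <= score <= Nj + rT tD
  set.seed(42)
  for (i in 1:20) {
    gr <- random_genome(controller_spec("ff"), grid_spec(), sigma = 1)
    trr <- rollout(gr, env_config(noise_sigma = 0.5, pd = 0.5), seed = i)
    sc <- fitness(trr, czech)$score
    expect_gte(sc, -64 - 0.5 * 25)
    expect_lte(sc, 64 + 0.25 * 25)
  }
})

test_that("l2 penalty covers the entire flat genome and is sign-symmetric", {
  expect_equal(l2_penalty(c(1, -2), 0.01), 0.05)
  expect_equal(l2_penalty(numeric(10), 0.3), 0)
  expect_equal(l2_penalty(c(1, 2, 0.7), 0.01), l2_penalty(c(-1, 2, -0.7), 0.01))
  gs <- grid_spec(2, 2)
  arch <- controller_spec("ff")
  g <- genome(matrix(1, 4, 4), rep(0.5, param_count(arch, gs)), arch, gs,
              competency = 2)
  flat <- genome_flatten(g)
  tgt <- solid_target(0L)
  tr <- rollout(g, env_config(dev_steps = 2, pd = NA), seed = 1)
  w <- fitness_weights(l2_rate = 0.01)
  fb <- fitness(tr, tgt, w, genome_flat = flat)
  expect_equal(fb$l2, 0.01 * sum(flat^2))
  expect_error(fitness(tr, tgt, w), "flat genome")
})

test_that("replicate evaluation is deterministic and averages independent rollouts", {
  czech <- make_flag_pattern("czech")
  g <- make_saturated_genome(czech)
  env <- env_config(noise_sigma = 0.4, actions_enabled = FALSE)
  f1 <- evaluate_genome(g, czech, env, n_reps = 4, seed = 77)
  f2 <- evaluate_genome(g, czech, env, n_reps = 4, seed = 77)
  expect_identical(f1$mean_score, f2$mean_score)
  expect_identical(f1$rep_seeds, f2$rep_seeds)
  expect_equal(f1$mean_score, mean(f1$scores))
  # explicit seeds reproduce each replicate individually
  for (k in seq_along(f1$rep_seeds))
    expect_identical(
      evaluate_genome(g, czech, env, rep_seeds = f1$rep_seeds[k])$mean_score,
      f1$scores[k])
  # no stochasticity: every replicate identical at zero noise
  f0 <- evaluate_genome(g, czech, env_config(actions_enabled = FALSE),
                        n_reps = 8, seed = 1)
  expect_true(all(f0$scores == f0$scores[1]))
  expect_equal(f0$mean_score, 70.25)
})

test_that("structural fitness disables agency but keeps the evaluation protocol", {
  czech <- make_flag_pattern("czech")
  # nonzero controller weights cannot act under disabled agency
  g <- make_saturated_genome(czech)
  g$functional <- rnorm(length(g$functional), sd = 2)
  env <- env_config(noise_sigma = 0, pd = 1)
  expect_equal(structural_fitness(g, czech, env, n_reps = 2,
                                  seed = 3)$mean_score, 70.25)
  # at pd = 0 phenotypic and structural fitness coincide (same seeds)
  set.seed(51)
  gr <- random_genome(controller_spec("rgrn"), grid_spec(), sigma = 0.8)
  env0 <- env_config(noise_sigma = 0.3, pd = 0)
  seeds <- c(11L, 12L, 13L)
  expect_identical(
    evaluate_genome(gr, czech, env0, rep_seeds = seeds)$mean_score,
    structural_fitness(gr, czech, env0, rep_seeds = seeds)$mean_score)
  # random structural genes at zero noise: first term is 2k - 64
  trr <- rollout(gr, env_config(actions_enabled = FALSE), seed = 1)
  k <- sum(trr$type_maps[[26]] == czech$types)
  fb <- structural_fitness(gr, czech, env_config(pd = 1), rep_seeds = 1L)
  expect_equal(fb$breakdowns[[1]]$n_correct, k)
  expect_equal(2 * k - 64,
               fb$breakdowns[[1]]$score +
                 0.5 * fb$breakdowns[[1]]$n_stagnant -
                 0.25 * fb$breakdowns[[1]]$n_target_steps)
})
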