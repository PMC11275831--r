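#' Developmental environment configuration
#'
#' Collects the knobs of a developmental rollout. Each of the `dev_steps`
#' synchronous steps updates every cell `i` as
#' `c_i(t+1) = clip(c_i(t) + gate_i * a_i(t) + noise_i, state_limits)`,
#' where `a_i` is the (clipped) controller action computed from the
#' state at time `t`, `gate_i ~ Bernoulli(pd)` decides whether the proposed
#' action is executed in the environment (drawn independently per cell per
#' step), and `noise_i` is a vector of `nc` independent `N(0, noise_sigma^2)`
#' deviates, applied regardless of gating (cell states drift passively even
#' when no action is executed). `noise_sigma` is counted in units of the
#' action limit `max(action_limits) = 1`.
#'
#' @param dev_steps Number of developmental steps `t_D`.
#' @param noise_sigma Developmental noise standard deviation per state
#'   channel per step.
#' @param pd Decision-making probability in `[0, 1]`, or `NA` to decode it
#'   from the genome's competency gene at rollout time.
#' @param state_limits,action_limits Clip intervals for cell states and for
#'   the mean action.
#' @param actions_enabled `FALSE` disables all agency (every action is
#'   forced to the zero vector), which turns the rollout into the
#'   direct-encoding limit; noise still applies.
#' @param gate_memory If `TRUE`, an RGRN's internal memory update is also
#'   suppressed for cells whose action is gated off. The default (`FALSE`)
#'   gates only the environmental execution of the action, not the cell's
#'   internal computation.
#' @return An object of class `env_config`.
#' @export
env_config <- function(dev_steps = 25L, noise_sigma = 0, pd = 1,
                       state_limits = c(-3, 3), action_limits = c(-1, 1),
                       actions_enabled = TRUE, gate_memory = FALSE) {
  dev_steps <- as.integer(dev_steps)
  if (dev_steps < 1L) stop("dev_steps must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.na(pd) && (pd < 0 || pd > 1)) stop("pd must lie in [0, 1] (or NA)")
  stopifnot(length(state_limits) == 2L, length(action_limits) == 2L,
            state_limits[1] < state_limits[2],
            action_limits[1] < action_limits[2])
  structure(list(dev_steps = dev_steps, noise_sigma = noise_sigma, pd = pd,
                 state_limits = as.numeric(state_limits),
                 action_limits = as.numeric(action_limits),
                 actions_enabled = isTRUE(actions_enabled),
                 gate_memory = isTRUE(gate_memory)),
            class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf("<env_config> %d steps, noise %.3g, pd %s, actions %s\n",
              x$dev_steps, x$noise_sigma,
              if (is.na(x$pd)) "from competency gene" else format(x$pd),
              if (x$actions_enabled) "enabled" else "disabled"))
  invisible(x)
}

#' Moore neighborhood of a grid cell
#'
#' Returns the 9 perceived cell states of cell `(row, col)`: itself plus its
#' 8 Moore neighbors. The grid has fixed boundary conditions: positions off
#' the grid are filled with a virtual boundary cell of constant zero state,
#' so the perception always aggregates exactly 9 states.
#'
#' @param state `n_cells x nc` cell-state matrix (cell-major, see
#'   [genome()]).
#' @param row,col 1-based grid coordinates (row 1 = top).
#' @param grid A [grid_spec()].
#' @return A `9 x nc` matrix; row 1 is the cell itself, then the 8 neighbor
#'   offsets in row-major order.
#' @export
neighborhood <- function(state, row, col, grid) {
  if (row < 1L || row > grid$ny || col < 1L || col > grid$nx)
    stop("query cell lies outside the grid")
  offs <- rbind(c(0L, 0L),
                c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, -1L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))
  out <- matrix(0, 9L, grid$nc)
  for (k in seq_len(9L)) {
    r <- row + offs[k, 1L]; c <- col + offs[k, 2L]
    if (r >= 1L && r <= grid$ny && c >= 1L && c <= grid$nx)
      out[k, ] <- state[(r - 1L) * grid$nx + c, ]
  }
  out
}

#' Cell-type readout of a state
#'
#' Each cell's type is the 0-based index of the maximum entry among its
#' first `ng` state channels (the type indicators); ties break toward the
#' lowest index. Hidden channels never affect the readout.
#'
#' @param state `n_cells x nc` cell-state matrix.
#' @param grid A [grid_spec()].
#' @return `ny x nx` integer matrix of 0-based cell types.
#' @export
cell_types <- function(state, grid) {
  state <- matrix(state, grid$n_cells, grid$nc)
  ind <- state[, seq_len(grid$ng), drop = FALSE]
  types <- max.col(ind, ties.method = "first") - 1L
  matrix(types, grid$ny, grid$nx, byrow = TRUE)
}

resolve_pd <- function(genome, env) {
  if (is.na(env$pd)) {
    if (is.null(genome$competency))
      stop("env pd is NA but the genome carries no competency gene")
    decode_competency(genome$competency)
  } else {
    if (!is.null(genome$competency))
      stop("conflicting decision-probability sources: env fixes pd but the ",
           "genome carries a competency gene (set pd = NA to use the gene)")
    env$pd
  }
}

#' Run a developmental rollout
#'
#' Compiles the genome onto the grid (the structural part, clipped to the
#' state limits, is the exact initial state; no noise at t0) and performs
#' `env$dev_steps` synchronous developmental steps. All cells perceive the
#' state at time `t` before any cell updates (so the result cannot depend on
#' cell visitation order). Per step, the engine consumes the random stream
#' in a fixed order -- first `n_cells` gate uniforms, then `n_cells * nc`
#' noise normals -- independently of `pd`, `noise_sigma` and
#' `actions_enabled`, so changing one knob never reshuffles the draws of
#' another.
#'
#' @param genome An [genome()].
#' @param env An [env_config()]. If `env$pd` is `NA` the decision
#'   probability is decoded from the genome's competency gene; fixing
#'   `env$pd` while the genome carries a competency gene is an error.
#' @param seed Optional integer; when given, the rollout runs under its own
#'   temporary RNG state (the caller's stream is left untouched).
#' @param engine `"cpp"` (fast path) or `"r"` (naive per-cell reference
#'   loop). Both consume the random stream identically and produce
#'   bit-identical trajectories under the same seed.
#' @param keep_states Retain the full state history? With `FALSE` only the
#'   final state is kept (type maps are always retained for every step);
#'   used by bulk evaluation where only the type history matters.
#' @return An object of class `nca_trajectory`: list with `states` (an
#'   `n_cells x nc x (dev_steps+1)` array; a single final-state slab when
#'   `keep_states = FALSE`), `type_maps` (list of `ny x nx` integer
#'   matrices, one per step t0..tD), `gate_mask` (`n_cells x dev_steps`
#'   logical: action executed?), `pd`, `env`, `grid`.
#' @examples
#' g <- make_saturated_genome(make_flag_pattern("czech"))
#' tr <- rollout(g, env_config(noise_sigma = 0, actions_enabled = FALSE))
#' identical(tr$type_maps[[26]], make_flag_pattern("czech")$types)
#' @export
rollout <- function(genome, env = env_config(), seed = NULL,
                    engine = c("cpp", "r"), keep_states = TRUE) {
  engine <- match.arg(engine)
  pd <- resolve_pd(genome, env)
  if (!is.null(seed))
    with_preserved_rng(seed, rollout_impl(genome, env, pd, engine,
                                          keep_states))
  else
    rollout_impl(genome, env, pd, engine, keep_states)
}

rollout_impl <- function(genome, env, pd, engine, keep_states = TRUE) {
  grid <- genome$grid
  arch <- genome$arch
  lc <- env$state_limits
  state0 <- pmin(pmax(genome$structural, lc[1]), lc[2])
  if (engine == "cpp") {
    res <- rollout_engine_cpp(
      state0, genome$functional,
      arch_code = if (arch$arch == "ff") 0L else 1L,
      s = arch$embed_dim, m = arch$memory_dim, r_copies = arch$redundancy,
      cycles = arch$cycles, nx = grid$nx, ny = grid$ny, ng = grid$ng,
      nc = grid$nc, steps = env$dev_steps, noise = env$noise_sigma, pd = pd,
      actions_enabled = env$actions_enabled, gate_memory = env$gate_memory,
      lc_lo = lc[1], lc_hi = lc[2],
      la_lo = env$action_limits[1], la_hi = env$action_limits[2],
      keep_states = keep_states)
    states <- res$states
    gates <- res$gates
    ny <- grid$ny; nx <- grid$nx
    type_maps <- lapply(seq_len(env$dev_steps + 1L), function(k)
      matrix(res$types[, k], ny, nx, byrow = TRUE))
  } else {
    res <- rollout_reference(state0, genome, env, pd)
    states <- res$states
    gates <- res$gates
    type_maps <- lapply(seq_len(env$dev_steps + 1L), function(k)
      cell_types(matrix(states[, , k], grid$n_cells, grid$nc), grid))
    if (!keep_states)
      states <- states[, , env$dev_steps + 1L, drop = FALSE]
  }
  structure(list(states = states, type_maps = type_maps, gate_mask = gates,
                 pd = pd, env = env, grid = grid),
            class = "nca_trajectory")
}

#' @export
print.nca_trajectory <- function(x, ...) {
  cat(sprintf("<nca_trajectory> %d+1 states on a %dx%d grid (pd %.3g, noise %.3g)\n",
              x$env$dev_steps, x$grid$nx, x$grid$ny, x$pd,
              x$env$noise_sigma))
  invisible(x)
}

# Naive per-cell, per-step reference implementation of the rollout,
# written as literal scalar loops (no BLAS, no vectorized algebra) so that
# it performs the same IEEE operation sequence as the compiled engine; it
# is the oracle the fast engine is checked against for exact equality.
rollout_reference <- function(state0, genome, env, pd) {
  grid <- genome$grid
  arch <- genome$arch
  nj <- grid$n_cells
  nc <- grid$nc
  s <- arch$embed_dim
  m <- arch$memory_dim
  r_n <- arch$redundancy
  net <- unpack_theta(genome$functional, arch, grid)
  lc <- env$state_limits
  la <- env$action_limits
  states <- array(0, c(nj, nc, env$dev_steps + 1L))
  gates <- matrix(FALSE, nj, env$dev_steps)
  states[, , 1L] <- state0
  mem <- matrix(0, nj, max(1L, r_n * m))
  state <- state0
  offs <- rbind(c(0L, 0L),
                c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, -1L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (k in seq_len(env$dev_steps)) {
    u <- stats::runif(nj)
    eps <- matrix(stats::rnorm(nj * nc), nj, nc)
    actions <- matrix(0, nj, nc)
    new_mem <- mem
    if (env$actions_enabled) {
      # shared sensor embeddings of every real cell
      emb <- matrix(0, nj, s)
      for (i in seq_len(nj)) for (e in seq_len(s)) {
        acc <- 0
        for (c in seq_len(nc)) acc <- acc + net$w_s[e, c] * state[i, c]
        emb[i, e] <- tanh(acc)
      }
      for (row in seq_len(grid$ny)) for (col in seq_len(grid$nx)) {
        i <- (row - 1L) * grid$nx + col
        # context: mean embedding over self + 8 Moore neighbors,
        # virtual zero-state boundary cells embedding to tanh(0) = 0
        ctx <- numeric(s)
        for (e in seq_len(s)) {
          acc <- 0
          for (q in seq_len(9L)) {
            r2 <- row + offs[q, 1L]; c2 <- col + offs[q, 2L]
            if (r2 >= 1L && r2 <= grid$ny && c2 >= 1L && c2 <= grid$nx)
              acc <- acc + emb[(r2 - 1L) * grid$nx + c2, e]
          }
          ctx[e] <- acc / 9
        }
        gate_i <- u[i] < pd
        gates[i, k] <- gate_i
        if (env$gate_memory && !gate_i && arch$arch == "rgrn") next
        act <- numeric(nc)
        for (r in seq_len(r_n)) {
          cp <- net$copies[[r]]
          if (arch$arch == "ff") {
            for (a in seq_len(nc)) {
              acc <- 0
              for (e in seq_len(s)) acc <- acc + cp$w_out[a, e] * ctx[e]
              act[a] <- act[a] + acc
            }
          } else {
            mem_r <- mem[i, (r - 1L) * m + seq_len(m)]
            for (cyc in seq_len(arch$cycles)) {
              mem_new <- numeric(m)
              for (q in seq_len(m)) {
                acc <- 0
                for (e in seq_len(s)) acc <- acc + cp$w_in[q, e] * ctx[e]
                for (p in seq_len(m)) acc <- acc + cp$w_rec[q, p] * mem_r[p]
                mem_new[q] <- tanh(acc)
              }
              mem_r <- mem_new
            }
            new_mem[i, (r - 1L) * m + seq_len(m)] <- mem_r
            for (a in seq_len(nc)) {
              acc <- cp$b[a]
              for (q in seq_len(m)) acc <- acc + cp$w_out[a, q] * mem_r[q]
              act[a] <- act[a] + acc
            }
          }
        }
        for (a in seq_len(nc))
          actions[i, a] <- min(max(act[a] / r_n, la[1]), la[2])
      }
    }
    new_state <- state
    for (c in seq_len(nc)) for (i in seq_len(nj)) {
      a <- if (gates[i, k]) actions[i, c] else 0
      v <- state[i, c] + a + env$noise_sigma * eps[i, c]
      new_state[i, c] <- min(max(v, lc[1]), lc[2])
    }
    state <- new_state
    mem <- new_mem
    states[, , k + 1L] <- state
  }
  list(states = states, gates = gates)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Per-step correctness of a trajectory
#'
#' @param trajectory An [rollout()] result.
#' @param target A [target_pattern()].
#' @return Integer vector of length `dev_steps + 1`: number of cells whose
#'   type matches the target at each retained state (t0 first).
#' @export
trajectory_correct_cells <- function(trajectory, target) {
  vapply(trajectory$type_maps,
         function(tm) sum(tm == target$types), integer(1))
}
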