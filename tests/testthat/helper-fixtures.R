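# shared fixtures for the suite; everything is built in code

solid_target <- function(type = 0L, nx = 2L, ny = 2L, ng = 3L, nh = 1L) {
  gs <- grid_spec(nx, ny, ng, nh)
  target_pattern(matrix(as.integer(type), ny, nx), gs,
                 name = paste0("solid", type))
}

random_genome <- function(arch = controller_spec("ff"), grid = grid_spec(),
                          sigma = 0.5, competency = FALSE) {
  init_genome(arch, grid, include_competency = competency,
              sigma_init = sigma)
}

# a trajectory stub carrying only what the fitness scorer consumes
fake_trajectory <- function(type_maps, grid) {
  structure(list(states = NULL, type_maps = type_maps, gate_mask = NULL,
                 pd = NA, env = list(dev_steps = length(type_maps) - 1L),
                 grid = grid),
            class = "nca_trajectory")
}

# independent recount of the fitness components, written element-wise
# (the oracle the vectorized scorer is checked against)
recount_fitness <- function(maps, target_types, rt, rs, nj) {
  td <- length(maps) - 1L
  ng <- 0L
  for (i in seq_along(target_types))
    if (maps[[td + 1L]][i] == target_types[i]) ng <- ng + 1L
  nt <- 0L
  for (k in 2:(td + 1L))
    if (!any(maps[[k]] != target_types)) nt <- nt + 1L
  ns <- 0L
  for (k in 1:td) {
    same <- !any(maps[[k]] != maps[[k + 1L]])
    wrong <- any(maps[[k]] != target_types)
    if (same && wrong) ns <- ns + 1L
  }
  list(ng = ng, nt = nt, ns = ns,
       score = (2 * ng - nj) + rt * nt - rs * ns)
}
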