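test_that("parameter counts match an independent enumeration of weight shapes", {
  # the two default architectures reproduce the printed counts
  expect_identical(param_count(controller_spec("ff"), grid_spec()), 192L)
  expect_identical(param_count(controller_spec("rgrn"), grid_spec()), 164L)
  expect_identical(param_count(controller_spec("ff", redundancy = 2),
                               grid_spec()), 288L)

  # brute-force oracle over random specs: enumerate every weight array
  set.seed(101)
  for (i in 1:10) {
    arch <- controller_spec(sample(c("ff", "rgrn"), 1),
                            embed_dim = sample(2:30, 1),
                            memory_dim = sample(1:8, 1),
                            redundancy = sample(1:16, 1))
    grid <- grid_spec(sample(1:6, 1), sample(1:6, 1),
                      ng = sample(2:4, 1), nh = sample(0:3, 1))
    nc <- grid$ng + grid$nh
    shapes <- list(c(arch$embed_dim, nc))  # shared sensor
    for (r in seq_len(arch$redundancy)) {
      shapes <- c(shapes, if (arch$arch == "ff") {
        list(c(nc, arch$embed_dim))
      } else {
        list(c(arch$memory_dim, arch$embed_dim),
             c(arch$memory_dim, arch$memory_dim),
             c(nc, arch$memory_dim), c(nc, 1))
      })
    }
    oracle <- sum(vapply(shapes, prod, numeric(1)))
    expect_identical(param_count(arch, grid), as.integer(oracle))
    # and the unpacked matrices jointly account for every entry
    net <- ncamorph:::unpack_theta(seq_len(oracle), arch, grid)
    n_unpacked <- length(net$w_s) +
      sum(vapply(net$copies, function(cp) sum(lengths(cp)), numeric(1)))
    expect_identical(as.integer(n_unpacked), as.integer(oracle))
  }
  # param_count is strictly increasing in the redundancy number
  pc <- vapply(1:16, function(r)
    param_count(controller_spec("rgrn", redundancy = r), grid_spec()),
    integer(1))
  expect_true(all(diff(pc) > 0))
})

test_that("genome flatten/unflatten round-trips exactly", {
  set.seed(7)
  for (comp in c(FALSE, TRUE)) {
    arch <- controller_spec("rgrn", redundancy = 3)
    grid <- grid_spec(3, 5, ng = 3, nh = 2)
    g <- init_genome(arch, grid, include_competency = comp)
    flat <- genome_flatten(g)
    expect_identical(length(flat), genome_length(arch, grid, comp))
    g2 <- genome_unflatten(flat, arch, grid, comp)
    expect_identical(g2$structural, g$structural)
    expect_identical(g2$functional, g$functional)
    expect_identical(g2$competency, g$competency)
    expect_identical(genome_flatten(g2), flat)
  }
  expect_identical(
    length(genome_flatten(init_genome(controller_spec("ff"), grid_spec(),
                                      include_competency = TRUE))),
    449L)  # 256 structural + 192 functional + 1 competency
})

test_that("random initialization is seed-reproducible", {
  arch <- controller_spec("ff")
  g1 <- withr::with_seed(3, init_genome(arch, grid_spec()))
  g2 <- withr::with_seed(3, init_genome(arch, grid_spec()))
  expect_identical(genome_flatten(g1), genome_flatten(g2))
  expect_null(g1$competency)
})

test_that("competency gene decodes through clipped tanh", {
  expect_equal(decode_competency(0), 0.5)
  expect_equal(decode_competency(3), (tanh(3) + 1) / 2)
  expect_equal(decode_competency(3), 0.997527376843365, tolerance = 1e-12)
  expect_identical(decode_competency(10), decode_competency(3))
  expect_identical(decode_competency(-50), decode_competency(-3))
  x <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(decode_competency(x)) >= 0))
  expect_equal(decode_competency(-x), 1 - decode_competency(x))
  expect_true(all(decode_competency(x) >= 0 & decode_competency(x) <= 1))
})

test_that("sensor aggregation is permutation invariant and matches a naive oracle", {
  set.seed(11)
  w_s <- matrix(rnorm(24 * 4), 24, 4)
  nb <- matrix(rnorm(9 * 4), 9, 4)
  ctx <- embed_and_aggregate(nb, w_s)
  expect_length(ctx, 24)
  # exact equality of the mean under input permutation
  for (i in 1:5)
    expect_identical(embed_and_aggregate(nb[sample(9), ], w_s), ctx)
  # naive per-element recomputation
  oracle <- numeric(24)
  for (e in 1:24) {
    tot <- 0
    for (q in 1:9) tot <- tot + tanh(sum(w_s[e, ] * nb[q, ]))
    oracle[e] <- tot / 9
  }
  expect_equal(ctx, oracle, tolerance = 1e-12)
  expect_identical(embed_and_aggregate(matrix(0, 9, 4), w_s), rep(0, 24))
  expect_error(embed_and_aggregate(nb[1:8, ], w_s), "9")
})

test_that("controller averages redundant copies and clips the mean action", {
  grid <- grid_spec()
  arch1 <- controller_spec("ff")
  net0 <- ncamorph:::unpack_theta(rep(0, param_count(arch1, grid)),
                                  arch1, grid)
  z <- controller_forward(rnorm(24), NULL, net0, arch1)
  expect_identical(z$action, rep(0, 4))

  # R = 2 with opposite copies cancels exactly
  arch2 <- controller_spec("ff", redundancy = 2)
  th <- rnorm(param_count(arch2, grid))
  th[97:192] <- th[193:288] <- rnorm(96)   # copy 1
  th[193:288] <- -th[97:192]               # copy 2 = -copy 1
  net2 <- ncamorph:::unpack_theta(th, arch2, grid)
  ctx <- rnorm(24)
  expect_equal(controller_forward(ctx, NULL, net2, arch2)$action, rep(0, 4))

  # clip of the averaged pre-clip output
  net1 <- net0
  target_out <- c(1.7, -0.2, 0.4, -3.0)
  ctxu <- rep(1, 24)
  net1$copies[[1]]$w_out <- outer(target_out / 24, rep(1, 24))
  out <- controller_forward(ctxu, NULL, net1, arch1)$action
  expect_equal(out, c(1.0, -0.2, 0.4, -1.0))

  # FF is linear in the context before clipping
  set.seed(12)
  netr <- ncamorph:::unpack_theta(rnorm(192, sd = 0.01), arch1, grid)
  base <- controller_forward(ctx, NULL, netr, arch1)$action
  for (alpha in c(0.25, 0.5, 0.75))
    expect_equal(controller_forward(alpha * ctx, NULL, netr, arch1)$action,
                 alpha * base, tolerance = 1e-12)
})

test_that("rgrn copies own independent memory slices", {
  grid <- grid_spec()
  arch <- controller_spec("rgrn", redundancy = 2)
  set.seed(13)
  net <- ncamorph:::unpack_theta(rnorm(param_count(arch, grid), sd = 0.5),
                                 arch, grid)
  ctx <- rnorm(16)
  res <- controller_forward(ctx, rep(0, 8), net, arch)
  expect_length(res$memory, 8)
  # perturbing copy 2's memory leaves copy 1's update untouched
  res2 <- controller_forward(ctx, c(rep(0, 4), rnorm(4)), net, arch)
  expect_identical(res$memory[1:4], res2$memory[1:4])
  expect_false(identical(res$memory[5:8], res2$memory[5:8]))
})

test_that("genome files round-trip exactly", {
  set.seed(21)
  for (arch in list(controller_spec("ff"),
                    controller_spec("rgrn", redundancy = 2, cycles = 2))) {
    g <- init_genome(arch, grid_spec(3, 4, ng = 2, nh = 1),
                     include_competency = TRUE, sigma_init = 2)
    f <- withr::local_tempfile(fileext = ".txt")
    save_genome(g, f)
    g2 <- load_genome(f)
    expect_identical(g2$structural, g$structural)
    expect_identical(g2$functional, g$functional)
    expect_identical(g2$competency, g$competency)
    expect_identical(g2$arch, g$arch)
    expect_identical(g2$grid, g$grid)
  }
  expect_error(load_genome(withr::local_tempfile(lines = "not a genome")),
               "genome file")
})
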