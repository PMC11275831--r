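#' Cell controller architecture specification
#'
#' Every cell of the automaton runs the same two-stage network. A shared
#' sensor stage maps each perceived cell state (its own plus the 8 Moore
#' neighbors, 9 states in total) through a bias-free linear layer followed by
#' `tanh` into an `s`-dimensional embedding; the 9 embeddings are averaged
#' into the cell's context vector, which makes perception invariant to any
#' permutation of the neighbors. A controller stage of `redundancy` (R)
#' independently parameterized copies then maps the context to a proposed
#' action of dimension `nc` (one additive update per state channel); the R
#' copy outputs are averaged and clipped to the action limits.
#'
#' Two controller architectures are supported:
#' * `"ff"` (feedforward): each copy is a single bias-free linear map
#'   `s -> nc`. With `s = 24`, `nc = 4`, R = 1 the functional genome has
#'   192 parameters.
#' * `"rgrn"` (recurrent, gene-regulatory-network inspired): each copy owns
#'   an `m`-dimensional internal memory, updated as
#'   `m' = tanh(W_in context + W_rec m)`, and emits
#'   `action = W_out m' + b`. The memory is private to the cell (neighbors
#'   cannot perceive it) and is zeroed at the start of every rollout. With
#'   `s = 16`, `m = 4`, `nc = 4`, R = 1 the functional genome has 164
#'   parameters.
#'
#' @param arch `"ff"` or `"rgrn"`.
#' @param embed_dim Sensor embedding size `s` (default 24 for FF, 16 for
#'   RGRN).
#' @param memory_dim Memory size `m` (RGRN only, default 4).
#' @param redundancy Number R >= 1 of redundant controller copies.
#' @param cycles Internal controller cycles per developmental step (the
#'   context is computed once; an RGRN iterates its memory `cycles` times).
#' @return An object of class `controller_spec`.
#' @examples
#' param_count(controller_spec("ff"), grid_spec())    # 192
#' param_count(controller_spec("rgrn"), grid_spec())  # 164
#' @export
controller_spec <- function(arch = c("ff", "rgrn"), embed_dim = NULL,
                            memory_dim = NULL, redundancy = 1L, cycles = 1L) {
  arch <- match.arg(arch)
  if (is.null(embed_dim)) embed_dim <- if (arch == "ff") 24L else 16L
  if (arch == "rgrn" && is.null(memory_dim)) memory_dim <- 4L
  if (arch == "ff") memory_dim <- 0L
  embed_dim <- as.integer(embed_dim)
  memory_dim <- as.integer(memory_dim)
  redundancy <- as.integer(redundancy)
  cycles <- as.integer(cycles)
  if (embed_dim < 1L) stop("embed_dim must be >= 1")
  if (arch == "rgrn" && memory_dim < 1L) stop("rgrn memory_dim must be >= 1")
  if (redundancy < 1L) stop("redundancy must be >= 1")
  if (cycles < 1L) stop("cycles must be >= 1")
  structure(list(arch = arch, embed_dim = embed_dim, memory_dim = memory_dim,
                 redundancy = redundancy, cycles = cycles),
            class = "controller_spec")
}

#' @export
print.controller_spec <- function(x, ...) {
  cat(sprintf("<controller_spec> %s: s=%d%s, R=%d, cycles=%d\n",
              toupper(x$arch), x$embed_dim,
              if (x$arch == "rgrn") sprintf(", m=%d", x$memory_dim) else "",
              x$redundancy, x$cycles))
  invisible(x)
}

#' Number of functional (controller) parameters
#'
#' Counts the trainable weights of the shared sensor stage plus the
#' `redundancy` controller copies. For FF: `nc*s + R*(s*nc)`. For RGRN:
#' `nc*s + R*(s*m + m*m + m*nc + nc)` (input, recurrent and output weights
#' plus the output bias of each copy).
#'
#' @param arch A [controller_spec()].
#' @param spec A [grid_spec()] (supplies the state dimension `nc`, which is
#'   both the sensor input and the action output size).
#' @return Integer parameter count.
#' @export
param_count <- function(arch, spec) {
  nc <- spec$nc
  s <- arch$embed_dim
  r <- arch$redundancy
  sensor <- nc * s
  per_copy <- switch(arch$arch,
    ff = s * nc,
    rgrn = {
      m <- arch$memory_dim
      s * m + m * m + m * nc + nc
    })
  as.integer(sensor + r * per_copy)
}

#' Decode the competency gene into a decision-making probability
#'
#' The competency gene is a single real; it is clipped to `[-3, 3]` and
#' mapped through `(tanh(x) + 1) / 2` to a probability in `[0, 1]`. The map
#' is symmetric, `pd(-x) = 1 - pd(x)`, so an L2 penalty on the gene favors
#' neither the minimal nor the maximal competency level.
#'
#' @param x_c Numeric vector of competency gene values.
#' @return Decision-making probabilities in `[0, 1]`.
#' @examples
#' decode_competency(0)    # 0.5
#' decode_competency(10)   # same as decode_competency(3)
#' @export
decode_competency <- function(x_c) {
  (tanh(pmin(pmax(x_c, -3), 3)) + 1) / 2
}

# Split a flat functional parameter vector into weight matrices.
# Layout (all matrices filled column-major, matching matrix()):
#   sensor W_s (s x nc), then per copy r = 1..R:
#     ff:   W_out_r (nc x s)
#     rgrn: W_in_r (m x s), W_rec_r (m x m), W_out_r (nc x m), b_r (nc)
unpack_theta <- function(theta, arch, spec) {
  nc <- spec$nc
  s <- arch$embed_dim
  np <- param_count(arch, spec)
  if (length(theta) != np)
    stop(sprintf("functional genome has length %d, expected %d",
                 length(theta), np))
  w_s <- matrix(theta[seq_len(s * nc)], s, nc)
  off <- s * nc
  copies <- vector("list", arch$redundancy)
  for (r in seq_len(arch$redundancy)) {
    if (arch$arch == "ff") {
      copies[[r]] <- list(w_out = matrix(theta[off + seq_len(nc * s)], nc, s))
      off <- off + nc * s
    } else {
      m <- arch$memory_dim
      w_in <- matrix(theta[off + seq_len(m * s)], m, s); off <- off + m * s
      w_rec <- matrix(theta[off + seq_len(m * m)], m, m); off <- off + m * m
      w_out <- matrix(theta[off + seq_len(nc * m)], nc, m); off <- off + nc * m
      b <- theta[off + seq_len(nc)]; off <- off + nc
      copies[[r]] <- list(w_in = w_in, w_rec = w_rec, w_out = w_out, b = b)
    }
  }
  list(w_s = w_s, copies = copies)
}

#' Sensor stage: embed a neighborhood and aggregate to a context vector
#'
#' Each of the 9 perceived cell states (self + 8 Moore neighbors; positions
#' off the grid contribute a fixed zero-state boundary cell) is passed
#' through the shared bias-free linear sensor followed by `tanh`, and the 9
#' embeddings are averaged. The arithmetic mean makes the result exactly
#' invariant to any permutation of the inputs.
#'
#' @param neighborhood A `9 x nc` matrix of cell states, one row per
#'   perceived cell (ordering is irrelevant).
#' @param w_s The `s x nc` sensor weight matrix.
#' @return Context vector of length `s`.
#' @export
embed_and_aggregate <- function(neighborhood, w_s) {
  neighborhood <- as.matrix(neighborhood)
  if (nrow(neighborhood) != 9L)
    stop("a Moore neighborhood perception has exactly 9 cell states")
  if (ncol(neighborhood) != ncol(w_s))
    stop("state dimension does not match the sensor weights")
  emb <- tanh(neighborhood %*% t(w_s))   # 9 x s
  colMeans(emb)
}

#' Controller stage: map a context vector to a clipped action
#'
#' Runs all `redundancy` controller copies on the same context, averages
#' their outputs and clips the mean elementwise to the action limits.
#' RGRN copies first update their private memory slice
#' (`m' = tanh(W_in context + W_rec m)`), repeated `cycles` times, and read
#' the action off the final memory.
#'
#' @param context Context vector (length `s`).
#' @param memory Numeric vector of length `R * m` (RGRN; copy `r` owns
#'   entries `((r-1)m + 1):(rm)`), or `NULL` for FF.
#' @param net Unpacked weights as produced by the genome compiler (fields
#'   `w_s`, `copies`).
#' @param arch A [controller_spec()].
#' @param action_limits Clip interval for the mean action.
#' @return `list(action = <length-nc vector>, memory = <updated memory>)`.
#' @export
controller_forward <- function(context, memory, net, arch,
                               action_limits = c(-1, 1)) {
  r_n <- arch$redundancy
  outs <- NULL
  if (arch$arch == "ff") {
    outs <- vapply(net$copies, function(cp) drop(cp$w_out %*% context),
                   numeric(nrow(net$copies[[1]]$w_out)))
    new_memory <- memory
  } else {
    m <- arch$memory_dim
    if (length(memory) != r_n * m)
      stop("memory vector has the wrong length")
    new_memory <- memory
    outs <- matrix(0, nrow(net$copies[[1]]$w_out), r_n)
    for (r in seq_len(r_n)) {
      idx <- (r - 1L) * m + seq_len(m)
      mem_r <- memory[idx]
      for (cyc in seq_len(arch$cycles)) {
        mem_r <- tanh(drop(net$copies[[r]]$w_in %*% context) +
                      drop(net$copies[[r]]$w_rec %*% mem_r))
      }
      outs[, r] <- drop(net$copies[[r]]$w_out %*% mem_r) + net$copies[[r]]$b
      new_memory[idx] <- mem_r
    }
  }
  outs <- matrix(outs, ncol = r_n)
  action <- rowMeans(outs)
  action <- pmin(pmax(action, action_limits[1]), action_limits[2])
  list(action = action, memory = new_memory)
}
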