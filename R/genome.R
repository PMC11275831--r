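#' Construct a genome
#'
#' A genome bundles everything an evolutionary search optimizes: the
#' structural part (the initial state of every cell, an `n_cells x nc`
#' matrix), the functional part (the flat controller weight vector, see
#' [controller_spec()]), and optionally a scalar competency gene that
#' decodes to the decision-making probability via [decode_competency()].
#'
#' @param structural `n_cells x nc` matrix of initial cell states (cell
#'   index runs row-major over the grid: cell `i = (row-1)*nx + col`, row 1
#'   at the top).
#' @param functional Numeric vector of controller parameters, length
#'   [param_count()].
#' @param arch A [controller_spec()].
#' @param grid A [grid_spec()].
#' @param competency Scalar competency gene, or `NULL` if absent.
#' @return An object of class `nca_genome`.
#' @export
genome <- function(structural, functional, arch, grid, competency = NULL) {
  structural <- as.matrix(structural)
  if (!all(dim(structural) == c(grid$n_cells, grid$nc)))
    stop(sprintf("structural part must be %d x %d", grid$n_cells, grid$nc))
  np <- param_count(arch, grid)
  if (length(functional) != np)
    stop(sprintf("functional part has length %d, expected %d",
                 length(functional), np))
  if (!is.null(competency) && length(competency) != 1L)
    stop("the competency gene is a single scalar")
  structure(list(structural = structural,
                 functional = as.numeric(functional),
                 competency = if (is.null(competency)) NULL
                              else as.numeric(competency),
                 arch = arch, grid = grid),
            class = "nca_genome")
}

#' @export
print.nca_genome <- function(x, ...) {
  cat(sprintf("<nca_genome> %d structural + %d functional%s genes (%s, R=%d, %dx%d grid)\n",
              length(x$structural), length(x$functional),
              if (is.null(x$competency)) "" else " + 1 competency",
              toupper(x$arch$arch), x$arch$redundancy, x$grid$nx, x$grid$ny))
  if (!is.null(x$competency))
    cat(sprintf("  competency gene %.4f -> pd = %.4f\n",
                x$competency, decode_competency(x$competency)))
  invisible(x)
}

#' Flatten a genome / rebuild a genome from a flat vector
#'
#' The flat layout is `[structural, functional, competency?]`, with the
#' structural matrix stored column-major (all cells' channel 1 first). This
#' is the search-space representation used by the evolution driver;
#' `genome_unflatten(genome_flatten(g), ...)` is the identity.
#'
#' @param g An [genome()].
#' @return `genome_flatten()`: numeric vector; `genome_unflatten()`: an
#'   `nca_genome`.
#' @export
genome_flatten <- function(g) {
  c(as.numeric(g$structural), g$functional,
    if (!is.null(g$competency)) g$competency)
}

#' @param flat Numeric vector as produced by `genome_flatten()`.
#' @param arch,grid Architecture and grid the vector belongs to.
#' @param has_competency Whether the final entry is a competency gene.
#' @rdname genome_flatten
#' @export
genome_unflatten <- function(flat, arch, grid, has_competency = FALSE) {
  ns <- grid$n_cells * grid$nc
  np <- param_count(arch, grid)
  want <- ns + np + as.integer(has_competency)
  if (length(flat) != want)
    stop(sprintf("flat genome has length %d, expected %d", length(flat), want))
  genome(structural = matrix(flat[seq_len(ns)], grid$n_cells, grid$nc),
         functional = flat[ns + seq_len(np)],
         arch = arch, grid = grid,
         competency = if (has_competency) flat[ns + np + 1L] else NULL)
}

#' Total number of genes of a genome layout
#'
#' @inheritParams genome_unflatten
#' @return Integer: `n_cells*nc + param_count + (1 if competency)`.
#' @export
genome_length <- function(arch, grid, has_competency = FALSE) {
  grid$n_cells * grid$nc + param_count(arch, grid) +
    as.integer(has_competency)
}

#' Random genome initialization
#'
#' All genes are drawn i.i.d. from `N(0, sigma_init^2)`; used as the
#' starting mean of an evolutionary search.
#'
#' @inheritParams genome_unflatten
#' @param include_competency Append a competency gene?
#' @param sigma_init Standard deviation of the initial genes.
#' @return An `nca_genome`. Reproducible under `set.seed()`.
#' @export
init_genome <- function(arch, grid, include_competency = FALSE,
                        sigma_init = 0.1) {
  n <- genome_length(arch, grid, include_competency)
  genome_unflatten(stats::rnorm(n, 0, sigma_init), arch, grid,
                   include_competency)
}

#' Saturated target-encoding genome
#'
#' An analytically known fixture: the structural part writes the target
#' pattern at maximal margin (the indicator of each cell's target type at
#' the upper state limit `+3`, all other indicators at `-3`, hidden channels
#' at 0), the functional part is all zeros (every proposed action is the
#' zero vector), and no competency gene is present. With actions disabled
#' and no developmental noise, a rollout reproduces the target type map at
#' every step and attains the analytic maximum fitness.
#'
#' @param pattern A [target_pattern()].
#' @param arch A [controller_spec()].
#' @param state_limit Saturation magnitude (the state clip limit).
#' @return An `nca_genome`.
#' @export
make_saturated_genome <- function(pattern, arch = controller_spec("ff"),
                                  state_limit = 3) {
  grid <- pattern$spec
  tv <- as.vector(t(pattern$types))          # cell-major (row-major grid order)
  structural <- matrix(0, grid$n_cells, grid$nc)
  structural[, seq_len(grid$ng)] <- -state_limit
  structural[cbind(seq_len(grid$n_cells), tv + 1L)] <- state_limit
  genome(structural, rep(0, param_count(arch, grid)), arch, grid)
}

#' Read and write genome files
#'
#' Genomes are stored as a self-describing plain-text container: `#`-style
#' metadata lines (format version, architecture, grid, competency flag)
#' followed by one section per genome segment whose numbers are written with
#' 17 significant digits, so a save/load round trip is exact.
#'
#' @param g An [genome()].
#' @param path File path.
#' @return `save_genome()` returns `path` invisibly; `load_genome()` the
#'   reconstructed `nca_genome`.
#' @export
save_genome <- function(g, path) {
  stopifnot(inherits(g, "nca_genome"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "# ncamorph-genome v1",
    sprintf("# arch: %s", g$arch$arch),
    sprintf("# embed_dim: %d", g$arch$embed_dim),
    sprintf("# memory_dim: %d", g$arch$memory_dim),
    sprintf("# redundancy: %d", g$arch$redundancy),
    sprintf("# cycles: %d", g$arch$cycles),
    sprintf("# grid: %d %d %d %d", g$grid$nx, g$grid$ny, g$grid$ng, g$grid$nh),
    "structural:",
    vapply(seq_len(nrow(g$structural)),
           function(i) num(g$structural[i, ]), character(1)),
    "functional:",
    num(g$functional))
  if (!is.null(g$competency))
    lines <- c(lines, "competency:", num(g$competency))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_genome
#' @export
load_genome <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  meta <- function(key, mode = "integer") {
    hit <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (length(hit) == 0L) stop("genome file missing header: ", key)
    val <- trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1]))
    if (mode == "character") val else as.integer(strsplit(val, "\\s+")[[1]])
  }
  if (!any(grepl("^#\\s*ncamorph-genome", lines)))
    stop("not an ncamorph genome file: ", path)
  arch <- controller_spec(meta("arch", "character"),
                          embed_dim = meta("embed_dim"),
                          memory_dim = max(meta("memory_dim"), 1L),
                          redundancy = meta("redundancy"),
                          cycles = meta("cycles"))
  gdim <- meta("grid")
  grid <- grid_spec(nx = gdim[1], ny = gdim[2], ng = gdim[3], nh = gdim[4])
  section <- function(name) {
    i <- match(paste0(name, ":"), lines)
    if (is.na(i)) return(NULL)
    j <- i + 1L
    out <- numeric(0)
    while (j <= length(lines) && !grepl(":$", lines[j]) &&
           !startsWith(lines[j], "#")) {
      if (nzchar(lines[j]))
        out <- c(out, as.numeric(strsplit(lines[j], "\\s+")[[1]]))
      j <- j + 1L
    }
    out
  }
  structural <- matrix(section("structural"), grid$n_cells, grid$nc,
                       byrow = TRUE)
  genome(structural, section("functional"), arch, grid,
         competency = section("competency"))
}
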