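#' Grid specification for a neural cellular automaton
#'
#' Describes the geometry and state layout of the cell grid: `nx * ny` cells,
#' each carrying an `nc`-dimensional real state of which the first `ng`
#' entries are cell-type indicators and the remaining `nh = nc - ng` entries
#' are hidden channels usable for intercellular communication. Cells perceive
#' their 8-cell Moore neighborhood (plus themselves).
#'
#' @param nx,ny Grid width and height in cells.
#' @param ng Number of discrete cell types (indicator channels).
#' @param nh Number of hidden state channels.
#' @return An object of class `grid_spec` with fields `nx`, `ny`, `ng`, `nh`,
#'   `nc = ng + nh`, `n_cells = nx * ny` and `n_neighbors = 8`.
#' @examples
#' gs <- grid_spec()           # the 8x8, 3-type, 1-hidden default
#' gs$n_cells                  # 64
#' @export
grid_spec <- function(nx = 8L, ny = 8L, ng = 3L, nh = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  ng <- as.integer(ng); nh <- as.integer(nh)
  if (nx < 1L || ny < 1L) stop("grid dimensions must be >= 1")
  if (ng < 1L) stop("need at least one cell type")
  if (nh < 0L) stop("hidden channel count must be >= 0")
  if (ng + nh < 1L) stop("state dimension must be >= 1")
  structure(
    list(nx = nx, ny = ny, ng = ng, nh = nh, nc = ng + nh,
         n_cells = nx * ny, n_neighbors = 8L),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%d grid (%d cells), %d types + %d hidden = %d state channels\n",
              x$nx, x$ny, x$n_cells, x$ng, x$nh, x$nc))
  invisible(x)
}

#' Construct a target cell-type pattern
#'
#' A target pattern is an `ny x nx` integer matrix of type indices in
#' `0 .. ng-1`, row 1 being the top row and column 1 the left (hoist) column.
#'
#' @param types Integer matrix (`ny` rows, `nx` columns) of 0-based type
#'   indices.
#' @param spec A [grid_spec()].
#' @param name Optional label.
#' @return An object of class `target_pattern` with fields `types`, `spec`,
#'   `name`.
#' @export
target_pattern <- function(types, spec, name = "custom") {
  types <- as.matrix(types)
  storage.mode(types) <- "integer"
  if (nrow(types) != spec$ny || ncol(types) != spec$nx)
    stop(sprintf("pattern is %dx%d but grid is %dx%d (rows x cols)",
                 nrow(types), ncol(types), spec$ny, spec$nx))
  if (any(is.na(types)) || any(types < 0L) || any(types >= spec$ng))
    stop(sprintf("type indices must lie in [0, %d]", spec$ng - 1L))
  structure(list(types = types, spec = spec, name = name),
            class = "target_pattern")
}

#' @export
print.target_pattern <- function(x, ...) {
  cat(sprintf("<target_pattern> '%s' on a %dx%d grid, %d types\n",
              x$name, x$spec$nx, x$spec$ny, x$spec$ng))
  tab <- tabulate(as.vector(x$types) + 1L, nbins = x$spec$ng)
  cat("  cells per type:", paste(sprintf("%d:%d", seq_along(tab) - 1L, tab),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Built-in flag target patterns
#'
#' Generates the 8x8 flag patterns used throughout the morphogenesis
#' experiments. Type indices are 0 = blue, 1 = white, 2 = red. The
#' rasterizations are fixed conventions of this package (the patterns are
#' usually only shown as figure insets elsewhere); arbitrary rasters can be
#' supplied via [load_pattern()].
#'
#' * `czech`: a blue hoist triangle (cell blue when `col <= min(row, ny-1-row)`
#'   with 0-based indices), white above the horizontal midline, red below.
#' * `blue`, `white`, `red`: solid single-type flags.
#' * `viennese`: top half red, bottom half white.
#' * `blue_white_diag` / `blue_red_diag`: blue strictly below the main
#'   diagonal (`row > col`), white/red elsewhere.
#'
#' @param name One of `"czech"`, `"blue"`, `"white"`, `"red"`, `"viennese"`,
#'   `"blue_white_diag"`, `"blue_red_diag"`.
#' @param spec A [grid_spec()]; the built-ins require an 8x8 grid with 3
#'   types.
#' @return A [target_pattern()].
#' @examples
#' czech <- make_flag_pattern("czech")
#' table(czech$types)      # 16 blue, 24 white, 24 red
#' @export
make_flag_pattern <- function(name, spec = grid_spec()) {
  name <- match.arg(name, c("czech", "blue", "white", "red", "viennese",
                            "blue_white_diag", "blue_red_diag"))
  if (spec$nx != 8L || spec$ny != 8L || spec$ng != 3L)
    stop("built-in flags are defined on an 8x8 grid with 3 cell types")
  row0 <- matrix(rep(0:(spec$ny - 1L), spec$nx), spec$ny, spec$nx)
  col0 <- matrix(rep(0:(spec$nx - 1L), each = spec$ny), spec$ny, spec$nx)
  types <- switch(name,
    czech = ifelse(col0 <= pmin(row0, spec$ny - 1L - row0), 0L,
                   ifelse(row0 <= 3L, 1L, 2L)),
    blue = matrix(0L, spec$ny, spec$nx),
    white = matrix(1L, spec$ny, spec$nx),
    red = matrix(2L, spec$ny, spec$nx),
    viennese = ifelse(row0 <= 3L, 2L, 1L),
    blue_white_diag = ifelse(row0 > col0, 0L, 1L),
    blue_red_diag = ifelse(row0 > col0, 0L, 2L)
  )
  target_pattern(types, spec, name = name)
}

#' Read and write pattern files
#'
#' The pattern file format is UTF-8 text: optional `#`-prefixed header lines
#' (`# name: <label>` and `# ng: <count>` are recognized), then one line per
#' grid row (top row first) of whitespace-separated integer type indices
#' (left column first). All rows must have the same length and every token
#' must lie in `[0, ng)`.
#'
#' @param path File path.
#' @param ng Number of cell types; defaults to the `# ng:` header if present,
#'   otherwise to `max(type) + 1`.
#' @param nh Hidden channels for the constructed [grid_spec()].
#' @return `load_pattern()` returns a [target_pattern()]; `save_pattern()`
#'   returns `path` invisibly. Saving then loading reproduces the pattern
#'   exactly.
#' @export
load_pattern <- function(path, ng = NULL, nh = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  headers <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) stop("pattern file has no grid rows: ", path)
  name <- "custom"
  for (h in headers) {
    m <- regmatches(h, regexec("^#\\s*name:\\s*(\\S+)", h))[[1]]
    if (length(m) == 2L) name <- m[2]
    m <- regmatches(h, regexec("^#\\s*ng:\\s*([0-9]+)", h))[[1]]
    if (length(m) == 2L && is.null(ng)) ng <- as.integer(m[2])
  }
  toks <- strsplit(body, "\\s+")
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L)
    stop("ragged pattern file: rows have differing lengths")
  vals <- suppressWarnings(lapply(toks, as.integer))
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1))))
    stop("pattern file contains non-integer tokens")
  types <- do.call(rbind, vals)
  if (is.null(ng)) ng <- max(types) + 1L
  spec <- grid_spec(nx = ncol(types), ny = nrow(types), ng = ng, nh = nh)
  target_pattern(types, spec, name = name)
}

#' @param pattern A [target_pattern()].
#' @rdname load_pattern
#' @export
save_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "target_pattern"))
  rows <- apply(pattern$types, 1L, paste, collapse = " ")
  writeLines(c(sprintf("# name: %s", pattern$name),
               sprintf("# ng: %d", pattern$spec$ng),
               rows), path)
  invisible(path)
}

#' Plot a cell-type pattern
#'
#' @param x A [target_pattern()] or an integer type-map matrix.
#' @param ... Passed to [graphics::image()].
#' @export
plot.target_pattern <- function(x, ...) {
  plot_type_map(x$types, ng = x$spec$ng, main = x$name, ...)
}

#' @param type_map `ny x nx` integer matrix of 0-based type indices.
#' @param ng Number of types (fixes the color scale).
#' @param ... Passed to [graphics::image()].
#' @rdname plot.target_pattern
#' @export
plot_type_map <- function(type_map, ng = max(type_map) + 1L, ...) {
  pal <- c("#11457e", "#ffffff", "#d7141a", "#888888", "#f2b705", "#3fa34d")
  pal <- rep_len(pal, max(ng, 1L))
  # image() draws column-major bottom-up; transpose and flip for row 1 = top
  z <- t(type_map[rev(seq_len(nrow(type_map))), , drop = FALSE])
  graphics::image(z, col = pal, zlim = c(0, ng - 1L), axes = FALSE, asp = 1, ...)
  invisible(NULL)
}
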