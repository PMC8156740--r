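#' Create a rectangular cell grid
#'
#' A cell grid is the basic state container of the simulator: an integer
#' matrix whose entries are 0 (healthy cell) or 1 (cancerous cell), one entry
#' per lattice site. The default study system is a 128 x 128 grid
#' (16384 sites).
#'
#' Grids must have at least two rows and two columns because the triangular
#' (d = 3) cluster decomposition needs a full unit square to exist.
#'
#' @param height number of rows (>= 2).
#' @param width number of columns (>= 2).
#' @param fill cell state used to fill the grid, 0 or 1.
#' @return A `cell_grid` object: an integer matrix with `height` rows and
#'   `width` columns, every entry equal to `fill`.
#' @examples
#' g <- make_grid(8, 8)
#' cancer_fraction(g)
#' @export
make_grid <- function(height, width, fill = 0L) {
  if (length(height) != 1L || length(width) != 1L ||
      !is.finite(height) || !is.finite(width) ||
      height != as.integer(height) || width != as.integer(width)) {
    stop("`height` and `width` must be single whole numbers", call. = FALSE)
  }
  if (height < 2 || width < 2) {
    stop("grid must be at least 2 x 2 (triangular clusters need a full unit square)",
         call. = FALSE)
  }
  fill <- as_cell_state(fill)
  g <- matrix(fill, nrow = as.integer(height), ncol = as.integer(width))
  class(g) <- c("cell_grid", class(g))
  g
}

as_cell_state <- function(x) {
  if (length(x) != 1L || !(x %in% c(0L, 1L))) {
    stop("cell states must be 0 (healthy) or 1 (cancer)", call. = FALSE)
  }
  as.integer(x)
}

#' Coerce a 0/1 matrix to a cell grid
#'
#' @param x matrix of 0/1 values.
#' @return A `cell_grid`.
#' @export
as_cell_grid <- function(x) {
  if (inherits(x, "cell_grid")) return(x)
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("grid must be at least 2 x 2", call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) {
    stop("cell states must be 0 (healthy) or 1 (cancer)", call. = FALSE)
  }
  g <- matrix(as.integer(x), nrow = nrow(x))
  class(g) <- c("cell_grid", class(g))
  g
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("cell_grid: %d x %d lattice, %d cancer site%s (fraction %.4g)\n",
              nrow(x), ncol(x), sum(x), if (sum(x) == 1) "" else "s",
              cancer_fraction(x)))
  invisible(x)
}

#' Fraction of cancerous sites
#'
#' @param grid a `cell_grid`.
#' @return Proportion of sites in state 1, in `[0, 1]`.
#' @export
cancer_fraction <- function(grid) {
  sum(grid == 1L) / length(grid)
}

#' Number of cancerous sites
#'
#' @param grid a `cell_grid`.
#' @return Integer count of sites in state 1.
#' @export
cancer_count <- function(grid) {
  sum(grid == 1L)
}

#' Orthogonal neighbours of a lattice site
#'
#' Returns the 2--4 in-bounds nearest neighbours of `site` on the square
#' lattice. Boundaries are open: there is no periodic wraparound, so corner
#' sites have 2 neighbours and edge sites 3.
#'
#' @param grid a `cell_grid`.
#' @param site integer vector `c(row, col)`, 1-based.
#' @return A matrix with one `(row, col)` neighbour per row.
#' @export
neighbors4 <- function(grid, site) {
  i <- site[1L]; j <- site[2L]
  if (i < 1 || i > nrow(grid) || j < 1 || j > ncol(grid)) {
    stop("site out of bounds", call. = FALSE)
  }
  nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
  nb[nb[, 1L] >= 1L & nb[, 1L] <= nrow(grid) &
     nb[, 2L] >= 1L & nb[, 2L] <= ncol(grid), , drop = FALSE]
}

#' Seed cancerous cells into a grid
#'
#' Supported seeding patterns:
#' \describe{
#'   \item{`single_center`}{one cancer cell at `(floor(H/2) + 1, floor(W/2) + 1)`.}
#'   \item{`block`}{a solid rectangular primary site given by `origin` (top-left
#'     row/col) and `extent` (rows/cols); models the primary tumour site in the
#'     metastasis scenario.}
#'   \item{`blob`}{a 4-connected cluster of exactly `count` cells grown from the
#'     grid centre by breadth-first accretion, ring by ring, row-major within
#'     each ring. Deterministic, so a given `count` always yields the same
#'     cluster. The apoptosis scenarios use blobs of 41 and 172 cells.}
#' }
#'
#' @param grid a `cell_grid` to seed (typically all healthy).
#' @param pattern one of `"single_center"`, `"block"`, `"blob"`.
#' @param count target cancer-site count (blob pattern only).
#' @param origin `c(row, col)` of the block's top-left corner (block only).
#' @param extent `c(rows, cols)` of the block (block only).
#' @return The seeded `cell_grid`.
#' @examples
#' g <- seed_grid(make_grid(16, 16), "blob", count = 10)
#' cancer_count(g)
#' @export
seed_grid <- function(grid, pattern = c("single_center", "block", "blob"),
                      count = NULL, origin = NULL, extent = NULL) {
  pattern <- match.arg(pattern)
  H <- nrow(grid); W <- ncol(grid)
  center <- c(H %/% 2L + 1L, W %/% 2L + 1L)
  if (pattern == "single_center") {
    grid[center[1L], center[2L]] <- 1L
    return(grid)
  }
  if (pattern == "block") {
    if (is.null(origin) || is.null(extent)) {
      stop("block pattern needs `origin` and `extent`", call. = FALSE)
    }
    r2 <- origin[1L] + extent[1L] - 1L
    c2 <- origin[2L] + extent[2L] - 1L
    if (origin[1L] < 1 || origin[2L] < 1 || r2 > H || c2 > W) {
      stop("block does not fit inside the grid", call. = FALSE)
    }
    grid[origin[1L]:r2, origin[2L]:c2] <- 1L
    return(grid)
  }
  ## blob: breadth-first accretion from the centre until exactly `count`
  ## sites are cancerous; ring order, row-major within each ring.
  if (is.null(count) || count < 1) {
    stop("blob pattern needs a positive `count`", call. = FALSE)
  }
  if (count > H * W) {
    stop("`count` exceeds the number of lattice sites", call. = FALSE)
  }
  member <- matrix(FALSE, H, W)
  member[center[1L], center[2L]] <- TRUE
  n <- 1L
  while (n < count) {
    ## ring = healthy sites 4-adjacent to the current cluster
    ring <- frontier_sites(member)
    take <- min(nrow(ring), count - n)
    for (k in seq_len(take)) member[ring[k, 1L], ring[k, 2L]] <- TRUE
    n <- n + take
  }
  grid[member] <- 1L
  grid
}

## Healthy sites 4-adjacent to the TRUE cluster, in row-major order.
frontier_sites <- function(member) {
  H <- nrow(member); W <- ncol(member)
  adj <- matrix(FALSE, H, W)
  adj[-H, ] <- adj[-H, ] | member[-1L, ]
  adj[-1L, ] <- adj[-1L, ] | member[-H, ]
  adj[, -W] <- adj[, -W] | member[, -1L]
  adj[, -1L] <- adj[, -1L] | member[, -W]
  adj <- adj & !member
  idx <- which(adj)                       # column-major linear indices
  ring <- cbind(row = (idx - 1L) %% H + 1L, col = (idx - 1L) %/% H + 1L)
  ring[order(ring[, 1L], ring[, 2L]), , drop = FALSE]
}

#' Write / read a grid as a dense integer CSV
#'
#' One CSV row per lattice row, no header; a portable plain-text snapshot
#' format.
#'
#' @param grid a `cell_grid`.
#' @param file path to write to / read from.
#' @return `write_grid_csv` returns `file` invisibly; `read_grid_csv` returns a
#'   `cell_grid`.
#' @export
write_grid_csv <- function(grid, file) {
  utils::write.table(unclass(grid), file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(file) {
  m <- as.matrix(utils::read.table(file, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  as_cell_grid(m)
}
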