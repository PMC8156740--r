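## Configuration tables are indexed by the binary configuration of the
## region's sites taken in canonical (row-major offset) order, first site most
## significant: a pair table has entries for 00, 01, 10, 11 in that order, a
## triangle table 000 ... 111. Index = 1 + sum_k x_k * 2^(size - k).
config_labels <- function(size) {
  if (size > 16L) stop("configuration tables limited to 16 sites", call. = FALSE)
  vapply(0:(2^size - 1L), function(v) {
    paste(rev((v %/% 2^(0:(size - 1L))) %% 2L), collapse = "")
  }, "")
}

#' Cluster marginal tables
#'
#' Container for per-shape-class probability tables over binary cluster
#' configurations. Under the translation-homogeneity assumption of the
#' classical cluster-variation treatment there is one table per region shape
#' class (site, pair by orientation, triangle by orientation), not one per
#' region instance; free energies are then totals computed as per-shape
#' expectation times instance count.
#'
#' @param tables named list of probability vectors, one per shape class; each
#'   of length `2^size` for that class and summing to 1. Configurations are
#'   indexed with the first site of the canonical offset order as the most
#'   significant bit.
#' @param grid_shape integer `c(H, W)` of the lattice the tables refer to.
#' @param order_d approximation order the tables support: 1, 2, 3 or `"full"`.
#' @param counts optional named list of raw occurrence counts behind each
#'   table.
#' @return A `cluster_marginals` object.
#' @export
cluster_marginals <- function(tables, grid_shape, order_d, counts = NULL) {
  order_d <- validate_order(order_d)
  cls <- region_classes(grid_shape, order_d)
  n_inst <- class_instance_counts(grid_shape)
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    size <- round(log2(length(tbl)))
    if (2^size != length(tbl)) {
      stop("table `", nm, "` length is not a power of 2", call. = FALSE)
    }
    if (any(tbl < -1e-12) || abs(sum(tbl) - 1) > 1e-8) {
      stop("table `", nm, "` is not a probability table", call. = FALSE)
    }
  }
  missing <- setdiff(cls$class[cls$c_total != 0], names(tables))
  if (length(missing) > 0L) {
    stop("missing tables for shape classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(tables = tables, counts = counts,
                 grid_shape = as.integer(grid_shape), order_d = order_d,
                 n_instances = n_inst),
            class = "cluster_marginals")
}

## Translated instance counts of every shape class on an H x W lattice.
class_instance_counts <- function(grid_shape) {
  H <- grid_shape[1L]; W <- grid_shape[2L]
  c(site = H * W,
    pair_h = H * (W - 1L), pair_v = (H - 1L) * W,
    pair_ad = (H - 1L) * (W - 1L),
    tri_ul = (H - 1L) * (W - 1L), tri_lr = (H - 1L) * (W - 1L),
    full = 1L)
}

## Occurrence counts of each binary configuration of `class` across all of
## its translated instances in the grid. Vectorised via shifted submatrices.
class_config_counts <- function(g, class) {
  H <- nrow(g); W <- ncol(g)
  idx <- switch(class,
    site    = g,
    pair_h  = 2L * g[, -W, drop = FALSE] + g[, -1L, drop = FALSE],
    pair_v  = 2L * g[-H, , drop = FALSE] + g[-1L, , drop = FALSE],
    pair_ad = 2L * g[-H, -1L, drop = FALSE] + g[-1L, -W, drop = FALSE],
    tri_ul  = 4L * g[-H, -W, drop = FALSE] + 2L * g[-H, -1L, drop = FALSE] +
              g[-1L, -W, drop = FALSE],
    tri_lr  = 4L * g[-H, -1L, drop = FALSE] + 2L * g[-1L, -W, drop = FALSE] +
              g[-1L, -1L, drop = FALSE],
    full    = {
      N <- H * W
      if (N > 16L) {
        stop("full-lattice marginal requires at most 16 sites", call. = FALSE)
      }
      bits <- as.vector(t(unclass(g)))        # row-major site order
      sum(bits * 2^(N - seq_len(N)))
    },
    stop("unknown shape class: ", class, call. = FALSE))
  size <- switch(class, site = 1L, full = H * W, pair_h = , pair_v = ,
                 pair_ad = 2L, tri_ul = , tri_lr = 3L)
  cnt <- tabulate(as.vector(idx) + 1L, nbins = 2^size)
  names(cnt) <- config_labels(size)
  cnt
}

#' Empirical cluster marginals of a grid
#'
#' Estimates, for each region shape class of the given region graph, the
#' relative frequency of every binary configuration across all translated
#' instances of the shape in the grid. Horizontal and vertical pair tables are
#' always included (the interaction energy needs them) even at orders whose
#' entropy does not. Configurations never observed get probability 0; with
#' `pseudo_count > 0` an additive pseudo-count is applied before normalising.
#'
#' @param grid a `cell_grid`.
#' @param region_graph a `region_graph` for the grid's shape (or an order
#'   passed to [build_region_graph()]).
#' @param pseudo_count additive smoothing count per configuration (default 0).
#' @return A `cluster_marginals` object with both `tables` and raw `counts`.
#' @examples
#' g <- seed_grid(make_grid(8, 8), "blob", count = 5)
#' m <- empirical_marginals(g, build_region_graph(dim(g), 3, explicit = FALSE))
#' m$tables$pair_h
#' @export
empirical_marginals <- function(grid, region_graph, pseudo_count = 0) {
  if (!inherits(region_graph, "region_graph")) {
    region_graph <- build_region_graph(dim(grid), region_graph, explicit = FALSE)
  }
  if (!all(dim(grid) == region_graph$grid_shape)) {
    stop("region graph was built for a different grid shape", call. = FALSE)
  }
  g <- unclass(grid)
  wanted <- union(region_graph$classes$class, c("site", "pair_h", "pair_v"))
  counts <- lapply(stats::setNames(wanted, wanted),
                   function(cl) class_config_counts(g, cl))
  tables <- lapply(counts, function(cnt) {
    cnt <- cnt + pseudo_count
    cnt / sum(cnt)
  })
  cluster_marginals(tables, dim(grid), region_graph$order_d, counts = counts)
}

#' Shared mean-field site marginal of a grid
#'
#' The mean-field family assumes fully factorised, translation-homogeneous
#' site marginals, so a single shared table suffices:
#' `Q(1) = cancer_fraction(grid)`.
#'
#' @param grid a `cell_grid`.
#' @return Named numeric vector `c("0" = 1 - p, "1" = p)`.
#' @export
meanfield_marginal <- function(grid) {
  p <- cancer_fraction(grid)
  c("0" = 1 - p, "1" = p)
}

#' Product-form (independent-site) cluster marginals
#'
#' Builds the idealised marginals of an independent-site distribution with
#' cancer probability `p`: each cluster table is the product of site factors.
#' Useful for checking the exact-counting condition (at any order the
#' cluster-variation entropy of a product distribution equals the total site
#' entropy).
#'
#' @param p cancer probability in `[0, 1]`.
#' @param grid_shape integer `c(H, W)`.
#' @param order_d approximation order.
#' @return A `cluster_marginals` object.
#' @export
product_marginals <- function(p, grid_shape, order_d) {
  order_d <- validate_order(order_d)
  cls <- region_classes(grid_shape, order_d)
  wanted <- union(cls$class, c("site", "pair_h", "pair_v"))
  if ("full" %in% wanted && prod(grid_shape) > 16L) {
    stop("full-lattice product table requires at most 16 sites", call. = FALSE)
  }
  tables <- lapply(stats::setNames(wanted, wanted), function(cl) {
    size <- if (cl == "full") prod(grid_shape) else nrow(region_shape_offsets(cl))
    cfg <- 0:(2^size - 1L)
    ones <- vapply(cfg, function(v) sum((v %/% 2^(0:(size - 1L))) %% 2L), 0)
    tbl <- p^ones * (1 - p)^(size - ones)
    names(tbl) <- config_labels(size)
    tbl
  })
  cluster_marginals(tables, grid_shape, order_d)
}

#' Marginalise a configuration table over one site
#'
#' Sums a cluster configuration table over the site at position `drop` of the
#' canonical site order, returning the table over the remaining sites. Used to
#' check consistency between triangle and pair marginals.
#'
#' @param table probability (or count) vector of length `2^k`.
#' @param drop 1-based position of the site to sum out (1 = most significant).
#' @return A vector of length `2^(k-1)`.
#' @export
marginalize_config_table <- function(table, drop) {
  size <- round(log2(length(table)))
  if (2^size != length(table)) stop("table length is not a power of 2", call. = FALSE)
  if (drop < 1 || drop > size) stop("`drop` out of range", call. = FALSE)
  cfg <- 0:(2^size - 1)
  bits <- vapply(cfg, function(v) (v %/% 2^(size - seq_len(size))) %% 2,
                 numeric(size))
  keep <- matrix(bits[-drop, , drop = FALSE], nrow = size - 1L)
  out_idx <- colSums(keep * 2^((size - 2L):0)) + 1L
  out <- numeric(2^(size - 1L))
  for (k in seq_along(cfg)) out[out_idx[k]] <- out[out_idx[k]] + table[k]
  names(out) <- config_labels(size - 1L)
  out
}

#' @export
print.cluster_marginals <- function(x, ...) {
  cat(sprintf("cluster_marginals: %d x %d lattice, order d = %s\n",
              x$grid_shape[1L], x$grid_shape[2L], as.character(x$order_d)))
  for (nm in names(x$tables)) {
    cat(" ", nm, ": ", paste(sprintf("%s=%.4g", names(x$tables[[nm]]),
                                     x$tables[[nm]]), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Export marginal tables as JSON
#'
#' @param marginals a `cluster_marginals` object.
#' @param file path of the JSON file to write.
#' @return `file`, invisibly.
#' @export
write_marginals_json <- function(marginals, file) {
  jsonlite::write_json(
    list(grid_shape = marginals$grid_shape,
         order_d = as.character(marginals$order_d),
         tables = lapply(marginals$tables, as.list)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
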