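## Region shapes used by the cluster-variation decompositions. Each shape is
## a set of (row, col) offsets from the anchor (top-left of the bounding box):
##   site     single site
##   pair_h   horizontal nearest-neighbour pair
##   pair_v   vertical nearest-neighbour pair
##   pair_ad  anti-diagonal pair (the hypotenuse shared by the two triangles
##            of a unit square; not a nearest-neighbour pair)
##   tri_ul   upper-left right triangle  {(0,0),(0,1),(1,0)}
##   tri_lr   lower-right right triangle {(0,1),(1,0),(1,1)}
##   full     the whole lattice (exact limit)
region_shape_offsets <- function(class) {
  switch(class,
    site    = cbind(0L, 0L),
    pair_h  = cbind(c(0L, 0L), c(0L, 1L)),
    pair_v  = cbind(c(0L, 1L), c(0L, 0L)),
    pair_ad = cbind(c(0L, 1L), c(1L, 0L)),
    tri_ul  = cbind(c(0L, 0L, 1L), c(0L, 1L, 0L)),
    tri_lr  = cbind(c(0L, 1L, 1L), c(1L, 0L, 1L)),
    stop("unknown region shape class: ", class, call. = FALSE)
  )
}

#' Per-shape-class summary of a region graph
#'
#' Under translation homogeneity the cluster-variation free energy only needs,
#' for each region shape class, the number of translated instances of the
#' shape on the lattice and the total Moebius counting number summed over the
#' instances that are regions. Both have closed forms on an open-boundary
#' `H x W` lattice; [build_region_graph()] verifies them against the explicit
#' Moebius enumeration on small grids.
#'
#' Counting-number totals by order:
#' \describe{
#'   \item{d = 1 (mean field)}{every site a region with `c = 1`.}
#'   \item{d = 2 (Bethe)}{every nearest-neighbour pair has `c = 1`; each site
#'     has `c = 1 - degree`, so the site total is `N - 2 * n_pairs`.}
#'   \item{d = 3 (B3 triangles)}{each unit square carries two triangles
#'     (`c = 1`); the shared anti-diagonal pair has `c = -1`; interior
#'     horizontal/vertical pairs shared by two adjacent triangles have
#'     `c = -1` (boundary-row horizontal and boundary-column vertical pairs
#'     belong to a single triangle and are not regions); interior sites have
#'     `c = 1`, boundary sites `c = 0`.}
#'   \item{full}{a single region containing all sites, `c = 1`.}
#' }
#' Every order satisfies the exact-counting condition: for each lattice site
#' the counting numbers of the regions containing it sum to 1.
#'
#' @param grid_shape integer `c(H, W)`, both >= 2.
#' @param order_d cluster size: 1, 2, 3 or `"full"`.
#' @return A data frame with columns `class`, `size` (sites per region),
#'   `n_instances` (translated instances of the shape) and `c_total` (summed
#'   counting numbers of the region instances).
#' @export
region_classes <- function(grid_shape, order_d) {
  H <- as.integer(grid_shape[1L]); W <- as.integer(grid_shape[2L])
  if (H < 2 || W < 2) stop("grid must be at least 2 x 2", call. = FALSE)
  N <- H * W
  order_d <- validate_order(order_d)
  if (identical(order_d, "full")) {
    return(data.frame(class = "full", size = N, n_instances = 1L,
                      c_total = 1L, stringsAsFactors = FALSE))
  }
  nh <- H * (W - 1L); nv <- (H - 1L) * W; nsq <- (H - 1L) * (W - 1L)
  if (order_d == 1L) {
    df <- data.frame(class = "site", size = 1L, n_instances = N, c_total = N)
  } else if (order_d == 2L) {
    df <- data.frame(
      class = c("pair_h", "pair_v", "site"),
      size = c(2L, 2L, 1L),
      n_instances = c(nh, nv, N),
      c_total = c(nh, nv, N - 2L * (nh + nv)))
  } else {
    df <- data.frame(
      class = c("tri_ul", "tri_lr", "pair_ad", "pair_h", "pair_v", "site"),
      size = c(3L, 3L, 2L, 2L, 2L, 1L),
      n_instances = c(nsq, nsq, nsq, nh, nv, N),
      c_total = c(nsq, nsq, -nsq,
                  -(H - 2L) * (W - 1L), -(H - 1L) * (W - 2L),
                  (H - 2L) * (W - 2L)))
  }
  df$class <- as.character(df$class)
  df
}

validate_order <- function(order_d) {
  if (identical(order_d, "full")) return("full")
  if (length(order_d) == 1L && order_d %in% c(1, 2, 3)) return(as.integer(order_d))
  stop("`order_d` must be 1, 2, 3 or \"full\"", call. = FALSE)
}

#' Build the region graph for a lattice
#'
#' Constructs the base clusters for the requested approximation order, closes
#' the set under pairwise intersection (intersections, intersections of
#' intersections, ...), and computes the Moebius overcounting number of every
#' region: `c_r = 1 - sum over strict super-regions s of c_s`, evaluated from
#' the largest regions downward. Base clusters by order:
#'
#' * `order_d = 1`: single sites (mean-field limit);
#' * `order_d = 2`: all horizontal and vertical nearest-neighbour pairs
#'   (Bethe approximation);
#' * `order_d = 3`: the two right triangles tiling each unit square — for the
#'   square with corners `(i,j)` and `(i+1,j+1)`, triangles
#'   `{(i,j),(i,j+1),(i+1,j)}` and `{(i,j+1),(i+1,j),(i+1,j+1)}` (the B3
#'   cluster of the Kikuchi--Brush hierarchy);
#' * `order_d = "full"`: a single region containing all sites (exact limit).
#'
#' Boundaries are open: only fully in-bounds clusters are regions, and the
#' exact-counting condition (counting numbers of the regions containing any
#' site sum to 1) is restored automatically by the Moebius recursion because
#' boundary sites simply have fewer super-regions.
#'
#' Sites are identified by row-major linear id `(i - 1) * W + j`, so ids match
#' a row-by-row numbering of the lattice. Regions are canonicalised as sorted
#' id vectors.
#'
#' The explicit enumeration is meant for small lattices (worked examples,
#' debugging, tests); set `explicit = FALSE` to get only the closed-form class
#' summary, which is all the evaluators need.
#'
#' @param grid_shape integer `c(H, W)`, both >= 2.
#' @param order_d cluster size: 1, 2, 3 or `"full"`.
#' @param explicit enumerate regions explicitly? Defaults to `TRUE` for
#'   lattices of at most 400 sites.
#' @return A `region_graph` object with elements `grid_shape`, `order_d`,
#'   `classes` (see [region_classes()]), and when explicit: `regions` (list of
#'   sorted site-id vectors), `level` (`"base"` or `"intersection"`),
#'   `counting` (integer `c_r` per region) and `region_class` (shape class per
#'   region).
#' @examples
#' rg <- build_region_graph(c(2, 3), 3)
#' table(rg$level)
#' counting_numbers(rg)
#' @export
build_region_graph <- function(grid_shape, order_d,
                               explicit = prod(grid_shape) <= 400) {
  H <- as.integer(grid_shape[1L]); W <- as.integer(grid_shape[2L])
  if (H < 2 || W < 2) stop("grid must be at least 2 x 2", call. = FALSE)
  order_d <- validate_order(order_d)
  rg <- list(grid_shape = c(H, W), order_d = order_d,
             classes = region_classes(c(H, W), order_d))
  class(rg) <- "region_graph"
  if (!explicit) return(rg)

  base <- base_regions(H, W, order_d)
  regions <- close_under_intersection(base)
  level <- c(rep("base", length(base)),
             rep("intersection", length(regions) - length(base)))
  counting <- mobius_counting(regions)
  rg$regions <- regions
  rg$level <- level
  rg$counting <- counting
  rg$region_class <- vapply(regions, classify_region, "", W = W, N = H * W)
  rg
}

base_regions <- function(H, W, order_d) {
  id <- function(i, j) (i - 1L) * W + j
  if (identical(order_d, "full")) return(list(seq_len(H * W)))
  if (order_d == 1L) {
    return(lapply(seq_len(H * W), identity))
  }
  regions <- list()
  if (order_d == 2L) {
    for (i in seq_len(H)) for (j in seq_len(W - 1L)) {
      regions[[length(regions) + 1L]] <- c(id(i, j), id(i, j + 1L))
    }
    for (i in seq_len(H - 1L)) for (j in seq_len(W)) {
      regions[[length(regions) + 1L]] <- c(id(i, j), id(i + 1L, j))
    }
  } else {
    for (i in seq_len(H - 1L)) for (j in seq_len(W - 1L)) {
      regions[[length(regions) + 1L]] <-
        sort(c(id(i, j), id(i, j + 1L), id(i + 1L, j)))
      regions[[length(regions) + 1L]] <-
        sort(c(id(i, j + 1L), id(i + 1L, j), id(i + 1L, j + 1L)))
    }
  }
  regions
}

## Close a list of sorted integer vectors under pairwise intersection.
close_under_intersection <- function(base) {
  seen <- new.env(parent = emptyenv())
  keyof <- function(r) paste(r, collapse = ",")
  out <- list()
  add <- function(r) {
    k <- keyof(r)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      out[[length(out) + 1L]] <<- r
      TRUE
    } else FALSE
  }
  for (r in base) add(r)
  frontier <- out
  repeat {
    new_regions <- list()
    for (f in frontier) {
      for (r in out) {
        s <- intersect(f, r)
        if (length(s) > 0L && length(s) < length(f) && keyof(s) != keyof(r)) {
          if (add(s)) new_regions[[length(new_regions) + 1L]] <- s
        }
      }
    }
    if (length(new_regions) == 0L) break
    frontier <- new_regions
  }
  out
}

## Moebius recursion over ALL strict super-regions, largest regions first.
mobius_counting <- function(regions) {
  n <- length(regions)
  sizes <- lengths(regions)
  ord <- order(sizes, decreasing = TRUE)
  counting <- integer(n)
  for (k in seq_along(ord)) {
    idx <- ord[k]
    r <- regions[[idx]]
    csum <- 0L
    if (k > 1L) {
      for (m in seq_len(k - 1L)) {
        s <- regions[[ord[m]]]
        if (length(s) > length(r) && all(r %in% s)) csum <- csum + counting[ord[m]]
      }
    }
    counting[idx] <- 1L - csum
  }
  counting
}

classify_region <- function(sites, W, N) {
  if (length(sites) == N && N > 3L) return("full")
  i <- (sites - 1L) %/% W; j <- (sites - 1L) %% W
  off <- cbind(i - min(i), j - min(j))
  for (cl in c("site", "pair_h", "pair_v", "pair_ad", "tri_ul", "tri_lr")) {
    tmpl <- region_shape_offsets(cl)
    if (nrow(off) == nrow(tmpl) && all(off == tmpl)) return(cl)
  }
  if (length(sites) == N) return("full")
  "other"
}

#' Moebius counting numbers of a region graph
#'
#' @param region_graph an explicit `region_graph` from [build_region_graph()].
#' @return Named integer vector: one counting number per region, named by the
#'   comma-separated sorted site ids of the region.
#' @export
counting_numbers <- function(region_graph) {
  if (is.null(region_graph$regions)) {
    stop("region graph was built without explicit regions; ",
         "rebuild with `explicit = TRUE`", call. = FALSE)
  }
  stats::setNames(region_graph$counting,
                  vapply(region_graph$regions, paste, "", collapse = ","))
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("region_graph: %d x %d lattice, order d = %s\n",
              x$grid_shape[1L], x$grid_shape[2L], as.character(x$order_d)))
  print(x$classes, row.names = FALSE)
  if (!is.null(x$regions)) {
    cat(sprintf("explicit regions: %d (%d base, %d intersection)\n",
                length(x$regions), sum(x$level == "base"),
                sum(x$level == "intersection")))
  }
  invisible(x)
}

#' Export an explicit region graph as JSON
#'
#' Dumps one record per region (site ids, level, shape class, counting number)
#' for debugging and fixtures.
#'
#' @param region_graph an explicit `region_graph`.
#' @param file path of the JSON file to write.
#' @return `file`, invisibly.
#' @export
write_region_graph_json <- function(region_graph, file) {
  if (is.null(region_graph$regions)) {
    stop("region graph was built without explicit regions", call. = FALSE)
  }
  recs <- lapply(seq_along(region_graph$regions), function(k) {
    list(sites = region_graph$regions[[k]],
         level = region_graph$level[k],
         class = region_graph$region_class[k],
         counting = region_graph$counting[k])
  })
  jsonlite::write_json(
    list(grid_shape = region_graph$grid_shape,
         order_d = as.character(region_graph$order_d),
         regions = recs),
    file, auto_unbox = TRUE)
  invisible(file)
}
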