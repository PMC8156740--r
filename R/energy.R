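#' Pairwise interaction-energy convention
#'
#' The lattice Hamiltonian is a sum of nearest-neighbour pair energies with
#' zero activation energy. The default convention assigns energy `-eps_in` to
#' a cancer--cancer contact and 0 to every other contact: a positive
#' interaction parameter lowers the energy (and hence the free energy) when
#' cancerous cells sit next to each other, a negative one penalises
#' cancer--cancer contacts so healthy/mixed contacts are favoured.
#'
#' @param eps_in interaction parameter (natural units per pair).
#' @param u optional length-4 vector `c(u00, u01, u10, u11)` overriding the
#'   default `c(0, 0, 0, -eps_in)`.
#' @return A `pair_energy` object.
#' @export
pair_energy <- function(eps_in, u = c(0, 0, 0, -eps_in)) {
  stopifnot(length(u) == 4L, is.finite(eps_in))
  structure(list(eps_in = eps_in,
                 u = stats::setNames(u, c("00", "01", "10", "11"))),
            class = "pair_energy")
}

#' Direct lattice Hamiltonian of a configuration
#'
#' Sums the pair energy over every horizontal and vertical nearest-neighbour
#' pair of the grid (open boundaries). With the default convention this is
#' `-eps_in` times the number of cancer--cancer contacts.
#'
#' @param grid a `cell_grid` (or 0/1 matrix).
#' @param convention a `pair_energy` object, or a numeric `eps_in`.
#' @return Energy scalar in natural units.
#' @export
lattice_hamiltonian <- function(grid, convention) {
  if (!inherits(convention, "pair_energy")) convention <- pair_energy(convention)
  g <- unclass(as_cell_grid(grid))
  H <- nrow(g); W <- ncol(g)
  idx_h <- 2L * g[, -W, drop = FALSE] + g[, -1L, drop = FALSE] + 1L
  idx_v <- 2L * g[-H, , drop = FALSE] + g[-1L, , drop = FALSE] + 1L
  sum(convention$u[idx_h]) + sum(convention$u[idx_v])
}

#' Interaction energy from pair marginals
#'
#' Total internal energy `U` of the lattice: the expected pair energy under
#' the horizontal and vertical pair tables times the number of pair instances
#' of each orientation. When the marginals are empirical this equals the
#' direct lattice sum [lattice_hamiltonian()] exactly, because the empirical
#' table is the instance-average of the indicator of each configuration.
#'
#' @param marginals a `cluster_marginals` containing `pair_h` and `pair_v`
#'   tables.
#' @param convention a `pair_energy` object, or a numeric `eps_in`.
#' @return Energy scalar (lattice total, natural units).
#' @export
interaction_energy <- function(marginals, convention) {
  if (!inherits(convention, "pair_energy")) convention <- pair_energy(convention)
  tb <- marginals$tables
  if (is.null(tb$pair_h) || is.null(tb$pair_v)) {
    stop("marginals lack nearest-neighbour pair tables", call. = FALSE)
  }
  n <- marginals$n_instances
  n[["pair_h"]] * sum(convention$u * tb$pair_h) +
    n[["pair_v"]] * sum(convention$u * tb$pair_v)
}

## Shannon entropy of a probability table in nats, with 0 log 0 = 0.
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Cluster-variation entropy
#'
#' The region-based entropy `S = sum_r c_r S_r`, where `S_r` is the Shannon
#' entropy of region r's configuration table and `c_r` its Moebius counting
#' number. Under translation homogeneity this aggregates per shape class:
#' `S = sum_class c_total(class) * S(class table)`. With pair clusters
#' (d = 2) this is the Bethe entropy — pair entropies summed, overcounted site
#' entropies subtracted; with d = 3 it is the triangle-based entropy whose
#' worked 2 x 3 example subtracts the three doubly-counted pairs.
#'
#' For a product (independent-site) distribution the exact-counting condition
#' `sum over regions containing i of c_r = 1` makes the result equal the total
#' site entropy at every order; for `order_d = "full"` the entropy of the full
#' configuration table is returned (the exact limit).
#'
#' @param marginals a `cluster_marginals` of the same order as `region_graph`.
#' @param region_graph a `region_graph` (explicit regions not required).
#' @return Entropy scalar in nats (lattice total).
#' @export
entropy_cvm <- function(marginals, region_graph) {
  if (!identical(marginals$order_d, region_graph$order_d)) {
    stop("marginals (order ", marginals$order_d, ") and region graph (order ",
         region_graph$order_d, ") disagree", call. = FALSE)
  }
  if (!all(marginals$grid_shape == region_graph$grid_shape)) {
    stop("marginals and region graph were built for different grid shapes",
         call. = FALSE)
  }
  cls <- region_graph$classes
  total <- 0
  for (k in seq_len(nrow(cls))) {
    if (cls$c_total[k] == 0) next
    tbl <- marginals$tables[[cls$class[k]]]
    if (is.null(tbl)) {
      stop("marginals lack a table for class `", cls$class[k], "`",
           call. = FALSE)
    }
    total <- total + cls$c_total[k] * shannon(tbl)
  }
  total
}

#' Free energy of a grid configuration
#'
#' Evaluates the internal energy, entropy and free energy `F = U - S` of a
#' grid at the requested approximation order, using empirical cluster
#' marginals:
#'
#' * `order_d = 1`: the mean-field free energy of the fully factorised family
#'   with the shared site marginal `Q(1) = cancer_fraction(grid)` — pair
#'   expectations are product-form and the entropy is `N` times the site
#'   entropy;
#' * `order_d = 2` (Bethe) and `order_d = 3` (B3 triangles): `U` from the
#'   empirical pair tables (equal to the direct lattice sum) and `S` from
#'   [entropy_cvm()];
#' * `order_d = "full"`: the exact empirical limit (single region; only
#'   feasible on tiny lattices).
#'
#' All quantities are lattice totals in natural units (natural logarithms),
#' with inverse temperature fixed at 1 and activation energy 0.
#'
#' @param grid a `cell_grid`.
#' @param order_d approximation order: 1, 2, 3 or `"full"`.
#' @param eps_in interaction parameter, or a `pair_energy` convention.
#' @return A `free_energy_report`: list with `order_d`, `internal_energy`,
#'   `entropy`, `free_energy` and `eps_in`.
#' @examples
#' g <- seed_grid(make_grid(16, 16), "blob", count = 8)
#' free_energy(g, 3, 2.77259)
#' @export
free_energy <- function(grid, order_d, eps_in) {
  conv <- if (inherits(eps_in, "pair_energy")) eps_in else pair_energy(eps_in)
  grid <- as_cell_grid(grid)
  order_d <- validate_order(order_d)
  if (identical(order_d, 1L)) {
    p <- cancer_fraction(grid)
    n <- class_instance_counts(dim(grid))
    pr <- c(1 - p, p)
    e_pair <- sum(conv$u * as.vector(outer(pr, pr)[c(1, 3, 2, 4)]))
    U <- (n[["pair_h"]] + n[["pair_v"]]) * e_pair
    S <- length(grid) * shannon(pr)
  } else {
    rg <- build_region_graph(dim(grid), order_d, explicit = FALSE)
    marg <- empirical_marginals(grid, rg)
    U <- interaction_energy(marg, conv)
    S <- entropy_cvm(marg, rg)
  }
  structure(list(order_d = order_d, internal_energy = U, entropy = S,
                 free_energy = U - S, eps_in = conv$eps_in),
            class = "free_energy_report")
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat(sprintf("free energy (order d = %s, eps = %g): F = %.6g  (U = %.6g, S = %.6g)\n",
              as.character(x$order_d), x$eps_in, x$free_energy,
              x$internal_energy, x$entropy))
  invisible(x)
}

#' Exact Helmholtz free energy of a tiny lattice
#'
#' Brute-force oracle: enumerates all `2^N` configurations of an `H x W`
#' lattice, computes the direct pair-energy Hamiltonian of each, and returns
#' `F_H = -ln Z` with `Z = sum_x exp(-beta * H(x))`. The variational free
#' energy `U(Q) - S(Q)` of any normalised distribution upper-bounds this
#' value.
#'
#' @param grid_shape integer `c(H, W)` with at most 16 sites.
#' @param eps_in interaction parameter, or a `pair_energy` convention.
#' @param beta inverse temperature (the simulator fixes `beta = 1`).
#' @return The Helmholtz free energy scalar, in natural units.
#' @examples
#' exact_free_energy(c(1, 2), 0)   # -log(4): four equiprobable states
#' @export
exact_free_energy <- function(grid_shape, eps_in, beta = 1) {
  energies <- exact_state_energies(grid_shape, eps_in)
  -log(sum(exp(-beta * energies)))
}

## Hamiltonian of every configuration of a tiny lattice, in the row-major
## first-site-MSB state order used by the full-lattice marginal tables.
exact_state_energies <- function(grid_shape, eps_in) {
  conv <- if (inherits(eps_in, "pair_energy")) eps_in else pair_energy(eps_in)
  h <- as.integer(grid_shape[1L]); w <- as.integer(grid_shape[2L])
  N <- h * w
  if (N > 16L) {
    stop("exact enumeration limited to 16 sites (2^N states)", call. = FALSE)
  }
  cfg <- 0:(2^N - 1)
  bits <- vapply(seq_len(N), function(k) (cfg %/% 2^(N - k)) %% 2,
                 numeric(length(cfg)))                  # states x sites
  e <- numeric(length(cfg))
  id <- function(i, j) (i - 1L) * w + j
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (j < w) {
      idx <- 2L * bits[, id(i, j)] + bits[, id(i, j + 1L)] + 1L
      e <- e + conv$u[idx]
    }
    if (i < h) {
      idx <- 2L * bits[, id(i, j)] + bits[, id(i + 1L, j)] + 1L
      e <- e + conv$u[idx]
    }
  }
  unname(e)
}
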