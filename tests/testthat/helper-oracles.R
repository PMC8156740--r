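## Independent brute-force oracles for tiny lattices. These deliberately use
## naive loops (not the package's vectorised evaluators) so that agreement is
## a genuine cross-check.

## All 2^(h*w) configurations as rows of a 0/1 matrix, sites in row-major
## order, first site most significant.
oracle_states <- function(h, w) {
  n <- h * w
  m <- matrix(0L, 2^n, n)
  for (s in 0:(2^n - 1)) {
    for (k in 1:n) m[s + 1, k] <- (s %/% 2^(n - k)) %% 2
  }
  m
}

## Direct Hamiltonian of one configuration vector (row-major) by explicit
## neighbour loops: energy -eps per cancer-cancer nearest-neighbour contact.
oracle_hamiltonian <- function(x, h, w, eps) {
  g <- matrix(x, nrow = h, byrow = TRUE)
  e <- 0
  for (i in 1:h) for (j in 1:w) {
    if (j < w && g[i, j] == 1 && g[i, j + 1] == 1) e <- e - eps
    if (i < h && g[i, j] == 1 && g[i + 1, j] == 1) e <- e - eps
  }
  e
}

oracle_state_energies <- function(h, w, eps) {
  st <- oracle_states(h, w)
  apply(st, 1, oracle_hamiltonian, h = h, w = w, eps = eps)
}

## Exact Helmholtz free energy -ln Z at beta = 1.
oracle_helmholtz <- function(h, w, eps) {
  -log(sum(exp(-oracle_state_energies(h, w, eps))))
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

## Random normalised distribution over n outcomes.
random_distribution <- function(n) {
  q <- stats::runif(n)
  q / sum(q)
}

random_grid <- function(h, w, p = 0.5) {
  as_cell_grid(matrix(stats::rbinom(h * w, 1, p), h, w))
}

## sim_params copy with a different RNG seed.
within_seed <- function(params, seed) {
  params$seed <- seed
  params
}

binary_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log(p) - (1 - p) * log(1 - p)
}
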