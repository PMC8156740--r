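#' Linear parameter schedule
#'
#' A scalar parameter that ramps linearly from `start` at the first trial to
#' `end` at the last; used for the metastasis scenario's decaying noise and
#' increasing growth rate.
#'
#' @param start value at the first trial.
#' @param end value at the last trial.
#' @return A `schedule` object.
#' @export
schedule <- function(start, end) {
  stopifnot(is.finite(start), is.finite(end))
  structure(list(start = start, end = end, kind = "linear"),
            class = "schedule")
}

#' Evaluate a (possibly scheduled) parameter at a trial
#'
#' @param x a scalar or a [schedule()].
#' @param trial 1-based trial index.
#' @param trials total number of trials.
#' @return The parameter value at `trial`.
#' @export
schedule_value <- function(x, trial, trials) {
  if (!inherits(x, "schedule")) return(x)
  if (trials <= 1L) return(x$start)
  x$start + (x$end - x$start) * (trial - 1) / (trials - 1)
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("schedule: %g -> %g (linear)\n", x$start, x$end))
  invisible(x)
}

#' Simulation parameters
#'
#' Bundles the four scenario hyperparameters plus run controls:
#' \describe{
#'   \item{`tol`}{tolerance in `[0,1]`: sets the target state of proposed
#'     flips (cancer if `tol > 0.5`, healthy otherwise) and caps the
#'     admissible cancer fraction for cancer-adding flips.}
#'   \item{`eps_in`}{interaction parameter of the pair Hamiltonian.}
#'   \item{`alpha`}{growth rate as percent of the lattice flipped per trial;
#'     the per-trial flip count is `J = max(1, round(alpha/100 * N))`. Scalar
#'     or [schedule()].}
#'   \item{`noise`}{noise in `[0,1]` governing the proposal kind (see
#'     [propose_site()]). Scalar or [schedule()].}
#'   \item{`rho`}{Bernoulli parameter of the auxiliary cluster-membership
#'     variable; consumed only in `proposal_mode = "literal"`.}
#' }
#'
#' @param tol tolerance threshold in `[0, 1]`.
#' @param eps_in interaction parameter.
#' @param alpha growth rate (percent of N per trial), scalar or schedule.
#' @param noise noise parameter in `[0, 1]`, scalar or schedule.
#' @param rho Bernoulli parameter in `[0, 1]` (default 0.2).
#' @param trials number of trials (default 100).
#' @param seed RNG seed, or `NULL` to leave the RNG state alone.
#' @param proposal_mode `"uniform_noise"` (default: noise is the global-
#'   proposal probability) or `"literal"` (auxiliary Bernoulli draw compared
#'   against the noise).
#' @return A `sim_params` object.
#' @export
sim_params <- function(tol, eps_in, alpha, noise, rho = 0.2, trials = 100L,
                       seed = NULL,
                       proposal_mode = c("uniform_noise", "literal")) {
  proposal_mode <- match.arg(proposal_mode)
  chk01 <- function(x, nm) {
    v <- if (inherits(x, "schedule")) c(x$start, x$end) else x
    if (any(v < 0 | v > 1)) stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
  }
  chk01(tol, "tol"); chk01(noise, "noise"); chk01(rho, "rho")
  av <- if (inherits(alpha, "schedule")) c(alpha$start, alpha$end) else alpha
  if (any(av <= 0)) stop("`alpha` must be positive", call. = FALSE)
  if (trials < 1) stop("`trials` must be at least 1", call. = FALSE)
  structure(list(tol = tol, eps_in = eps_in, alpha = alpha, noise = noise,
                 rho = rho, trials = as.integer(trials), seed = seed,
                 proposal_mode = proposal_mode),
            class = "sim_params")
}

#' Flips proposed per trial
#'
#' `J = max(1, round(alpha_t / 100 * n_sites))`: the growth rate is a percent
#' of the lattice, and sub-unit counts are clamped to one proposal so an early
#' shallow ramp still moves the system.
#'
#' @param alpha_t growth rate at this trial (percent of N).
#' @param n_sites lattice site count N.
#' @return Positive integer flip count.
#' @export
flips_per_trial <- function(alpha_t, n_sites) {
  max(1L, as.integer(round(alpha_t / 100 * n_sites)))
}

#' Target state implied by the tolerance
#'
#' Proposed flips always move a site towards the target state: cancer (1) when
#' `tol > 0.5`, healthy (0) when `tol <= 0.5`.
#'
#' @param tol tolerance threshold in `[0, 1]`.
#' @return 0 or 1.
#' @export
target_state <- function(tol) {
  if (tol > 0.5) 1L else 0L
}

#' Propose a site to flip
#'
#' Picks a site currently NOT in the target state, by one of two kinds of
#' proposal:
#' \describe{
#'   \item{LOCAL}{uniform among non-target sites 4-adjacent to the existing
#'     cluster of target-state sites; if none is adjacent, uniform among the
#'     non-target sites nearest (Manhattan distance) to the cluster; if no
#'     target-state site exists at all, falls back to GLOBAL.}
#'   \item{GLOBAL}{uniform among all non-target sites.}
#' }
#' In mode `"uniform_noise"` the proposal is GLOBAL with probability
#' `noise_t` and LOCAL otherwise, so `noise = 0` gives purely local growth
#' and larger noise gives dispersive dynamics. In mode `"literal"` an
#' auxiliary `v ~ Bernoulli(rho)` is drawn and the proposal is LOCAL iff
#' `v >= noise_t`.
#'
#' Per-flip draw order: the proposal-type draw first, then the site draw.
#'
#' @param grid a `cell_grid`.
#' @param target target state 0 or 1.
#' @param noise_t noise value at this trial.
#' @param rho Bernoulli parameter (literal mode only).
#' @param mode `"uniform_noise"` or `"literal"`.
#' @return A list with `site = c(row, col)` and `type` (`"local"` or
#'   `"global"`), or `NULL` if every site is already in the target state
#'   (saturation).
#' @export
propose_site <- function(grid, target, noise_t, rho = 0.2,
                         mode = c("uniform_noise", "literal")) {
  mode <- match.arg(mode)
  g <- unclass(grid)
  flippable <- which(g != target)
  if (length(flippable) == 0L) return(NULL)

  global <- if (mode == "uniform_noise") {
    stats::runif(1) < noise_t
  } else {
    v <- stats::rbinom(1L, 1L, rho)
    v < noise_t
  }
  has_target <- any(g == target)
  type <- if (global || !has_target) "global" else "local"

  if (type == "local") {
    cand <- local_candidates(g, target)
    pick <- cand[sample.int(length(cand), 1L)]
  } else {
    pick <- flippable[sample.int(length(flippable), 1L)]
  }
  H <- nrow(g)
  list(site = c((pick - 1L) %% H + 1L, (pick - 1L) %/% H + 1L), type = type)
}

## Linear (column-major) indices of non-target sites adjacent to the target
## cluster; falls back to the nearest non-target sites if none is adjacent.
local_candidates <- function(g, target) {
  H <- nrow(g); W <- ncol(g)
  member <- g == target
  adj <- matrix(FALSE, H, W)
  adj[-H, ] <- adj[-H, ] | member[-1L, ]
  adj[-1L, ] <- adj[-1L, ] | member[-H, ]
  adj[, -W] <- adj[, -W] | member[, -1L]
  adj[, -1L] <- adj[, -1L] | member[, -W]
  cand <- which(adj & !member)
  if (length(cand) > 0L) return(cand)
  d <- manhattan_distance(member)
  d[member] <- NA
  which(!member & d == min(d[!member]))
}

## Exact 4-connected (Manhattan) distance to the TRUE set, by two-pass
## dynamic programming.
manhattan_distance <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  big <- H + W + 1L
  d <- matrix(big, H, W)
  d[mask] <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (i > 1L) d[i, j] <- min(d[i, j], d[i - 1L, j] + 1L)
    if (j > 1L) d[i, j] <- min(d[i, j], d[i, j - 1L] + 1L)
  }
  for (j in rev(seq_len(W))) for (i in rev(seq_len(H))) {
    if (i < H) d[i, j] <- min(d[i, j], d[i + 1L, j] + 1L)
    if (j < W) d[i, j] <- min(d[i, j], d[i, j + 1L] + 1L)
  }
  d
}

#' Greedy acceptance rule
#'
#' A proposed flip is retained iff it does not increase the Kikuchi free
#' energy (`delta_f <= 0`; neutral moves are accepted so exact ties in
#' degenerate early states do not deadlock) and, when the flip adds a cancer
#' cell, the resulting cancer fraction stays within the tolerance cap.
#'
#' @param delta_f Kikuchi free-energy change of the flip.
#' @param frac_after cancer fraction the grid would have after the flip.
#' @param tol tolerance threshold.
#' @param adds_cancer does the flip turn a healthy cell cancerous?
#' @return `TRUE` to accept, `FALSE` to revert.
#' @export
accept_flip <- function(delta_f, frac_after, tol, adds_cancer = TRUE) {
  if (delta_f > 0) return(FALSE)
  if (adds_cancer && frac_after > tol) return(FALSE)
  TRUE
}

## ---- incremental free-energy state -------------------------------------
## The d = 3 free energy depends on the grid only through the per-class
## configuration counts, so a flip needs only the handful of instances
## covering the flipped site to be re-counted.

dyn_classes <- c("tri_ul", "tri_lr", "pair_ad", "pair_h", "pair_v", "site")

fe_state_init <- function(grid, eps_in) {
  conv <- if (inherits(eps_in, "pair_energy")) eps_in else pair_energy(eps_in)
  g <- unclass(grid)
  counts <- lapply(stats::setNames(dyn_classes, dyn_classes),
                   function(cl) class_config_counts(g, cl))
  st <- list(g = g, counts = counts, conv = conv,
             classes3 = region_classes(dim(g), 3L),
             n_inst = class_instance_counts(dim(g)))
  st$F <- fe_from_counts(st)
  st
}

## Kikuchi (d = 3) and mean-field free energies from the count state.
fe_from_counts <- function(st) {
  U <- sum(st$conv$u * st$counts$pair_h) + sum(st$conv$u * st$counts$pair_v)
  S <- 0
  cls <- st$classes3
  for (k in seq_len(nrow(cls))) {
    if (cls$c_total[k] == 0) next
    cnt <- st$counts[[cls$class[k]]]
    S <- S + cls$c_total[k] * shannon(cnt / sum(cnt))
  }
  p <- st$counts$site[["1"]] / sum(st$counts$site)
  pr <- c(1 - p, p)
  U_mf <- (st$n_inst[["pair_h"]] + st$n_inst[["pair_v"]]) *
    sum(st$conv$u * as.vector(outer(pr, pr)[c(1, 3, 2, 4)]))
  S_mf <- sum(st$counts$site) * shannon(pr)
  list(U = U, S = S, F_K = U - S, F_MF = U_mf - S_mf)
}

## Counts after flipping site (i, j) to `newval`, touching only the
## instances that cover the site.
update_counts <- function(counts, g, i, j, newval) {
  H <- nrow(g); W <- ncol(g)
  for (cl in names(counts)) {
    offs <- region_shape_offsets(cl)
    size <- nrow(offs)
    amax <- c(H, W) - c(max(offs[, 1L]), max(offs[, 2L]))
    for (k in seq_len(size)) {
      ai <- i - offs[k, 1L]; aj <- j - offs[k, 2L]
      if (ai < 1L || aj < 1L || ai > amax[1L] || aj > amax[2L]) next
      rows <- ai + offs[, 1L]; cols <- aj + offs[, 2L]
      vals <- g[cbind(rows, cols)]
      old_idx <- sum(vals * 2^(size - seq_len(size))) + 1L
      vals[k] <- newval
      new_idx <- sum(vals * 2^(size - seq_len(size))) + 1L
      counts[[cl]][old_idx] <- counts[[cl]][old_idx] - 1L
      counts[[cl]][new_idx] <- counts[[cl]][new_idx] + 1L
    }
  }
  counts
}

## Evaluate a prospective flip without committing it.
fe_eval_flip <- function(st, i, j, newval) {
  st2 <- st
  st2$counts <- update_counts(st$counts, st$g, i, j, newval)
  st2$g[i, j] <- newval
  st2$F <- fe_from_counts(st2)
  st2
}

## One trial: J propose -> evaluate -> accept/revert steps on the state.
trial_step <- function(st, params, alpha_t, noise_t) {
  N <- length(st$g)
  J <- flips_per_trial(alpha_t, N)
  target <- target_state(params$tol)
  proposals <- 0L; accepted <- 0L; saturated <- FALSE
  for (k in seq_len(J)) {
    prop <- propose_site(structure(st$g, class = "cell_grid"), target,
                         noise_t, params$rho, params$proposal_mode)
    if (is.null(prop)) { saturated <- TRUE; break }
    proposals <- proposals + 1L
    i <- prop$site[1L]; j <- prop$site[2L]
    st2 <- fe_eval_flip(st, i, j, target)
    delta_f <- st2$F$F_K - st$F$F_K
    frac_after <- st2$counts$site[["1"]] / N
    if (accept_flip(delta_f, frac_after, params$tol,
                    adds_cancer = (target == 1L))) {
      st <- st2
      accepted <- accepted + 1L
    }
  }
  list(state = st, proposals = proposals, accepted = accepted,
       saturated = saturated)
}

#' Run a single trial
#'
#' Performs `J = flips_per_trial(alpha_t, N)` sequential propose/evaluate/
#' accept-or-revert steps on the grid and reports the post-trial free
#' energies. [run_simulation()] is the multi-trial driver; this entry point
#' exists for stepping a system by hand.
#'
#' @param grid a `cell_grid`.
#' @param params a [sim_params()] object.
#' @param trial_index 1-based trial index used to evaluate schedules.
#' @return A list with `grid` (the updated grid) and `record` (one-row data
#'   frame: trial, alpha, noise, proposals, accepted, cancer_count, F_K, U, S,
#'   F_MF, saturated).
#' @export
run_trial <- function(grid, params, trial_index = 1L) {
  alpha_t <- schedule_value(params$alpha, trial_index, params$trials)
  noise_t <- schedule_value(params$noise, trial_index, params$trials)
  st <- fe_state_init(as_cell_grid(grid), params$eps_in)
  res <- trial_step(st, params, alpha_t, noise_t)
  list(grid = as_cell_grid(res$state$g),
       record = trial_record(trial_index, alpha_t, noise_t, res))
}

trial_record <- function(trial, alpha_t, noise_t, res) {
  f <- res$state$F
  data.frame(trial = trial, alpha = alpha_t, noise = noise_t,
             proposals = res$proposals, accepted = res$accepted,
             cancer_count = res$state$counts$site[["1"]],
             F_K = f$F_K, U = f$U, S = f$S, F_MF = f$F_MF,
             saturated = res$saturated)
}

#' Run a full simulation
#'
#' Evolves the grid over `params$trials` trials, evaluating scheduled
#' parameters per trial, and records the Kikuchi (d = 3) and mean-field free
#' energies, interaction energy, entropy, proposal/acceptance counts and
#' cancer count after every trial. Fixing `params$seed` makes the trajectory
#' exactly reproducible (per flip: proposal-type draw, then site draw).
#'
#' If the lattice saturates (no site left to flip towards the target) the
#' remaining trials complete with zero proposals.
#'
#' @param initial_grid the starting `cell_grid`.
#' @param params a [sim_params()] object.
#' @param snapshot_every store a copy of the grid every this many trials
#'   (`NULL` = no snapshots; the final grid is always kept).
#' @return A `cvm_trajectory`: list with `records` (one data-frame row per
#'   trial), `initial` (trial-0 evaluation), `final_grid`, `snapshots`,
#'   `params` and `saturated`.
#' @examples
#' g <- seed_grid(make_grid(16, 16), "single_center")
#' p <- sim_params(tol = 0.6, eps_in = 2.77259, alpha = 0.4, noise = 0,
#'                 trials = 10, seed = 1)
#' traj <- run_simulation(g, p)
#' tail(traj$records, 3)
#' @export
run_simulation <- function(initial_grid, params, snapshot_every = NULL) {
  if (!is.null(params$seed)) set.seed(params$seed)
  st <- fe_state_init(as_cell_grid(initial_grid), params$eps_in)
  f0 <- st$F
  initial <- data.frame(trial = 0L, cancer_count = st$counts$site[["1"]],
                        F_K = f0$F_K, U = f0$U, S = f0$S, F_MF = f0$F_MF)
  records <- vector("list", params$trials)
  snapshots <- list()
  saturated <- FALSE
  for (t in seq_len(params$trials)) {
    alpha_t <- schedule_value(params$alpha, t, params$trials)
    noise_t <- schedule_value(params$noise, t, params$trials)
    res <- trial_step(st, params, alpha_t, noise_t)
    st <- res$state
    saturated <- saturated || res$saturated
    records[[t]] <- trial_record(t, alpha_t, noise_t, res)
    if (!is.null(snapshot_every) && t %% snapshot_every == 0L) {
      snapshots[[sprintf("trial_%04d", t)]] <- as_cell_grid(st$g)
    }
  }
  structure(list(records = do.call(rbind, records), initial = initial,
                 final_grid = as_cell_grid(st$g), snapshots = snapshots,
                 params = params, saturated = saturated),
            class = "cvm_trajectory")
}

#' @export
print.cvm_trajectory <- function(x, ...) {
  r <- x$records
  cat(sprintf("cvm_trajectory: %d trials on a %d x %d lattice\n",
              nrow(r), nrow(x$final_grid), ncol(x$final_grid)))
  cat(sprintf("  cancer count: %d -> %d; F_K: %.4g -> %.4g; F_MF: %.4g -> %.4g\n",
              x$initial$cancer_count, r$cancer_count[nrow(r)],
              x$initial$F_K, r$F_K[nrow(r)],
              x$initial$F_MF, r$F_MF[nrow(r)]))
  if (x$saturated) cat("  (lattice saturated during the run)\n")
  invisible(x)
}
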