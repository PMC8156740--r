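test_that("flips_per_trial applies the percent rule with a floor of one", {
  expect_equal(flips_per_trial(0.00610, 16384), 1L)   # 0.99946 rounds up
  expect_equal(flips_per_trial(0.00061, 16384), 1L)   # 0.0999 clamped
  expect_equal(flips_per_trial(100, 16384), 16384L)
  expect_equal(flips_per_trial(50, 100), 50L)
})

test_that("tolerance sets the target state with the boundary going healthy", {
  expect_equal(target_state(0.6), 1L)
  expect_equal(target_state(0.00001), 0L)
  expect_equal(target_state(0.5), 0L)
})

test_that("proposal kind follows the noise parameter", {
  g <- seed_grid(make_grid(12, 12), "blob", count = 6)
  set.seed(601)
  ## noise 0: always local
  types <- replicate(200, propose_site(g, 1L, noise_t = 0)$type)
  expect_true(all(types == "local"))
  ## noise 0.25: global fraction approx 0.25
  types <- replicate(10000, propose_site(g, 1L, noise_t = 0.25)$type)
  expect_equal(mean(types == "global"), 0.25, tolerance = 0.02)
  ## no target-state site yet: falls back to global
  empty <- make_grid(6, 6)
  prop <- propose_site(empty, 1L, noise_t = 0)
  expect_equal(prop$type, "global")
  ## saturation: nothing left to flip
  expect_null(propose_site(make_grid(4, 4), 0L, noise_t = 0))
})

test_that("local proposals touch the boundary of the target cluster", {
  g <- seed_grid(make_grid(16, 16), "blob", count = 9)
  set.seed(602)
  for (rep in 1:50) {
    prop <- propose_site(g, 1L, noise_t = 0)
    expect_equal(unname(g[prop$site[1], prop$site[2]]), 0L)
    nb <- neighbors4(g, prop$site)
    expect_true(any(g[nb] == 1L))
  }
})

test_that("literal proposal mode uses the auxiliary Bernoulli draw", {
  g <- seed_grid(make_grid(10, 10), "blob", count = 5)
  set.seed(603)
  ## rho = 1: v = 1 always, local iff 1 >= noise
  types <- replicate(100, propose_site(g, 1L, noise_t = 0.5, rho = 1,
                                       mode = "literal")$type)
  expect_true(all(types == "local"))
  ## rho = 0: v = 0, local iff 0 >= noise; noise > 0 forces global
  types <- replicate(100, propose_site(g, 1L, noise_t = 0.5, rho = 0,
                                       mode = "literal")$type)
  expect_true(all(types == "global"))
})

test_that("greedy acceptance requires descent and respects the cancer cap", {
  expect_true(accept_flip(-0.3, frac_after = 0.1, tol = 0.6))
  expect_true(accept_flip(0, frac_after = 0.1, tol = 0.6))     # neutral moves
  expect_false(accept_flip(0.1, frac_after = 0.1, tol = 0.6))
  ## cancer-adding flip at the cap is rejected
  expect_false(accept_flip(-0.5, frac_after = 0.6 + 1 / 256, tol = 0.6))
  ## removals are never capped
  expect_true(accept_flip(-0.5, frac_after = 0.3, tol = 0.00001,
                          adds_cancer = FALSE))
})

test_that("incremental free-energy change equals full re-evaluation", {
  set.seed(604)
  for (rep in 1:15) {
    g <- random_grid(8, 9, 0.4)
    eps <- stats::runif(1, -2, 3)
    st <- cvmniche:::fe_state_init(g, eps)
    i <- sample(8, 1); j <- sample(9, 1)
    newv <- 1L - g[i, j]
    st2 <- cvmniche:::fe_eval_flip(st, i, j, newv)
    g2 <- g; g2[i, j] <- newv
    fe1 <- free_energy(g, 3, eps); fe2 <- free_energy(g2, 3, eps)
    expect_equal(st2$F$F_K - st$F$F_K, fe2$free_energy - fe1$free_energy,
                 tolerance = 1e-9)
    ## the count state itself matches a fresh count
    st_fresh <- cvmniche:::fe_state_init(as_cell_grid(g2), eps)
    expect_identical(st2$counts, st_fresh$counts)
  }
})

test_that("fixed seeds give bitwise-identical trajectories", {
  g <- seed_grid(make_grid(24, 24), "blob", count = 5)
  p <- sim_params(tol = 0.6, eps_in = 2.77259, alpha = 0.7, noise = 0.25,
                  trials = 15, seed = 42)
  t1 <- run_simulation(g, p)
  t2 <- run_simulation(g, p)
  expect_identical(t1$records, t2$records)
  expect_identical(unclass(t1$final_grid), unclass(t2$final_grid))
})

test_that("apoptosis dynamics only remove cancer and saturate cleanly", {
  g <- seed_grid(make_grid(24, 24), "blob", count = 12)
  p <- sim_params(tol = 0.00001, eps_in = -1.4267, alpha = 2, noise = 0.25,
                  trials = 30, seed = 7)
  traj <- run_simulation(g, p)
  counts <- c(traj$initial$cancer_count, traj$records$cancer_count)
  expect_true(all(diff(counts) <= 0))
  ## all-healthy start is saturated immediately: zero proposals, unchanged grid
  r0 <- run_trial(make_grid(8, 8), p, trial_index = 1)
  expect_equal(r0$record$proposals, 0L)
  expect_true(r0$record$saturated)
  expect_equal(cancer_count(r0$grid), 0L)
})

test_that("Kikuchi free energy is non-increasing along any run", {
  set.seed(605)
  g <- seed_grid(make_grid(20, 20), "single_center")
  p <- sim_params(tol = 0.6, eps_in = 1.88001, alpha = 1, noise = 0.3,
                  trials = 25, seed = 99)
  traj <- run_simulation(g, p)
  f <- c(traj$initial$F_K, traj$records$F_K)
  expect_true(all(diff(f) <= 1e-9))
  ## the cap keeps the cancer fraction within tolerance
  expect_true(all(traj$records$cancer_count / 400 <= p$tol + 1e-12))
})

test_that("schedules interpolate linearly between the stated endpoints", {
  s <- schedule(0.30, 0.25)
  expect_equal(schedule_value(s, 1, 100), 0.30)
  expect_equal(schedule_value(s, 100, 100), 0.25)
  expect_equal(schedule_value(s, 50, 100), 0.30 + (0.25 - 0.30) * 49 / 99)
  expect_equal(schedule_value(0.25, 37, 100), 0.25)  # scalars pass through
  a <- schedule(0.00061, 0.00610)
  expect_equal(schedule_value(a, 1, 100), 0.00061)
  expect_equal(schedule_value(a, 100, 100), 0.00610)
})

test_that("run_simulation produces one record per trial", {
  g <- seed_grid(make_grid(16, 16), "single_center")
  p <- sim_params(tol = 0.6, eps_in = 2.77259, alpha = 0.5, noise = 0.25,
                  trials = 12, seed = 3)
  traj <- run_simulation(g, p, snapshot_every = 5)
  expect_equal(nrow(traj$records), 12L)
  expect_equal(names(traj$snapshots), c("trial_0005", "trial_0010"))
  expect_true(all(traj$records$accepted <= traj$records$proposals))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(1.2, 1, 1, 0.2), "tol")
  expect_error(sim_params(0.6, 1, -1, 0.2), "alpha")
  expect_error(sim_params(0.6, 1, 1, 1.5), "noise")
  expect_error(sim_params(0.6, 1, 1, 0.2, trials = 0), "trials")
})
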