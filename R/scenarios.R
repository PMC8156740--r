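#' Scenario presets
#'
#' Named parameterisations of the three simulated cancer trajectories, on the
#' default 128 x 128 lattice with 100 trials and `rho = 0.2`:
#'
#' | name | tol | eps_in | alpha (% of N) | noise | seed pattern |
#' |------|-----|--------|----------------|-------|--------------|
#' | `local_growth_dispersive` | 0.60000 | 2.77259 | 0.00610 | 0.25 | single centre cell |
#' | `local_growth_localised`  | 0.60000 | 2.77259 | 0.00610 | 0.00 | single centre cell |
#' | `metastasis`              | 0.60000 | 1.88001 | 0.00061 -> 0.00610 | 0.30 -> 0.25 | 12 x 12 primary block |
#' | `apoptosis_small`         | 0.00001 | -1.42670 | 0.00610 | 0.25 | 41-cell blob |
#' | `apoptosis_large`         | 0.00001 | -1.42670 | 0.00610 | 0.25 | 172-cell blob |
#'
#' The two local-growth presets differ only in the noise parameter:
#' dispersive growth scatters global proposals, localised growth (`noise = 0`)
#' accretes strictly at the cluster boundary. The metastasis primary site is a
#' 12 x 12 block at rows/cols 21--32 (the source text fixes only "a small
#' region"; the block is configurable via `overrides`). The large apoptosis
#' blob uses the printed 172-cell figure.
#'
#' @param name preset name (see table).
#' @param overrides named list overriding any of `tol`, `eps_in`, `alpha`,
#'   `noise`, `rho`, `trials`, `seed`, `proposal_mode`, `grid_size`,
#'   `block_origin`, `block_extent`, `blob_count`.
#' @return A `scenario_config`: list with `name`, `params` ([sim_params()]),
#'   `grid_size` and `seed_spec`.
#' @examples
#' sc <- make_scenario("apoptosis_small")
#' sc$params$eps_in
#' @export
make_scenario <- function(name, overrides = list()) {
  presets <- list(
    local_growth_dispersive = list(
      tol = 0.60000, eps_in = 2.77259, alpha = 0.00610, noise = 0.25,
      seed_spec = list(pattern = "single_center")),
    local_growth_localised = list(
      tol = 0.60000, eps_in = 2.77259, alpha = 0.00610, noise = 0.00,
      seed_spec = list(pattern = "single_center")),
    metastasis = list(
      tol = 0.60000, eps_in = 1.88001,
      alpha = schedule(0.00061, 0.00610), noise = schedule(0.30, 0.25),
      seed_spec = list(pattern = "block", origin = c(21L, 21L),
                       extent = c(12L, 12L))),
    apoptosis_small = list(
      tol = 0.00001, eps_in = -1.42670, alpha = 0.00610, noise = 0.25,
      seed_spec = list(pattern = "blob", count = 41L)),
    apoptosis_large = list(
      tol = 0.00001, eps_in = -1.42670, alpha = 0.00610, noise = 0.25,
      seed_spec = list(pattern = "blob", count = 172L))
  )
  if (!name %in% names(presets)) {
    stop("unknown scenario `", name, "`; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  cfg <- presets[[name]]
  base <- list(tol = cfg$tol, eps_in = cfg$eps_in, alpha = cfg$alpha,
               noise = cfg$noise, rho = 0.2, trials = 100L, seed = NULL,
               proposal_mode = "uniform_noise", grid_size = 128L)
  seed_spec <- cfg$seed_spec
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (nm %in% names(base)) {
      base[[nm]] <- val
    } else if (nm == "blob_count") {
      seed_spec$count <- as.integer(val)
    } else if (nm == "block_origin") {
      seed_spec$origin <- as.integer(val)
    } else if (nm == "block_extent") {
      seed_spec$extent <- as.integer(val)
    } else {
      stop("unknown override `", nm, "`", call. = FALSE)
    }
  }
  params <- sim_params(tol = base$tol, eps_in = base$eps_in,
                       alpha = base$alpha, noise = base$noise, rho = base$rho,
                       trials = base$trials, seed = base$seed,
                       proposal_mode = base$proposal_mode)
  structure(list(name = name, params = params,
                 grid_size = as.integer(base$grid_size),
                 seed_spec = seed_spec),
            class = "scenario_config")
}

#' Names of the available scenario presets
#' @return Character vector of preset names.
#' @export
scenario_names <- function() {
  c("local_growth_dispersive", "local_growth_localised", "metastasis",
    "apoptosis_small", "apoptosis_large")
}

#' Initial grid of a scenario
#'
#' @param scenario a `scenario_config` from [make_scenario()].
#' @return The seeded initial `cell_grid`.
#' @export
scenario_grid <- function(scenario) {
  g <- make_grid(scenario$grid_size, scenario$grid_size)
  ss <- scenario$seed_spec
  seed_grid(g, ss$pattern, count = ss$count, origin = ss$origin,
            extent = ss$extent)
}

#' Run a scenario end to end
#'
#' Builds the scenario's initial grid and hands it to [run_simulation()].
#'
#' @param scenario a `scenario_config`, or a preset name.
#' @param seed RNG seed (overrides any seed already in the config).
#' @param snapshot_every passed to [run_simulation()].
#' @return A `cvm_trajectory`.
#' @export
run_scenario <- function(scenario, seed = NULL, snapshot_every = NULL) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  if (!is.null(seed)) scenario$params$seed <- seed
  run_simulation(scenario_grid(scenario), scenario$params,
                 snapshot_every = snapshot_every)
}

#' @export
print.scenario_config <- function(x, ...) {
  fmt <- function(v) {
    if (inherits(v, "schedule")) sprintf("%g -> %g", v$start, v$end)
    else sprintf("%g", v)
  }
  cat(sprintf("scenario `%s`: %d x %d lattice, %d trials\n", x$name,
              x$grid_size, x$grid_size, x$params$trials))
  cat(sprintf("  tol = %g, eps_in = %g, alpha = %s, noise = %s, rho = %g\n",
              x$params$tol, x$params$eps_in, fmt(x$params$alpha),
              fmt(x$params$noise), x$params$rho))
  cat(sprintf("  seed pattern: %s\n", x$seed_spec$pattern))
  invisible(x)
}

## ---- flat key/value config files ---------------------------------------
## Schedules use the "start->end" syntax, e.g. `noise = 0.30->0.25`.

#' Write / read a scenario configuration file
#'
#' Human-editable flat `key = value` format; scheduled parameters use the
#' `start->end` syntax. Round-trips exactly.
#'
#' @param scenario a `scenario_config`.
#' @param file path of the config file.
#' @return `write_scenario_config` returns `file` invisibly;
#'   `read_scenario_config` returns a `scenario_config`.
#' @export
write_scenario_config <- function(scenario, file) {
  p <- scenario$params
  fmt <- function(v) {
    if (inherits(v, "schedule")) sprintf("%.17g->%.17g", v$start, v$end)
    else sprintf("%.17g", v)
  }
  lines <- c(
    sprintf("name = %s", scenario$name),
    sprintf("grid_size = %d", scenario$grid_size),
    sprintf("trials = %d", p$trials),
    sprintf("tol = %s", fmt(p$tol)),
    sprintf("eps_in = %s", fmt(p$eps_in)),
    sprintf("alpha = %s", fmt(p$alpha)),
    sprintf("noise = %s", fmt(p$noise)),
    sprintf("rho = %s", fmt(p$rho)),
    sprintf("proposal_mode = %s", p$proposal_mode),
    sprintf("seed_pattern = %s", scenario$seed_spec$pattern))
  if (!is.null(p$seed)) lines <- c(lines, sprintf("seed = %d", p$seed))
  ss <- scenario$seed_spec
  if (!is.null(ss$count)) lines <- c(lines, sprintf("blob_count = %d", ss$count))
  if (!is.null(ss$origin)) {
    lines <- c(lines, sprintf("block_origin = %d,%d", ss$origin[1L], ss$origin[2L]),
               sprintf("block_extent = %d,%d", ss$extent[1L], ss$extent[2L]))
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(file) {
  lines <- grep("=", readLines(file), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  vals <- stats::setNames(kv[, 2L], kv[, 1L])
  parse_num <- function(s) {
    if (grepl("->", s, fixed = TRUE)) {
      parts <- as.numeric(strsplit(s, "->", fixed = TRUE)[[1L]])
      schedule(parts[1L], parts[2L])
    } else as.numeric(s)
  }
  overrides <- list(
    grid_size = as.integer(vals[["grid_size"]]),
    trials = as.integer(vals[["trials"]]),
    tol = parse_num(vals[["tol"]]),
    eps_in = parse_num(vals[["eps_in"]]),
    alpha = parse_num(vals[["alpha"]]),
    noise = parse_num(vals[["noise"]]),
    rho = parse_num(vals[["rho"]]),
    proposal_mode = vals[["proposal_mode"]])
  if ("seed" %in% names(vals)) overrides$seed <- as.integer(vals[["seed"]])
  if ("blob_count" %in% names(vals)) {
    overrides$blob_count <- as.integer(vals[["blob_count"]])
  }
  if ("block_origin" %in% names(vals)) {
    overrides$block_origin <-
      as.integer(strsplit(vals[["block_origin"]], ",")[[1L]])
    overrides$block_extent <-
      as.integer(strsplit(vals[["block_extent"]], ",")[[1L]])
  }
  make_scenario(vals[["name"]], overrides)
}
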