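#' Simulation configuration
#'
#' Defaults (model units: one monomer diameter is about 1 length unit):
#' a 20x20x20 box, a 0.01 s step (below the 0.1 s time-scale switching
#' threshold, so runs resolve queries through the agent system),
#' attraction over 5 monomer diameters at a speed that covers the
#' attraction radius in about 100 steps, and a process lifetime limit of
#' 5 s.
#'
#' @param dt simulation time step, s.
#' @param steps number of steps for [run()].
#' @param domain box dimensions, model units.
#' @param seed RNG seed fixed at [sim_init()]; a fixed seed makes the
#'   whole run (final string, logs, exports) reproducible.
#' @param t_max process lifetime limit, s (overrides the script global).
#' @param time_scale parameters of [time_scale_model()].
#' @param attraction `list(radius =, speed =)` for [attract_step()].
#' @param tol_pos binding position tolerance, model units.
#' @param tol_ang binding orientation tolerance, degrees. The driver
#'   default (180, i.e. no orientation gating) reflects that the placed
#'   monomer's orientation is imposed by the binding-site geometry at
#'   docking; tighten it to model orientation-limited binding kinetics.
#' @param steering list of timed steering edits, each
#'   `list(t =, type =, density =)` (replace a density schedule by a
#'   constant from time `t` on) or `list(t =, dt =)` (change the time
#'   step).
#' @export
sim_config <- function(dt = 0.01, steps = 500, domain = c(20, 20, 20),
                       seed = 1, t_max = 5,
                       time_scale = list(threshold = 0.1, midpoint = 1,
                                         steepness = 5),
                       attraction = list(radius = 5, speed = 5),
                       tol_pos = 0.25, tol_ang = 180,
                       steering = list()) {
  stopifnot(dt > 0, steps >= 0)
  list(dt = dt, steps = steps, domain = domain, seed = seed, t_max = t_max,
       time_scale = time_scale, attraction = attraction,
       tol_pos = tol_pos, tol_ang = tol_ang, steering = steering)
}

#' Initialize the fused simulation state
#'
#' Seeds the RNG, overrides the script's `t_max` global with the config
#' value, interprets the axiom (stamping anchor poses), reconciles the
#' agent population against the density targets at `t = 0` and builds
#' the initial query table.
#'
#' @param sc a [scenario()].
#' @param config a [sim_config()]; entries in `sc$config` override the
#'   defaults, and entries given here override both.
#' @export
sim_init <- function(sc, config = list()) {
  cfg <- utils::modifyList(utils::modifyList(sim_config(), sc$config),
                           config)
  # modifyList ignores unnamed entries, so merge the steering list itself
  cfg$steering <- config$steering %||% sc$config$steering %||% list()
  set.seed(cfg$seed)
  sc$ruleset$globals$t_max <- cfg$t_max
  domain <- make_domain(cfg$domain)
  ts_model <- do.call(time_scale_model, cfg$time_scale)
  interp <- interpret(sc$ruleset$axiom, sc$root, sc$bindings)
  s <- interp$string
  rec <- reconcile_counts(new_agents(), sc$densities, domain, 0)
  state <- list(scenario = sc, config = cfg, domain = domain,
                ts_model = ts_model,
                t = 0, step = 0L, string = s, agents = rec$agents,
                queries = sync_queries(s), next_id = rec$next_id,
                placements = interp$placements,
                log = list(), events = list(),
                totals = list(binds = 0L, spawned = sum(rec$spawn),
                              despawned = 0L, structures_added = 0L))
  state$log[[1]] <- log_row(state, binds = 0L, spawns = sum(rec$spawn),
                            despawns = 0L, resolved = 0L)
  class(state) <- "simstate"
  state
}

log_row <- function(state, binds, spawns, despawns, resolved) {
  s <- state$string
  counts <- table(factor(state$agents$type,
                         levels = names(state$scenario$agent_types)))
  row <- data.frame(step = state$step, t = state$t,
                    n_agents = nrow(state$agents),
                    n_structure = count_symbols(s, "structure"),
                    n_branches = count_branches(state),
                    n_queries = nrow(state$queries),
                    binds = binds, spawns = spawns, despawns = despawns,
                    resolved = resolved)
  for (ty in names(counts)) row[[paste0("count_", ty)]] <- as.integer(counts[[ty]])
  row
}

count_branches <- function(state) {
  bb <- branch_binding_names(state$scenario)
  if (length(bb) == 0) return(0L)
  sum(vapply(unclass(state$string), function(x)
    x$kind == "binding" && x$name %in% bb, logical(1)))
}

#' Advance the simulation by one step
#'
#' One step executes, in order: (1) the L-system evaluation -- process
#' aging, write-back of query results into the Communication symbols,
#' parallel derivation and geometric interpretation; (2) the system of
#' densities -- reconciliation of agent counts against the density
#' targets; (3) the communication system -- below the time-scale
#' threshold (`eval_P(dt) == 0`) the agent system runs (attraction,
#' diffusion, bind-on-arrival; or a fast-forward redistribution when no
#' query is live), above it queries resolve through the density-driven
#' probability channel. The clock then advances by `dt`. Errors abort
#' the step; since the state is modified copy-on-write, the caller's
#' state is unchanged on error.
#'
#' @param state a [sim_init()] state.
#' @return the advanced state.
#' @export
run_step <- function(state) {
  sc <- state$scenario
  cfg <- state$config
  # scheduled steering edits due within the coming step
  if (length(cfg$steering) > 0) {
    due <- vapply(cfg$steering, function(ev) ev$t <= state$t + cfg$dt,
                  logical(1))
    for (ev in cfg$steering[due]) {
      if (!is.null(ev$density))
        sc$densities[[ev$type]] <- density_schedule(0, ev$density)
      if (!is.null(ev$dt)) cfg$dt <- ev$dt
    }
    cfg$steering <- cfg$steering[!due]
    state$config <- cfg
    state$scenario <- sc
  }
  dt <- cfg$dt

  # (1) L-system: aging, result write-back, derivation, interpretation
  s <- age_processes(state$string, dt)
  resolved <- state$queries[state$queries$result != "EMPTY", , drop = FALSE]
  if (nrow(resolved) > 0)
    s <- set_results(s, resolved[, c("source", "result")])
  n_before <- count_symbols(s, "structure")
  s <- derive(s, sc$ruleset, branch_rules = sc$branch_rules)
  ev <- attr(s, "events")
  n_added <- count_symbols(s, "structure") - n_before
  interp <- interpret(s, sc$root, sc$bindings)
  s <- interp$string

  # (2) system of densities
  t_new <- state$t + dt
  rec <- reconcile_counts(state$agents, sc$densities, state$domain, t_new,
                          state$next_id)
  agents <- rec$agents

  # (3) communication: pick the temporal channel
  queries <- sync_queries(s)
  p <- eval_P(dt, state$ts_model)
  binds <- 0L
  if (p == 0) {
    live <- sum(queries$result == "EMPTY" & !queries$terminated)
    if (live > 0) {
      agents <- attract_step(agents, queries, cfg$attraction, dt)
      agents <- diffuse_step(agents, sc$agent_types, state$domain, dt)
      bb <- bind_queries(agents, queries, cfg$tol_pos, cfg$tol_ang)
      agents <- bb$agents
      queries <- bb$queries
      binds <- nrow(bb$bound)
    } else if (nrow(agents) > 0) {
      agents <- fast_forward(agents, state$domain)
    }
  } else if (nrow(queries) > 0) {
    for (k in seq_len(nrow(queries)))
      queries[k, ] <- resolve_query(queries[k, ], state$ts_model,
                                    sc$densities, sc$agent_types,
                                    "EMPTY", t_new, dt)
  }
  if (nrow(queries) > 0)
    for (k in seq_len(nrow(queries)))
      queries[k, ] <- expire_query(queries[k, ], cfg$t_max)

  state$t <- t_new
  state$step <- state$step + 1L
  state$string <- s
  state$agents <- agents
  state$queries <- queries
  state$next_id <- rec$next_id
  state$placements <- interp$placements
  state$totals$binds <- state$totals$binds + binds
  state$totals$spawned <- state$totals$spawned + sum(rec$spawn)
  state$totals$despawned <- state$totals$despawned + length(rec$despawn_ids)
  state$totals$structures_added <- state$totals$structures_added + n_added
  for (e in ev)
    state$events[[length(state$events) + 1]] <-
      data.frame(step = state$step, rule = e$rule, u = e$u,
                 theta = e$theta, is_branch = e$is_branch)
  state$log[[length(state$log) + 1]] <-
    log_row(state, binds = binds, spawns = sum(rec$spawn),
            despawns = length(rec$despawn_ids),
            resolved = sum(queries$result != "EMPTY"))
  state
}

#' Run a scenario
#'
#' @param sc a [scenario()] (or the name of a packaged one).
#' @param config [sim_config()] overrides.
#' @param steps number of steps (overrides the config).
#' @return list of class `"simrun"`: the final `state`, the per-step
#'   `log` (one row per step including `t = 0`), the derivation `events`
#'   and the final `placements`.
#' @export
run <- function(sc, config = list(), steps = NULL) {
  if (is.character(sc)) sc <- packaged_scenario(sc)
  if (!is.null(steps)) config$steps <- steps
  state <- sim_init(sc, config)
  for (i in seq_len(state$config$steps)) state <- run_step(state)
  structure(list(state = state,
                 log = do.call(rbind, state$log),
                 events = if (length(state$events))
                   do.call(rbind, state$events)
                 else data.frame(step = integer(), rule = character(),
                                 u = numeric(), theta = numeric(),
                                 is_branch = logical()),
                 placements = state$placements),
            class = "simrun")
}

#' @export
print.simrun <- function(x, ...) {
  cat(sprintf(
    "<simrun '%s': %d steps, t = %.3g s, %d monomers placed, %d agents>\n",
    x$state$scenario$name, x$state$step, x$state$t,
    nrow(x$placements), nrow(x$state$agents)))
  invisible(x)
}

#' Export placed geometry
#'
#' `csv` writes one row per placement (pose quaternion and annotations
#' included) with full double precision, so reading it back with
#' [read_structure_csv()] is lossless. `obj` writes a Wavefront OBJ
#' with one unit primitive (icosahedral sphere, cube or hexagonal
#' cylinder, per the placement's geometry tag) transformed by each
#' placement's pose.
#'
#' @param placements placement data frame (from [interpret()] or a
#'   [run()] result).
#' @param path output file path.
#' @param format `"csv"` or `"obj"`.
#' @export
export_structure <- function(placements, path, format = c("csv", "obj")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- placements
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    write_obj(placements, path)
  }
  invisible(path)
}

#' Read back a structure CSV written by [export_structure()]
#' @param path CSV file path.
#' @export
read_structure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("x", "y", "z", "qw", "qx", "qy", "qz",
                          "branch_u", "branch_theta", "uncertainty",
                          "branch_probability"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}

# Unit primitives centered at the origin, about one model unit across.
obj_primitive <- function(tag) {
  switch(tag,
    sphere = {
      p <- (1 + sqrt(5)) / 2
      v <- rbind(
        c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
        c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
        c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
      v <- v / sqrt(1 + p^2) * 0.5  # icosahedron scaled to radius 0.5
      f <- rbind(
        c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
        c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
        c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
        c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
      list(v = v, f = f)
    },
    cube = {
      g <- expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                       z = c(-0.5, 0.5))
      v <- as.matrix(g)
      f <- rbind(
        c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
        c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
        c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
      list(v = v, f = f)
    },
    cylinder = {
      ang <- (0:5) * pi / 3
      bot <- cbind(0.5 * cos(ang), 0.5 * sin(ang), -0.5)
      top <- cbind(0.5 * cos(ang), 0.5 * sin(ang), 0.5)
      v <- rbind(bot, top)
      side <- do.call(rbind, lapply(1:6, function(i) {
        j <- i %% 6 + 1
        rbind(c(i, j, j + 6), c(i, j + 6, i + 6))
      }))
      capf <- do.call(rbind, lapply(2:5, function(i)
        rbind(c(1, i + 1, i), c(7, i + 6, i + 7))))
      list(v = v, f = rbind(side, capf))
    },
    stop(sprintf("unknown geometry tag '%s'", tag)))
}

write_obj <- function(placements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# polymersim structure export", con)
  offset <- 0L
  for (i in seq_len(nrow(placements))) {
    pl <- placements[i, ]
    prim <- obj_primitive(pl$geometry)
    R <- quat_to_matrix(quat(pl$qw, pl$qx, pl$qy, pl$qz))
    v <- t(R %*% t(prim$v)) +
      matrix(c(pl$x, pl$y, pl$z), nrow(prim$v), 3, byrow = TRUE)
    writeLines(sprintf("o placement_%d", i), con)
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", prim$f[, 1] + offset,
                       prim$f[, 2] + offset, prim$f[, 3] + offset), con)
    offset <- offset + nrow(prim$v)
  }
  invisible(path)
}

#' Export a run's per-step log and event table as CSV
#'
#' @param res a [run()] result.
#' @param dir output directory.
#' @export
export_log <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$log, file.path(dir, "log.csv"), row.names = FALSE)
  utils::write.csv(res$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Export the agent population snapshot as CSV
#'
#' One row per agent: id, type, position, orientation quaternion and
#' the snapshot time.
#'
#' @param state a simulation state.
#' @param path CSV file path.
#' @export
export_agents <- function(state, path) {
  df <- state$agents[, c("id", "type", "x", "y", "z",
                         "qw", "qx", "qy", "qz")]
  df$t <- state$t
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
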