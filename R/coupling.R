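#' Time-scale switching model
#'
#' The probability function `P(dt)` decides which temporal scale governs
#' query resolution: it is exactly 0 for time steps below the switching
#' threshold (the simulation then runs at the monomer-motion scale and
#' the agent system resolves queries), and ramps monotonically toward 1
#' for larger steps (the growth is then computed directly from the
#' density channel). The ramp is a logistic
#' `1 / (1 + exp(-steepness * (dt - midpoint)))`, shifted and rescaled
#' to be continuous (= 0) at the threshold.
#'
#' @param threshold time-scale switching threshold, s.
#' @param midpoint logistic midpoint, s.
#' @param steepness logistic steepness, 1/s.
#' @export
time_scale_model <- function(threshold = 0.1, midpoint = 1, steepness = 5) {
  stopifnot(threshold > 0, steepness > 0)
  list(threshold = threshold, midpoint = midpoint, steepness = steepness)
}

#' Evaluate the time-scale probability P(dt)
#'
#' @param dt simulation time step, s (> 0).
#' @param m a [time_scale_model()].
#' @return a probability in `[0, 1]`; exactly 0 below the threshold,
#'   non-decreasing in `dt`.
#' @export
eval_P <- function(dt, m = time_scale_model()) {
  stopifnot(all(dt > 0))
  logis <- function(x) 1 / (1 + exp(-m$steepness * (x - m$midpoint)))
  L0 <- logis(m$threshold)
  p <- (logis(dt) - L0) / (1 - L0)
  p[dt < m$threshold] <- 0
  pmin(pmax(p, 0), 1)
}

#' Piecewise-linear density schedule
#'
#' Target density of one agent type over time, interpolated linearly
#' between breakpoints and held constant beyond them.
#'
#' @param t breakpoint times, s.
#' @param density target densities (count / volume), `>= 0`.
#' @export
density_schedule <- function(t, density) {
  stopifnot(length(t) == length(density), all(density >= 0),
            !is.unsorted(t))
  list(t = as.numeric(t), density = as.numeric(density))
}

#' Evaluate a density schedule at time t
#' @param sched a [density_schedule()].
#' @param t time, s.
#' @export
density_at <- function(sched, t) {
  if (length(sched$t) == 1) return(rep(sched$density, length(t)))
  stats::approx(sched$t, sched$density, xout = t, rule = 2)$y
}

#' Build the query table from an interpreted L-string
#'
#' Creates exactly one live query per unresolved Communication symbol,
#' copying the symbol's anchor pose (stamped by [interpret()]) into the
#' query position/orientation and mirroring its elapsed process time.
#' The table is rebuilt from scratch each step, so queries whose source
#' symbols were rewritten are dropped automatically.
#'
#' @param s an interpreted [lstring()] (anchor poses fresh).
#' @return data frame with columns `source, process, type, x, y, z, qw,
#'   qx, qy, qz, time, result, terminated`.
#' @export
sync_queries <- function(s) {
  syms <- unclass(s)
  rows <- list()
  for (i in seq_along(syms)) {
    x <- syms[[i]]
    if (x$kind != "comm" || x$r != "EMPTY") next
    if (is.null(x$anchor))
      stop(sprintf("communication symbol at %d has no anchor pose; interpret the string first", i))
    rows[[length(rows) + 1]] <- data.frame(
      source = i, process = x$process, type = x$type,
      x = x$anchor$pos[1], y = x$anchor$pos[2], z = x$anchor$pos[3],
      qw = x$anchor$ori[1], qx = x$anchor$ori[2],
      qy = x$anchor$ori[3], qz = x$anchor$ori[4],
      time = x$t, result = "EMPTY", terminated = FALSE,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(source = integer(), process = character(),
                      type = character(), x = numeric(), y = numeric(),
                      z = numeric(), qw = numeric(), qx = numeric(),
                      qy = numeric(), qz = numeric(), time = numeric(),
                      result = character(), terminated = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Resolve one query across the two temporal channels
#'
#' Implements the blend between the large-time-scale (density-driven)
#' channel and the agent-system outcome: with `p = eval_P(dt, m)` the
#' large-scale channel fires with probability
#' `clamp(p * d_type(t) * a_type, 0, 1)` and sets the result to the
#' requested type; otherwise the agent-system outcome `as_result` is
#' adopted with weight `1 - p`. In the limits: `p = 0` reproduces the
#' agent outcome exactly, `p = 1` ignores the agent system entirely.
#'
#' @param q one-row query table entry (unresolved).
#' @param m a [time_scale_model()].
#' @param densities named list of [density_schedule()]s per agent type.
#' @param specs named list of [agent_type_spec()]s.
#' @param as_result agent-system outcome: `"EMPTY"` or an agent-type
#'   label.
#' @param t current simulation time, s.
#' @param dt simulation time step, s.
#' @return the query with its `result` possibly filled.
#' @export
resolve_query <- function(q, m, densities, specs, as_result = "EMPTY",
                          t = 0, dt) {
  if (q$result != "EMPTY") return(q)
  p <- eval_P(dt, m)
  d <- density_at(densities[[q$type]], t)
  a <- specs[[q$type]]$affinity
  da <- d * a
  if (is.nan(da)) da <- 0   # zero density beats infinite affinity
  p_large <- min(max(p * da, 0), 1)
  if (stats::runif(1) < p_large) {
    q$result <- q$type
  } else if (as_result != "EMPTY" && stats::runif(1) < (1 - p)) {
    q$result <- as_result
  }
  q
}

#' Mark an over-age query as terminated
#'
#' A query that stays unresolved past the global process lifetime
#' `t_max` is marked terminated, so the grammar's aging rules (condition
#' `t > t_max`) rewrite its source symbol. A resolved query is never
#' terminated.
#'
#' @param q one-row query table entry.
#' @param t_max maximum process lifetime, s.
#' @export
expire_query <- function(q, t_max) {
  if (q$result == "EMPTY" && q$time > t_max) q$terminated <- TRUE
  q
}

#' Reconcile agent counts against the density targets
#'
#' For each type the target count is `round(d_type(t) * V)`
#' (round-half-to-even, so targets are deterministic); surplus agents
#' are removed uniformly at random and deficits are filled with
#' uniform-random spawns. After application every type's count equals
#' its target exactly.
#'
#' @param agents agent data frame.
#' @param densities named list of [density_schedule()]s.
#' @param domain a [make_domain()].
#' @param t simulation time, s.
#' @param start_id first id for newly spawned agents.
#' @return `list(spawn, despawn_ids, agents)`: per-type spawn counts,
#'   ids of removed agents, and the reconciled population.
#' @export
reconcile_counts <- function(agents, densities, domain, t,
                             start_id = NULL) {
  if (is.null(start_id))
    start_id <- if (nrow(agents)) max(agents$id) + 1L else 1L
  spawn <- integer()
  despawn_ids <- integer()
  for (ty in names(densities)) {
    d <- density_at(densities[[ty]], t)
    if (d < 0) stop("negative density target")
    target <- round(d * domain$volume)
    have <- sum(agents$type == ty)
    if (have > target) {
      ids <- agents$id[agents$type == ty]
      drop <- ids[sample.int(length(ids), have - target)]
      despawn_ids <- c(despawn_ids, drop)
      agents <- agents[!(agents$id %in% drop), , drop = FALSE]
    } else if (have < target) {
      n <- target - have
      spawn[ty] <- n
      new <- spawn_agents(n, ty, domain, start_id)
      start_id <- start_id + n
      agents <- rbind(agents, new)
    }
  }
  list(spawn = spawn, despawn_ids = despawn_ids, agents = agents,
       next_id = start_id)
}
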