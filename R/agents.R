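#' Agent-type specification
#'
#' @param name agent-type label (e.g. `"Dglucose"`).
#' @param D translational diffusion coefficient, model units^2 / s.
#' @param affinity dimensionless binding affinity used by the
#'   large-time-scale resolution channel (the `a_type` factor of the
#'   blend `P(dt) * d_type(t) * a_type`).
#' @param geometry placeholder geometry tag.
#' @param D_rot rotational diffusion coefficient, rad^2 / s; defaults to
#'   `D` (small molecules reorient about as fast as they translate on
#'   the model scale).
#' @export
agent_type_spec <- function(name, D = 1, affinity = 1,
                            geometry = "sphere", D_rot = D) {
  stopifnot(D >= 0, affinity >= 0, D_rot >= 0)
  list(name = name, D = D, affinity = affinity, geometry = geometry,
       D_rot = D_rot)
}

#' Simulation domain
#'
#' Cuboid box `[0, dims[1]] x [0, dims[2]] x [0, dims[3]]` with
#' reflective walls.
#'
#' @param dims positive numeric 3-vector of box dimensions.
#' @export
make_domain <- function(dims = c(20, 20, 20)) {
  stopifnot(length(dims) == 3, all(dims > 0))
  list(dims = as.numeric(dims), volume = prod(dims))
}

agent_columns <- c("id", "type", "x", "y", "z",
                   "qw", "qx", "qy", "qz", "vx", "vy", "vz")

#' Create an empty agent population
#' @export
new_agents <- function() {
  data.frame(id = integer(), type = character(),
             x = numeric(), y = numeric(), z = numeric(),
             qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric(),
             vx = numeric(), vy = numeric(), vz = numeric(),
             stringsAsFactors = FALSE)
}

#' Spawn agents uniformly in the domain
#'
#' Positions are uniform in the box, orientations uniform on the
#' rotation group.
#'
#' @param n number of agents.
#' @param type agent-type label.
#' @param domain a [make_domain()].
#' @param start_id first agent id to assign.
#' @export
spawn_agents <- function(n, type, domain, start_id = 1L) {
  if (n == 0) return(new_agents())
  q <- quat_random(n)
  data.frame(id = seq.int(start_id, length.out = n), type = type,
             x = stats::runif(n, 0, domain$dims[1]),
             y = stats::runif(n, 0, domain$dims[2]),
             z = stats::runif(n, 0, domain$dims[3]),
             qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
             vx = 0, vy = 0, vz = 0,
             stringsAsFactors = FALSE)
}

# Reflect coordinates into [0, L] (handles multiple wall crossings).
reflect_axis <- function(p, L) {
  p <- p %% (2 * L)
  over <- p > L
  p[over] <- 2 * L - p[over]
  p
}

#' Brownian step for the whole agent population
#'
#' Each position coordinate receives the standard random-walk increment
#' `sqrt(2 D dt) * xi` (`xi` standard normal) plus the drift `v * dt`
#' accumulated by [attract_step()]; walls are reflective. Orientations
#' receive a small random rotation of angle `N(0, sqrt(2 D_rot dt))`
#' about a uniform axis (rotational diffusion). Agents with `D = 0` and
#' zero drift do not move.
#'
#' @param agents agent data frame.
#' @param specs named list of [agent_type_spec()]s.
#' @param domain a [make_domain()].
#' @param dt time step, s.
#' @export
diffuse_step <- function(agents, specs, domain, dt) {
  stopifnot(dt > 0)
  n <- nrow(agents)
  if (n == 0) return(agents)
  D <- vapply(agents$type, function(ty) specs[[ty]]$D, numeric(1))
  Dr <- vapply(agents$type, function(ty) specs[[ty]]$D_rot, numeric(1))
  sdev <- sqrt(2 * D * dt)
  agents$x <- reflect_axis(agents$x + agents$vx * dt + stats::rnorm(n, 0, sdev),
                           domain$dims[1])
  agents$y <- reflect_axis(agents$y + agents$vy * dt + stats::rnorm(n, 0, sdev),
                           domain$dims[2])
  agents$z <- reflect_axis(agents$z + agents$vz * dt + stats::rnorm(n, 0, sdev),
                           domain$dims[3])
  active <- Dr > 0
  if (any(active)) {
    dq <- quat_random_small(sum(active), sqrt(2 * Dr[active] * dt))
    q <- as.matrix(agents[active, c("qw", "qx", "qy", "qz")])
    q <- quat_mul_rows(q, dq)
    q <- q / sqrt(rowSums(q^2))
    agents[active, c("qw", "qx", "qy", "qz")] <- q
  }
  agents
}

#' Bias agents toward active binding sites
#'
#' Every unresolved query attracts agents of its requested type inside
#' the attraction radius: such agents get a drift velocity of magnitude
#' `speed` pointed at the query anchor (capped so one step never
#' overshoots the anchor); all other agents get zero drift. The drift is
#' additive to diffusion and applied by the next [diffuse_step()].
#'
#' @param agents agent data frame.
#' @param queries query table ([sync_queries()]); only unresolved,
#'   non-terminated rows attract.
#' @param params `list(radius =, speed =)`, attraction radius (model
#'   units) and approach speed (units/s).
#' @param dt time step, s (used for the overshoot cap).
#' @export
attract_step <- function(agents, queries, params, dt) {
  n <- nrow(agents)
  if (n == 0) return(agents)
  agents$vx <- 0; agents$vy <- 0; agents$vz <- 0
  if (is.null(queries) || nrow(queries) == 0) return(agents)
  live <- queries[queries$result == "EMPTY" & !queries$terminated, ,
                  drop = FALSE]
  if (nrow(live) == 0) return(agents)
  best_d2 <- rep(Inf, n)
  for (k in seq_len(nrow(live))) {
    q <- live[k, ]
    sel <- agents$type == q$type
    if (!any(sel)) next
    dx <- q$x - agents$x; dy <- q$y - agents$y; dz <- q$z - agents$z
    d2 <- dx^2 + dy^2 + dz^2
    upd <- sel & d2 <= params$radius^2 & d2 < best_d2 & d2 > 0
    if (!any(upd)) next
    d <- sqrt(d2[upd])
    # cap: do not overshoot the anchor within one step
    sp <- pmin(params$speed, d / dt)
    agents$vx[upd] <- sp * dx[upd] / d
    agents$vy[upd] <- sp * dy[upd] / d
    agents$vz[upd] <- sp * dz[upd] / d
    best_d2[upd] <- d2[upd]
  }
  agents
}

#' Test whether an agent can bind at a query site
#'
#' `TRUE` iff the agent has the requested type, sits within `tol_pos` of
#' the query position, and its orientation is within `tol_ang` degrees
#' of the query orientation. On success the caller removes the agent
#' from the population and writes the agent type into the query result
#' (monomer conservation).
#'
#' @param agent one-row agent data frame (or equivalent list).
#' @param query one-row query table entry.
#' @param tol_pos positional tolerance, model units.
#' @param tol_ang angular tolerance, degrees.
#' @export
try_bind <- function(agent, query, tol_pos = 0.25, tol_ang = 30) {
  if (agent$type != query$type) return(FALSE)
  d2 <- (agent$x - query$x)^2 + (agent$y - query$y)^2 + (agent$z - query$z)^2
  if (d2 > tol_pos^2) return(FALSE)
  ang <- quat_angle(quat(agent$qw, agent$qx, agent$qy, agent$qz),
                    quat(query$qw, query$qx, query$qy, query$qz))
  ang <= tol_ang
}

#' Bind arriving agents to unresolved queries
#'
#' For each unresolved query (in table order) the nearest agent passing
#' [try_bind()] is consumed: the agent is removed and the query result
#' is set to its type. Each agent can satisfy at most one query.
#'
#' @inheritParams try_bind
#' @param agents agent data frame.
#' @param queries query table.
#' @return `list(agents, queries, bound)` where `bound` is a data frame
#'   of `(source, type, agent_id)` for this step's binding events.
#' @export
bind_queries <- function(agents, queries, tol_pos = 0.25, tol_ang = 30) {
  bound <- list()
  if (!is.null(queries) && nrow(queries) > 0 && nrow(agents) > 0) {
    for (k in seq_len(nrow(queries))) {
      if (queries$result[k] != "EMPTY" || queries$terminated[k]) next
      if (nrow(agents) == 0) break
      q <- queries[k, ]
      cand <- which(agents$type == q$type)
      if (length(cand) == 0) next
      d2 <- (agents$x[cand] - q$x)^2 + (agents$y[cand] - q$y)^2 +
        (agents$z[cand] - q$z)^2
      cand <- cand[d2 <= tol_pos^2]
      ord <- cand[order(d2[d2 <= tol_pos^2])]
      for (a in ord) {
        if (!try_bind(agents[a, ], q, tol_pos, tol_ang)) next
        queries$result[k] <- agents$type[a]
        bound[[length(bound) + 1]] <- data.frame(
          source = q$source, type = agents$type[a],
          agent_id = agents$id[a], stringsAsFactors = FALSE)
        agents <- agents[-a, , drop = FALSE]
        break
      }
    }
  }
  bound <- if (length(bound)) do.call(rbind, bound) else
    data.frame(source = integer(), type = character(),
               agent_id = integer(), stringsAsFactors = FALSE)
  list(agents = agents, queries = queries, bound = bound)
}

#' Fast-forward the population to the next binding event
#'
#' Between two binding events the monomers move so fast relative to the
#' binding time scale that there is no visual frame-to-frame
#' correlation: every agent's position is redrawn uniformly in the
#' domain and its orientation uniformly on the rotation group. Count and
#' types are preserved.
#'
#' @param agents agent data frame.
#' @param domain a [make_domain()].
#' @export
fast_forward <- function(agents, domain) {
  n <- nrow(agents)
  if (n == 0) return(agents)
  agents$x <- stats::runif(n, 0, domain$dims[1])
  agents$y <- stats::runif(n, 0, domain$dims[2])
  agents$z <- stats::runif(n, 0, domain$dims[3])
  q <- quat_random(n)
  agents$qw <- q[, 1]; agents$qx <- q[, 2]
  agents$qy <- q[, 3]; agents$qz <- q[, 4]
  agents$vx <- 0; agents$vy <- 0; agents$vz <- 0
  agents
}
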