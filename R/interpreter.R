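#' Interpreter pose
#'
#' The turtle state of the interpreter: a position in model units (one
#' monomer diameter is about 1 unit) and an orientation quaternion.
#'
#' @param pos numeric 3-vector.
#' @param ori unit quaternion ([quat()]).
#' @export
pose <- function(pos = c(0, 0, 0), ori = quat_identity()) {
  stopifnot(length(pos) == 3, is.finite(pos))
  if (!quat_is_unit(ori, 1e-6)) stop("pose orientation must be a unit quaternion")
  structure(list(pos = as.numeric(pos), ori = quat_normalize(ori)),
            class = "pose")
}

#' Advance a pose across a binding
#'
#' The binding offset is expressed in the local frame of the current
#' pose: the new position is `pos + rotate(ori, bin_pos)` and the new
#' orientation is the Hamilton product `ori * bin_ori` (local-frame,
#' right-multiplied), renormalized.
#'
#' @param state a [pose()].
#' @param bin_pos binding offset, numeric 3-vector in the local frame.
#' @param bin_ori binding rotation, unit quaternion.
#' @export
compose_pose <- function(state, bin_pos, bin_ori) {
  if (!quat_is_unit(bin_ori, 1e-6)) stop("bin_ori must be a unit quaternion")
  pose(state$pos + quat_rotate(state$ori, bin_pos),
       quat_normalize(quat_mul(state$ori, bin_ori)))
}

#' Describe one binding symbol's geometry
#'
#' @param offset local-frame offset vector between the two monomers.
#' @param axis,angle rotation between consecutive monomer frames as
#'   axis-angle, angle in degrees.
#' @param branch_start whether this binding opens a new branch (the
#'   interpreter pushes its pose, to be restored by the matching End
#'   symbol).
#' @export
binding_param <- function(offset = c(0, 0, 1), axis = c(0, 0, 1),
                          angle = 0, branch_start = FALSE) {
  list(offset = as.numeric(offset), axis = as.numeric(axis),
       angle = as.numeric(angle), branch_start = isTRUE(branch_start),
       ori = quat_axis_angle(axis, angle))
}

#' Interpret an L-string into placed 3-D geometry
#'
#' Reads the string left to right with a moving pose. Structure symbols
#' emit a placement at the current pose; Binding symbols advance the pose
#' via [compose_pose()] (pushing it first when the binding opens a
#' branch); End symbols pop the pose stack, restoring the pre-branch
#' pose, and act as plain chain terminators when no branch is open;
#' Communication symbols are stamped with the current pose as their
#' anchor, which later becomes the position/orientation of the binding
#' site queried from the agent system.
#'
#' @param s an [lstring()].
#' @param root root [pose()] of the polymer.
#' @param bindings named list of [binding_param()] entries, one per
#'   binding-symbol name.
#' @return `list(placements = <data frame>, string = <lstring with
#'   anchors>)`. The placements have one row per Structure symbol:
#'   `symbol_index, name, type, geometry, x, y, z, qw, qx, qy, qz,
#'   branch_id, branch_u, branch_theta, from_branch`.
#' @export
interpret <- function(s, root = pose(), bindings = list()) {
  syms <- unclass(s)
  cur <- root
  stack <- list()
  branch_counter <- 0L
  cur_branch <- 0L
  n <- length(syms)
  # flat accumulators; placements are typically a large fraction of n
  p_idx <- integer(n); p_name <- character(n); p_type <- character(n)
  p_geo <- character(n); p_pose <- matrix(0, n, 7)
  p_branch <- integer(n); p_u <- numeric(n); p_theta <- numeric(n)
  p_from <- logical(n)
  np <- 0L
  for (i in seq_len(n)) {
    x <- syms[[i]]
    if (x$kind == "structure") {
      np <- np + 1L
      p_idx[np] <- i; p_name[np] <- x$name; p_type[np] <- x$type
      p_geo[np] <- x$geometry
      p_pose[np, ] <- c(cur$pos, unclass(cur$ori))
      p_branch[np] <- cur_branch
      p_u[np] <- if (is.null(x$branch_u)) NA_real_ else x$branch_u
      p_theta[np] <- if (is.null(x$branch_theta)) NA_real_ else x$branch_theta
      p_from[np] <- isTRUE(x$from_branch)
    } else if (x$kind == "binding") {
      bp <- bindings[[x$name]]
      if (is.null(bp)) stop(sprintf("unknown binding symbol '%s'", x$name))
      if (bp$branch_start) {
        stack[[length(stack) + 1]] <- list(pose = cur, branch = cur_branch)
        branch_counter <- branch_counter + 1L
        cur_branch <- branch_counter
      }
      cur <- compose_pose(cur, bp$offset, bp$ori)
    } else if (x$kind == "end") {
      if (length(stack) > 0) {
        top <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        cur <- top$pose
        cur_branch <- top$branch
      }
      # an End beyond the open-branch depth terminates the main axis
    } else if (x$kind == "comm") {
      syms[[i]]$anchor <- cur
    }
  }
  k <- seq_len(np)
  placements <- data.frame(
    symbol_index = p_idx[k], name = p_name[k], type = p_type[k],
    geometry = p_geo[k],
    x = p_pose[k, 1], y = p_pose[k, 2], z = p_pose[k, 3],
    qw = p_pose[k, 4], qx = p_pose[k, 5], qy = p_pose[k, 6],
    qz = p_pose[k, 7],
    branch_id = p_branch[k], branch_u = p_u[k], branch_theta = p_theta[k],
    from_branch = p_from[k], stringsAsFactors = FALSE)
  list(placements = placements, string = lstring(syms))
}

#' Summarize an interpreted structure
#'
#' Reports monomer and branch counts and, for tubular assemblies, the
#' number of distinct longitudinal columns (protofilaments in the
#' microtubule case). Columns are found by projecting the placements
#' onto the plane orthogonal to the structure's principal axis and
#' clustering their azimuth angles with a gap threshold below the
#' inter-column spacing.
#'
#' @param placements placement data frame from [interpret()].
#' @param bin_deg angular gap (degrees) separating two columns; must be
#'   below the expected inter-column spacing (27.7 degrees for a
#'   13-protofilament tube).
#' @return list with `n_monomers`, `n_branches`, `main_chain_length`,
#'   `branch_sizes` (monomers per branch) and `n_columns`.
#' @export
measure_structure <- function(placements, bin_deg = 10) {
  if (nrow(placements) == 0) stop("no placements to measure")
  branch_tab <- table(placements$branch_id)
  branch_ids <- as.integer(names(branch_tab))
  branch_sizes <- as.integer(branch_tab)[branch_ids != 0]
  list(
    n_monomers = nrow(placements),
    n_branches = sum(branch_ids != 0),
    main_chain_length = sum(placements$branch_id == 0),
    branch_sizes = branch_sizes,
    n_columns = count_columns(placements, bin_deg)
  )
}

count_columns <- function(placements, bin_deg = 10) {
  pos <- as.matrix(placements[, c("x", "y", "z")])
  if (nrow(pos) < 2) return(1L)
  ctr <- colMeans(pos)
  centered <- sweep(pos, 2, ctr)
  axis <- fit_tube_axis(centered)
  # orthonormal in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  u <- centered %*% e1
  v <- centered %*% e2
  radial <- sqrt(u^2 + v^2)
  if (max(radial) < 0.25) return(1L)  # effectively a linear chain
  ang <- atan2(v, u) * 180 / pi
  ang <- sort(ang %% 360)
  gaps <- diff(c(ang, ang[1] + 360))
  n <- sum(gaps > bin_deg)
  max(n, 1L)
}

# Tube-axis direction: the direction minimizing the variance of the
# radial distances (a cylinder has constant radius about its axis; a
# straight chain degenerates to radius zero). Principal components and
# the coordinate axes seed a Nelder-Mead refinement -- plain PCA alone
# tilts badly on short helices because the azimuthal phase correlates
# with height.
fit_tube_axis <- function(centered) {
  r2 <- rowSums(centered^2)
  obj <- function(par) {
    d <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]),
           cos(par[1]))
    proj <- centered %*% d
    stats::var(sqrt(pmax(r2 - proj[, 1]^2, 0)))
  }
  seeds <- c(lapply(1:3, function(j)
    stats::prcomp(centered, center = FALSE)$rotation[, j]),
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  best <- NULL
  for (d0 in seeds) {
    par0 <- c(acos(max(min(d0[3], 1), -1)), atan2(d0[2], d0[1]))
    o <- stats::optim(par0, obj, method = "Nelder-Mead")
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
}
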