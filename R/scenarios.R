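#' Assemble a simulation scenario
#'
#' A scenario bundles everything needed for a run: the rule script, the
#' binding-parameter table (geometry of every binding symbol), the
#' agent-type specifications, the per-type density schedules, the root
#' pose and optional simulation-config overrides.
#'
#' @param name scenario name.
#' @param script rule-DSL source (string).
#' @param bindings named list of [binding_param()]s, one per binding
#'   symbol.
#' @param agent_types named list of [agent_type_spec()]s.
#' @param densities named list of [density_schedule()]s per agent type.
#' @param config named list of [sim_config()] overrides.
#' @param branch_rules ids of the production rules that carry the
#'   stochastic branch-versus-grow decision (used for uncertainty
#'   annotation).
#' @param root root [pose()] of the polymer.
#' @export
scenario <- function(name, script, bindings = list(), agent_types = list(),
                     densities = list(), config = list(),
                     branch_rules = character(), root = pose()) {
  rs <- parse_rule_script(script, binding_names = names(bindings))
  bsyms <- names(rs$categories)[rs$categories == "binding"]
  missing <- setdiff(bsyms, names(bindings))
  if (length(missing) > 0)
    stop(sprintf("binding symbol '%s' has no entry in the binding table",
                 missing[1]))
  undeclared <- setdiff(names(densities), names(agent_types))
  if (length(undeclared) > 0)
    stop(sprintf("density schedule for undeclared agent type '%s'",
                 undeclared[1]))
  bad_rules <- setdiff(branch_rules, names(rs$rules))
  if (length(bad_rules) > 0)
    stop(sprintf("unknown branch rule '%s'", bad_rules[1]))
  structure(list(name = name, script = script, ruleset = rs,
                 bindings = bindings, agent_types = agent_types,
                 densities = densities, config = config,
                 branch_rules = branch_rules, root = root),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d rules, %d binding symbols, %d agent types>\n",
              x$name, length(x$ruleset$rules), length(x$bindings),
              length(x$agent_types)))
  invisible(x)
}

# Affinity saturating the density channel (clamp(p * d * a) = 1 at the
# scenario's nominal density); inert when the density is zero.
sat_affinity <- function(density) if (density > 0) 1 / density else 1

branch_binding_names <- function(sc) {
  names(Filter(function(b) b$branch_start, sc$bindings))
}

#' Cellulose: linear homopolymer of D-glucose
#'
#' One structure symbol (D-glucose), one binding symbol `g` advancing by
#' one monomer diameter along the chain axis with a 180-degree rotation
#' about it (each monomer is flipped relative to its predecessor, the
#' beta-1,4 linkage geometry), a growth rule consuming the bound agent
#' and an expiry rule terminating the chain. No branching.
#'
#' @param density D-glucose density, count per model-unit^3.
#' @param t_max process lifetime limit, s.
#' @export
build_cellulose <- function(density = 0.0125, t_max = 5.0) {
  script <- paste(
    "# cellulose: unbranched D-glucose chain, consecutive monomers flipped 180 deg",
    "alphabet: m, g, E, C",
    "structure: m = Dglucose sphere",
    "binding: g",
    "end: E",
    sprintf("global: t_max = %g", t_max),
    "axiom: C(grow, Dglucose, 0, EMPTY)",
    "rule p1: C(grow,T,t,r) : r != EMPTY -> m g C(grow,T,0,EMPTY) : 1.0",
    "rule p2: C(grow,T,t,r) : t > t_max -> E : 1.0",
    sep = "\n")
  scenario(
    name = "cellulose", script = script,
    bindings = list(g = binding_param(offset = c(0, 0, 1),
                                      axis = c(0, 0, 1), angle = 180)),
    agent_types = list(Dglucose = agent_type_spec("Dglucose", D = 1,
                                                  affinity = sat_affinity(density))),
    densities = list(Dglucose = density_schedule(0, density)),
    config = list(t_max = t_max))
}

#' Poly-ADP-ribose: branched homopolymer
#'
#' Growth events draw the branch decision with probability `p_branch`
#' (rule `p1`, listed first so its independent Bernoulli draw has
#' priority); a started branching process, once an NAD agent is
#' consumed, opens a side branch through the branch-start binding `b`
#' which then grows like the main chain. The branch's closing End symbol
#' is placed together with the branch, so the string stays well-formed
#' while the branch grows; the aging rules `p4`/`p5` erase growth and
#' branching processes that outlive `t_max`.
#'
#' @param p_branch per-growth-event branching probability; the default
#'   0.05 gives the 20-25 monomers per branch characteristic of
#'   poly-ADP-ribose.
#' @param density NAD density, count per model-unit^3.
#' @param t_max process lifetime limit, s.
#' @export
build_parp <- function(p_branch = 0.05, density = 0.0125, t_max = 5.0) {
  stopifnot(p_branch >= 0, p_branch <= 1)
  script <- paste(
    "# poly-ADP-ribose: branched chain; p1 carries the branch decision",
    "alphabet: m, g, b, E, C",
    "structure: m = NAD sphere",
    "binding: g, b",
    "end: E",
    sprintf("global: t_max = %g", t_max),
    "axiom: C(grow, NAD, 0, EMPTY)",
    sprintf(
      "rule p1: C(grow,T,t,r) : r != EMPTY -> m C(branch,T,0,EMPTY) g C(grow,T,0,EMPTY) : %g",
      p_branch),
    "rule p2: C(grow,T,t,r) : r != EMPTY -> m g C(grow,T,0,EMPTY) : 1.0",
    "rule p3: C(branch,T,t,r) : r != EMPTY -> b m g C(grow,T,0,EMPTY) E : 1.0",
    "rule p4: C(grow,T,t,r) : t > t_max -> nil : 1.0",
    "rule p5: C(branch,T,t,r) : t > t_max -> nil : 1.0",
    sep = "\n")
  scenario(
    name = "parp", script = script,
    bindings = list(
      g = binding_param(offset = c(0, 0, 1), axis = c(0, 0, 1), angle = 30),
      b = binding_param(offset = c(0.7, 0, 0.7), axis = c(0, 1, 0),
                        angle = 65, branch_start = TRUE)),
    agent_types = list(NAD = agent_type_spec("NAD", D = 1,
                                             affinity = sat_affinity(density))),
    densities = list(NAD = density_schedule(0, density)),
    config = list(t_max = t_max),
    branch_rules = "p1")
}

#' Microtubule: 13-protofilament tube of tubulin dimers
#'
#' One growth event attaches a whole tubulin dimer: alpha tubulin, the
#' intra-dimer binding `v` (one monomer diameter along the tube axis),
#' beta tubulin, then the lateral inter-dimer binding `h`. `h` is the
#' constant screw transform whose repeated application winds a helix
#' with `n_protofilaments` dimers per turn and a rise of one dimer
#' height (2 units) per turn, so the longitudinal columns of the helix
#' form the protofilaments and the tubular geometry is produced
#' directly, without any sheet folding.
#'
#' @param n_protofilaments dimers per helical turn (canonically 13).
#' @param density tubulin-dimer density, count per model-unit^3.
#' @param t_max process lifetime limit, s.
#' @export
build_microtubule <- function(n_protofilaments = 13, density = 0.0125,
                              t_max = 5.0) {
  theta <- 2 * pi / n_protofilaments
  R <- 1 / (2 * sin(theta / 2))  # circumference fits n dimers of width 1
  rise <- 2 / n_protofilaments   # one dimer height (2 units) per turn
  script <- paste(
    "# microtubule: helical dimer lattice, 13 dimers per turn",
    "alphabet: a, b, v, h, E, C",
    "structure: a = alpha_tubulin sphere, b = beta_tubulin sphere",
    "binding: v, h",
    "end: E",
    "agents: tubulin",
    sprintf("global: t_max = %g", t_max),
    "axiom: C(grow, tubulin, 0, EMPTY)",
    "rule p1: C(grow,T,t,r) : r != EMPTY -> a v b h C(grow,T,0,EMPTY) : 1.0",
    "rule p2: C(grow,T,t,r) : t > t_max -> E : 1.0",
    sep = "\n")
  scenario(
    name = "microtubule", script = script,
    bindings = list(
      v = binding_param(offset = c(0, 0, 1), axis = c(0, 0, 1), angle = 0),
      h = binding_param(
        offset = c(R * (cos(theta) - 1), R * sin(theta), rise - 1),
        axis = c(0, 0, 1), angle = theta * 180 / pi)),
    agent_types = list(tubulin = agent_type_spec("tubulin", D = 1,
                                                 affinity = sat_affinity(density))),
    densities = list(tubulin = density_schedule(0, density)),
    config = list(t_max = t_max))
}

#' Synthetic showcase: helical main branch with a terminal star
#'
#' The main branch is a helix of sphere-type subunits that stochastically
#' sprouts side branches of the same type. When the main growth process
#' ages out, the star rules replace it with `star_branches` linear
#' branches whose subunits alternate between cube and cylinder types
#' with period two; the main branch stops growing from that point on.
#'
#' @param star_branches number of terminal star branches (0 gives a
#'   plain helical polymer).
#' @param p_side per-growth-event probability of sprouting a side
#'   branch.
#' @param density density shared by the three agent types.
#' @param t_max process lifetime limit, s.
#' @export
build_showcase <- function(star_branches = 5, p_side = 0.1,
                           density = 0.0125, t_max = 5.0) {
  stopifnot(star_branches >= 0)
  k <- star_branches
  star_names <- if (k > 0) paste0("u", seq_len(k)) else character()
  star_succ <- if (k > 0)
    paste(vapply(star_names, function(u)
      sprintf("%s c C(star,cylunit,0,EMPTY) E", u), character(1)),
      collapse = " ")
  else "E"
  script <- paste(
    "# synthetic showcase: helical main branch, side branches, terminal star",
    sprintf("alphabet: s, c, y, g, l, b, E, C%s%s",
            if (k > 0) ", " else "", paste(star_names, collapse = ", ")),
    "structure: s = sphereunit sphere, c = cubeunit cube, y = cylunit cylinder",
    sprintf("binding: g, l, b%s%s", if (k > 0) ", " else "",
            paste(star_names, collapse = ", ")),
    "end: E",
    sprintf("global: t_max = %g", t_max),
    "axiom: C(grow, sphereunit, 0, EMPTY)",
    sprintf(
      "rule p1: C(grow,T,t,r) : r != EMPTY -> s C(branch,T,0,EMPTY) g C(grow,T,0,EMPTY) : %g",
      p_side),
    "rule p2: C(grow,T,t,r) : r != EMPTY -> s g C(grow,T,0,EMPTY) : 1.0",
    "rule p3: C(branch,T,t,r) : r != EMPTY -> b s g C(sidegrow,T,0,EMPTY) E : 1.0",
    "rule p4: C(sidegrow,T,t,r) : r != EMPTY -> s g C(sidegrow,T,0,EMPTY) : 1.0",
    "rule p5: C(sidegrow,T,t,r) : t > t_max -> nil : 1.0",
    "rule p6: C(branch,T,t,r) : t > t_max -> nil : 1.0",
    sprintf("rule p7: C(grow,T,t,r) : t > t_max -> %s : 1.0", star_succ),
    "rule p8: C(star,cylunit,t,r) : r != EMPTY -> l y C(star,cubeunit,0,EMPTY) : 1.0",
    "rule p9: C(star,cubeunit,t,r) : r != EMPTY -> l c C(star,cylunit,0,EMPTY) : 1.0",
    "rule p10: C(star,T,t,r) : t > t_max -> nil : 1.0",
    sep = "\n")
  bindings <- list(
    # constant screw: offset along local z, rotation about a tilted axis
    g = binding_param(offset = c(0, 0, 1), axis = c(0.25, 0, 0.97),
                      angle = 40),
    l = binding_param(offset = c(0, 0, 1), axis = c(0, 0, 1), angle = 0),
    b = binding_param(offset = c(0.7, 0, 0.7), axis = c(0, 1, 0),
                      angle = 65, branch_start = TRUE))
  for (i in seq_len(k)) {
    # star branch i: spread 60 deg off the axis, azimuth i * 360 / k
    q <- quat_mul(quat_axis_angle(c(0, 0, 1), (i - 1) * 360 / k),
                  quat_axis_angle(c(0, 1, 0), 60))
    aa <- quat_to_axis_angle(q)
    bindings[[star_names[i]]] <- binding_param(
      offset = quat_rotate(q, c(0, 0, 1)), axis = aa$axis,
      angle = aa$angle, branch_start = TRUE)
  }
  types <- list(
    sphereunit = agent_type_spec("sphereunit", D = 1,
                                 affinity = 1 / density),
    cubeunit = agent_type_spec("cubeunit", D = 1, affinity = sat_affinity(density),
                               geometry = "cube"),
    cylunit = agent_type_spec("cylunit", D = 1, affinity = sat_affinity(density),
                              geometry = "cylinder"))
  scenario(
    name = "showcase", script = script, bindings = bindings,
    agent_types = types,
    densities = list(sphereunit = density_schedule(0, density),
                     cubeunit = density_schedule(0, density),
                     cylunit = density_schedule(0, density)),
    config = list(t_max = t_max),
    branch_rules = "p1")
}

# Recover an axis-angle (degrees) from a unit quaternion.
quat_to_axis_angle <- function(q) {
  q <- unclass(quat_normalize(q))
  if (q[1] < 0) q <- -q
  ang <- 2 * acos(min(q[1], 1)) * 180 / pi
  s <- sqrt(max(1 - q[1]^2, 0))
  axis <- if (s < 1e-12) c(0, 0, 1) else q[2:4] / s
  list(axis = axis, angle = ang)
}

#' Annotate placements with branching uncertainty
#'
#' For every monomer created by a growth event in which a branch rule
#' competed, the derivation recorded the uniform draw `u` and the
#' branching threshold `theta`. Monomers that actually started a branch
#' get `uncertainty = exp(-(u - theta)^2 / (2 sigma^2))` -- a Gaussian
#' kernel of the draw around the threshold, peak-normalized to 1, so a
#' draw right at the decision boundary is maximally uncertain. Monomers
#' from plain growth events instead carry the branch probability that
#' was in force.
#'
#' @param placements placement data frame from [interpret()] carrying
#'   the derivation provenance columns (`branch_u`, `branch_theta`,
#'   `from_branch`).
#' @param sigma kernel bandwidth on the probability axis.
#' @return the placements with `uncertainty` and `branch_probability`
#'   columns added.
#' @export
annotate_uncertainty <- function(placements, sigma = 0.1) {
  if (!all(c("branch_u", "branch_theta", "from_branch") %in%
           names(placements)))
    stop("placements carry no rule history (derive the string with its scenario first)")
  u <- placements$branch_u
  th <- placements$branch_theta
  placements$uncertainty <- ifelse(
    placements$from_branch, exp(-(u - th)^2 / (2 * sigma^2)), NA_real_)
  placements$branch_probability <- ifelse(
    !placements$from_branch & !is.na(th), th, NA_real_)
  placements
}

#' Write a scenario bundle to a directory
#'
#' A bundle is a directory holding `rules.txt` (the DSL script) and
#' `config.yaml` (bindings, agent types, densities, overrides).
#'
#' @param sc a [scenario()].
#' @param dir target directory (created if needed).
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(sc$script, file.path(dir, "rules.txt"))
  cfg <- list(
    name = sc$name,
    bindings = lapply(sc$bindings, function(b)
      list(offset = b$offset, axis = b$axis, angle = b$angle,
           branch_start = b$branch_start)),
    agents = lapply(sc$agent_types, function(a)
      list(D = a$D, affinity = a$affinity, geometry = a$geometry,
           D_rot = a$D_rot)),
    densities = lapply(sc$densities, function(d)
      list(t = d$t, density = d$density)),
    config = sc$config,
    branch_rules = as.list(sc$branch_rules),
    root = list(position = sc$root$pos,
                orientation = as.numeric(sc$root$ori)))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a scenario bundle from a directory
#'
#' @param dir bundle directory containing `rules.txt` and `config.yaml`.
#' @export
load_scenario <- function(dir) {
  rules_path <- file.path(dir, "rules.txt")
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(rules_path) || !file.exists(cfg_path))
    stop(sprintf("'%s' is not a scenario bundle (rules.txt + config.yaml)", dir))
  script <- paste(readLines(rules_path), collapse = "\n")
  cfg <- yaml::read_yaml(cfg_path)
  bindings <- lapply(cfg$bindings, function(b)
    binding_param(unlist(b$offset), unlist(b$axis), b$angle,
                  isTRUE(b$branch_start)))
  agent_types <- list()
  for (nm in names(cfg$agents)) {
    a <- cfg$agents[[nm]]
    agent_types[[nm]] <- agent_type_spec(nm, a$D, a$affinity, a$geometry,
                                         a$D_rot)
  }
  densities <- lapply(cfg$densities, function(d)
    density_schedule(unlist(d$t), unlist(d$density)))
  ori <- if (is.null(cfg$root$orientation)) quat_identity() else
    quat(cfg$root$orientation[1], cfg$root$orientation[2],
         cfg$root$orientation[3], cfg$root$orientation[4])
  root <- pose(if (is.null(cfg$root$position)) c(0, 0, 0) else
    unlist(cfg$root$position), ori)
  scenario(name = cfg$name, script = script, bindings = bindings,
           agent_types = agent_types, densities = densities,
           config = if (is.null(cfg$config)) list() else cfg$config,
           branch_rules = unlist(cfg$branch_rules) %||% character(),
           root = root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' List or fetch the packaged scenario bundles
#'
#' @param name one of `"cellulose"`, `"parp"`, `"microtubule"`,
#'   `"showcase"`; omit to list the available names.
#' @export
packaged_scenario <- function(name = NULL) {
  base <- system.file("extdata", "scenarios", package = "polymersim")
  if (is.null(name)) return(list.dirs(base, recursive = FALSE,
                                      full.names = FALSE))
  dir <- file.path(base, name)
  if (!dir.exists(dir))
    stop(sprintf("no packaged scenario '%s'", name))
  load_scenario(dir)
}
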