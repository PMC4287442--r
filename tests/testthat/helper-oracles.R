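# Independent oracles used across the suite.

# Quaternion (w,x,y,z) -> rotation matrix, written independently of the
# package's converter.
oracle_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

# 4x4 homogeneous transform from a pose-like (pos, quat) pair.
oracle_homog <- function(pos, q) {
  M <- diag(4)
  M[1:3, 1:3] <- oracle_rotmat(q)
  M[1:3, 4] <- pos
  M
}

# Textbook D0L rewrite on plain character vectors.
oracle_d0l <- function(axiom, rules, n) {
  s <- axiom
  for (i in seq_len(n)) {
    s <- unlist(lapply(s, function(ch) {
      if (ch %in% names(rules)) rules[[ch]] else ch
    }))
  }
  s
}

# Tiny two-rule reference grammar: grow on a delivered result, expire
# past t_max.
example_ruleset <- function(t_max = 5.0) {
  parse_rule_script(paste(
    "alphabet: m, g, E, C",
    "structure: m = molecule sphere",
    "binding: g",
    "end: E",
    sprintf("global: t_max = %g", t_max),
    "axiom: C(grow, molecule, 0, EMPTY)",
    "rule p1: C(grow,T,t,r) : r != EMPTY -> m g C(grow,T,0,EMPTY) : 1.0",
    "rule p2: C(grow,T,t,r) : t > t_max -> E : 1.0",
    sep = "\n"))
}

# A density-steering scenario with no binding processes: one inert
# structure symbol, two diffusing types with crossing density ramps.
ramp_scenario <- function(VA = c(0.0125, 0.0025), VB = c(0.0025, 0.0125),
                          t_end = 5) {
  scenario(
    name = "ramp",
    script = paste(
      "alphabet: m",
      "structure: m = A sphere",
      "agents: B",
      "axiom: m",
      sep = "\n"),
    agent_types = list(A = agent_type_spec("A", D = 1),
                       B = agent_type_spec("B", D = 1)),
    densities = list(A = density_schedule(c(0, t_end), VA),
                     B = density_schedule(c(0, t_end), VB)))
}

# Deterministic large-time-scale config: dt far above the switching
# threshold, so growth is driven by the (saturating) density channel.
large_scale <- function(steps, seed = 1) {
  list(dt = 5, steps = steps, seed = seed)
}

row_quat <- function(df, i) quat(df$qw[i], df$qx[i], df$qy[i], df$qz[i])
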