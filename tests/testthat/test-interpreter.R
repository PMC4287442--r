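test_that("pose composition matches the homogeneous-matrix oracle", {
  # identity cases
  p <- compose_pose(pose(), c(0, 0, 1), quat_identity())
  expect_equal(p$pos, c(0, 0, 1))
  expect_equal(quat_angle(p$ori), 0)
  # a 180-degree rotation applied twice is the identity rotation
  flip <- quat_axis_angle(c(0, 0, 1), 180)
  p2 <- compose_pose(compose_pose(pose(), c(0, 0, 0), flip), c(0, 0, 0), flip)
  expect_equal(quat_angle(p2$ori), 0, tolerance = 1e-9)
  # random poses against 4x4 matrix composition
  set.seed(3)
  for (i in 1:25) {
    q0 <- quat_normalize(quat(rnorm(1), rnorm(1), rnorm(1), rnorm(1)))
    qb <- quat_normalize(quat(rnorm(1), rnorm(1), rnorm(1), rnorm(1)))
    p0 <- rnorm(3); off <- rnorm(3)
    got <- compose_pose(pose(p0, q0), off, qb)
    M <- oracle_homog(p0, unclass(q0)) %*% oracle_homog(off, unclass(qb))
    expect_equal(got$pos, M[1:3, 4], tolerance = 1e-9)
    expect_equal(quat_to_matrix(got$ori), M[1:3, 1:3], tolerance = 1e-9)
  }
  expect_error(compose_pose(pose(), c(0, 0, 1), quat(2, 0, 0, 0)), "unit")
})

test_that("interpretation walks the string and handles the empty case", {
  out <- interpret(lstring(), pose(c(1, 2, 3)))
  expect_equal(nrow(out$placements), 0)
  # m g m with a 180-degree flip binding: unit spacing, flipped frames
  bindings <- list(g = binding_param(c(0, 0, 1), c(0, 0, 1), 180))
  s <- lstring(list(sym_structure("m", "molecule"), sym_binding("g"),
                    sym_structure("m", "molecule")))
  pl <- interpret(s, pose(), bindings)$placements
  expect_equal(nrow(pl), 2)
  d <- sqrt(sum((pl[2, c("x", "y", "z")] - pl[1, c("x", "y", "z")])^2))
  expect_equal(d, 1, tolerance = 1e-9)
  expect_equal(quat_angle(row_quat(pl, 1), row_quat(pl, 2)), 180,
               tolerance = 1e-9)
})

test_that("branch push/pop restores the pose exactly (de-branching oracle)", {
  bindings <- list(
    g = binding_param(c(0, 0, 1), c(0, 0, 1), 30),
    b = binding_param(c(0.7, 0, 0.7), c(0, 1, 0), 65, branch_start = TRUE))
  mk <- function(...) lstring(list(...))
  m <- function() sym_structure("m", "molecule")
  branched <- mk(m(), sym_binding("b"), m(), sym_end(), sym_binding("g"), m())
  plain <- mk(m(), sym_binding("g"), m())
  pb <- interpret(branched, pose(), bindings)$placements
  pp <- interpret(plain, pose(), bindings)$placements
  # the post-branch monomer sits exactly where it would without the branch
  expect_equal(unlist(pb[3, c("x", "y", "z")]),
               unlist(pp[2, c("x", "y", "z")]), tolerance = 1e-12)
  expect_equal(pb$branch_id, c(0, 1, 0))
  # communication anchors take the pose at their string position
  cs <- mk(m(), sym_binding("g"), sym_comm("C", "grow", "molecule"))
  anch <- unclass(interpret(cs, pose(), bindings)$string)[[3]]$anchor
  expect_equal(anch$pos, unlist(pp[2, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(interpret(mk(m(), sym_binding("x")), pose(), bindings),
               "unknown binding")
})

test_that("interpretation is rigid-motion equivariant and idempotent", {
  sc <- build_parp(p_branch = 0.5)
  set.seed(5)
  s <- sc$ruleset$axiom
  for (i in 1:6) {
    s <- set_results(s, data.frame(
      source = which(vapply(unclass(s), function(x)
        x$kind == "comm" && x$r == "EMPTY", logical(1))),
      result = "NAD"))
    s <- derive(s, sc$ruleset)
  }
  base <- interpret(s, pose(), sc$bindings)$placements
  again <- interpret(s, pose(), sc$bindings)$placements
  expect_identical(base, again)
  # transformed root: all placements move by the same rigid motion
  q <- quat_axis_angle(c(1, 2, 3), 77)
  shift <- c(4, -5, 6)
  moved <- interpret(s, pose(shift, q), sc$bindings)$placements
  R <- quat_to_matrix(q)
  expected <- t(R %*% t(as.matrix(base[, c("x", "y", "z")]))) +
    matrix(shift, nrow(base), 3, byrow = TRUE)
  expect_equal(as.matrix(moved[, c("x", "y", "z")]), expected,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("structure measurement counts chains, branches and helix columns", {
  expect_error(measure_structure(interpret(lstring())$placements), "no placements")
  one <- interpret(lstring(list(sym_structure("m", "a"))))$placements
  m1 <- measure_structure(one)
  expect_equal(m1$n_monomers, 1)
  expect_equal(m1$n_branches, 0)
  # linear 10-mer
  b <- list(g = binding_param(c(0, 0, 1), c(0, 0, 1), 180))
  syms <- list()
  for (i in 1:10) {
    syms[[length(syms) + 1]] <- sym_structure("m", "a")
    if (i < 10) syms[[length(syms) + 1]] <- sym_binding("g")
  }
  m10 <- measure_structure(interpret(lstring(syms), pose(), b)$placements)
  expect_equal(m10$n_monomers, 10)
  expect_equal(m10$main_chain_length, 10)
  expect_equal(m10$n_branches, 0)
  expect_equal(m10$n_columns, 1)
  # constructed helix: 13 placements per turn over 3 turns -> 13 columns
  n_per <- 13; theta <- 2 * pi / n_per; R <- 1 / (2 * sin(theta / 2))
  k <- 0:(3 * n_per - 1)
  helix <- data.frame(
    symbol_index = k + 1, name = "m", type = "a", geometry = "sphere",
    x = R * cos(k * theta), y = R * sin(k * theta), z = k * 2 / n_per,
    qw = 1, qx = 0, qy = 0, qz = 0, branch_id = 0L,
    branch_u = NA_real_, branch_theta = NA_real_, from_branch = FALSE)
  expect_equal(measure_structure(helix)$n_columns, 13)
})

test_that("well-formedness tracks branch-start/end balance", {
  m <- sym_structure("m", "a")
  expect_true(lstring_well_formed(
    lstring(list(m, sym_binding("b"), m, sym_end())), "b"))
  expect_false(lstring_well_formed(
    lstring(list(m, sym_binding("b"), m)), "b"))
  # terminal End beyond branch depth is a plain chain terminator
  expect_true(lstring_well_formed(lstring(list(m, sym_end())), "b"))
})
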