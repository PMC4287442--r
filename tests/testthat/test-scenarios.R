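test_that("packaged bundles load and mirror the programmatic builders", {
  names <- packaged_scenario()
  expect_setequal(names, c("cellulose", "parp", "microtubule", "showcase"))
  for (nm in names) {
    sc <- packaged_scenario(nm)
    expect_s3_class(sc, "scenario")
    built <- switch(nm, cellulose = build_cellulose(), parp = build_parp(),
                    microtubule = build_microtubule(),
                    showcase = build_showcase())
    expect_equal(sc$script, built$script)
    expect_equal(names(sc$bindings), names(built$bindings))
    expect_equal(sc$branch_rules, built$branch_rules)
  }
  expect_error(packaged_scenario("nonesuch"), "no packaged scenario")
})

test_that("cellulose grows a single unbranched chain of flipped monomers", {
  res <- run(build_cellulose(), config = large_scale(22, seed = 4))
  pl <- res$placements
  m <- measure_structure(pl)
  expect_gte(m$n_monomers, 20)
  expect_equal(m$n_branches, 0)
  expect_equal(m$main_chain_length, m$n_monomers)
  for (i in seq_len(nrow(pl) - 1))
    expect_equal(quat_angle(row_quat(pl, i), row_quat(pl, i + 1)), 180,
                 tolerance = 1e-9)
  # starvation: zero density means the chain never grows
  starved <- run(build_cellulose(density = 0), config = large_scale(20, 4))
  expect_equal(nrow(starved$placements), 0)
})

test_that("poly-ADP-ribose branching follows the configured probability", {
  # degenerate case: no branching reduces to a linear chain
  lin <- run(build_parp(p_branch = 0), config = large_scale(30, seed = 8))
  ml <- measure_structure(lin$placements)
  expect_equal(ml$n_branches, 0)
  expect_equal(ml$main_chain_length, ml$n_monomers)
  # stochastic case: branch rate among growth events matches p_branch,
  # and every opened branch is closed (string stays well-formed)
  res <- run(build_parp(p_branch = 0.1), config = large_scale(70, seed = 9))
  expect_true(lstring_well_formed(res$state$string, "b"))
  ev <- res$events
  dec <- ev[!is.na(ev$theta) & ev$rule %in% c("p1", "p2"), ]
  n <- nrow(dec)
  k <- sum(dec$is_branch)
  expect_gt(n, 200)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(k / n - 0.1), 3 * se)
  m <- measure_structure(res$placements)
  expect_gt(m$n_branches, 0)
})

test_that("the microtubule assembles 13 protofilaments of alternating tubulins", {
  res <- run(build_microtubule(), config = large_scale(45, seed = 2))
  pl <- res$placements
  expect_gte(nrow(pl), 2 * 39)   # at least three full turns of dimers
  m <- measure_structure(pl)
  expect_equal(m$n_columns, 13)
  expect_equal(m$n_branches, 0)
  types <- pl$type
  expect_true(all(types[seq(1, length(types), 2)] == "alpha_tubulin"))
  expect_true(all(types[seq(2, length(types), 2)] == "beta_tubulin"))
  # the tube is produced directly: monomers over whole turns sit on one
  # cylinder wall (centering needs balanced turns)
  whole <- pl[seq_len(2 * 39), ]
  cent <- scale(as.matrix(whole[, c("x", "y")]), scale = FALSE)
  radial <- sqrt(rowSums(cent^2))
  expect_lt(max(radial) - min(radial), 1e-6)
})

test_that("the showcase ends its main branch in an alternating star", {
  sc <- build_showcase(star_branches = 5, p_side = 0.05)
  res <- run(sc, config = list(dt = 5, steps = 45, seed = 5,
    steering = list(list(t = 100, type = "sphereunit", density = 0))))
  pl <- res$placements
  star_ids <- unique(pl$branch_id[pl$type %in% c("cubeunit", "cylunit")])
  expect_length(star_ids, 5)
  for (b in star_ids) {
    ty <- pl$type[pl$branch_id == b]
    expect_equal(ty, rep(c("cubeunit", "cylunit"), length.out = length(ty)))
  }
  # the main branch stops growing once the star fires
  lg <- res$log
  star_step <- min(lg$step[lg$t > 100 + 10])
  main_before <- sum(pl$type == "sphereunit" & pl$branch_id == 0)
  res2 <- run(sc, config = list(dt = 5, steps = 60, seed = 5,
    steering = list(list(t = 100, type = "sphereunit", density = 0))))
  main_after <- sum(res2$placements$type == "sphereunit" &
                      res2$placements$branch_id == 0)
  expect_equal(main_after, main_before)
  # zero star branches degenerate to a plain (possibly side-branched) helix
  sc0 <- build_showcase(star_branches = 0, p_side = 0)
  res0 <- run(sc0, config = list(dt = 5, steps = 30, seed = 5,
    steering = list(list(t = 75, type = "sphereunit", density = 0))))
  expect_true(all(res0$placements$type == "sphereunit"))
  expect_equal(measure_structure(res0$placements)$n_branches, 0)
})

test_that("branching uncertainty is a peak-normalized Gaussian of the draw", {
  pl <- data.frame(symbol_index = 1:3, name = "m", type = "NAD",
                   geometry = "sphere", x = 0, y = 0, z = 0,
                   qw = 1, qx = 0, qy = 0, qz = 0, branch_id = 0L,
                   branch_u = c(0.05, 0.55, 0.02),
                   branch_theta = c(0.05, 0.05, 0.05),
                   from_branch = c(TRUE, TRUE, FALSE))
  ann <- annotate_uncertainty(pl, sigma = 0.1)
  expect_equal(ann$uncertainty[1], 1.0)                 # draw at threshold
  expect_lt(ann$uncertainty[2], 1e-4)                   # |u - theta| = 5 sigma
  expect_true(is.na(ann$uncertainty[3]))
  expect_equal(ann$branch_probability[3], 0.05)
  expect_error(annotate_uncertainty(pl[, 1:11]), "history")
  # a run without branching carries no branch uncertainty
  res <- run(build_parp(p_branch = 0), config = large_scale(20, seed = 3))
  ann0 <- annotate_uncertainty(res$placements)
  expect_true(all(is.na(ann0$uncertainty)))
})

test_that("all scenarios run at the default agent-scale config and only grow", {
  for (nm in c("cellulose", "parp", "microtubule", "showcase")) {
    sc <- packaged_scenario(nm)
    res <- run(sc, config = list(steps = 500, seed = 6))
    counts <- res$log$n_structure
    expect_true(all(diff(counts) >= 0),
                info = paste(nm, "structure count must never decrease"))
    expect_gt(max(counts), 0, label = paste(nm, "grew at least one monomer"))
  }
})
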