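test_that("the reference derivation cases of the growth grammar reproduce exactly", {
  rs <- example_ruleset(t_max = 5.0)
  # pending process, no result: string unchanged
  s <- age_processes(rs$axiom, 0.05)
  expect_equal(format(derive(s, rs)), "C(grow,molecule,0.05,EMPTY)")
  # result delivered: one new monomer + fresh growth process
  s2 <- set_results(s, data.frame(source = 1, result = "molecule"))
  d2 <- derive(s2, rs)
  expect_equal(format(d2), "m g C(grow,molecule,0,EMPTY)")
  expect_equal(count_symbols(d2, "structure"), 1)
  # over-age process: rewritten to the End symbol
  s3 <- age_processes(rs$axiom, 5.05)
  d3 <- derive(s3, rs)
  expect_equal(format(d3), "E")
  expect_equal(count_symbols(d3, "comm"), 0)
})

test_that("rule matching honours parameters, conditions and literals", {
  rs <- example_ruleset(t_max = 5.0)
  p1 <- rs$rules$p1; p2 <- rs$rules$p2
  pending <- sym_comm("C", "grow", "molecule", t = 0.05, r = "EMPTY")
  done <- sym_comm("C", "grow", "molecule", t = 0.05, r = "molecule")
  old <- sym_comm("C", "grow", "molecule", t = 5.05, r = "EMPTY")
  expect_null(match_rule(pending, p1, rs))
  b <- match_rule(done, p1, rs)
  expect_equal(b$t, 0.05)
  expect_equal(b$r, "molecule")
  expect_null(match_rule(pending, p2, rs))
  expect_false(is.null(match_rule(old, p2, rs)))
  # literal parameter in the predecessor gates on the symbol's value
  rs2 <- parse_rule_script(paste(
    "alphabet: m, C",
    "structure: m = molecule",
    "axiom: C(grow, molecule, 0, EMPTY)",
    "rule q1: C(grow,molecule,t,r) : r != EMPTY -> m : 1.0",
    sep = "\n"))
  other <- sym_comm("C", "grow", "other", t = 0, r = "other")
  expect_null(match_rule(other, rs2$rules$q1, rs2))
})

test_that("rule selection is per-rule Bernoulli with first-wins resolution", {
  mk <- function(p, id) list(rule = list(id = id, probability = p), bindings = list())
  set.seed(42)
  for (i in 1:50) expect_equal(select_rule(list(mk(1, "a")))$rule$id, "a")
  for (i in 1:50) expect_null(select_rule(list(mk(0, "a"))))
  # brute-force oracle over the four joint outcomes of two draws
  p1 <- 0.3; p2 <- 0.7
  oracle <- c(first = p1,                 # rule 1 fires (wins regardless)
              second = (1 - p1) * p2,     # only rule 2 fires
              none = (1 - p1) * (1 - p2))
  n <- 1e5
  set.seed(7)
  picks <- replicate(n, {
    sel <- select_rule(list(mk(p1, "first"), mk(p2, "second")))
    if (is.null(sel)) "none" else sel$rule$id
  })
  freq <- table(factor(picks, levels = names(oracle))) / n
  for (k in names(oracle)) {
    se <- sqrt(oracle[[k]] * (1 - oracle[[k]]) / n)
    expect_lt(abs(freq[[k]] - oracle[[k]]), 3 * se)
  }
})

test_that("derivation is parallel, context-free and deterministic under a seed", {
  sc <- build_parp(p_branch = 0.3)
  rs <- sc$ruleset
  s <- lstring(list(
    sym_comm("C", "grow", "NAD", t = 1, r = "NAD"),
    sym_structure("m", "NAD"),
    sym_comm("C", "branch", "NAD", t = 0.5, r = "NAD"),
    sym_comm("C", "grow", "NAD", t = 6, r = "EMPTY")))
  set.seed(11)
  whole <- derive(s, rs)
  # context-free: per-symbol derivation with the same draws concatenates
  set.seed(11)
  parts <- lapply(seq_along(unclass(s)), function(i) derive(s[i], rs))
  part_syms <- unlist(lapply(parts, function(p)
    vapply(unclass(p), format, character(1))))
  expect_equal(vapply(unclass(whole), format, character(1)), part_syms)
  # determinism
  set.seed(99)
  a <- derive(s, rs)
  set.seed(99)
  b <- derive(s, rs)
  expect_identical(format(a), format(b))
})

test_that("deterministic grammars match a textbook D0L oracle", {
  rs <- parse_rule_script(paste(
    "alphabet: a, b",
    "axiom: a",
    "rule r1: a -> a b : 1.0",
    "rule r2: b -> a : 1.0",
    sep = "\n"))
  rules <- list(a = c("a", "b"), b = "a")
  s <- rs$axiom
  chars <- "a"
  for (step in 1:8) {
    s <- derive(s, rs)
    chars <- oracle_d0l(chars, rules, 1)
    expect_equal(vapply(unclass(s), function(x) x$name, character(1)), chars)
  }
  # Fibonacci word lengths as a cross-check
  expect_length(unclass(s), length(oracle_d0l("a", rules, 8)))
})

test_that("process aging is exact, additive and touches only communication symbols", {
  rs <- example_ruleset()
  s <- lstring(list(sym_structure("m", "molecule"), sym_binding("g"),
                    sym_comm("C", "grow", "molecule")))
  expect_equal(format(age_processes(s, 0)), format(s))
  aged <- s
  for (i in 1:101) aged <- age_processes(aged, 0.05)
  expect_equal(unclass(aged)[[3]]$t, 5.05, tolerance = 1e-9)
  expect_equal(unclass(aged)[[1]], unclass(s)[[1]])
  expect_error(age_processes(s, -0.1), "non-negative")
  no_comm <- lstring(list(sym_structure("m", "molecule")))
  expect_equal(format(age_processes(no_comm, 1)), format(no_comm))
})

test_that("result write-back targets only communication symbols", {
  rs <- example_ruleset()
  s <- lstring(list(sym_structure("m", "molecule"),
                    sym_comm("C", "grow", "molecule")))
  s2 <- set_results(s, data.frame(source = 2, result = "molecule"))
  expect_equal(unclass(s2)[[2]]$r, "molecule")
  expect_error(set_results(s, data.frame(source = 1, result = "molecule")),
               "not a communication symbol")
})
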