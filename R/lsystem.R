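#' L-system symbols
#'
#' The grammar alphabet falls into four semantic categories:
#' * **Structure** symbols place a monomer (they carry the agent type and a
#'   placeholder geometry tag),
#' * **Binding** symbols advance the interpreter pose between two monomers
#'   and may open a branch,
#' * **End** symbols close a branch (or terminate the main axis),
#' * **Communication** symbols `C(process, type, t, r)` represent an
#'   in-progress process (growing, branching) that awaits a result `r`
#'   from the environment; `t` is the elapsed process lifetime in seconds.
#'
#' `r` is the reserved literal `"EMPTY"` until an agent of the requested
#' type arrives (or the density channel fires), after which it holds the
#' agent-type label.
#'
#' @param name symbol name as declared in the alphabet.
#' @param type agent-type label of the monomer / requested agent.
#' @param geometry placeholder geometry tag (`"sphere"`, `"cube"`,
#'   `"cylinder"`).
#' @return a list with class `"lsymbol"`.
#' @export
sym_structure <- function(name, type, geometry = "sphere") {
  structure(list(kind = "structure", name = name, type = type,
                 geometry = geometry), class = "lsymbol")
}

#' @rdname sym_structure
#' @export
sym_binding <- function(name) {
  structure(list(kind = "binding", name = name), class = "lsymbol")
}

#' @rdname sym_structure
#' @export
sym_end <- function(name = "E") {
  structure(list(kind = "end", name = name), class = "lsymbol")
}

#' @rdname sym_structure
#' @param process process identifier (e.g. `"grow"`, `"branch"`).
#' @param t elapsed process time in seconds.
#' @param r process result: `"EMPTY"` or an agent-type label.
#' @export
sym_comm <- function(name, process, type, t = 0, r = "EMPTY") {
  stopifnot(t >= 0)
  structure(list(kind = "comm", name = name, process = process, type = type,
                 t = t, r = r, anchor = NULL), class = "lsymbol")
}

#' @export
format.lsymbol <- function(x, ...) {
  if (x$kind == "comm")
    sprintf("%s(%s,%s,%g,%s)", x$name, x$process, x$type, x$t, x$r)
  else x$name
}

#' @export
print.lsymbol <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Create an L-system string
#'
#' An L-string is an ordered list of [sym_structure()]-family symbols.
#'
#' @param symbols list of `lsymbol` objects.
#' @export
lstring <- function(symbols = list()) {
  stopifnot(all(vapply(symbols, inherits, logical(1), "lsymbol")))
  structure(symbols, class = "lstring")
}

#' @export
format.lstring <- function(x, ...) {
  paste(vapply(unclass(x), format, character(1)), collapse = " ")
}

#' @export
print.lstring <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`[.lstring` <- function(x, i) {
  lstring(unclass(x)[i])
}

#' Count symbols of one semantic category in an L-string
#' @param s an [lstring()].
#' @param kind one of `"structure"`, `"binding"`, `"end"`, `"comm"`.
#' @export
count_symbols <- function(s, kind) {
  sum(vapply(unclass(s), function(x) x$kind == kind, logical(1)))
}

#' Check branch well-formedness of an L-string
#'
#' Every branch opened by a binding symbol with `branch_start = TRUE`
#' must eventually be closed by an End symbol. End symbols beyond the
#' open-branch depth terminate the main axis and are permitted.
#'
#' @param s an [lstring()].
#' @param branch_bindings names of binding symbols that open a branch.
#' @return `TRUE` if well-formed, otherwise `FALSE`.
#' @export
lstring_well_formed <- function(s, branch_bindings = character()) {
  depth <- 0L
  for (x in unclass(s)) {
    if (x$kind == "binding" && x$name %in% branch_bindings) depth <- depth + 1L
    if (x$kind == "end" && depth > 0L) depth <- depth - 1L
  }
  depth == 0L
}

#' Advance the elapsed time of every pending process
#'
#' Adds `dt` to the lifetime parameter `t` of every Communication symbol;
#' all other symbols are untouched. The driver calls this once per
#' simulation step, before derivation, so that `t` accumulates simulation
#' time and aging conditions such as `t > t_max` can fire.
#'
#' @param s an [lstring()].
#' @param dt time increment in seconds, `>= 0`.
#' @export
age_processes <- function(s, dt) {
  if (dt < 0) stop("dt must be non-negative")
  if (dt == 0) return(s)
  lstring(lapply(unclass(s), function(x) {
    if (x$kind == "comm") x$t <- x$t + dt
    x
  }))
}

#' Match one symbol against one production rule
#'
#' A rule matches when the symbol has the predecessor's name (and, for
#' Communication predecessors, its process identifier and any literal
#' parameters), and the rule condition evaluates to `TRUE` under the
#' parameter bindings. Literal predecessor parameters are numbers, the
#' `EMPTY` sentinel and declared agent-type labels; other identifiers are
#' pattern variables.
#'
#' @param symbol an `lsymbol`.
#' @param rule a rule from a [parse_rule_script()] rule set.
#' @param rs the enclosing rule set (supplies globals and declared names).
#' @return A named list of variable bindings, or `NULL` if no match.
#' @export
match_rule <- function(symbol, rule, rs) {
  p <- rule$pred
  if (symbol$name != p$name) return(NULL)
  bindings <- list()
  if (!is.null(p$args)) {
    if (symbol$kind != "comm") return(NULL)
    vals <- list(symbol$process, symbol$type, symbol$t, symbol$r)
    for (i in seq_along(p$args)) {
      a <- p$args[[i]]
      if (a$kind == "var") {
        bindings[[a$value]] <- vals[[i]]
      } else if (!identical(as.character(vals[[i]]), as.character(a$value)) &&
                 !(is.numeric(vals[[i]]) && suppressWarnings(
                   isTRUE(vals[[i]] == as.numeric(a$value))))) {
        return(NULL)
      }
    }
  }
  if (!is.null(rule$condition)) {
    env <- cond_env(bindings, rs)
    ok <- tryCatch(eval(rule$condition, env),
                   error = function(e)
                     stop(sprintf("rule %s: condition error: %s",
                                  rule$id, conditionMessage(e)), call. = FALSE))
    if (!isTRUE(ok)) return(NULL)
  }
  bindings
}

# Evaluation environment for rule conditions: parameter bindings, globals,
# the EMPTY sentinel and declared labels as self-valued strings.
cond_env <- function(bindings, rs) {
  env <- new.env(parent = baseenv())
  for (ty in rs$types) assign(ty, ty, envir = env)
  for (pr in rs$processes) assign(pr, pr, envir = env)
  assign("EMPTY", "EMPTY", envir = env)
  for (g in names(rs$globals)) assign(g, rs$globals[[g]], envir = env)
  for (v in names(bindings)) assign(v, bindings[[v]], envir = env)
  env
}

#' Pick which matching rule fires on a symbol
#'
#' Each candidate rule fires independently with its own probability
#' (one uniform draw per candidate); if several fire, the first in script
#' order wins; if none fires the symbol is copied unchanged.
#'
#' @param candidates list of `list(rule =, bindings =)` entries that all
#'   matched the same symbol, in script order.
#' @return `NULL` (no rule fires) or
#'   `list(rule, bindings, draws, fired_index)` where `draws` holds the
#'   uniform variate drawn for each candidate.
#' @export
select_rule <- function(candidates) {
  if (length(candidates) == 0) return(NULL)
  probs <- vapply(candidates, function(c) c$rule$probability, numeric(1))
  draws <- stats::runif(length(candidates))
  fired <- which(draws < probs)
  if (length(fired) == 0) return(NULL)
  i <- fired[1]
  list(rule = candidates[[i]]$rule, bindings = candidates[[i]]$bindings,
       draws = draws, fired_index = i)
}

# Instantiate a successor template under variable bindings.
instantiate_symbol <- function(tpl, bindings, rs) {
  if (tpl$kind == "comm") {
    getv <- function(a) if (a$kind == "var") bindings[[a$value]] else a$value
    sym_comm(tpl$name, as.character(getv(tpl$args[[1]])),
             as.character(getv(tpl$args[[2]])),
             as.numeric(getv(tpl$args[[3]])),
             as.character(getv(tpl$args[[4]])))
  } else if (tpl$kind == "structure") {
    st <- rs$structures[[tpl$name]]
    sym_structure(tpl$name, st$type, st$geometry)
  } else if (tpl$kind == "binding") {
    sym_binding(tpl$name)
  } else {
    sym_end(tpl$name)
  }
}

#' One parallel derivation step
#'
#' Rewrites every symbol of `s` from the same input generation: for each
#' symbol the matching rules are collected in script order, one of them is
#' selected stochastically via [select_rule()], and its successor
#' sequence (possibly empty, i.e. erasure) replaces the symbol; symbols
#' with no firing rule are copied verbatim. The grammar is context-free,
#' so the result equals the concatenation of the per-symbol rewrites.
#'
#' When a branch-decision rule (named in `branch_rules`, e.g. the rule
#' that starts a branching process) competes for a symbol, the uniform
#' draw for that rule and its probability threshold are recorded on the
#' newly created Structure symbols; [annotate_uncertainty()] turns these
#' records into branching-uncertainty annotations.
#'
#' @param s an [lstring()].
#' @param rs a rule set from [parse_rule_script()].
#' @param branch_rules ids of the rules that carry the stochastic
#'   branch-versus-grow decision (from the scenario).
#' @return The derived [lstring()]; attribute `"events"` lists one record
#'   per rewritten symbol (rule id, draws, branch threshold).
#' @export
derive <- function(s, rs, branch_rules = character()) {
  syms <- unclass(s)
  by_name <- rs$rules_by_name
  out <- vector("list", length(syms))
  events <- list()
  for (i in seq_along(syms)) {
    sym <- syms[[i]]
    rules <- by_name[[sym$name]]
    if (is.null(rules)) {
      out[[i]] <- list(sym)
      next
    }
    candidates <- list()
    for (r in rules) {
      b <- match_rule(sym, r, rs)
      if (!is.null(b)) candidates[[length(candidates) + 1]] <-
          list(rule = r, bindings = b)
    }
    sel <- select_rule(candidates)
    if (is.null(sel)) {
      out[[i]] <- list(sym)
      next
    }
    # branch bookkeeping: threshold and draw of the first branch-decision
    # candidate, if one competed for this symbol
    br_idx <- which(vapply(candidates, function(c)
      c$rule$id %in% branch_rules, logical(1)))
    ev <- list(symbol_index = i, rule = sel$rule$id,
               u = NA_real_, theta = NA_real_, is_branch = FALSE)
    if (length(br_idx) > 0) {
      j <- br_idx[1]
      ev$u <- sel$draws[j]
      ev$theta <- candidates[[j]]$rule$probability
      ev$is_branch <- sel$fired_index == j
    }
    events[[length(events) + 1]] <- ev
    succ <- lapply(sel$rule$successors, instantiate_symbol,
                   bindings = sel$bindings, rs = rs)
    # stamp provenance on freshly created structure symbols
    if (length(br_idx) > 0) {
      succ <- lapply(succ, function(x) {
        if (x$kind == "structure") {
          x$branch_u <- ev$u; x$branch_theta <- ev$theta
          x$from_branch <- ev$is_branch
        }
        x
      })
    }
    out[[i]] <- succ
  }
  res <- lstring(do.call(c, out))
  attr(res, "events") <- events
  res
}

#' Write environment results back into Communication symbols
#'
#' @param s an [lstring()].
#' @param results named-by-index list or a data frame with columns
#'   `source` (symbol index) and `result` (agent-type label).
#' @export
set_results <- function(s, results) {
  syms <- unclass(s)
  if (is.data.frame(results)) {
    idx <- results$source; val <- results$result
  } else {
    idx <- as.integer(names(results)); val <- unlist(results)
  }
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (i < 1 || i > length(syms) || syms[[i]]$kind != "comm")
      stop(sprintf("result targets symbol %d which is not a communication symbol", i))
    syms[[i]]$r <- val[k]
  }
  lstring(syms)
}
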