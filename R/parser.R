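#' Parse a rule script into a rule set
#'
#' The rule DSL is line-oriented; `#` starts a comment. Recognized
#' directives:
#'
#' ```
#' alphabet:  m, g, E, C
#' structure: m = Dglucose sphere        # symbol = agent-type geometry
#' binding:   g, b
#' end:       E
#' agents:    tubulin                    # agent types with no structure symbol
#' global:    t_max = 5.0
#' axiom:     C(grow, Dglucose, 0, EMPTY)
#' rule p1:   C(grow,T,t,r) : r != EMPTY -> m g C(grow,T,0,EMPTY) : 1.0
#' rule p2:   C(grow,T,t,r) : t > t_max  -> E : 1.0
#' ```
#'
#' Rule lines read `rule <id>: <predecessor> [: <condition>] ->
#' <successors> : <probability>`. A Communication predecessor
#' `C(process, Type, t, r)` binds pattern variables: its parameters are
#' literals when they are numbers, `EMPTY`, or declared agent-type
#' labels, and variables otherwise (the process identifier is always a
#' literal). Conditions are boolean expressions over bound variables and
#' globals (`t > t_max`, `r != EMPTY`, ...). The successor list may be
#' `nil` for erasure. The trailing number is the probability, in `[0,1]`,
#' that the rule fires at all.
#'
#' Category directives (`structure:`/`binding:`/`end:`) are optional: an
#' undirected symbol is inferred to be an End symbol if it is named `E`,
#' a Communication symbol if it is used with parenthesized parameters, a
#' Binding symbol if listed in `binding_names` (normally the names of
#' the scenario's binding table), and a Structure symbol otherwise.
#'
#' @param text rule script source (single string or character vector of
#'   lines).
#' @param binding_names optional binding-symbol names used for category
#'   inference when the script has no `binding:` directive.
#' @return An object of class `"ruleset"`: alphabet, per-symbol
#'   categories, structure declarations, globals, axiom ([lstring()]) and
#'   parsed rules.
#' @export
parse_rule_script <- function(text, binding_names = character()) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  err <- function(ln, msg) stop(sprintf("line %d: %s", ln, msg), call. = FALSE)

  alphabet <- character()
  extra_types <- character()
  structures <- list()
  declared <- list(structure = character(), binding = character(),
                   end = character())
  globals <- list()
  axiom_raw <- NULL; axiom_line <- NA_integer_
  rules_raw <- list()

  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (grepl("^alphabet\\s*:", line)) {
      alphabet <- c(alphabet, split_csv(sub("^alphabet\\s*:", "", line)))
    } else if (grepl("^structure\\s*:", line)) {
      for (ent in split_csv(sub("^structure\\s*:", "", line))) {
        m <- regmatches(ent, regexec(
          "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([A-Za-z_][A-Za-z0-9_]*)(\\s+([A-Za-z_][A-Za-z0-9_]*))?$", ent))[[1]]
        if (length(m) == 0) err(ln, sprintf("malformed structure declaration '%s'", ent))
        geo <- if (m[5] == "") "sphere" else m[5]
        structures[[m[2]]] <- list(type = m[3], geometry = geo)
        declared$structure <- c(declared$structure, m[2])
      }
    } else if (grepl("^binding\\s*:", line)) {
      declared$binding <- c(declared$binding,
                            split_csv(sub("^binding\\s*:", "", line)))
    } else if (grepl("^end\\s*:", line)) {
      declared$end <- c(declared$end, split_csv(sub("^end\\s*:", "", line)))
    } else if (grepl("^agents\\s*:", line)) {
      extra_types <- c(extra_types, split_csv(sub("^agents\\s*:", "", line)))
    } else if (grepl("^global\\s*:", line)) {
      for (ent in split_csv(sub("^global\\s*:", "", line))) {
        m <- regmatches(ent, regexec(
          "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-+0-9.eE]+)$", ent))[[1]]
        if (length(m) == 0) err(ln, sprintf("malformed global '%s'", ent))
        globals[[m[2]]] <- as.numeric(m[3])
      }
    } else if (grepl("^axiom\\s*:", line)) {
      axiom_raw <- sub("^axiom\\s*:", "", line); axiom_line <- ln
    } else if (grepl("^rule\\b", line)) {
      m <- regmatches(line, regexec("^rule\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) == 0) err(ln, "malformed rule header (expected 'rule <id>: ...')")
      rules_raw[[length(rules_raw) + 1]] <- list(id = m[2], body = m[3], line = ln)
    } else {
      err(ln, sprintf("unrecognized directive '%s'",
                      sub("\\s.*$", "", line)))
    }
  }
  if (is.null(axiom_raw)) stop("rule script declares no axiom", call. = FALSE)

  # category assignment ------------------------------------------------
  used_with_args <- character()
  scan_tokens <- c(axiom_raw,
                   vapply(rules_raw, function(r) r$body, character(1)))
  for (tok in unlist(regmatches(scan_tokens,
      gregexpr("[A-Za-z_][A-Za-z0-9_]*\\s*\\(", scan_tokens))))
    used_with_args <- c(used_with_args, sub("\\s*\\($", "", tok))
  categories <- character()
  for (a in alphabet) {
    categories[a] <-
      if (a %in% declared$structure) "structure"
      else if (a %in% declared$binding) "binding"
      else if (a %in% declared$end) "end"
      else if (a %in% binding_names) "binding"
      else if (a == "E") "end"
      else if (a %in% used_with_args) "comm"
      else "structure"
    if (categories[a] == "structure" && is.null(structures[[a]]))
      structures[[a]] <- list(type = a, geometry = "sphere")
  }
  undecl <- setdiff(c(declared$structure, declared$binding, declared$end),
                    alphabet)
  if (length(undecl) > 0)
    stop(sprintf("undeclared symbol '%s' (not in alphabet)", undecl[1]),
         call. = FALSE)

  types <- unique(c(vapply(structures, function(s) s$type, character(1)),
                    extra_types))

  rs <- list(alphabet = alphabet, categories = categories,
             structures = structures, types = types,
             processes = character(), globals = globals,
             axiom = NULL, rules = list())
  class(rs) <- "ruleset"

  # axiom ---------------------------------------------------------------
  ax_tpl <- parse_symbol_sequence(axiom_raw, rs, axiom_line, err,
                                  allow_vars = FALSE)
  rs$processes <- unique(c(rs$processes, attr(ax_tpl, "processes")))
  # also collect process names and comm type literals from rule bodies
  for (rr in rules_raw) {
    for (call_tok in regmatches(rr$body,
        gregexpr("[A-Za-z_][A-Za-z0-9_]*\\s*\\(\\s*[A-Za-z_][A-Za-z0-9_]*",
                 rr$body))[[1]]) {
      rs$processes <- unique(c(rs$processes,
        sub("^.*\\(\\s*", "", call_tok)))
    }
  }
  rs$axiom <- lstring(lapply(ax_tpl, instantiate_symbol,
                             bindings = list(), rs = rs))

  # rules ---------------------------------------------------------------
  for (rr in rules_raw) {
    rs$rules[[length(rs$rules) + 1]] <- parse_rule_body(rr, rs, err)
  }
  names(rs$rules) <- vapply(rs$rules, function(r) r$id, character(1))
  rs$rules_by_name <- split(rs$rules,
                            vapply(rs$rules, function(r) r$pred$name,
                                   character(1)))
  rs
}

split_csv <- function(x) {
  out <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  out[out != ""]
}

# Tokenize a symbol sequence: names optionally followed by (...)
parse_symbol_sequence <- function(text, rs, ln, err, allow_vars,
                                  bound_vars = character()) {
  text <- trimws(text)
  if (text == "" || text == "nil") return(structure(list(), processes = character()))
  pat <- "[A-Za-z_][A-Za-z0-9_]*(\\s*\\([^()]*\\))?"
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  leftover <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", leftover))
    err(ln, sprintf("syntax error near '%s'", trimws(leftover)))
  processes <- character()
  out <- lapply(toks, function(tok) {
    name <- sub("\\s*\\(.*$", "", tok)
    if (!(name %in% rs$alphabet))
      err(ln, sprintf("undeclared symbol '%s'", name))
    has_args <- grepl("(", tok, fixed = TRUE)
    cat_ <- rs$categories[[name]]
    if (has_args) {
      if (cat_ != "comm")
        err(ln, sprintf("symbol '%s' is not a communication symbol but has parameters", name))
      args_txt <- split_csv(sub("^.*\\(", "", sub("\\)$", "", tok)))
      if (length(args_txt) != 4)
        err(ln, sprintf("communication symbol '%s' needs 4 parameters (process, type, t, r)", name))
      args <- vector("list", 4)
      args[[1]] <- list(kind = "lit", value = args_txt[1])
      processes <<- c(processes, args_txt[1])
      for (i in 2:4) {
        a <- args_txt[i]
        if (grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", a)) {
          args[[i]] <- list(kind = "lit", value = as.numeric(a))
        } else if (a == "EMPTY" || a %in% rs$types) {
          args[[i]] <- list(kind = "lit", value = a)
        } else if (allow_vars) {
          args[[i]] <- list(kind = "var", value = a)
        } else {
          err(ln, sprintf("parameter '%s' is not a literal (number, EMPTY or declared agent type)", a))
        }
      }
      list(kind = "comm", name = name, args = args)
    } else {
      if (cat_ == "comm")
        err(ln, sprintf("communication symbol '%s' used without parameters", name))
      list(kind = cat_, name = name)
    }
  })
  structure(out, processes = unique(processes))
}

parse_rule_body <- function(rr, rs, err) {
  ln <- rr$line
  halves <- strsplit(rr$body, "->", fixed = TRUE)[[1]]
  if (length(halves) != 2) err(ln, "rule needs exactly one '->'")
  lhs <- trimws(halves[1]); rhs <- trimws(halves[2])

  # lhs: predecessor [: condition]
  ci <- regexpr(":", lhs, fixed = TRUE)
  if (ci > 0) {
    pred_txt <- trimws(substr(lhs, 1, ci - 1))
    cond_txt <- trimws(substr(lhs, ci + 1, nchar(lhs)))
  } else {
    pred_txt <- lhs; cond_txt <- NULL
  }
  pred_seq <- parse_symbol_sequence(pred_txt, rs, ln, err, allow_vars = TRUE)
  if (length(pred_seq) != 1) err(ln, "predecessor must be a single symbol")
  pred <- pred_seq[[1]]
  bound <- character()
  if (!is.null(pred$args))
    bound <- vapply(Filter(function(a) a$kind == "var", pred$args),
                    function(a) a$value, character(1))

  # rhs: successors : probability (split at last top-level colon)
  pi_ <- max(gregexpr(":", rhs, fixed = TRUE)[[1]])
  if (pi_ < 0) err(ln, "rule is missing its probability")
  succ_txt <- trimws(substr(rhs, 1, pi_ - 1))
  prob_txt <- trimws(substr(rhs, pi_ + 1, nchar(rhs)))
  prob <- suppressWarnings(as.numeric(prob_txt))
  if (is.na(prob)) err(ln, sprintf("malformed probability '%s'", prob_txt))
  if (prob < 0 || prob > 1) err(ln, "probability outside [0,1]")

  succ <- parse_symbol_sequence(succ_txt, rs, ln, err, allow_vars = TRUE)
  for (tpl in succ) {
    if (tpl$kind == "comm") {
      for (a in tpl$args[2:4]) {
        if (a$kind == "var" && !(a$value %in% bound))
          err(ln, sprintf("unbound variable '%s' in successor", a$value))
      }
    }
  }

  condition <- NULL
  if (!is.null(cond_txt) && cond_txt != "" &&
      tolower(cond_txt) != "true") {
    condition <- tryCatch(str2lang(cond_txt), error = function(e)
      err(ln, sprintf("syntax error in condition '%s'", cond_txt)))
    known <- c(bound, names(rs$globals), "EMPTY", rs$types, rs$processes)
    for (nm in all.vars(condition)) {
      if (!(nm %in% known))
        err(ln, sprintf("unbound variable '%s' in condition", nm))
    }
    allowed_ops <- c("==", "!=", "<", ">", "<=", ">=", "&&", "||",
                     "&", "|", "!", "(", "+", "-", "*", "/")
    for (fn in setdiff(all.names(condition), all.vars(condition))) {
      if (!(fn %in% allowed_ops))
        err(ln, sprintf("operator '%s' not allowed in condition", fn))
    }
  }

  list(id = rr$id, pred = pred, condition = condition,
       successors = unclass(succ), probability = prob, line = ln)
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("<ruleset: %d symbols, %d rules>\n",
              length(x$alphabet), length(x$rules)))
  cat("axiom:", format(x$axiom), "\n")
  for (r in x$rules) {
    cat(sprintf("  rule %s (p=%g)\n", r$id, r$probability))
  }
  invisible(x)
}
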