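# Logic rule representation.
#
# A rule is one of four kinds:
#   link  - structured (activators | ...) AND_NOT / OR_NOT !(inhibitors | ...)
#   expr  - free expression tree over regulators with & | ! (language object)
#   input - regulator-free node; identity on its own value
#   count - multi-level output rule: level = clip(#active pos - #active neg,
#           0, max_level); pos/neg are lists of regulator expressions so
#           that model reduction can substitute eliminated nodes into them.
#
# Multi-level values in Boolean contexts use threshold semantics: a
# regulator counts as active when its level >= 1.

rule_link <- function(node, activators, inhibitors,
                      link_op = c("AND_NOT", "OR_NOT")) {
  link_op <- match.arg(link_op)
  structure(list(node = node, kind = "link",
                 activators = sort(unique(activators)),
                 inhibitors = sort(unique(inhibitors)),
                 link_op = link_op),
            class = "logic_rule")
}

rule_expr <- function(node, expr) {
  if (is.character(expr)) expr <- str2lang(expr)
  structure(list(node = node, kind = "expr", expr = expr),
            class = "logic_rule")
}

rule_input <- function(node) {
  structure(list(node = node, kind = "input"), class = "logic_rule")
}

rule_count <- function(node, pos, neg = list()) {
  as_lang <- function(x) if (is.character(x)) as.name(x) else x
  structure(list(node = node, kind = "count",
                 pos = lapply(pos, as_lang), neg = lapply(neg, as_lang)),
            class = "logic_rule")
}

#' Regulators referenced by a rule
#' @param rule a logic rule.
#' @return character vector of regulator node names (an input node
#'   references itself).
#' @export
rule_regulators <- function(rule) {
  switch(rule$kind,
         link = c(rule$activators, rule$inhibitors),
         expr = all.vars(rule$expr),
         input = rule$node,
         count = unique(unlist(c(lapply(rule$pos, all.vars),
                                 lapply(rule$neg, all.vars)))))
}

# Evaluate a rule, vectorized over states. `values` is a named list of
# equal-length numeric vectors (levels); scalars recycle. Returns the next
# level(s) of the node.
eval_rule <- function(rule, values, max_level = 1L) {
  active <- function(nm) values[[nm]] >= 1
  or_all <- function(nms) Reduce(`|`, lapply(nms, active))
  switch(rule$kind,
    input = as.numeric(values[[rule$node]]),
    link = {
      has_a <- length(rule$activators) > 0
      has_i <- length(rule$inhibitors) > 0
      if (has_a && has_i) {
        a <- or_all(rule$activators); i <- or_all(rule$inhibitors)
        out <- if (rule$link_op == "AND_NOT") a & !i else a | !i
      } else if (has_a) {
        out <- or_all(rule$activators)
      } else {
        out <- !or_all(rule$inhibitors)
      }
      as.numeric(out)
    },
    expr = {
      env <- lapply(values[all.vars(rule$expr)], function(v) v >= 1)
      as.numeric(eval(rule$expr, envir = env))
    },
    count = {
      bool_env <- lapply(values, function(v) v >= 1)
      tally <- function(exprs) {
        if (!length(exprs)) return(0)
        Reduce(`+`, lapply(exprs, function(e) {
          as.numeric(eval(e, envir = bool_env))
        }))
      }
      lev <- tally(rule$pos) - tally(rule$neg)
      pmin(pmax(lev, 0), max_level)
    })
}

#' @export
print.logic_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Human-readable rule text
#' @param rule a logic rule.
#' @return a single string such as `"AKT_f = (ILK | mTORC2_c) & !PPP1CA"`.
#' @export
format_rule <- function(rule) {
  rhs <- switch(rule$kind,
    input = rule$node,
    expr = deparse1(rule$expr),
    link = {
      a <- paste(rule$activators, collapse = " | ")
      i <- paste(rule$inhibitors, collapse = " | ")
      wrap <- function(s, many) if (many) paste0("(", s, ")") else s
      if (length(rule$activators) && length(rule$inhibitors)) {
        op <- if (rule$link_op == "AND_NOT") " & !" else " | !"
        paste0(wrap(a, length(rule$activators) > 1), op,
               wrap(i, length(rule$inhibitors) > 1))
      } else if (length(rule$activators)) {
        a
      } else {
        paste0("!", wrap(i, length(rule$inhibitors) > 1))
      }
    },
    count = paste0("@count(",
                   paste(c(vapply(rule$pos, function(e)
                            paste0("+", deparse1(e)), ""),
                          vapply(rule$neg, function(e)
                            paste0("-", deparse1(e)), "")),
                         collapse = " "), ")"))
  paste(rule$node, "=", rhs)
}

# --- expression helpers -----------------------------------------------------

# Build (x1 | x2 | ...) as a language object.
or_lang <- function(names) {
  Reduce(function(a, b) call("|", a, b), lapply(names, as.name))
}

# Convert any rule to an equivalent expression-style rule (count rules keep
# their own kind; they are substitution-aware already).
rule_as_expr <- function(rule) {
  if (rule$kind %in% c("expr", "count")) return(rule)
  if (rule$kind == "input") return(rule_expr(rule$node, as.name(rule$node)))
  a <- if (length(rule$activators)) or_lang(rule$activators)
  i <- if (length(rule$inhibitors)) {
    call("!", call("(", or_lang(rule$inhibitors)))
  }
  e <- if (!is.null(a) && !is.null(i)) {
    op <- if (rule$link_op == "AND_NOT") "&" else "|"
    call(op, call("(", a), i)
  } else if (!is.null(a)) a else i
  rule_expr(rule$node, e)
}

# Substitute `replacement` (language) for symbol `name` inside a rule.
substitute_rule <- function(rule, name, replacement) {
  repl <- list(call("(", replacement))
  names(repl) <- name
  sub1 <- function(e) do.call(substitute, list(e, repl))
  if (rule$kind == "link") rule <- rule_as_expr(rule)
  if (rule$kind == "expr") {
    rule$expr <- sub1(rule$expr)
  } else if (rule$kind == "count") {
    rule$pos <- lapply(rule$pos, sub1)
    rule$neg <- lapply(rule$neg, sub1)
  } else if (rule$kind == "input") {
    stop("cannot substitute into an input rule")
  }
  rule
}

# Polarity of each variable in an expression: +1 under an even number of
# negations, -1 under odd, or both (dual). Returns data.frame(var, sign).
expr_polarity <- function(e, neg = FALSE) {
  if (is.name(e)) {
    return(data.frame(var = as.character(e),
                      sign = if (neg) -1L else 1L,
                      stringsAsFactors = FALSE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "!") {
      return(expr_polarity(args[[1]], !neg))
    }
    return(do.call(rbind, lapply(args, expr_polarity, neg = neg)))
  }
  data.frame(var = character(), sign = integer(), stringsAsFactors = FALSE)
}

# Signed edge list implied by a rule (used to rebuild reduced networks).
rule_edges <- function(rule) {
  pol <- switch(rule$kind,
    input = data.frame(var = rule$node, sign = 1L,
                       stringsAsFactors = FALSE),
    link = rbind(
      if (length(rule$activators))
        data.frame(var = rule$activators, sign = 1L,
                   stringsAsFactors = FALSE),
      if (length(rule$inhibitors))
        data.frame(var = rule$inhibitors, sign = -1L,
                   stringsAsFactors = FALSE)),
    expr = expr_polarity(rule$expr),
    count = rbind(
      do.call(rbind, c(lapply(rule$pos, expr_polarity),
                       list(NULL))),
      do.call(rbind, c(lapply(rule$neg, function(e)
        expr_polarity(e, neg = TRUE)), list(NULL)))))
  if (is.null(pol) || !nrow(pol)) {
    return(data.frame(source = character(), sign = integer(),
                      target = character(), stringsAsFactors = FALSE))
  }
  unique(data.frame(source = pol$var, sign = pol$sign, target = rule$node,
                    stringsAsFactors = FALSE))
}
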