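#' Construct a logical model
#'
#' A logical model attaches one rule per network node plus a maximum level
#' per node (1 for ordinary signaling nodes; 3 for the two phenotype output
#' nodes, which count their active regulators; other nodes may be declared
#' multi-level, e.g. a forkhead-box family node after refinement).
#'
#' @param network a [regulatory_network()].
#' @param rules named list of logic rules, one per node.
#' @param max_level named integer vector of maximum levels (default 1).
#' @param edit_log list of applied edits (provenance).
#' @return An object of class `logical_model`.
#' @export
logical_model <- function(network, rules, max_level = NULL,
                          edit_log = list()) {
  nodes <- network$nodes
  if (!setequal(names(rules), nodes)) {
    stop("rules must cover exactly the network nodes")
  }
  rules <- rules[sort(names(rules))]
  if (is.null(max_level)) {
    max_level <- stats::setNames(rep(1L, length(nodes)), nodes)
  }
  ml <- stats::setNames(rep(1L, length(nodes)), nodes)
  ml[names(max_level)] <- as.integer(max_level)
  for (n in nodes) {
    regs <- setdiff(rule_regulators(rules[[n]]), n)
    missing <- setdiff(regs, nodes)
    if (length(missing)) {
      stop("rule for ", n, " references unknown node(s): ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(network = network, rules = rules, max_level = ml,
                 edit_log = edit_log),
            class = "logical_model")
}

#' @export
print.logical_model <- function(x, ...) {
  cat("logical_model:", length(x$network$nodes), "nodes (",
      sum(x$max_level > 1), "multi-level )\n")
  for (r in x$rules) cat(" ", format_rule(r), "\n")
  invisible(x)
}

#' Generate default rules from a signed network
#'
#' Every activating regulator of a node is linked by OR, every inhibiting
#' regulator by OR, and the two clauses are combined by AND NOT (inhibitors
#' dominate) unless the node is listed in `link_overrides`, in which case
#' OR NOT is used (activation favored; the convention needed to keep a
#' p38/MAPK14-style node active despite an active phosphatase). Nodes with
#' regulators of one sign only get the single clause; regulator-free nodes
#' get identity (input) rules so that both of their values are admissible
#' fixed points until calibration pins them. Output nodes get a multi-level
#' counting rule over their regulators.
#'
#' @param net a [regulatory_network()].
#' @param link_overrides character vector of node names whose link operator
#'   is OR_NOT instead of the default AND_NOT.
#' @param output_rule_mode `"net_count"` (level = clip(#active activators -
#'   #active inhibitors, 0, max)) or `"pos_count"` (activators only).
#' @param max_levels optional named integer vector; output nodes default
#'   to 3, all others to 1.
#' @return A [logical_model()].
#' @export
default_rules <- function(net, link_overrides = character(),
                          output_rule_mode = c("net_count", "pos_count"),
                          max_levels = NULL) {
  output_rule_mode <- match.arg(output_rule_mode)
  unknown <- setdiff(link_overrides, net$nodes)
  if (length(unknown)) {
    stop("link override names unknown node(s): ",
         paste(unknown, collapse = ", "))
  }
  rules <- list()
  ml <- stats::setNames(rep(1L, length(net$nodes)), net$nodes)
  for (n in net$nodes) {
    inc <- net$edges[net$edges$target == n, , drop = FALSE]
    act <- inc$source[inc$sign > 0]
    inh <- inc$source[inc$sign < 0]
    if (!is.null(net$output_nodes) && n %in% net$output_nodes) {
      rules[[n]] <- rule_count(n, pos = as.list(sort(act)),
                               neg = if (output_rule_mode == "net_count")
                                 as.list(sort(inh)) else list())
      ml[n] <- 3L
    } else if (!nrow(inc)) {
      rules[[n]] <- rule_input(n)
    } else {
      op <- if (n %in% link_overrides) "OR_NOT" else "AND_NOT"
      rules[[n]] <- rule_link(n, act, inh, link_op = op)
    }
  }
  if (!is.null(max_levels)) ml[names(max_levels)] <- as.integer(max_levels)
  logical_model(net, rules, max_level = ml)
}

#' Synchronous image of a state
#'
#' Applies every rule once to a complete state; Boolean rules yield 0/1,
#' output counting rules yield integer levels clamped to `[0, max_level]`.
#'
#' @param model a [logical_model()].
#' @param state named numeric vector over all model nodes.
#' @param clamps optional named numeric vector of nodes held fixed.
#' @return named numeric vector (the next state).
#' @export
evaluate_state <- function(model, state, clamps = NULL) {
  nodes <- names(model$rules)
  missing <- setdiff(nodes, names(state))
  if (length(missing)) {
    stop("state is missing node(s): ", paste(missing, collapse = ", "))
  }
  values <- as.list(state[nodes])
  nxt <- vapply(nodes, function(n) {
    eval_rule(model$rules[[n]], values, model$max_level[[n]])
  }, numeric(1))
  if (!is.null(clamps) && length(clamps)) {
    nxt[names(clamps)] <- as.numeric(clamps)
  }
  nxt
}

# Replace clamped nodes' rules by constants; returns modified rule list.
clamped_rules <- function(model, clamps) {
  rules <- model$rules
  if (!is.null(clamps) && length(clamps)) {
    bad <- setdiff(names(clamps), names(rules))
    if (length(bad)) stop("clamp names unknown node(s): ",
                          paste(bad, collapse = ", "))
    for (n in names(clamps)) {
      rules[[n]] <- rule_expr(n, as.numeric(clamps[[n]]))
    }
  }
  rules
}

#' Exact fixed points of a logical model
#'
#' Computes the complete set of stable states (states equal to their
#' synchronous image, fixed points of the dynamics under any update
#' scheme). The solver works on the condensation of the regulatory
#' dependency graph: strongly connected components are processed in
#' topological order; values of acyclic nodes are propagated, while each
#' feedback component is solved by exhaustive enumeration of its own state
#' space against the already-assigned upstream values. This is exact and
#' complete, and is pinned by a brute-force whole-state-space oracle in the
#' test suite.
#'
#' @param model a [logical_model()].
#' @param clamps named numeric vector of nodes held at fixed levels (drug
#'   targets, influence-sweep fixations). Clamped rules are rewritten to
#'   constants, so fixed points of the clamped dynamics are returned.
#' @param scc_limit maximum number of candidate assignments enumerated for
#'   a single feedback component before erroring.
#' @param max_solutions cap on the number of partial solutions tracked.
#' @return list of stable states (named numeric vectors), in lexicographic
#'   order of their values over the sorted node names; empty list when no
#'   fixed point exists.
#' @export
stable_states <- function(model, clamps = NULL, scc_limit = 2^16,
                          max_solutions = 2^15) {
  rules <- clamped_rules(model, clamps)
  nodes <- sort(names(rules))
  if (!length(nodes)) return(list())
  regs <- lapply(rules, function(r) intersect(rule_regulators(r), nodes))
  dep <- do.call(rbind, lapply(nodes, function(n) {
    if (length(regs[[n]]))
      data.frame(from = regs[[n]], to = n, stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(
    if (is.null(dep)) data.frame(from = character(), to = character())
    else dep,
    directed = TRUE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[nodes]
  cedges <- unique(data.frame(
    from = memb[if (is.null(dep)) character() else dep$from],
    to = memb[if (is.null(dep)) character() else dep$to]))
  cedges <- cedges[cedges$from != cedges$to, , drop = FALSE]
  cg <- igraph::graph_from_data_frame(
    cedges, directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(comp$no))))
  order_sccs <- as.integer(names(igraph::topo_sort(cg, mode = "out")))

  asg <- matrix(numeric(0), nrow = 1, ncol = 0)
  colnames(asg) <- character(0)
  for (ci in order_sccs) {
    S <- sort(nodes[memb == ci])
    self_dep <- any(unlist(regs[S]) %in% S)
    if (!self_dep && length(S) == 1L) {
      n <- S
      values <- lapply(seq_len(ncol(asg)),
                       function(j) asg[, j, drop = TRUE])
      names(values) <- colnames(asg)
      v <- eval_rule(rules[[n]], values, model$max_level[[n]])
      if (length(v) == 1L) v <- rep(v, nrow(asg))
      asg <- cbind(asg, matrix(v, ncol = 1, dimnames = list(NULL, n)))
    } else {
      domains <- lapply(S, function(n) 0:model$max_level[[n]])
      ncombo <- prod(vapply(domains, length, 1L))
      if (ncombo > scc_limit) {
        stop("feedback component too large to enumerate (",
             ncombo, " states): ", paste(S, collapse = ", "))
      }
      combos <- as.matrix(expand.grid(domains,
                                      KEEP.OUT.ATTRS = FALSE))
      colnames(combos) <- S
      keep_rows <- list()
      for (r in seq_len(nrow(asg))) {
        values <- as.list(asg[r, , drop = TRUE])
        for (s in S) values[[s]] <- combos[, s, drop = TRUE]
        ok <- rep(TRUE, nrow(combos))
        for (s in S) {
          v <- eval_rule(rules[[s]], values, model$max_level[[s]])
          ok <- ok & (v == combos[, s])
        }
        if (any(ok)) {
          kept <- combos[ok, , drop = FALSE]
          prefix <- matrix(rep(asg[r, , drop = TRUE], each = nrow(kept)),
                           nrow = nrow(kept),
                           dimnames = list(NULL, colnames(asg)))
          keep_rows[[length(keep_rows) + 1L]] <- cbind(prefix, kept)
        }
      }
      if (!length(keep_rows)) return(list())
      asg <- do.call(rbind, keep_rows)
      if (nrow(asg) > max_solutions) {
        stop("too many candidate fixed points (> ", max_solutions, ")")
      }
    }
  }
  asg <- asg[, nodes, drop = FALSE]
  ord <- do.call(order, as.data.frame(asg))
  asg <- asg[ord, , drop = FALSE]
  lapply(seq_len(nrow(asg)), function(i) {
    stats::setNames(as.numeric(asg[i, ]), nodes)
  })
}

#' Reduce a model by eliminating intermediate nodes
#'
#' Eliminates every node outside `retain` that does not regulate itself by
#' substituting its rule into all downstream rules, iteratively, in sorted
#' node order. Self-regulating nodes cannot be eliminated (removing them
#' would lose dynamics); those outside `retain` are kept and reported as
#' irreducible, and a substitution that turns a retained node into a
#' self-regulator (a 2-cycle whose partner was eliminated) is reported
#' through the `self_regulated` attribute. Elimination of a
#' non-self-regulating node preserves the fixed points of the model
#' projected onto the remaining nodes, which is the contract pinned by the
#' test suite. Output nodes and multi-level nodes are always retained.
#'
#' @param model a [logical_model()].
#' @param retain character vector of nodes to keep.
#' @return A reduced [logical_model()] with attributes `irreducible` (kept
#'   self-loop nodes outside `retain`), `self_regulated` (nodes whose
#'   reduced rule references themselves) and `retain` (the effective set).
#' @export
reduce_model <- function(model, retain) {
  nodes <- names(model$rules)
  unknown <- setdiff(retain, nodes)
  if (length(unknown)) {
    stop("retain set contains unknown node(s): ",
         paste(unknown, collapse = ", "))
  }
  retain <- union(retain, model$network$output_nodes)
  retain <- union(retain, nodes[model$max_level > 1])
  rules <- lapply(model$rules, rule_as_expr)
  current <- nodes
  repeat {
    candidates <- sort(setdiff(current, retain))
    elim <- NULL
    for (x in candidates) {
      if (!(x %in% rule_regulators(rules[[x]]))) { elim <- x; break }
    }
    if (is.null(elim)) break
    ex <- rules[[elim]]$expr
    for (n in setdiff(current, elim)) {
      if (elim %in% rule_regulators(rules[[n]])) {
        rules[[n]] <- substitute_rule(rules[[n]], elim, ex)
      }
    }
    rules[[elim]] <- NULL
    current <- setdiff(current, elim)
  }
  irreducible <- sort(setdiff(current, retain))
  self_regulated <- sort(Filter(function(n) {
    n %in% rule_regulators(rules[[n]])
  }, current))
  edges <- do.call(rbind, lapply(rules, rule_edges))
  edges <- edges[edges$source %in% current, , drop = FALSE]
  net <- regulatory_network(
    edges, nodes = current,
    output_nodes = if (!is.null(model$network$output_nodes) &&
                       all(model$network$output_nodes %in% current))
      model$network$output_nodes,
    drug_targets = intersect(model$network$drug_targets, current))
  out <- logical_model(net, rules, max_level = model$max_level[current],
                       edit_log = model$edit_log)
  attr(out, "irreducible") <- irreducible
  attr(out, "self_regulated") <- self_regulated
  attr(out, "retain") <- sort(intersect(retain, current))
  out
}

#' Attractors of the asynchronous dynamics
#'
#' Builds the full asynchronous state transition graph (one node updated
#' per step; multi-level nodes step by one level toward their rule's
#' target) and returns its terminal strongly connected components.
#' Singleton terminal components are the fixed points; larger ones are
#' complex attractors with nodes oscillating among the member states.
#' Intended for reduced models whose state space is small.
#'
#' @param model a [logical_model()].
#' @param clamps named numeric vector of clamped nodes.
#' @param max_states cap on the explored state space; when the full state
#'   space exceeds it, an explicit undecided result is returned (never a
#'   silent truncation).
#' @return An object of class `attractor_set`: list with `undecided`
#'   (logical) and `attractors`, each attractor a list with `kind`
#'   (`"stable_state"` or `"complex"`) and `states` (list of named
#'   numeric vectors).
#' @export
async_attractors <- function(model, clamps = NULL, max_states = 4096) {
  rules <- clamped_rules(model, clamps)
  nodes <- sort(names(rules))
  domains <- lapply(nodes, function(n) 0:model$max_level[[n]])
  names(domains) <- nodes
  if (!is.null(clamps)) {
    for (n in intersect(names(clamps), nodes)) {
      domains[[n]] <- as.numeric(clamps[[n]])
    }
  }
  sizes <- vapply(domains, length, 1L)
  total <- prod(sizes)
  if (total > max_states) {
    return(structure(list(undecided = TRUE, attractors = list(),
                          n_states = total),
                     class = "attractor_set"))
  }
  M <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
  colnames(M) <- nodes
  values <- lapply(nodes, function(n) M[, n, drop = TRUE])
  names(values) <- nodes
  # mixed-radix encoding of states
  mins <- vapply(domains, min, 1)
  w <- cumprod(c(1, sizes[-length(sizes)]))
  encode <- function(S) as.integer(1 + (S - rep(mins, each = nrow(S))) %*% w)
  from <- integer(0); to <- integer(0)
  for (j in seq_along(nodes)) {
    n <- nodes[j]
    tgt <- eval_rule(rules[[n]], values, model$max_level[[n]])
    if (length(tgt) == 1L) tgt <- rep(tgt, nrow(M))
    if (n %in% names(clamps)) tgt <- rep(as.numeric(clamps[[n]]), nrow(M))
    moving <- which(tgt != M[, j])
    if (length(moving)) {
      Mn <- M[moving, , drop = FALSE]
      Mn[, j] <- Mn[, j] + sign(tgt[moving] - Mn[, j])
      from <- c(from, moving)
      to <- c(to, encode(Mn))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(M), directed = TRUE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  nonterminal <- unique(memb[from][memb[from] != memb[to]])
  terminal <- setdiff(seq_len(comp$no), nonterminal)
  atts <- lapply(terminal, function(ci) {
    idx <- sort(which(memb == ci))
    states <- lapply(idx, function(i) {
      stats::setNames(as.numeric(M[i, ]), nodes)
    })
    list(kind = if (length(idx) == 1L) "stable_state" else "complex",
         states = states)
  })
  first_idx <- vapply(terminal, function(ci) min(which(memb == ci)), 1L)
  atts <- atts[order(first_idx)]
  structure(list(undecided = FALSE, attractors = atts, n_states = total),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  if (x$undecided) {
    cat("attractor_set: undecided (state space", x$n_states,
        "exceeds cap)\n")
  } else {
    kinds <- vapply(x$attractors, `[[`, "", "kind")
    cat("attractor_set:", sum(kinds == "stable_state"), "stable state(s),",
        sum(kinds == "complex"), "complex attractor(s)\n")
  }
  invisible(x)
}

#' Apply a sequence of model edits
#'
#' Generic rule/topology edit operations: `add_node`, `add_edge`,
#' `remove_edge`, `set_rule`, `set_max_level`, `set_link_operator`.
#' Edits are applied in order and recorded in the model's edit log. This is
#' the mechanism for literature-guided refinements (e.g. removing a kinase
#' edge, rewiring AKT regulation through a new PIP3 node, or adding an
#' MXD1 node inhibiting MYC).
#'
#' @param model a [logical_model()].
#' @param edits list of edits; each edit is a list with a `kind` field and
#'   kind-specific payload: `add_node(node, rule = NULL, max_level = 1)`,
#'   `add_edge(source, sign, target)`, `remove_edge(source, target)`,
#'   `set_rule(node, rule)` (rule as expression text),
#'   `set_max_level(node, level)`, `set_link_operator(node, op)`.
#' @return The edited [logical_model()].
#' @export
apply_edits <- function(model, edits) {
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    model <- tryCatch(
      apply_one_edit(model, e),
      error = function(err) {
        stop("edit ", i, " (", e$kind, "): ", conditionMessage(err),
             call. = FALSE)
      })
    model$edit_log[[length(model$edit_log) + 1L]] <- e
  }
  model
}

apply_one_edit <- function(model, e) {
  net <- model$network
  rules <- model$rules
  ml <- model$max_level
  need_node <- function(n) {
    if (!n %in% net$nodes) stop("unknown node ", n)
  }
  switch(e$kind,
    add_node = {
      if (e$node %in% net$nodes) stop("node already exists: ", e$node)
      rule <- if (is.null(e$rule)) rule_input(e$node)
              else rule_expr(e$node, e$rule)
      new_edges <- rule_edges(rule)
      net <- regulatory_network(rbind(net$edges, new_edges),
                                nodes = c(net$nodes, e$node),
                                output_nodes = net$output_nodes,
                                drug_targets = net$drug_targets)
      rules[[e$node]] <- rule
      ml <- c(ml, stats::setNames(
        as.integer(if (is.null(e$max_level)) 1L else e$max_level), e$node))
    },
    add_edge = {
      need_node(e$source); need_node(e$target)
      net <- regulatory_network(
        rbind(net$edges, data.frame(source = e$source, sign = e$sign,
                                    target = e$target)),
        nodes = net$nodes, output_nodes = net$output_nodes,
        drug_targets = net$drug_targets)
      r <- rules[[e$target]]
      if (r$kind == "input") {
        r <- rule_link(e$target,
                       activators = if (e$sign > 0) e$source else character(),
                       inhibitors = if (e$sign < 0) e$source else character())
      } else if (r$kind == "link") {
        if (e$sign > 0) r$activators <- sort(unique(c(r$activators, e$source)))
        else r$inhibitors <- sort(unique(c(r$inhibitors, e$source)))
      } else if (r$kind == "count") {
        if (e$sign > 0) r$pos <- c(r$pos, list(as.name(e$source)))
        else r$neg <- c(r$neg, list(as.name(e$source)))
      } else {
        stop("target has a free-form rule; use set_rule instead")
      }
      rules[[e$target]] <- r
    },
    remove_edge = {
      need_node(e$source); need_node(e$target)
      hit <- net$edges$source == e$source & net$edges$target == e$target
      if (!is.null(e$sign)) hit <- hit & net$edges$sign == e$sign
      if (!any(hit)) stop("no such edge ", e$source, " -> ", e$target)
      net <- regulatory_network(net$edges[!hit, , drop = FALSE],
                                nodes = net$nodes,
                                output_nodes = net$output_nodes,
                                drug_targets = net$drug_targets)
      r <- rules[[e$target]]
      if (r$kind == "link") {
        r$activators <- setdiff(r$activators, e$source)
        r$inhibitors <- setdiff(r$inhibitors, e$source)
        if (!length(r$activators) && !length(r$inhibitors)) {
          r <- rule_input(e$target)
        }
      } else if (r$kind == "count") {
        keep <- function(exprs) {
          Filter(function(x) !identical(x, as.name(e$source)), exprs)
        }
        r$pos <- keep(r$pos); r$neg <- keep(r$neg)
      } else if (r$kind == "expr") {
        stop("target has a free-form rule; use set_rule to rewrite it")
      }
      rules[[e$target]] <- r
    },
    set_rule = {
      need_node(e$node)
      r <- rule_expr(e$node, e$rule)
      missing <- setdiff(rule_regulators(r), net$nodes)
      if (length(missing)) stop("rule references unknown node(s): ",
                                paste(missing, collapse = ", "))
      keep <- net$edges$target != e$node
      net <- regulatory_network(rbind(net$edges[keep, , drop = FALSE],
                                      rule_edges(r)),
                                nodes = net$nodes,
                                output_nodes = net$output_nodes,
                                drug_targets = net$drug_targets)
      rules[[e$node]] <- r
    },
    set_max_level = {
      need_node(e$node)
      ml[e$node] <- as.integer(e$level)
    },
    set_link_operator = {
      need_node(e$node)
      if (rules[[e$node]]$kind != "link") {
        stop("node ", e$node, " does not have a link-operator rule")
      }
      rules[[e$node]]$link_op <- e$op
    },
    stop("unknown edit kind: ", e$kind))
  logical_model(net, rules, max_level = ml, edit_log = model$edit_log)
}

#' Write model rules to a plain-text rule file
#'
#' One line per node in the dialect `targets, factors, max_level`
#' (compatible with common Boolean-network rule formats); multi-level
#' counting rules use the token `@count(+A +B -C)`.
#'
#' @param model a [logical_model()].
#' @param path output path.
#' @export
write_rules <- function(model, path) {
  lines <- c("targets, factors, max_level")
  for (n in names(model$rules)) {
    r <- model$rules[[n]]
    rhs <- sub("^.* = ", "", format_rule(r))
    lines <- c(lines, paste(n, rhs, model$max_level[[n]], sep = ", "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read model rules from a plain-text rule file
#'
#' Inverse of [write_rules()]. The network topology (signed edges) is
#' reconstructed from the syntactic polarity of each regulator in the
#' parsed rules.
#'
#' @param path rule file path.
#' @param output_nodes optional `c(prosurvival, antisurvival)` pair.
#' @param drug_targets optional drug-target node set.
#' @return A [logical_model()].
#' @export
read_rules <- function(path, output_nodes = NULL,
                       drug_targets = character()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^\\s*targets\\s*,", lines[1],
                             ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  rules <- list(); ml <- integer()
  for (ln in lines) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed rule line: ", ln)
    node <- trimws(parts[1])
    lev <- if (length(parts) >= 3)
      as.integer(trimws(parts[length(parts)])) else 1L
    rhs <- trimws(paste(parts[2:(max(2, length(parts) - 1))],
                        collapse = ","))
    if (grepl("^@count\\(", rhs)) {
      inner <- sub("^@count\\((.*)\\)$", "\\1", rhs)
      toks <- strsplit(trimws(inner), "\\s+(?=[+-])", perl = TRUE)[[1]]
      pos <- list(); neg <- list()
      for (tk in toks) {
        sgn <- substr(tk, 1, 1)
        ex <- str2lang(trimws(substring(tk, 2)))
        if (sgn == "+") pos <- c(pos, list(ex)) else neg <- c(neg, list(ex))
      }
      rules[[node]] <- rule_count(node, pos, neg)
    } else if (identical(rhs, node)) {
      rules[[node]] <- rule_input(node)
    } else {
      rules[[node]] <- rule_expr(node, rhs)
    }
    ml[node] <- lev
  }
  edges <- do.call(rbind, lapply(rules, rule_edges))
  net <- regulatory_network(edges, nodes = names(rules),
                            output_nodes = output_nodes,
                            drug_targets = drug_targets)
  logical_model(net, rules, max_level = ml)
}
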