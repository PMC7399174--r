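# Independent oracles used across the suite. These deliberately avoid the
# package's solver machinery: states are enumerated exhaustively, shortest
# paths come from a hand-rolled Floyd-Warshall, and betweenness from
# explicit shortest-path enumeration.

# Next value of a single node from a plain interpretation of the rule
# structure (scalar, direct `any()` semantics).
oracle_next_value <- function(model, n, state) {
  r <- model$rules[[n]]
  on <- function(m) state[[m]] >= 1
  v <- switch(r$kind,
    input = state[[n]],
    link = {
      a <- if (length(r$activators)) any(vapply(r$activators, on, TRUE))
      i <- if (length(r$inhibitors)) any(vapply(r$inhibitors, on, TRUE))
      res <- if (!is.null(a) && !is.null(i)) {
        if (r$link_op == "AND_NOT") a && !i else a || !i
      } else if (!is.null(a)) a else !i
      as.numeric(res)
    },
    expr = {
      env <- lapply(as.list(state[all.vars(r$expr)]), function(z) z >= 1)
      as.numeric(eval(r$expr, envir = env))
    },
    count = {
      env <- lapply(as.list(state), function(z) z >= 1)
      p <- sum(vapply(r$pos, function(e) as.numeric(eval(e, env)), 0))
      q <- sum(vapply(r$neg, function(e) as.numeric(eval(e, env)), 0))
      p - q
    })
  min(max(v, 0), model$max_level[[n]])
}

oracle_next_state <- function(model, state, clamps = NULL) {
  out <- vapply(names(model$rules), function(n) {
    oracle_next_value(model, n, state)
  }, numeric(1))
  if (!is.null(clamps)) out[names(clamps)] <- as.numeric(clamps)
  out
}

# All states of a model (rows of a matrix, columns = sorted node names).
oracle_all_states <- function(model, clamps = NULL) {
  nodes <- sort(names(model$rules))
  domains <- lapply(nodes, function(n) {
    if (!is.null(clamps) && n %in% names(clamps))
      as.numeric(clamps[[n]])
    else 0:model$max_level[[n]]
  })
  names(domains) <- nodes
  M <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
  colnames(M) <- nodes
  M
}

# Brute-force fixed points by exhaustive enumeration of the whole state
# space; returns a matrix of fixed-point rows in lexicographic order.
oracle_fixed_points <- function(model, clamps = NULL) {
  M <- oracle_all_states(model, clamps)
  keep <- vapply(seq_len(nrow(M)), function(i) {
    st <- M[i, ]
    nxt <- oracle_next_state(model, st, clamps)
    all(nxt[colnames(M)] == st)
  }, TRUE)
  fp <- M[keep, , drop = FALSE]
  fp[do.call(order, as.data.frame(fp)), , drop = FALSE]
}

states_to_matrix <- function(states) {
  if (!length(states)) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  do.call(rbind, lapply(states, function(s) s[sort(names(s))]))
}

# Asynchronous single-node-update successors of a state (own stepping).
oracle_successors <- function(model, st, clamps = NULL) {
  succ <- list()
  for (n in names(model$rules)) {
    if (!is.null(clamps) && n %in% names(clamps)) next
    tgt <- oracle_next_value(model, n, st)
    if (tgt != st[[n]]) {
      s2 <- st
      s2[[n]] <- st[[n]] + sign(tgt - st[[n]])
      succ[[length(succ) + 1L]] <- s2
    }
  }
  succ
}

# --- graph oracles ----------------------------------------------------------

# Adjacency matrix of a regulatory_network (signs ignored).
oracle_adj <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$source[i], net$edges$target[i]] <- TRUE
  }
  A
}

# All-pairs shortest path lengths via Floyd-Warshall.
oracle_distances <- function(net) {
  A <- oracle_adj(net)
  n <- nrow(A)
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_efficiency <- function(net) {
  D <- oracle_distances(net)
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_pci <- function(net, node) {
  e0 <- oracle_efficiency(net)
  keep <- setdiff(net$nodes, node)
  sub <- regulatory_network(
    net$edges[net$edges$source %in% keep & net$edges$target %in% keep, ,
              drop = FALSE],
    nodes = keep)
  (e0 - oracle_efficiency(sub)) / e0
}

# All shortest paths s -> t by depth-first enumeration at the known
# shortest length; returns the list of node sequences.
oracle_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (v in colnames(A)[A[u, ]]) {
      if ((length(path) - 1) + 1 + D[v, t] == D[s, t] && !(v %in% path)) {
        walk(c(path, v))
      }
    }
  }
  walk(s)
  paths
}

# Betweenness by explicit path counting (directed, endpoints excluded).
oracle_betweenness <- function(net) {
  A <- oracle_adj(net)
  D <- oracle_distances(net)
  nodes <- net$nodes
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  for (s in nodes) {
    for (t in nodes) {
      if (s == t || !is.finite(D[s, t])) next
      paths <- oracle_shortest_paths(A, D, s, t)
      if (!length(paths)) next
      for (v in setdiff(nodes, c(s, t))) {
        through <- sum(vapply(paths, function(p) v %in% p, TRUE))
        btw[v] <- btw[v] + through / length(paths)
      }
    }
  }
  btw
}

oracle_harmonic_closeness <- function(net) {
  D <- oracle_distances(net)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  rowSums(inv) / (nrow(D) - 1)
}
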