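#' Global efficiency of a directed network
#'
#' `E = (1 / (N (N - 1))) * sum over ordered pairs i != j of 1 / d(i, j)`
#' with directed shortest-path lengths; unreachable pairs contribute 0.
#' Equals 1 exactly on a complete directed graph and 0 on an edgeless one.
#' Edge signs are ignored.
#'
#' @param net a [regulatory_network()] or an igraph graph.
#' @return numeric in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  g <- if (inherits(net, "igraph")) net else network_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- igraph::distances(g, mode = "out")
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Pathway cross-talk inhibition index (PCI)
#'
#' Relative reduction of global network efficiency caused by removing a
#' node and its incident edges:
#' `PCI(v) = (E(G) - E(G \ v)) / E(G)`, with the residual efficiency
#' computed over the remaining N - 1 nodes. High-PCI nodes carry
#' disproportionate information flow between pathways.
#'
#' @param net a [regulatory_network()] or igraph graph.
#' @param node node name (or vector of node names).
#' @return numeric PCI value(s), named when `node` has length > 1.
#' @export
pci <- function(net, node) {
  g <- if (inherits(net, "igraph")) net else network_igraph(net)
  e0 <- global_efficiency(g)
  if (e0 == 0) stop("PCI undefined: network has zero global efficiency")
  missing <- setdiff(node, igraph::V(g)$name)
  if (length(missing)) stop("unknown node(s): ",
                            paste(missing, collapse = ", "))
  out <- vapply(node, function(v) {
    (e0 - global_efficiency(igraph::delete_vertices(g, v))) / e0
  }, numeric(1))
  if (length(out) == 1L) unname(out) else out
}

#' Structural node centralities
#'
#' Out-degree, directed betweenness (endpoints excluded) and directed
#' closeness. Closeness uses the harmonic variant by default (mean of
#' inverse distances to every other node, well-defined on disconnected
#' graphs); the classic form (inverse mean distance within the reachable
#' set) is available via `closeness = "classic"`.
#'
#' @param net a [regulatory_network()] or igraph graph.
#' @param closeness `"harmonic"` (default) or `"classic"`.
#' @return data.frame with columns `node`, `out_degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(net, closeness = c("harmonic", "classic")) {
  closeness <- match.arg(closeness)
  g <- if (inherits(net, "igraph")) net else network_igraph(net)
  n <- igraph::vcount(g)
  btw <- igraph::betweenness(g, directed = TRUE)
  outdeg <- igraph::degree(g, mode = "out")
  d <- igraph::distances(g, mode = "out")
  if (closeness == "harmonic") {
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    cls <- rowSums(inv) / (n - 1)
  } else {
    cls <- igraph::closeness(g, mode = "out")
    cls[is.nan(cls)] <- 0
  }
  data.frame(node = igraph::V(g)$name,
             out_degree = as.integer(unname(outdeg)),
             betweenness = unname(btw),
             closeness = unname(cls),
             stringsAsFactors = FALSE)
}

#' Assemble a node feature table
#'
#' Structural features (out-degree, betweenness, closeness, PCI) for every
#' node, optionally joined with pass-through annotation columns (pathway
#' memberships, oncogene/tumor-suppressor flags) and an influence label.
#'
#' @param net a [regulatory_network()].
#' @param labels optional named vector (`"high"`/`"low"` or logical) of
#'   influence labels.
#' @param annotations optional data.frame with a `node` column; extra
#'   columns are passed through.
#' @inheritParams centralities
#' @return data.frame, one row per node.
#' @export
node_feature_table <- function(net, labels = NULL, annotations = NULL,
                               closeness = "harmonic") {
  tab <- centralities(net, closeness = closeness)
  tab$pci <- pci(net, tab$node)
  if (!is.null(labels)) {
    if (is.logical(labels)) {
      labels <- ifelse(labels, "high", "low")
    }
    tab$label <- factor(unname(labels[tab$node]),
                        levels = c("low", "high"))
  }
  if (!is.null(annotations)) {
    stopifnot("node" %in% names(annotations))
    tab <- merge(tab, annotations, by = "node", all.x = TRUE,
                 sort = FALSE)
  }
  tab[order(tab$node), , drop = FALSE]
}

#' Rank feature importance for influence classification
#'
#' Fits a random-forest classifier of the high/low influence label on the
#' feature columns and reports the Gini (mean decrease in impurity)
#' importance per feature, averaged over `n_repeats` seeded fits. In
#' balanced mode each tree subsamples the majority class down to the
#' minority class size.
#'
#' @param table data.frame of numeric/logical feature columns.
#' @param labels factor/character vector of class labels (2 classes).
#' @param balanced subsample the majority class per tree (default TRUE).
#' @param seed integer seed; run `r` uses `seed + r - 1`.
#' @param n_repeats number of seeded forest fits averaged (default 5).
#' @param ntree trees per forest.
#' @return data.frame with `feature`, `importance` (Gini importance
#'   normalized to sum to 1) and `raw_gini`, sorted by decreasing
#'   importance (class `importance_ranking`).
#' @export
importance_ranking <- function(table, labels, balanced = TRUE, seed = 1,
                               n_repeats = 5, ntree = 500) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("labels must contain 2 classes")
  X <- as.data.frame(table)
  X[] <- lapply(X, function(col) {
    if (is.logical(col)) as.integer(col) else col
  })
  sampsize <- if (balanced) {
    rep(min(base::table(labels)), nlevels(labels))
  } else {
    length(labels)
  }
  imp <- matrix(0, ncol(X), n_repeats,
                dimnames = list(colnames(X), NULL))
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r - 1L)
    fit <- randomForest::randomForest(
      x = X, y = labels, ntree = ntree, importance = FALSE,
      sampsize = sampsize, strata = if (balanced) labels)
    imp[, r] <- fit$importance[, "MeanDecreaseGini"]
  }
  raw <- rowMeans(imp)
  out <- data.frame(feature = rownames(imp),
                    importance = if (sum(raw) > 0) raw / sum(raw) else raw,
                    raw_gini = raw,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Pairwise Pearson correlations between feature columns
#'
#' Standard Pearson coefficients; zero-variance columns yield NA entries.
#'
#' @param table data.frame with at least 3 rows of numeric features.
#' @return correlation matrix.
#' @export
feature_correlations <- function(table) {
  X <- as.data.frame(table)
  X <- X[vapply(X, is.numeric, TRUE)]
  if (nrow(X) < 3) stop("need at least 3 rows to correlate features")
  suppressWarnings(stats::cor(as.matrix(X), method = "pearson"))
}
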