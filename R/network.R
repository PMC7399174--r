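#' Construct a signed regulatory network
#'
#' A regulatory network is a signed directed graph over named signaling
#' entities. Node names follow the field convention `SYMBOL` for a single
#' protein, `SYMBOL_f` for a family, `SYMBOL_g` for a gene and `SYMBOL_c`
#' for a complex. Two designated output nodes (a prosurvival and an
#' antisurvival phenotype node) collect the signal used for the Viability
#' readout; drug-target nodes are the entities clamped by inhibitors.
#'
#' @param edges data.frame with columns `source`, `sign` (+1 activation,
#'   -1 inhibition) and `target`.
#' @param nodes optional character vector of node names; defaults to the
#'   union of edge endpoints. Extra names declare isolated nodes.
#' @param output_nodes optional length-2 character vector
#'   `c(prosurvival, antisurvival)`.
#' @param drug_targets optional character vector of drug-target nodes.
#' @return An object of class `regulatory_network` with fields `nodes`
#'   (sorted), `edges` (deduplicated), `output_nodes`, `drug_targets`.
#' @export
regulatory_network <- function(edges, nodes = NULL, output_nodes = NULL,
                               drug_targets = character()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(), sign = integer(),
                        target = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop("edge signs must be +1 or -1")
  }
  edges <- unique(edges[, c("source", "sign", "target")])
  all_nodes <- sort(unique(c(edges$source, edges$target, nodes)))
  all_nodes <- all_nodes[nzchar(all_nodes)]
  if (anyDuplicated(all_nodes)) stop("duplicate node identifiers")
  if (!is.null(output_nodes)) {
    output_nodes <- as.character(output_nodes)
    if (length(output_nodes) != 2L) {
      stop("output_nodes must be c(prosurvival, antisurvival)")
    }
    missing <- setdiff(output_nodes, all_nodes)
    if (length(missing)) stop("output node not in network: ",
                              paste(missing, collapse = ", "))
  }
  missing_t <- setdiff(drug_targets, all_nodes)
  if (length(missing_t)) stop("drug target not in network: ",
                              paste(missing_t, collapse = ", "))
  edges <- edges[order(edges$source, edges$target, edges$sign), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = all_nodes, edges = edges,
                 output_nodes = output_nodes,
                 drug_targets = sort(unique(drug_targets))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "signed edges\n")
  if (!is.null(x$output_nodes)) {
    cat("  outputs: prosurvival =", x$output_nodes[1],
        "| antisurvival =", x$output_nodes[2], "\n")
  }
  if (length(x$drug_targets)) {
    cat("  drug targets:", paste(x$drug_targets, collapse = ", "), "\n")
  }
  invisible(x)
}

# Recognized sign vocabularies for SIF-like interaction files.
.default_sign_tokens <- c(
  "activate" = 1L, "activates" = 1L, "inhibit" = -1L, "inhibits" = -1L,
  "->" = 1L, "-|" = -1L, "1" = 1L, "-1" = -1L
)

#' Parse a signed interaction network from SIF-like text
#'
#' Reads a 3-column (source, sign, target) delimited file in the dialect
#' used by deposited prior-knowledge networks such as CASCADE. The sign
#' vocabulary is configurable; by default `activate`/`inhibit`, `->`/`-|`
#' and `1`/`-1` are all accepted. A header row is auto-detected when its
#' first field matches `header_keyword` (case-insensitive).
#'
#' @param path path to a file, or a character vector of lines via `text`.
#' @param text optional character vector of raw lines (overrides `path`).
#' @param sep field separator (default tab).
#' @param sign_tokens named integer vector mapping sign tokens to +1/-1.
#' @param header_keyword first-column keyword that marks a header row.
#' @param output_nodes,drug_targets passed to [regulatory_network()].
#' @return A [regulatory_network()].
#' @export
parse_network <- function(path = NULL, text = NULL, sep = "\t",
                          sign_tokens = .default_sign_tokens,
                          header_keyword = "source",
                          output_nodes = NULL, drug_targets = character()) {
  if (is.null(text)) text <- readLines(path, warn = FALSE)
  text <- text[nzchar(trimws(text))]
  if (!length(text)) {
    return(regulatory_network(NULL, output_nodes = output_nodes,
                              drug_targets = drug_targets))
  }
  fields <- strsplit(text, sep, fixed = TRUE)
  first <- trimws(fields[[1]])
  if (length(first) >= 1 &&
      tolower(first[1]) == tolower(header_keyword)) {
    fields <- fields[-1]
    text <- text[-1]
  }
  n <- length(fields)
  if (!n) {
    return(regulatory_network(NULL, output_nodes = output_nodes,
                              drug_targets = drug_targets))
  }
  bad <- which(vapply(fields, length, 1L) != 3L)
  if (length(bad)) {
    stop("malformed network line ", bad[1], " (expected 3 columns): ",
         text[bad[1]])
  }
  m <- do.call(rbind, lapply(fields, trimws))
  sgn <- sign_tokens[m[, 2]]
  if (anyNA(sgn)) {
    i <- which(is.na(sgn))[1]
    stop("unknown sign token on line ", i, ": '", m[i, 2], "'")
  }
  edges <- data.frame(source = m[, 1], sign = as.integer(sgn),
                      target = m[, 3], stringsAsFactors = FALSE)
  regulatory_network(edges, output_nodes = output_nodes,
                     drug_targets = drug_targets)
}

#' Write a network as a 3-column TSV
#'
#' Inverse of [parse_network()]: edges are written in canonical (sorted)
#' order with `activate`/`inhibit` sign tokens and no header.
#'
#' @param net a [regulatory_network()].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  tok <- ifelse(net$edges$sign > 0, "activate", "inhibit")
  writeLines(paste(net$edges$source, tok, net$edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' Validate network connectivity and structure
#'
#' Report-only diagnostics: nodes unreachable from any drug target, nodes
#' with no directed path to either output node, self-loops, dual (both-sign)
#' regulations, isolated nodes, and output nodes with no incoming edge.
#'
#' @param net a [regulatory_network()].
#' @return A list of class `network_validation` with one character vector
#'   per issue class and a logical `ok` (TRUE when every connectivity check
#'   is clean).
#' @export
validate_network <- function(net) {
  g <- network_igraph(net)
  nodes <- net$nodes
  unreachable <- character()
  if (length(net$drug_targets)) {
    d <- igraph::distances(g, v = net$drug_targets, mode = "out")
    reach <- apply(is.finite(d), 2, any)
    unreachable <- sort(setdiff(nodes[!reach], net$drug_targets))
  }
  no_path_to_output <- character()
  disconnected_outputs <- character()
  if (!is.null(net$output_nodes)) {
    d <- igraph::distances(g, v = net$output_nodes, mode = "in")
    reach <- apply(is.finite(d), 2, any)
    no_path_to_output <- sort(setdiff(nodes[!reach], net$output_nodes))
    indeg <- igraph::degree(g, v = net$output_nodes, mode = "in")
    disconnected_outputs <- net$output_nodes[indeg == 0]
  }
  self_loops <- sort(unique(
    net$edges$source[net$edges$source == net$edges$target]))
  pair_key <- paste(net$edges$source, net$edges$target)
  dual <- sort(unique(pair_key[duplicated(pair_key)]))
  deg <- igraph::degree(g, mode = "all")
  isolated <- sort(nodes[deg == 0])
  res <- list(unreachable_from_targets = unreachable,
              no_path_to_output = no_path_to_output,
              disconnected_outputs = disconnected_outputs,
              self_loops = self_loops,
              dual_regulations = dual,
              isolated_nodes = isolated)
  res$ok <- !length(unreachable) && !length(no_path_to_output) &&
    !length(disconnected_outputs)
  class(res) <- "network_validation"
  res
}

#' @export
print.network_validation <- function(x, ...) {
  for (nm in setdiff(names(x), "ok")) {
    cat(nm, ": ", if (length(x[[nm]])) paste(x[[nm]], collapse = ", ")
        else "none", "\n", sep = "")
  }
  invisible(x)
}

# igraph view of the network (signs kept as an edge attribute)
network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  igraph::E(g)$sign <- net$edges$sign
  g
}

#' Construct a drug panel
#'
#' Maps drug abbreviations to the network nodes they inhibit. A drug may
#' target more than one node (e.g. a TGFBR inhibitor hitting both TGFBR1
#' and ACVR1C); simulation clamps the union of targets to 0.
#'
#' @param targets named list: drug abbreviation -> character vector of
#'   target node names.
#' @param full_names optional named character vector of full drug names.
#' @param net optional [regulatory_network()] used to check that every
#'   target exists.
#' @return An object of class `drug_panel`.
#' @export
drug_panel <- function(targets, full_names = NULL, net = NULL) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  targets <- lapply(targets, function(x) sort(unique(trimws(x))))
  if (!is.null(net)) {
    for (d in names(targets)) {
      missing <- setdiff(targets[[d]], net$nodes)
      if (length(missing)) {
        stop("drug ", d, " targets node(s) not in network: ",
             paste(missing, collapse = ", "))
      }
    }
  }
  structure(list(targets = targets[order(names(targets))],
                 full_names = full_names),
            class = "drug_panel")
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("drug_panel:", length(x$targets), "drugs\n")
  for (d in names(x$targets)) {
    cat("  ", d, " -> ", paste(x$targets[[d]], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Parse a drug panel table
#'
#' Expects a delimited table with a drug-abbreviation column and a
#' comma-separated target-node column (optionally a full-name column).
#' A header row is auto-detected when the first field is `drug`.
#'
#' @param path file path.
#' @param net optional network for target validation.
#' @param sep field separator (default tab).
#' @return A [drug_panel()].
#' @export
parse_panel <- function(path, net = NULL, sep = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (length(fields) && tolower(trimws(fields[[1]][1])) == "drug") {
    fields <- fields[-1]
  }
  targets <- list()
  full <- character()
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) < 2) stop("malformed panel line ", i)
    targets[[f[1]]] <- trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    if (length(f) >= 3) full[f[1]] <- f[3]
  }
  drug_panel(targets, full_names = if (length(full)) full else NULL,
             net = net)
}

#' Write a drug panel as TSV
#' @param panel a [drug_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  lines <- vapply(names(panel$targets), function(d) {
    paste(d, paste(panel$targets[[d]], collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' All unordered drug pairs of a panel
#'
#' @param drugs a [drug_panel()] or a character vector of drug names.
#' @return data.frame with columns `drug_a`, `drug_b`, one row per
#'   unordered pair (d*(d-1)/2 rows for d drugs).
#' @export
drug_pairs <- function(drugs) {
  if (inherits(drugs, "drug_panel")) drugs <- names(drugs$targets)
  drugs <- sort(unique(as.character(drugs)))
  if (length(drugs) < 2) {
    return(data.frame(drug_a = character(), drug_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(length(drugs), 2)
  data.frame(drug_a = drugs[idx[1, ]], drug_b = drugs[idx[2, ]],
             stringsAsFactors = FALSE)
}
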