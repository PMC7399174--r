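# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a random signed regulatory network
#'
#' Builds a connected signed digraph over a layer of interior nodes (a
#' random spine guaranteeing connectivity plus random forward edges, and
#' optionally `n_cycles` feedback back-edges), wires two output nodes
#' `Prosurvival` and `Antisurvival` from the terminal portion of the layer
#' (up to 3 regulators each, fewer when the edge budget is tight), and
#' designates the earliest interior nodes as drug targets. Deterministic
#' given `seed`.
#'
#' @param n_nodes total node count (including the two outputs).
#' @param n_edges total edge count.
#' @param frac_inhibitory fraction of inhibitory interior edges.
#' @param n_targets number of designated drug-target nodes.
#' @param n_cycles number of feedback back-edges (default 0: acyclic).
#' @param seed integer seed.
#' @return A [regulatory_network()].
#' @export
gen_network <- function(n_nodes, n_edges, frac_inhibitory = 0.25,
                        n_targets = 4, n_cycles = 0, seed = 1) {
  m <- n_nodes - 2
  if (m < 3) stop("need at least 5 nodes (3 interior + 2 outputs)")
  if (n_targets >= n_nodes - 2) stop("n_targets must be < n_nodes - 2")
  n_out_regs <- max(1, min(3, floor((n_edges - (m - 1) - n_cycles) / 2)))
  base_needed <- (m - 1) + 2 * n_out_regs + n_cycles
  if (n_edges < base_needed) {
    stop("n_edges too small: need at least ", base_needed)
  }
  max_forward <- m * (m - 1) / 2
  n_extra <- n_edges - base_needed
  if ((m - 1) + n_extra > max_forward) stop("n_edges too large for ",
                                            m, " interior nodes")
  with_seed(seed, {
    interior <- sprintf("V%02d", seq_len(m))
    spine <- data.frame(
      from = vapply(2:m, function(i) sample.int(i - 1, 1), 1L),
      to = 2:m)
    pool <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
    pool_key <- paste(pool[, 1], pool[, 2])
    used <- paste(spine$from, spine$to)
    free <- setdiff(pool_key, used)
    extra <- if (n_extra > 0) {
      picked <- sample(free, n_extra)
      ij <- do.call(rbind, strsplit(picked, " "))
      data.frame(from = as.integer(ij[, 1]), to = as.integer(ij[, 2]))
    }
    back <- if (n_cycles > 0) {
      picked <- sample(pool_key, n_cycles)
      ij <- do.call(rbind, strsplit(picked, " "))
      data.frame(from = as.integer(ij[, 2]), to = as.integer(ij[, 1]))
    }
    ie <- rbind(spine, extra, back)
    edges <- data.frame(
      source = interior[ie$from],
      sign = ifelse(stats::runif(nrow(ie)) < frac_inhibitory, -1L, 1L),
      target = interior[ie$to], stringsAsFactors = FALSE)
    tail_pool <- utils::tail(interior, max(n_out_regs,
                                           ceiling(m / 3)))
    out_edges <- do.call(rbind, lapply(
      c("Prosurvival", "Antisurvival"), function(o) {
        data.frame(source = sample(tail_pool, n_out_regs),
                   sign = 1L, target = o, stringsAsFactors = FALSE)
      }))
    regulatory_network(rbind(edges, out_edges),
                       nodes = c(interior, "Prosurvival", "Antisurvival"),
                       output_nodes = c("Prosurvival", "Antisurvival"),
                       drug_targets = interior[seq_len(n_targets)])
  })
}

#' Generate baseline profiles around a planted stable state
#'
#' Emulates the two real-world profile sources: an omics-inferred profile
#' covering (nearly) all nodes but carrying a configurable error rate, and
#' a sparse literature profile covering only a small curated node subset
#' without error. The truth profile is the planted stable state binarized
#' at level >= 1.
#'
#' @param planted_model the planted [logical_model()] (used when `state`
#'   is NULL to compute its unique stable state).
#' @param flip_fraction fraction of omics entries inverted (error rate).
#' @param na_fraction fraction of omics entries set to NA (missingness).
#' @param n_literature number of nodes covered by the literature profile
#'   (default: a quarter of the nodes, emulating sparse curation).
#' @param state optional planted stable state (named numeric).
#' @param cell_line label for the generated profiles.
#' @param seed integer seed.
#' @return list with [activity_profile()] elements `literature`, `omics`,
#'   `truth`.
#' @export
gen_profiles <- function(planted_model, flip_fraction = 0,
                         na_fraction = 0, n_literature = NULL,
                         state = NULL, cell_line = "SYN-1", seed = 1) {
  if (flip_fraction < 0 || flip_fraction > 1 ||
      na_fraction < 0 || na_fraction > 1) {
    stop("fractions must be in [0, 1]")
  }
  if (is.null(state)) {
    sts <- stable_states(planted_model)
    if (length(sts) != 1L) {
      stop("planted model must have a unique stable state; pass `state`")
    }
    state <- sts[[1]]
  }
  truth_v <- stats::setNames(as.integer(state >= 1), names(state))
  n <- length(truth_v)
  if (is.null(n_literature)) n_literature <- max(1L, ceiling(n / 4))
  if (n_literature > n) stop("n_literature exceeds node count")
  with_seed(seed, {
    om <- truth_v
    n_flip <- floor(flip_fraction * n)
    if (n_flip > 0) {
      idx <- sample.int(n, n_flip)
      om[idx] <- 1L - om[idx]
    }
    n_na <- floor(na_fraction * n)
    if (n_na > 0) om[sample.int(n, n_na)] <- NA_integer_
    lit <- rep(NA_integer_, n)
    names(lit) <- names(truth_v)
    keep <- sample.int(n, n_literature)
    lit[keep] <- truth_v[keep]
    list(literature = activity_profile(cell_line, lit, "literature"),
         omics = activity_profile(cell_line, om, "omics"),
         truth = activity_profile(cell_line, truth_v, "combined"))
  })
}

#' Generate a dose-matrix screen with planted synergies
#'
#' Monotone single-agent dose-response curves per drug; each combination
#' cell equals the stronger single-agent viability at the matched doses
#' plus `excess_depth` for planted pairs (0 otherwise) plus Gaussian noise.
#' At zero noise, binarizing the mean HSA excess at any cutoff between
#' `excess_depth` and 0 recovers the planted synergy set exactly.
#'
#' @param panel a [drug_panel()].
#' @param planted_synergies data.frame with `drug_a`, `drug_b` (or list of
#'   length-2 character vectors).
#' @param n_doses doses per drug (default 4).
#' @param excess_depth planted mean HSA excess for synergistic pairs
#'   (default -0.2; must undercut the calling cutoff).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param cell_line label.
#' @param seed integer seed.
#' @return list of [screen_record()] objects, one per drug pair.
#' @export
gen_screen <- function(panel, planted_synergies, n_doses = 4,
                       excess_depth = -0.2, noise_sd = 0,
                       cell_line = "SYN-1", seed = 1) {
  if (is.list(planted_synergies) && !is.data.frame(planted_synergies)) {
    planted_synergies <- do.call(rbind, lapply(planted_synergies,
      function(p) data.frame(drug_a = p[1], drug_b = p[2])))
  }
  planted_keys <- if (!is.null(planted_synergies) &&
                      nrow(planted_synergies))
    pair_key(planted_synergies$drug_a, planted_synergies$drug_b)
  else character()
  drugs <- names(panel$targets)
  bad <- setdiff(planted_keys, pair_key(drug_pairs(drugs)$drug_a,
                                        drug_pairs(drugs)$drug_b))
  if (length(bad)) stop("planted pair(s) not in panel: ",
                        paste(bad, collapse = ", "))
  with_seed(seed, {
    doses <- as.character(seq_len(n_doses))
    curves <- lapply(drugs, function(d) {
      top <- stats::runif(1, 0.9, 1.0)
      bottom <- stats::runif(1, 0.35, 0.55)
      stats::setNames(seq(top, bottom, length.out = n_doses), doses)
    })
    names(curves) <- drugs
    pairs <- drug_pairs(drugs)
    records <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$drug_a[i]; b <- pairs$drug_b[i]
      depth <- if (pair_key(a, b) %in% planted_keys) excess_depth else 0
      combo <- outer(curves[[a]], curves[[b]], pmin) + depth
      if (noise_sd > 0) {
        combo <- combo + matrix(stats::rnorm(length(combo), 0, noise_sd),
                                nrow(combo))
      }
      dimnames(combo) <- list(doses, doses)
      screen_record(cell_line, a, b, curves[[a]], curves[[b]], combo)
    })
    names(records) <- pair_key(pairs$drug_a, pairs$drug_b)
    records
  })
}

#' Generate a complete synthetic study bundle with planted ground truth
#'
#' Constructs a fixed signaling motif in which three drug-target branches
#' converge redundantly (via a majority gate) on a hub sustaining the
#' Prosurvival output, so that no single drug but any pair of the three
#' branch drugs drops Viability: the three branch-drug pairs are the
#' planted synergies, expressible in the planted model by construction.
#' The remaining drugs hit redundantly buffered or inert side chains and
#' are planted non-synergistic. The generic model differs from the planted
#' cell-line model by known AND_NOT -> OR_NOT link-operator flips on the
#' two inhibitor-carrying branch nodes, which calibration against the
#' planted stable state must recover. Profiles and a dose-matrix screen
#' with the planted synergy set complete the bundle.
#'
#' Motif layout (24 nodes with the default 6 decoys): a constitutively
#' active source `K`; six drug-target nodes `TGT1..TGT6`; branch nodes
#' `BR1..BR3` (BR1/BR2 inhibited by K, active only with the OR_NOT
#' operator); majority hub `HUB`; redundant prosurvival feeders
#' `RED1` (TGT4 or K) and `RED2` (K); antisurvival feeders `M1`
#' (TGT5 and not HUB), `M2` (TGT6 and not K), `N0` (not K); a decoy chain
#' off K feeding RED1; and the two output nodes.
#'
#' @param n_decoys length of the inert decoy chain (default 6).
#' @param flip_fraction,na_fraction,n_literature passed to
#'   [gen_profiles()].
#' @param noise_sd,n_doses,excess_depth passed to [gen_screen()].
#' @param cell_line label.
#' @param seed integer seed for all stochastic parts.
#' @return An object of class `synthetic_bundle`: `network`,
#'   `generic_model`, `planted_model`, `planted_flips`, `planted_state`,
#'   `profiles` (literature/omics/truth), `panel`, `screen`,
#'   `planted_synergies`, `params`.
#' @export
gen_bundle <- function(n_decoys = 6, flip_fraction = 0, na_fraction = 0,
                       n_literature = NULL, noise_sd = 0, n_doses = 4,
                       excess_depth = -0.2, cell_line = "SYN-1",
                       seed = 1) {
  tgts <- paste0("TGT", 1:6)
  decoys <- if (n_decoys > 0) sprintf("DEC%02d", seq_len(n_decoys))
            else character()
  edges <- rbind(
    data.frame(source = "K", sign = 1L, target = tgts),
    data.frame(source = tgts[1:3], sign = 1L,
               target = c("BR1", "BR2", "BR3")),
    data.frame(source = "K", sign = -1L, target = c("BR1", "BR2")),
    data.frame(source = c("BR1", "BR2", "BR3"), sign = 1L,
               target = "HUB"),
    data.frame(source = c("TGT4", "K"), sign = 1L, target = "RED1"),
    data.frame(source = "K", sign = 1L, target = "RED2"),
    data.frame(source = c("TGT5", "HUB"), sign = c(1L, -1L),
               target = "M1"),
    data.frame(source = c("TGT6", "K"), sign = c(1L, -1L),
               target = "M2"),
    data.frame(source = "K", sign = -1L, target = "N0"),
    data.frame(source = c("HUB", "RED1", "RED2"), sign = 1L,
               target = "Prosurvival"),
    data.frame(source = c("M1", "M2", "N0"), sign = 1L,
               target = "Antisurvival"))
  if (n_decoys > 0) {
    edges <- rbind(edges,
      data.frame(source = c("K", utils::head(decoys, -1)), sign = 1L,
                 target = decoys),
      data.frame(source = decoys[n_decoys], sign = 1L, target = "RED1"))
  }
  net <- regulatory_network(edges,
                            output_nodes = c("Prosurvival",
                                             "Antisurvival"),
                            drug_targets = tgts)
  generic <- default_rules(net)
  # the source node is constitutively active, not a free input
  generic <- apply_edits(generic, list(
    list(kind = "set_rule", node = "K", rule = "1")))
  # the majority gate is the planted convergence mechanism
  generic <- apply_edits(generic, list(
    list(kind = "set_rule", node = "HUB",
         rule = "(BR1 & BR2) | (BR1 & BR3) | (BR2 & BR3)")))
  planted_flips <- c("BR1", "BR2")
  planted <- apply_edits(generic, lapply(planted_flips, function(n) {
    list(kind = "set_link_operator", node = n, op = "OR_NOT")
  }))
  sts <- stable_states(planted)
  stopifnot(length(sts) == 1L)
  planted_state <- sts[[1]]
  panel <- drug_panel(stats::setNames(as.list(tgts), paste0("D", 1:6)),
                      net = net)
  planted_synergies <- data.frame(drug_a = c("D1", "D1", "D2"),
                                  drug_b = c("D2", "D3", "D3"),
                                  stringsAsFactors = FALSE)
  profiles <- gen_profiles(planted, flip_fraction = flip_fraction,
                           na_fraction = na_fraction,
                           n_literature = n_literature,
                           state = planted_state, cell_line = cell_line,
                           seed = seed)
  screen <- gen_screen(panel, planted_synergies, n_doses = n_doses,
                       excess_depth = excess_depth, noise_sd = noise_sd,
                       cell_line = cell_line, seed = seed)
  structure(list(network = net, generic_model = generic,
                 planted_model = planted, planted_flips = planted_flips,
                 planted_state = planted_state, profiles = profiles,
                 panel = panel, screen = screen,
                 planted_synergies = planted_synergies,
                 params = list(n_decoys = n_decoys,
                               flip_fraction = flip_fraction,
                               na_fraction = na_fraction,
                               noise_sd = noise_sd, n_doses = n_doses,
                               excess_depth = excess_depth, seed = seed),
                 cell_line = cell_line),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", length(x$network$nodes), "nodes,",
      nrow(x$network$edges), "edges,", length(x$panel$targets),
      "drugs,", nrow(x$planted_synergies), "planted synergies\n")
  invisible(x)
}

#' Generate a random logical model (network plus default rules)
#'
#' Convenience wrapper for property testing: a random network via
#' [gen_network()] with default rules and a random subset of nodes flipped
#' to the OR_NOT link operator.
#'
#' @inheritParams gen_network
#' @param frac_or_not fraction of eligible nodes given OR_NOT.
#' @return A [logical_model()].
#' @export
gen_model <- function(n_nodes, n_edges, frac_inhibitory = 0.25,
                      n_targets = 2, n_cycles = 0, frac_or_not = 0.3,
                      seed = 1) {
  net <- gen_network(n_nodes, n_edges, frac_inhibitory, n_targets,
                     n_cycles, seed)
  model <- default_rules(net)
  eligible <- names(model$rules)[vapply(model$rules, function(r) {
    r$kind == "link" && length(r$activators) > 0 &&
      length(r$inhibitors) > 0
  }, TRUE)]
  with_seed(seed + 1L, {
    flip <- eligible[stats::runif(length(eligible)) < frac_or_not]
    if (length(flip)) {
      model <- apply_edits(model, lapply(flip, function(n) {
        list(kind = "set_link_operator", node = n, op = "OR_NOT")
      }))
    }
    model
  })
}

#' Write a full synthetic bundle to a directory as plain-text files
#'
#' Network TSV, generic/planted rule files, profile TSVs, panel TSV and
#' screen CSV.
#'
#' @param bundle a [gen_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bundle$network, file.path(dir, "network.tsv"))
  write_rules(bundle$generic_model, file.path(dir, "generic_rules.txt"))
  write_rules(bundle$planted_model, file.path(dir, "planted_rules.txt"))
  write_profile(bundle$profiles$literature,
                file.path(dir, "profile_literature.tsv"))
  write_profile(bundle$profiles$omics, file.path(dir, "profile_omics.tsv"))
  write_profile(bundle$profiles$truth, file.path(dir, "profile_truth.tsv"))
  write_panel(bundle$panel, file.path(dir, "panel.tsv"))
  write_screen(bundle$screen, file.path(dir, "screen.csv"))
  invisible(dir)
}
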