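# Per-condition prediction table used by the influence sweep: viability and
# attractor kind for every single-drug and drug-pair condition, plus the
# synergy call per pair.
condition_predictions <- function(model, panel, wt_state,
                                  extra_clamps = NULL, max_states = 4096) {
  drugs <- names(panel$targets)
  singles <- lapply(drugs, function(d) {
    simulate_perturbation(model, d, panel, wt_state = wt_state,
                          extra_clamps = extra_clamps,
                          max_states = max_states)
  })
  names(singles) <- drugs
  sv <- vapply(singles, `[[`, numeric(1), "viability")
  skind <- vapply(singles, `[[`, "", "attractor_kind")
  pairs <- drug_pairs(drugs)
  pv <- numeric(nrow(pairs)); pkind <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- simulate_perturbation(model, c(pairs$drug_a[i], pairs$drug_b[i]),
                               panel, wt_state = wt_state,
                               extra_clamps = extra_clamps,
                               max_states = max_states)
    pv[i] <- r$viability; pkind[i] <- r$attractor_kind
  }
  pairs$viability_ab <- pv
  pairs$predicted <- pv < pmin(sv[pairs$drug_a], sv[pairs$drug_b])
  pairs$kind <- pkind
  list(singles = data.frame(drug = drugs, viability = unname(sv),
                            kind = unname(skind),
                            stringsAsFactors = FALSE),
       pairs = pairs)
}

#' Systematic node-influence sweep
#'
#' For every Boolean non-output node and both perturbation modes the node
#' is clamped at its wild-type stable-state value (`fix`) or at one minus
#' that value (`invert`); all single-drug and drug-pair conditions are then
#' re-simulated on the mutated model and the synergy calls are compared
#' with the wild-type calls. For d drugs each mutant is evaluated on
#' `d + d*(d-1)/2` conditions, i.e. `2 * n_swept * (d + d*(d-1)/2)`
#' mutant-condition combinations in total (171 conditions per mutant for
#' an 18-drug panel). Drug clamps override the sweep clamp when a swept
#' node is itself a target of the condition's drugs.
#'
#' When `observed` calls are supplied each changed pair is classified by
#' its wild-type and mutant confusion class, giving per-class gain/loss
#' counts (a TP turning into an FN counts one `tp_loss` and one
#' `fn_gain`). A condition whose mutant attractor is complex or undecided
#' counts toward `complex_attractors` (conservative toward high
#' influence).
#'
#' @param model calibrated [logical_model()].
#' @param panel a [drug_panel()].
#' @param observed optional `observed_calls` data.frame for confusion-class
#'   deltas.
#' @param wt_state wild-type stable state; selected from the model (first
#'   lexicographic) when NULL; error when the model has none.
#' @param max_states cap for the asynchronous fallback per condition.
#' @return An object of class `influence_records`: data.frame with one row
#'   per (node, mode) holding the gain/loss counts, `complex_attractors`,
#'   `total_changes`, and a list-column `changed_pairs` of pair keys.
#' @export
influence_sweep <- function(model, panel, observed = NULL,
                            wt_state = NULL, max_states = 4096) {
  if (is.null(wt_state)) {
    sts <- stable_states(model)
    if (!length(sts)) stop("model has no wild-type stable state")
    wt_state <- sts[[1]]
  }
  wt <- condition_predictions(model, panel, wt_state,
                              max_states = max_states)
  wt_pairs <- wt$pairs
  key <- pair_key(wt_pairs$drug_a, wt_pairs$drug_b)
  obs <- rep(NA, length(key))
  if (!is.null(observed)) {
    obs <- observed$observed[match(key, pair_key(observed$drug_a,
                                                 observed$drug_b))]
  }
  cls <- function(pred) {
    ifelse(is.na(pred) | is.na(obs), NA_character_,
           ifelse(pred & obs, "tp",
                  ifelse(pred & !obs, "fp",
                         ifelse(!pred & obs, "fn", "tn"))))
  }
  wt_cls <- cls(wt_pairs$predicted)

  outputs <- model$network$output_nodes
  swept <- sort(setdiff(names(model$rules)[model$max_level == 1],
                        outputs))
  rows <- list()
  for (n in swept) {
    for (mode in c("fix", "invert")) {
      value <- if (mode == "fix") wt_state[[n]] else 1 - wt_state[[n]]
      mut <- condition_predictions(
        model, panel, wt_state,
        extra_clamps = stats::setNames(value, n),
        max_states = max_states)
      complex_n <- sum(mut$pairs$kind != "stable_state") +
        sum(mut$singles$kind != "stable_state")
      changed <- !is.na(wt_pairs$predicted) & !is.na(mut$pairs$predicted) &
        wt_pairs$predicted != mut$pairs$predicted
      mut_cls <- cls(mut$pairs$predicted)
      count_cls <- function(class, which) {
        if (is.null(observed)) return(NA_integer_)
        sum(changed & !is.na(wt_cls) & !is.na(mut_cls) &
              (if (which == "loss") wt_cls == class else mut_cls == class))
      }
      gains_losses <- c(
        tp_gain = count_cls("tp", "gain"), tp_loss = count_cls("tp", "loss"),
        tn_gain = count_cls("tn", "gain"), tn_loss = count_cls("tn", "loss"),
        fp_gain = count_cls("fp", "gain"), fp_loss = count_cls("fp", "loss"),
        fn_gain = count_cls("fn", "gain"), fn_loss = count_cls("fn", "loss"))
      syn_gain <- sum(changed & mut$pairs$predicted)
      syn_loss <- sum(changed & wt_pairs$predicted)
      total <- if (is.null(observed)) syn_gain + syn_loss
               else sum(gains_losses)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(node = n, mode = mode, stringsAsFactors = FALSE),
        as.data.frame(as.list(gains_losses)),
        data.frame(syn_gain = syn_gain, syn_loss = syn_loss,
                   complex_attractors = complex_n,
                   total_changes = total))
      rows[[length(rows)]]$changed_pairs <- list(key[changed])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "wt_pairs") <- wt_pairs
  attr(out, "wt_state") <- wt_state
  class(out) <- c("influence_records", "data.frame")
  out
}

#' Classify and rank swept nodes by influence
#'
#' A node is high-influence when any of its fix/invert perturbations
#' changed at least one synergy prediction or produced a complex (or
#' undecided) attractor; all other swept nodes are low-influence. The
#' ranking orders nodes by their summed change counts (both modes),
#' descending, ties broken by node name.
#'
#' @param records an `influence_records` data.frame from
#'   [influence_sweep()].
#' @return An object of class `influence_classification`: `high_influence`
#'   and `low_influence` node sets and a `ranking` data.frame (`node`,
#'   `total_changes`, `complex_attractors`, `high`).
#' @export
classify_and_rank <- function(records) {
  agg <- stats::aggregate(
    cbind(total_changes, complex_attractors) ~ node,
    data = as.data.frame(records)[, c("node", "total_changes",
                                      "complex_attractors")],
    FUN = sum)
  agg$high <- agg$total_changes > 0 | agg$complex_attractors > 0
  agg <- agg[order(-agg$total_changes, agg$node), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(high_influence = sort(agg$node[agg$high]),
                 low_influence = sort(agg$node[!agg$high]),
                 ranking = agg),
            class = "influence_classification")
}

#' @export
print.influence_classification <- function(x, ...) {
  cat("influence_classification:", length(x$high_influence),
      "high-influence /", length(x$low_influence),
      "low-influence nodes\n")
  utils::head(x$ranking, 10) |> print()
  invisible(x)
}

#' Restricted-calibration comparison experiment
#'
#' Calibrates the generic model three times: with the full baseline
#' profile, with the profile restricted to the top `k_top` high-influence
#' nodes, and with the profile restricted to `k_bottom` non-influential
#' nodes; then predicts synergies with each calibrated model and scores
#' them against the observed calls. The defaults mirror a top-36 /
#' bottom-38 design.
#'
#' @param model generic [logical_model()].
#' @param profile combined [activity_profile()].
#' @param classification an `influence_classification`.
#' @param panel a [drug_panel()].
#' @param observed an `observed_calls` data.frame.
#' @param k_top number of top-ranked high-influence nodes (default 36).
#' @param k_bottom number of non-influential nodes (default 38).
#' @param max_rounds passed to [calibrate()].
#' @return data.frame with one row per calibration (`full`,
#'   `top_influential`, `bottom_noninfluential`): profile size, matched
#'   fraction, flips, confusion counts and metrics.
#' @export
restricted_calibration_experiment <- function(model, profile,
                                              classification, panel,
                                              observed, k_top = 36,
                                              k_bottom = 38,
                                              max_rounds = 10) {
  ranking <- classification$ranking
  high <- ranking$node[ranking$high]
  low <- classification$low_influence
  if (k_top > length(high)) {
    stop("k_top (", k_top, ") exceeds the ", length(high),
         " high-influence nodes")
  }
  if (k_bottom > length(low)) {
    stop("k_bottom (", k_bottom, ") exceeds the ", length(low),
         " non-influential nodes")
  }
  sets <- list(full = names(profile$values),
               top_influential = utils::head(high, k_top),
               bottom_noninfluential = utils::head(sort(low), k_bottom))
  rows <- lapply(names(sets), function(nm) {
    prof <- restrict_profile(profile, sets[[nm]])
    if (!any(!is.na(prof$values))) {
      stop("restricted profile '", nm, "' has no non-NA entries")
    }
    cal <- calibrate(model, prof, max_rounds = max_rounds)
    calls <- predict_synergies(cal$model, panel,
                               wt_state = cal$selected_state,
                               cell_line = profile$cell_line)
    cm <- confusion(calls, observed)
    data.frame(calibration = nm,
               n_profile_nodes = sum(!is.na(prof$values)),
               matched_fraction = cal$matched_fraction,
               flips = nrow(cal$changes),
               tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
               sensitivity = cm$sensitivity, ppv = cm$ppv, npv = cm$npv,
               balanced_accuracy = cm$balanced_accuracy, mcc = cm$mcc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mechanism subgraph for a predicted synergy
#'
#' Proposes the signaling mechanism behind a predicted synergistic pair:
#' (1) collect the pair-specific high-influence nodes (nodes whose fix or
#' invert changed this pair's call), excluding nodes whose perturbation
#' produced a complex attractor; (2) induce the network subgraph on them;
#' (3) find its furthest-downstream nodes (no outgoing edges within the
#' subgraph); (4) under the double perturbation, knock each such node out
#' (clamp 0) and in (clamp 1) and collect every node whose stable-state
#' activity changes; (5) add those activity-altered nodes to the subgraph;
#' (6) remove sink nodes that are not output nodes.
#'
#' @param model calibrated [logical_model()].
#' @param pair character vector `c(drug_a, drug_b)`.
#' @param records an `influence_records` from [influence_sweep()].
#' @param panel a [drug_panel()].
#' @param wt_state wild-type stable state (taken from `records` when NULL).
#' @return An object of class `mechanism_subgraph`: `nodes` data.frame
#'   (`node`, `role` in influence_loss/influence_gain/activity_altered/
#'   output), `edges` data.frame, and `downstream` (the step-3 node set).
#' @export
mechanism_subgraph <- function(model, pair, records, panel,
                               wt_state = NULL) {
  stopifnot(length(pair) == 2)
  key <- pair_key(pair[1], pair[2])
  wt_pairs <- attr(records, "wt_pairs")
  if (is.null(wt_state)) wt_state <- attr(records, "wt_state")
  wt_call <- wt_pairs$predicted[
    pair_key(wt_pairs$drug_a, wt_pairs$drug_b) == key]
  if (!length(wt_call) || !isTRUE(wt_call)) {
    stop("pair ", key, " is not predicted synergistic")
  }
  rec <- as.data.frame(records)
  rec$hit <- vapply(records$changed_pairs, function(k) key %in% k, TRUE)
  complex_nodes <- unique(rec$node[rec$complex_attractors > 0])
  hits <- rec[rec$hit & !(rec$node %in% complex_nodes), , drop = FALSE]
  infl_nodes <- unique(hits$node)
  if (!length(infl_nodes)) stop("no pair-specific influence nodes for ",
                                key)
  # synergy lost vs gained under the node perturbation
  role <- vapply(infl_nodes, function(n) {
    h <- hits[hits$node == n, ]
    if (any(h$syn_loss > 0)) "influence_loss" else "influence_gain"
  }, "")

  sub_edges <- function(nodes) {
    e <- model$network$edges
    e[e$source %in% nodes & e$target %in% nodes, , drop = FALSE]
  }
  e1 <- sub_edges(infl_nodes)
  downstream <- sort(setdiff(infl_nodes, unique(e1$source)))

  targets <- unique(unlist(panel$targets[pair]))
  base_clamps <- stats::setNames(rep(0, length(targets)), targets)
  base <- stable_states(model, clamps = base_clamps)
  altered <- character()
  if (length(base)) {
    base_st <- pick_continuation(base, wt_state)
    for (u in setdiff(downstream, targets)) {
      for (v in c(0, 1)) {
        cl <- c(base_clamps, stats::setNames(v, u))
        cl <- cl[!duplicated(names(cl))]
        sts <- tryCatch(stable_states(model, clamps = cl),
                        error = function(e) list())
        if (!length(sts)) next
        st <- pick_continuation(sts, base_st)
        diff <- names(st)[st != base_st[names(st)]]
        altered <- union(altered, setdiff(diff, u))
      }
    }
  }
  all_nodes <- union(infl_nodes, altered)
  e2 <- sub_edges(all_nodes)
  # prune non-output sinks
  sinks <- setdiff(all_nodes,
                   union(unique(e2$source), model$network$output_nodes))
  keep <- setdiff(all_nodes, sinks)
  e3 <- sub_edges(keep)
  roles <- stats::setNames(rep("activity_altered", length(keep)), keep)
  roles[intersect(keep, names(role))] <- role[intersect(keep, names(role))]
  outs <- intersect(keep, model$network$output_nodes)
  roles[outs] <- "output"
  structure(list(nodes = data.frame(node = sort(keep),
                                    role = unname(roles[sort(keep)]),
                                    stringsAsFactors = FALSE),
                 edges = e3, downstream = downstream, pair = sort(pair)),
            class = "mechanism_subgraph")
}

#' @export
print.mechanism_subgraph <- function(x, ...) {
  cat("mechanism_subgraph for", paste(x$pair, collapse = "+"), ":",
      nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  print(x$nodes)
  invisible(x)
}

#' Write an influence-records table as TSV
#' @param records an `influence_records` data.frame.
#' @param path output path.
#' @export
write_influence <- function(records, path) {
  df <- as.data.frame(records)
  df$changed_pairs <- vapply(records$changed_pairs, paste, "",
                             collapse = ";")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
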