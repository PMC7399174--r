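#' Construct a baseline activity profile
#'
#' Per-node unperturbed activity (0 inactive, 1 active, NA unknown) for one
#' cell line, from literature curation, omics inference, or their
#' combination.
#'
#' @param cell_line cell line label.
#' @param values named vector with entries 0, 1 or NA.
#' @param source one of `"literature"`, `"omics"`, `"combined"`.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(cell_line, values,
                             source = c("literature", "omics",
                                        "combined")) {
  source <- match.arg(source)
  v <- as.integer(values)
  names(v) <- names(values)
  if (!all(v %in% c(0L, 1L) | is.na(v))) {
    stop("profile values must be 0, 1 or NA")
  }
  structure(list(cell_line = cell_line, values = v[sort(names(v))],
                 source = source),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("activity_profile [", x$source, "] for ", x$cell_line, ": ",
      sum(!is.na(x$values)), " of ", length(x$values),
      " nodes assigned\n", sep = "")
  invisible(x)
}

#' Read / write profile TSV (node <TAB> value, NA token "NA")
#' @param path file path.
#' @param cell_line cell line label.
#' @param source profile source tag.
#' @return An [activity_profile()].
#' @export
read_profile <- function(path, cell_line, source = "literature") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("node", "value"),
                           na.strings = "NA",
                           stringsAsFactors = FALSE)
  activity_profile(cell_line,
                   stats::setNames(tab$value, tab$node), source)
}

#' @rdname read_profile
#' @param profile an [activity_profile()].
#' @export
write_profile <- function(profile, path) {
  writeLines(paste(names(profile$values),
                   ifelse(is.na(profile$values), "NA", profile$values),
                   sep = "\t"), path)
  invisible(path)
}

#' Combine literature and omics profiles
#'
#' Overlay with literature priority: per node the literature value is used
#' when non-NA, otherwise the omics-inferred value, otherwise NA.
#'
#' @param literature,omics [activity_profile()] objects for the same cell
#'   line.
#' @return Combined [activity_profile()].
#' @export
combine_profiles <- function(literature, omics) {
  if (!identical(literature$cell_line, omics$cell_line)) {
    stop("cell-line mismatch: ", literature$cell_line, " vs ",
         omics$cell_line)
  }
  nodes <- sort(union(names(literature$values), names(omics$values)))
  lit <- literature$values[nodes]
  om <- omics$values[nodes]
  v <- ifelse(!is.na(lit), lit, om)
  names(v) <- nodes
  activity_profile(literature$cell_line, v, source = "combined")
}

#' Restrict a profile to a node subset
#'
#' Values outside the subset are set to NA. Used for the high-influence
#' calibration experiment where baseline data is limited to the top
#' influential (or bottom non-influential) nodes.
#'
#' @param profile an [activity_profile()].
#' @param node_subset character vector of nodes to keep.
#' @return Restricted [activity_profile()].
#' @export
restrict_profile <- function(profile, node_subset) {
  v <- profile$values
  v[!(names(v) %in% node_subset)] <- NA
  activity_profile(profile$cell_line, v, source = profile$source)
}

#' Agreement between a state and a profile
#'
#' Fraction of non-NA profile entries matched by the state, where a
#' multi-level value counts as active when >= 1. NA entries are excluded
#' from the denominator.
#'
#' @param state named numeric state vector.
#' @param profile an [activity_profile()].
#' @return numeric in `[0, 1]`.
#' @export
agreement <- function(state, profile) {
  v <- profile$values
  v <- v[!is.na(v)]
  v <- v[names(v) %in% names(state)]
  if (!length(v)) stop("profile has no non-NA entries over the state")
  mean((state[names(v)] >= 1) == (v == 1))
}

# Select the stable state maximizing agreement; ties broken
# lexicographically (states arrive lex-sorted from stable_states()).
select_state <- function(states, profile) {
  if (!length(states)) return(NULL)
  agr <- vapply(states, agreement, numeric(1), profile = profile)
  states[[which.max(agr)]]
}

#' Calibrate a model to a baseline activity profile
#'
#' Iteratively modifies link operators until the model's stable state
#' matches the profile, following two alternating repair rounds:
#' round 1 targets nodes inactive in the stable state but active in the
#' baseline whose inhibitors are active (their link operator is flipped
#' AND_NOT -> OR_NOT so inhibition no longer dominates); round 2 targets
#' nodes active in the stable state but inactive in the baseline, flipping
#' the link operator of their currently inactive negative regulators to
#' push those regulators toward activity. Each candidate flip is accepted
#' only if it strictly increases the matched fraction (few changes are
#' preferred over many), so agreement is monotone over accepted edits.
#' Free input nodes (identity rules) with a non-NA baseline value are
#' first pinned to that value: topology leaves them undetermined and it
#' is the baseline data that decides them.
#'
#' @param model a [logical_model()] (the generic model).
#' @param profile an [activity_profile()].
#' @param max_rounds maximum number of round-1/round-2 sweeps (default 10).
#' @return An object of class `calibration_result`: `model` (calibrated),
#'   `changes` (data.frame of accepted link-operator flips), `selected_state`,
#'   `matched_fraction`, `converged` (TRUE when all non-NA entries match),
#'   `rounds` used and `pinned_inputs`.
#' @export
calibrate <- function(model, profile, max_rounds = 10) {
  # pin free input nodes to their baseline values: identity rules admit
  # both values, and it is the baseline data that decides them
  pinned <- character()
  for (n in names(model$rules)) {
    if (model$rules[[n]]$kind == "input" && n %in% names(profile$values) &&
        !is.na(profile$values[[n]])) {
      model$rules[[n]] <- rule_expr(n, as.numeric(profile$values[[n]]))
      pinned <- c(pinned, n)
    }
  }
  states <- stable_states(model)
  if (!length(states)) {
    return(structure(list(model = model, changes = empty_changes(),
                          selected_state = NULL, matched_fraction = NA_real_,
                          converged = FALSE, rounds = 0L,
                          pinned_inputs = sort(pinned),
                          failure = "no stable state in initial model"),
                     class = "calibration_result"))
  }
  state <- select_state(states, profile)
  agr <- agreement(state, profile)
  changes <- list()
  prof <- profile$values

  flippable <- function(n) {
    r <- model$rules[[n]]
    r$kind == "link" && length(r$activators) && length(r$inhibitors) &&
      r$link_op == "AND_NOT"
  }
  # A regulator counts as baseline-active when its profile value is 1, or
  # unknown in the baseline but active in the current stable state.
  baseline_active <- function(nodes, state) {
    vapply(nodes, function(m) {
      p <- if (m %in% names(prof)) prof[[m]] else NA
      if (!is.na(p)) p == 1 else state[[m]] >= 1
    }, TRUE)
  }
  try_flip <- function(n, round) {
    r <- model$rules[[n]]
    r$link_op <- "OR_NOT"
    cand <- model
    cand$rules[[n]] <- r
    cs <- tryCatch(stable_states(cand), error = function(e) list())
    if (!length(cs)) return(FALSE)
    cst <- select_state(cs, profile)
    cagr <- agreement(cst, profile)
    if (cagr > agr) {
      model <<- cand; state <<- cst; agr <<- cagr
      changes[[length(changes) + 1L]] <<-
        data.frame(node = n, from = "AND_NOT", to = "OR_NOT",
                   round = round, stringsAsFactors = FALSE)
      TRUE
    } else FALSE
  }

  rounds <- 0L
  while (agr < 1 && rounds < max_rounds) {
    rounds <- rounds + 1L
    accepted <- FALSE
    # round 1: should-be-active nodes suppressed by active inhibitors
    non_na <- names(prof)[!is.na(prof)]
    for (n in sort(non_na)) {
      if (!(n %in% names(state))) next
      if (prof[[n]] == 1 && state[[n]] < 1 && flippable(n)) {
        inh <- model$rules[[n]]$inhibitors
        if (any(baseline_active(inh, state))) {
          accepted <- try_flip(n, rounds) || accepted
        }
      }
      if (agr >= 1) break
    }
    # round 2: should-be-inactive nodes; activate their negative regulators
    if (agr < 1) {
      for (n in sort(non_na)) {
        if (!(n %in% names(state))) next
        if (prof[[n]] == 0 && state[[n]] >= 1 &&
            model$rules[[n]]$kind == "link") {
          for (m in sort(model$rules[[n]]$inhibitors)) {
            if (state[[m]] < 1 && flippable(m)) {
              accepted <- try_flip(m, rounds) || accepted
            }
            if (agr >= 1) break
          }
        }
        if (agr >= 1) break
      }
    }
    if (!accepted) break
  }
  structure(list(model = model,
                 changes = if (length(changes)) do.call(rbind, changes)
                           else empty_changes(),
                 selected_state = state, matched_fraction = agr,
                 converged = agr >= 1, rounds = rounds,
                 pinned_inputs = sort(pinned)),
            class = "calibration_result")
}

empty_changes <- function() {
  data.frame(node = character(), from = character(), to = character(),
             round = integer(), stringsAsFactors = FALSE)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result: matched fraction ",
      round(x$matched_fraction, 3), " after ", nrow(x$changes),
      " link-operator flip(s), ", x$rounds, " round(s)",
      if (isTRUE(x$converged)) " [converged]" else " [not converged]",
      "\n", sep = "")
  invisible(x)
}
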