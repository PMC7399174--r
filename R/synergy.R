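#' Simulate a drug perturbation
#'
#' Clamps the union of the targets of the given drugs to 0 (full
#' inhibition), computes the exact stable states, and reads the Viability
#' readout (Prosurvival level minus Antisurvival level) from the selected
#' state. When several stable states exist, the one closest in Hamming
#' distance to the calibrated wild-type state is selected (the perturbed
#' condition is a continuation of the calibrated one); ties are broken
#' lexicographically. When no stable state exists the model is reduced
#' (retaining drug targets, outputs and irreducible self-loop nodes) and
#' the asynchronous attractors of the reduced model are used, with the
#' output levels averaged over the attractor states (configurable to
#' min/max). An attractor search exceeding the state cap yields an NA
#' result flagged as undecided.
#'
#' @param model calibrated [logical_model()].
#' @param drugs character vector of 0, 1 or 2 drug abbreviations.
#' @param panel a [drug_panel()].
#' @param wt_state named numeric wild-type stable state used for state
#'   selection (optional; lexicographic first state used when NULL).
#' @param extra_clamps additional named clamps (influence-sweep fixations),
#'   applied before the drug clamps (drug clamps win on conflict).
#' @param complex_value how to summarize the per-state Viability over the
#'   states of a complex attractor: `"mean"` (default), `"min"` or
#'   `"max"`; the reported output levels are always state means.
#' @param max_states state-space cap for the asynchronous fallback.
#' @return An object of class `perturbation_result`: `condition`,
#'   `attractor_kind` (`"stable_state"`, `"complex"` or `"undecided"`),
#'   `prosurvival`, `antisurvival`, `viability` (NA when undecided).
#' @export
simulate_perturbation <- function(model, drugs, panel, wt_state = NULL,
                                  extra_clamps = NULL,
                                  complex_value = c("mean", "min", "max"),
                                  max_states = 4096) {
  complex_value <- match.arg(complex_value)
  if (length(drugs) > 2) stop("at most two drugs per condition")
  unknown <- setdiff(drugs, names(panel$targets))
  if (length(unknown)) stop("drug(s) not in panel: ",
                            paste(unknown, collapse = ", "))
  targets <- unique(unlist(panel$targets[drugs]))
  clamps <- numeric(0)
  if (!is.null(extra_clamps)) clamps[names(extra_clamps)] <-
    as.numeric(extra_clamps)
  if (length(targets)) clamps[targets] <- 0
  if (!length(clamps)) clamps <- NULL

  outputs <- model$network$output_nodes
  if (is.null(outputs)) stop("model has no designated output nodes")
  summarize <- switch(complex_value, mean = mean, min = min, max = max)

  states <- tryCatch(stable_states(model, clamps = clamps),
                     error = function(e) list())
  if (length(states)) {
    st <- pick_continuation(states, wt_state)
    pro <- st[[outputs[1]]]; anti <- st[[outputs[2]]]
    return(perturbation_result(drugs, "stable_state", pro, anti))
  }
  red <- reduce_model(model, retain = unique(c(
    unlist(panel$targets), outputs)))
  rclamps <- clamps[names(clamps) %in% names(red$rules)]
  att <- async_attractors(red, clamps = if (length(rclamps)) rclamps,
                          max_states = max_states)
  if (att$undecided || !length(att$attractors)) {
    return(perturbation_result(drugs, "undecided", NA_real_, NA_real_))
  }
  a <- pick_attractor(att$attractors, wt_state)
  pro_s <- vapply(a$states, `[[`, numeric(1), outputs[1])
  anti_s <- vapply(a$states, `[[`, numeric(1), outputs[2])
  # summarize the per-state Viability (not each output separately)
  res <- perturbation_result(drugs, a$kind, mean(pro_s), mean(anti_s))
  res$viability <- summarize(pro_s - anti_s)
  res
}

perturbation_result <- function(drugs, kind, pro, anti) {
  structure(list(condition = sort(drugs), attractor_kind = kind,
                 prosurvival = pro, antisurvival = anti,
                 viability = pro - anti),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cond <- if (length(x$condition)) paste(x$condition, collapse = "+")
          else "wild type"
  cat("perturbation_result [", cond, "]: viability = ", x$viability,
      " (", x$attractor_kind, ")\n", sep = "")
  invisible(x)
}

# Closest state to the wild-type state (Hamming on shared nodes), ties
# lexicographic (input order is lex-sorted).
pick_continuation <- function(states, wt_state) {
  if (is.null(wt_state) || length(states) == 1L) return(states[[1]])
  d <- vapply(states, function(s) {
    shared <- intersect(names(s), names(wt_state))
    sum(s[shared] != wt_state[shared])
  }, numeric(1))
  states[[which.min(d)]]
}

pick_attractor <- function(attractors, wt_state) {
  if (length(attractors) == 1L || is.null(wt_state)) {
    return(attractors[[1]])
  }
  d <- vapply(attractors, function(a) {
    mean(vapply(a$states, function(s) {
      shared <- intersect(names(s), names(wt_state))
      sum(s[shared] != wt_state[shared])
    }, numeric(1)))
  }, numeric(1))
  attractors[[which.min(d)]]
}

#' Predict synergies for every drug pair of a panel
#'
#' Runs the wild-type, every single-drug and every unordered pair
#' condition, and calls a pair synergistic when its Viability is strictly
#' below both single-drug Viabilities (a model analogue of the Highest
#' Single Agent criterion). Pairs with an undecided member condition get
#' an NA call.
#'
#' @param model calibrated [logical_model()].
#' @param panel a [drug_panel()] with at least 2 drugs.
#' @param wt_state optional calibrated wild-type state for state selection;
#'   computed from the unperturbed model when NULL.
#' @param cell_line label carried into the result.
#' @inheritParams simulate_perturbation
#' @return An object of class `synergy_calls`: data.frame with one row per
#'   unordered pair (`drug_a`, `drug_b`, `viability_a`, `viability_b`,
#'   `viability_ab`, `predicted`), plus attributes `singles` (named
#'   viability vector) and `wt_viability`.
#' @export
predict_synergies <- function(model, panel, wt_state = NULL,
                              cell_line = NA_character_,
                              extra_clamps = NULL,
                              complex_value = "mean", max_states = 4096) {
  drugs <- names(panel$targets)
  if (length(drugs) < 2) stop("panel must contain at least 2 drugs")
  if (is.null(wt_state)) {
    wt <- simulate_perturbation(model, character(), panel,
                                extra_clamps = extra_clamps,
                                complex_value = complex_value,
                                max_states = max_states)
    wt_states <- stable_states(model)
    if (length(wt_states)) wt_state <- wt_states[[1]]
  } else {
    wt <- simulate_perturbation(model, character(), panel,
                                wt_state = wt_state,
                                extra_clamps = extra_clamps,
                                complex_value = complex_value,
                                max_states = max_states)
  }
  singles <- vapply(drugs, function(d) {
    simulate_perturbation(model, d, panel, wt_state = wt_state,
                          extra_clamps = extra_clamps,
                          complex_value = complex_value,
                          max_states = max_states)$viability
  }, numeric(1))
  pairs <- drug_pairs(drugs)
  vab <- numeric(nrow(pairs)); pred <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- simulate_perturbation(model, c(pairs$drug_a[i], pairs$drug_b[i]),
                               panel, wt_state = wt_state,
                               extra_clamps = extra_clamps,
                               complex_value = complex_value,
                               max_states = max_states)
    vab[i] <- r$viability
  }
  va <- singles[pairs$drug_a]; vb <- singles[pairs$drug_b]
  pred <- vab < pmin(va, vb)  # strict inequality; NA propagates
  calls <- data.frame(cell_line = cell_line,
                      drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                      viability_a = unname(va), viability_b = unname(vb),
                      viability_ab = vab, predicted = pred,
                      stringsAsFactors = FALSE)
  structure(calls, singles = singles, wt_viability = wt$viability,
            class = c("synergy_calls", "data.frame"))
}

#' Write predictions CSV
#' @param calls a `synergy_calls` data.frame.
#' @param path output path.
#' @export
write_predictions <- function(calls, path) {
  out <- as.data.frame(calls)
  out$predicted <- ifelse(is.na(out$predicted), "NA",
                          as.integer(out$predicted))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
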