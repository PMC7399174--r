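#' Construct a dose-matrix screen record
#'
#' One drug pair in one cell line: single-agent viabilities (fraction of
#' untreated control) at each dose, and a combination matrix over the dose
#' grid.
#'
#' @param cell_line cell line label.
#' @param drug_a,drug_b drug abbreviations.
#' @param single_a,single_b numeric vectors of single-agent viabilities,
#'   named by dose.
#' @param combo numeric matrix of combination viabilities with rownames =
#'   doses of drug A and colnames = doses of drug B.
#' @return An object of class `screen_record`.
#' @export
screen_record <- function(cell_line, drug_a, drug_b, single_a, single_b,
                          combo) {
  stopifnot(is.matrix(combo), !is.null(rownames(combo)),
            !is.null(colnames(combo)))
  missing_a <- setdiff(rownames(combo), names(single_a))
  if (length(missing_a)) {
    stop("missing single-agent viability for ", drug_a, " at dose(s) ",
         paste(missing_a, collapse = ", "))
  }
  missing_b <- setdiff(colnames(combo), names(single_b))
  if (length(missing_b)) {
    stop("missing single-agent viability for ", drug_b, " at dose(s) ",
         paste(missing_b, collapse = ", "))
  }
  structure(list(cell_line = cell_line, drug_a = drug_a, drug_b = drug_b,
                 single_a = single_a, single_b = single_b, combo = combo),
            class = "screen_record")
}

#' Highest Single Agent excess of a screen record
#'
#' Per combination dose pair (a, b) the HSA excess is
#' `V_AB(a, b) - min(V_A(a), V_B(b))`: how much deeper the combination
#' drops viability than the stronger single agent at the matched doses.
#' Negative values indicate stronger-than-best-single effect. The mean is
#' taken over all combination cells of the grid.
#'
#' @param record a [screen_record()].
#' @return list with `excess` (matrix aligned to the combination grid) and
#'   `mean` (scalar mean over all cells).
#' @export
hsa_excess <- function(record) {
  va <- record$single_a[rownames(record$combo)]
  vb <- record$single_b[colnames(record$combo)]
  best_single <- outer(va, vb, pmin)
  excess <- record$combo - best_single
  dimnames(excess) <- dimnames(record$combo)
  list(excess = excess, mean = mean(excess))
}

#' Binarize mean HSA excesses into observed synergy calls
#'
#' A pair is observed-synergistic when its mean HSA excess across doses is
#' less than or equal to the cutoff (inclusive; default -0.11). Looser
#' (less negative) cutoffs call more synergies, so calls are monotone in
#' the cutoff.
#'
#' @param excess_means named numeric vector (names = pair keys) or a
#'   data.frame with columns `drug_a`, `drug_b`, `mean_excess`.
#' @param cutoff synergy-calling threshold on the mean HSA excess.
#' @return data.frame with columns `drug_a`, `drug_b`, `mean_excess`,
#'   `observed` (class `observed_calls`).
#' @export
binarize <- function(excess_means, cutoff = -0.11) {
  if (is.data.frame(excess_means)) {
    df <- excess_means
    stopifnot(all(c("drug_a", "drug_b", "mean_excess") %in% names(df)))
  } else {
    ab <- strsplit(names(excess_means), "|", fixed = TRUE)
    df <- data.frame(drug_a = vapply(ab, `[`, "", 1),
                     drug_b = vapply(ab, `[`, "", 2),
                     mean_excess = as.numeric(excess_means),
                     stringsAsFactors = FALSE)
  }
  df$observed <- df$mean_excess <= cutoff
  class(df) <- c("observed_calls", "data.frame")
  attr(df, "cutoff") <- cutoff
  df
}

#' Score a set of screen records
#'
#' Convenience wrapper: mean HSA excess per record, then [binarize()].
#'
#' @param records list of [screen_record()] objects.
#' @param cutoff passed to [binarize()].
#' @return An `observed_calls` data.frame.
#' @export
score_screen <- function(records, cutoff = -0.11) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(drug_a = r$drug_a, drug_b = r$drug_b,
               mean_excess = hsa_excess(r)$mean,
               stringsAsFactors = FALSE)
  }))
  binarize(df, cutoff = cutoff)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Confusion summary of predicted vs observed synergy calls
#'
#' Pairs with an NA call on either side (e.g. undecided attractors) are
#' excluded from all counts, mirroring the NA handling of the prediction
#' figures.
#'
#' @param predicted a `synergy_calls` data.frame (or any data.frame with
#'   `drug_a`, `drug_b`, `predicted`).
#' @param observed an `observed_calls` data.frame (or any data.frame with
#'   `drug_a`, `drug_b`, `observed`).
#' @return A `confusion_summary` (see [confusion_from_counts()]).
#' @export
confusion <- function(predicted, observed) {
  pk <- pair_key(predicted$drug_a, predicted$drug_b)
  ok <- pair_key(observed$drug_a, observed$drug_b)
  shared <- intersect(pk, ok)
  if (!length(shared)) stop("predicted and observed pair sets are disjoint")
  p <- predicted$predicted[match(shared, pk)]
  o <- observed$observed[match(shared, ok)]
  keep <- !is.na(p) & !is.na(o)
  p <- p[keep]; o <- o[keep]
  confusion_from_counts(tp = sum(p & o), fp = sum(p & !o),
                        tn = sum(!p & !o), fn = sum(!p & o))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP), negative predictive value TN/(TN+FN), balanced
#' accuracy (sensitivity+specificity)/2, and Matthews correlation
#' coefficient. Metrics with a zero denominator are NA; MCC follows the
#' convention of 0 when any marginal is empty.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return An object of class `confusion_summary`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_evaluable = tp + fp + tn + fn,
                 sensitivity = sens, specificity = spec,
                 ppv = frac(tp, tp + fp), npv = frac(tn, tn + fn),
                 balanced_accuracy = mean(c(sens, spec)),
                 mcc = mcc),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("confusion_summary: TP=", x$tp, " FP=", x$fp, " TN=", x$tn,
      " FN=", x$fn, " (n=", x$n_evaluable, ")\n", sep = "")
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("  sensitivity ", pct(x$sensitivity),
      " | PPV ", pct(x$ppv), " | NPV ", pct(x$npv),
      " | balanced accuracy ", sprintf("%.2f", x$balanced_accuracy),
      " | MCC ", sprintf("%.2f", x$mcc), "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo random prediction baseline
#'
#' Draws the predicted number of synergies uniformly without replacement
#' from the evaluable pair universe `reps` times and reports the expected
#' confusion counts and metrics of such random predictors. The number of
#' true positives per draw is hypergeometric, so the closed-form mean
#' `n_predicted * K / N` is reported alongside for cross-checking.
#'
#' @param n_predicted number of pairs a model predicted synergistic.
#' @param observed an `observed_calls` data.frame, or a list with elements
#'   `N` (evaluable pairs) and `K` (observed synergies).
#' @param reps number of Monte-Carlo draws (default 100000).
#' @param seed integer seed for reproducibility.
#' @return An object of class `random_baseline` with expected counts
#'   (`tp`, `fp`, `tn`, `fn`), expected metrics (means of the per-draw
#'   metric values), `expected_tp_closed`, and the call parameters.
#' @export
random_baseline <- function(n_predicted, observed, reps = 100000,
                            seed = 1) {
  if (is.data.frame(observed)) {
    o <- observed$observed[!is.na(observed$observed)]
    N <- length(o); K <- sum(o)
  } else {
    N <- observed$N; K <- observed$K
  }
  if (n_predicted > N) stop("n_predicted exceeds evaluable pairs (", N, ")")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  set.seed(seed)
  tp <- stats::rhyper(reps, m = K, n = N - K, k = n_predicted)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  fp <- n_predicted - tp
  fn <- K - tp
  tn <- N - K - fp
  sens <- if (K > 0) tp / K else NA_real_
  spec <- if (N - K > 0) tn / (N - K) else NA_real_
  ppv <- if (n_predicted > 0) tp / n_predicted else NA_real_
  npv_den <- tn + fn
  npv <- ifelse(npv_den > 0, tn / npv_den, NA_real_)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, 0)
  structure(list(N = N, K = K, n_predicted = n_predicted, reps = reps,
                 seed = seed,
                 tp = mean(tp), fp = mean(fp), tn = mean(tn),
                 fn = mean(fn),
                 sensitivity = mean(sens), specificity = mean(spec),
                 ppv = mean(ppv), npv = mean(npv, na.rm = TRUE),
                 balanced_accuracy = mean((sens + spec) / 2),
                 mcc = mean(mcc),
                 expected_tp_closed = n_predicted * K / N,
                 se_tp = stats::sd(tp) / sqrt(reps)),
            class = "random_baseline")
}

#' @export
print.random_baseline <- function(x, ...) {
  cat("random_baseline (N=", x$N, ", K=", x$K, ", n=", x$n_predicted,
      ", reps=", x$reps, "): E[TP]=", round(x$tp, 2),
      " (closed form ", round(x$expected_tp_closed, 3), ")\n", sep = "")
  invisible(x)
}

#' Read a dose-matrix screen CSV into screen records
#'
#' Expected columns: `cell_line, drug_a, drug_b, dose_a, dose_b,
#' viability`; single-agent rows are encoded with the other drug's dose
#' equal to 0.
#'
#' @param path CSV path.
#' @return list of [screen_record()] objects.
#' @export
read_screen <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_line", "drug_a", "drug_b", "dose_a", "dose_b",
              "viability")
  stopifnot(all(needed %in% names(df)))
  key <- paste(df$cell_line, df$drug_a, df$drug_b, sep = "\r")
  lapply(split(df, key), function(d) {
    sa <- d[d$dose_b == 0 & d$dose_a > 0, ]
    sb <- d[d$dose_a == 0 & d$dose_b > 0, ]
    cc <- d[d$dose_a > 0 & d$dose_b > 0, ]
    da <- sort(unique(cc$dose_a)); db <- sort(unique(cc$dose_b))
    combo <- matrix(NA_real_, length(da), length(db),
                    dimnames = list(as.character(da), as.character(db)))
    for (i in seq_len(nrow(cc))) {
      combo[as.character(cc$dose_a[i]), as.character(cc$dose_b[i])] <-
        cc$viability[i]
    }
    screen_record(d$cell_line[1], d$drug_a[1], d$drug_b[1],
                  stats::setNames(sa$viability, as.character(sa$dose_a)),
                  stats::setNames(sb$viability, as.character(sb$dose_b)),
                  combo)
  })
}

#' Write screen records as a long-format CSV
#' @param records list of [screen_record()] objects.
#' @param path output path.
#' @export
write_screen <- function(records, path) {
  rows <- lapply(records, function(r) {
    da <- as.numeric(names(r$single_a)); db <- as.numeric(names(r$single_b))
    rbind(
      data.frame(cell_line = r$cell_line, drug_a = r$drug_a,
                 drug_b = r$drug_b, dose_a = da, dose_b = 0,
                 viability = unname(r$single_a)),
      data.frame(cell_line = r$cell_line, drug_a = r$drug_a,
                 drug_b = r$drug_b, dose_a = 0, dose_b = db,
                 viability = unname(r$single_b)),
      expand.grid(dose_a = as.numeric(rownames(r$combo)),
                  dose_b = as.numeric(colnames(r$combo))) |>
        transform(cell_line = r$cell_line, drug_a = r$drug_a,
                  drug_b = r$drug_b,
                  viability = as.vector(r$combo)))
  })
  df <- do.call(rbind, lapply(rows, function(d)
    d[, c("cell_line", "drug_a", "drug_b", "dose_a", "dose_b",
          "viability")]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
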