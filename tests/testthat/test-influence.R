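test_that("an 18-drug panel yields 171 conditions per mutant", {
  drugs <- paste0("d", sprintf("%02d", 1:18))
  expect_equal(length(drugs) + nrow(drug_pairs(drugs)), 171)
})

test_that("the sweep ranks the planted convergence hub first", {
  rec <- shared_sweep()
  cl <- classify_and_rank(rec)
  expect_equal(cl$ranking$node[1], "HUB")
  expect_gt(cl$ranking$total_changes[1], cl$ranking$total_changes[2])
})

test_that("influence classification partitions the swept node set", {
  b <- shared_bundle()
  rec <- shared_sweep()
  cl <- classify_and_rank(rec)
  swept <- unique(rec$node)
  expect_setequal(c(cl$high_influence, cl$low_influence), swept)
  expect_length(intersect(cl$high_influence, cl$low_influence), 0)
  # output and multi-level nodes are not swept
  expect_false(any(b$network$output_nodes %in% swept))
  # the inert decoy chain never influences predictions
  expect_true(all(cl$ranking$total_changes[
    grepl("^DEC", cl$ranking$node)] == 0))
})

test_that("fixing nodes at wild-type values leaves inert nodes silent", {
  rec <- shared_sweep()
  dec_fix <- rec[grepl("^DEC", rec$node) & rec$mode == "fix", ]
  expect_true(all(dec_fix$total_changes == 0))
  expect_true(all(dec_fix$complex_attractors == 0))
})

test_that("per-class gains and losses are consistent", {
  rec <- shared_sweep()
  # every changed call contributes one loss and one gain
  gains <- rec$tp_gain + rec$tn_gain + rec$fp_gain + rec$fn_gain
  losses <- rec$tp_loss + rec$tn_loss + rec$fp_loss + rec$fn_loss
  expect_equal(gains, losses)
  expect_equal(rec$total_changes, gains + losses)
  n_pairs <- nrow(drug_pairs(names(shared_bundle()$panel$targets)))
  expect_true(all(gains <= n_pairs))
  # inverting the hub loses the three true-positive planted calls
  hub <- rec[rec$node == "HUB" & rec$mode == "invert", ]
  expect_equal(hub$tp_loss, 3)
  expect_equal(hub$fn_gain, 3)
})

test_that("the sweep is deterministic", {
  b <- shared_bundle()
  cal <- shared_calibration()
  rec1 <- shared_sweep()
  rec2 <- influence_sweep(cal$model, b$panel, observed = shared_observed(),
                          wt_state = cal$selected_state)
  expect_equal(as.data.frame(rec1), as.data.frame(rec2))
})

test_that("restricted calibration: top influential beats bottom set", {
  b <- shared_bundle()
  cl <- classify_and_rank(shared_sweep())
  out <- restricted_calibration_experiment(
    b$generic_model, b$profiles$truth, cl, b$panel, shared_observed(),
    k_top = 8, k_bottom = 8)
  expect_equal(out$calibration,
               c("full", "top_influential", "bottom_noninfluential"))
  top <- out[out$calibration == "top_influential", ]
  bot <- out[out$calibration == "bottom_noninfluential", ]
  full <- out[out$calibration == "full", ]
  # the planted flips sit on high-influence nodes, so top-k calibration
  # matches the full calibration while bottom-k cannot recover them
  expect_equal(top$tp, full$tp)
  expect_gte(top$matched_fraction, bot$matched_fraction)
  expect_gt(top$tp, bot$tp)
  expect_error(restricted_calibration_experiment(
    b$generic_model, b$profiles$truth, cl, b$panel, shared_observed(),
    k_top = 999, k_bottom = 8), "k_top")
})

test_that("mechanism subgraph funnels through the convergence hub", {
  b <- shared_bundle()
  cal <- shared_calibration()
  rec <- shared_sweep()
  ms <- mechanism_subgraph(cal$model, c("D1", "D2"), rec, b$panel)
  expect_true("HUB" %in% ms$nodes$node)
  expect_true(all(b$network$output_nodes %in% ms$nodes$node))
  # the hub is the furthest-downstream influence node
  expect_true("HUB" %in% ms$downstream)
  # activity-altered vs influence roles are distinguished
  expect_equal(ms$nodes$role[ms$nodes$node == "M1"], "activity_altered")
  expect_equal(ms$nodes$role[ms$nodes$node == "HUB"], "influence_loss")
  expect_error(mechanism_subgraph(cal$model, c("D4", "D5"), rec, b$panel),
               "not predicted synergistic")
})

test_that("knock-outs of influence nodes abolish the synergy, altered nodes only dampen it", {
  b <- shared_bundle()
  cal <- shared_calibration()
  rec <- shared_sweep()
  ms <- mechanism_subgraph(cal$model, c("D1", "D2"), rec, b$panel)
  pair_call <- function(extra) {
    va <- simulate_perturbation(cal$model, "D1", b$panel,
                                wt_state = cal$selected_state,
                                extra_clamps = extra)$viability
    vb <- simulate_perturbation(cal$model, "D2", b$panel,
                                wt_state = cal$selected_state,
                                extra_clamps = extra)$viability
    vab <- simulate_perturbation(cal$model, c("D1", "D2"), b$panel,
                                 wt_state = cal$selected_state,
                                 extra_clamps = extra)$viability
    vab < min(va, vb)
  }
  infl <- ms$nodes$node[startsWith(ms$nodes$role, "influence")]
  for (n in setdiff(infl, unlist(b$panel$targets[c("D1", "D2")]))) {
    expect_false(pair_call(stats::setNames(0, n)))
  }
  altered <- ms$nodes$node[ms$nodes$role == "activity_altered"]
  for (n in altered) {
    expect_true(pair_call(stats::setNames(0, n)))
  }
})

test_that("influence records serialize to TSV", {
  rec <- shared_sweep()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_influence(rec, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$total_changes, rec$total_changes)
})
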