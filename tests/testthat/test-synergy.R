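test_that("wild-type and single/double perturbations match hand values", {
  # In the planted motif: Prosurvival counts {HUB, RED1, RED2} and
  # Antisurvival counts {M1, M2, N0}; hand truth-table evaluation gives
  # wild-type viability 3 - 0 = 3, singles 3, and for a branch pair the
  # hub falls (Prosurvival 2) while M1 = TGT5 & !HUB awakens
  # (Antisurvival 1), so viability 2 - 1 = 1.
  b <- shared_bundle()
  cal <- shared_calibration()
  wt <- simulate_perturbation(cal$model, character(), b$panel,
                              wt_state = cal$selected_state)
  expect_equal(wt$viability, 3)
  expect_equal(wt$attractor_kind, "stable_state")
  s1 <- simulate_perturbation(cal$model, "D1", b$panel,
                              wt_state = cal$selected_state)
  expect_equal(s1$viability, 3)
  pair <- simulate_perturbation(cal$model, c("D1", "D2"), b$panel,
                                wt_state = cal$selected_state)
  expect_equal(pair$prosurvival, 2)
  expect_equal(pair$antisurvival, 1)
  expect_equal(pair$viability, 1)
})

test_that("multi-target drugs clamp all their targets", {
  b <- shared_bundle()
  cal <- shared_calibration()
  panel2 <- drug_panel(list(DX = c("TGT1", "TGT2"), D3 = "TGT3"),
                       net = b$network)
  # one dual-target drug reproduces the pair effect of its two singles
  r <- simulate_perturbation(cal$model, "DX", panel2,
                             wt_state = cal$selected_state)
  expect_equal(r$viability, 1)
})

test_that("simulation is symmetric in drug order", {
  b <- shared_bundle()
  cal <- shared_calibration()
  for (pr in list(c("D1", "D2"), c("D2", "D5"), c("D4", "D6"))) {
    r1 <- simulate_perturbation(cal$model, pr, b$panel,
                                wt_state = cal$selected_state)
    r2 <- simulate_perturbation(cal$model, rev(pr), b$panel,
                                wt_state = cal$selected_state)
    expect_equal(r1$viability, r2$viability)
  }
})

test_that("synergy calls use strict inequality and cover all pairs", {
  b <- shared_bundle()
  cal <- shared_calibration()
  calls <- predict_synergies(cal$model, b$panel,
                             wt_state = cal$selected_state)
  expect_equal(nrow(calls), choose(6, 2))
  planted <- paste(b$planted_synergies$drug_a,
                   b$planted_synergies$drug_b, sep = "|")
  got <- paste(calls$drug_a, calls$drug_b, sep = "|")[calls$predicted]
  expect_setequal(got, planted)
  # equal viability (boundary) is not synergistic: the non-branch pairs
  # all sit exactly at min(single) viability
  boundary <- calls[!calls$predicted, ]
  expect_true(all(boundary$viability_ab ==
                    pmin(boundary$viability_a, boundary$viability_b)))
})

test_that("viabilities are integers in [-3, 3] under unique stable states", {
  b <- shared_bundle()
  cal <- shared_calibration()
  calls <- predict_synergies(cal$model, b$panel,
                             wt_state = cal$selected_state)
  v <- c(calls$viability_a, calls$viability_b, calls$viability_ab)
  expect_true(all(v == round(v)))
  expect_true(all(v >= -3 & v <= 3))
})

test_that("clamping an already-inactive node keeps the stable state fixed", {
  b <- shared_bundle()
  cal <- shared_calibration()
  wt <- cal$selected_state
  zero_nodes <- names(wt)[wt == 0 & names(wt) %in%
                            names(cal$model$rules)]
  zero_nodes <- setdiff(zero_nodes, b$network$output_nodes)
  for (n in zero_nodes) {
    sts <- stable_states(cal$model, clamps = stats::setNames(0, n))
    keys <- vapply(sts, function(s) paste(s, collapse = ","), "")
    expect_true(paste(wt, collapse = ",") %in% keys)
  }
})

test_that("oscillating models fall back to reduced async attractors", {
  # a negative self-loop feeds Antisurvival, so no global stable state
  # exists; after reduction the oscillator survives as an irreducible
  # loop and viability averages over the complex attractor:
  # Prosurvival = 1 (driven by T -> B), Antisurvival oscillates 0/1,
  # so viability = 1 - 0.5 = 0.5
  net <- regulatory_network(data.frame(
    source = c("T", "B", "A", "A"), sign = c(1L, 1L, -1L, 1L),
    target = c("B", "Prosurvival", "A", "Antisurvival")),
    output_nodes = c("Prosurvival", "Antisurvival"), drug_targets = "T")
  m <- default_rules(net)
  panel <- drug_panel(list(DT = "T"), net = net)
  expect_length(stable_states(m, clamps = c(T = 1)), 0)
  r <- simulate_perturbation(m, character(), panel,
                             wt_state = NULL, extra_clamps = c(T = 1))
  expect_equal(r$attractor_kind, "complex")
  expect_equal(r$viability, 0.5)
  # min/max summaries bracket the mean
  rmin <- simulate_perturbation(m, character(), panel,
                                extra_clamps = c(T = 1),
                                complex_value = "min")
  rmax <- simulate_perturbation(m, character(), panel,
                                extra_clamps = c(T = 1),
                                complex_value = "max")
  expect_equal(rmin$viability, 0)
  expect_equal(rmax$viability, 1)
})

test_that("undecided conditions yield NA predictions", {
  net <- regulatory_network(data.frame(
    source = c("T", "U", "A", "A"), sign = c(1L, 1L, -1L, 1L),
    target = c("Prosurvival", "Prosurvival", "A", "Antisurvival")),
    output_nodes = c("Prosurvival", "Antisurvival"),
    drug_targets = c("T", "U"))
  m <- default_rules(net)
  panel <- drug_panel(list(DT = "T", DU = "U"), net = net)
  r <- simulate_perturbation(m, c("DT", "DU"), panel, max_states = 1)
  expect_equal(r$attractor_kind, "undecided")
  expect_true(is.na(r$viability))
  calls <- predict_synergies(m, panel, max_states = 1)
  expect_true(is.na(calls$predicted[1]))
})

test_that("predictions CSV writes 1/0/NA calls", {
  b <- shared_bundle()
  cal <- shared_calibration()
  calls <- predict_synergies(cal$model, b$panel,
                             wt_state = cal$selected_state,
                             cell_line = "SYN-1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(calls, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 15)
  expect_equal(sum(back$predicted == 1), 3)
})
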