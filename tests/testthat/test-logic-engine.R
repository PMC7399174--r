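test_that("default rules follow the AND-NOT convention with OR-NOT override", {
  net <- p38_network()
  m_and <- default_rules(net)
  m_or <- default_rules(net, link_overrides = "MAPK14")
  st <- function(k3, k4, d1) c(DUSP1 = d1, IN1 = 1, IN2 = 1, IN3 = 1,
                               MAP2K3 = k3, MAP2K4 = k4, MAPK14 = 0)
  # inhibitor dominates under AND_NOT
  expect_equal(evaluate_state(m_and, st(1, 0, 1))[["MAPK14"]], 0)
  # the OR_NOT exception keeps the node active despite the phosphatase
  expect_equal(evaluate_state(m_or, st(1, 0, 1))[["MAPK14"]], 1)
  # and active when kinases and phosphatase are all inactive
  expect_equal(evaluate_state(m_or, st(0, 0, 0))[["MAPK14"]], 1)
  expect_equal(evaluate_state(m_and, st(0, 0, 0))[["MAPK14"]], 0)
  expect_equal(format_rule(m_or$rules$MAPK14),
               "MAPK14 = (MAP2K3 | MAP2K4) | !DUSP1")
  expect_error(default_rules(net, link_overrides = "NOPE"), "NOPE")
})

test_that("input nodes admit both values as fixed points", {
  net <- regulatory_network(data.frame(source = "X", sign = 1L,
                                       target = "Y"))
  m <- default_rules(net)
  expect_equal(m$rules$X$kind, "input")
  fps <- stable_states(m)
  expect_length(fps, 2)
  expect_equal(fps[[1]], c(X = 0, Y = 0))
  expect_equal(fps[[2]], c(X = 1, Y = 1))
})

test_that("a negative self-loop has no fixed point but one complex attractor", {
  net <- regulatory_network(data.frame(source = "X", sign = -1L,
                                       target = "X"))
  m <- default_rules(net)
  expect_length(stable_states(m), 0)
  att <- async_attractors(m)
  expect_false(att$undecided)
  expect_length(att$attractors, 1)
  expect_equal(att$attractors[[1]]$kind, "complex")
  expect_equal(states_to_matrix(att$attractors[[1]]$states),
               matrix(c(0, 1), 2, 1, dimnames = list(NULL, "X")))
})

test_that("stable_states equals the brute-force oracle on random models", {
  for (seed in 1:40) {
    m <- random_model(seed)
    got <- states_to_matrix(stable_states(m))
    want <- oracle_fixed_points(m)
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(unname(got), unname(want), info = paste("seed", seed))
      expect_equal(colnames(got), colnames(want))
    }
  }
})

test_that("clamped stable states equal the oracle with held nodes", {
  for (seed in 1:12) {
    m <- random_model(seed)
    tgt <- m$network$drug_targets
    clamps <- stats::setNames(rep(0, length(tgt)), tgt)
    got <- states_to_matrix(stable_states(m, clamps = clamps))
    want <- oracle_fixed_points(m, clamps = clamps)
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(unname(got), unname(want), info = paste("seed", seed))
    }
    # and clamping equals rewriting the clamped rules to constants
    for (s in stable_states(m, clamps = clamps)) {
      expect_equal(s[names(clamps)], clamps[names(clamps)],
                   ignore_attr = TRUE)
    }
  }
})

test_that("reduction substitutes chains and preserves projected fixed points", {
  net <- regulatory_network(data.frame(
    source = c("A", "B"), sign = 1L, target = c("B", "C")))
  m <- default_rules(net)
  red <- reduce_model(m, retain = c("A", "C"))
  expect_setequal(names(red$rules), c("A", "C"))
  expect_equal(sort(rule_regulators(red$rules$C)), "A")
  fp_full <- states_to_matrix(stable_states(m))
  fp_red <- states_to_matrix(stable_states(red))
  expect_equal(unname(fp_red), unname(fp_full[, c("A", "C")]))
})

test_that("reduction preserves projected fixed points on random models", {
  for (seed in 1:25) {
    m <- random_model(seed)
    keep <- sort(unique(c(m$network$drug_targets,
                          m$network$output_nodes)))
    red <- reduce_model(m, retain = keep)
    proj <- sort(names(red$rules))
    fp_full <- oracle_fixed_points(m)[, proj, drop = FALSE]
    states_red <- stable_states(red)
    if (nrow(fp_full) == 0) {
      expect_length(states_red, 0)
    } else {
      fp_full <- unique(fp_full[do.call(order, as.data.frame(fp_full)), ,
                                drop = FALSE])
      fp_red <- states_to_matrix(states_red)[, proj, drop = FALSE]
      fp_red <- unique(fp_red[do.call(order, as.data.frame(fp_red)), ,
                              drop = FALSE])
      expect_equal(unname(fp_red), unname(fp_full),
                   info = paste("seed", seed))
    }
  }
  expect_error(reduce_model(random_model(1), retain = "NOPE"), "NOPE")
})

test_that("eliminating a 2-cycle partner reports the created self-loop", {
  # A <-> B with C reading B: eliminating B makes A self-regulated
  net <- regulatory_network(data.frame(
    source = c("A", "B", "B"), sign = 1L, target = c("B", "A", "C")))
  m <- default_rules(net)
  red <- reduce_model(m, retain = c("A", "C"))
  expect_setequal(names(red$rules), c("A", "C"))
  expect_equal(attr(red, "self_regulated"), "A")
  # projected fixed points preserved through the substitution
  expect_equal(unname(states_to_matrix(stable_states(red))),
               unname(states_to_matrix(stable_states(m))[, c("A", "C")]))
})

test_that("async attractors match a full transition-graph check", {
  for (seed in 1:10) {
    m <- random_model(seed)
    att <- async_attractors(m, max_states = 2^13)
    expect_false(att$undecided)
    # singleton attractors are exactly the fixed points
    singles <- Filter(function(a) a$kind == "stable_state",
                      att$attractors)
    got <- states_to_matrix(lapply(singles, function(a) a$states[[1]]))
    want <- oracle_fixed_points(m)
    if (nrow(want)) {
      expect_equal(unname(got[do.call(order, as.data.frame(got)), ,
                              drop = FALSE]), unname(want))
    } else {
      expect_equal(nrow(got), 0)
    }
    # every attractor is closed under the asynchronous successors and
    # mutually reachable within itself
    for (a in att$attractors) {
      keys <- vapply(a$states, function(s)
        paste(s[sort(names(s))], collapse = ","), "")
      for (s in a$states) {
        for (s2 in oracle_successors(m, s)) {
          expect_true(paste(s2[sort(names(s2))], collapse = ",") %in%
                        keys)
        }
      }
    }
  }
})

test_that("state spaces over the cap yield an explicit undecided result", {
  m <- random_model(3)
  att <- async_attractors(m, max_states = 4)
  expect_true(att$undecided)
  expect_length(att$attractors, 0)
})

test_that("a unique-fixed-point acyclic model has that single attractor", {
  net <- regulatory_network(data.frame(
    source = c("A", "B"), sign = 1L, target = c("B", "C")))
  m <- default_rules(net)
  att <- async_attractors(m, clamps = c(A = 1))
  expect_length(att$attractors, 1)
  expect_equal(att$attractors[[1]]$kind, "stable_state")
  expect_equal(att$attractors[[1]]$states[[1]], c(A = 1, B = 1, C = 1))
})

test_that("model edits rewrite rules, topology and the edit log", {
  net <- regulatory_network(data.frame(
    source = c("PIP3", "mTORC2_c", "ILK", "PPP1CA", "CK1_f", "AKT_f"),
    sign = c(1L, 1L, 1L, -1L, 1L, 1L),
    target = c("AKT_f", "AKT_f", "AKT_f", "AKT_f", "FOXO_f", "FOXO_f")))
  m <- default_rules(net)
  edited <- apply_edits(m, list(
    list(kind = "set_rule", node = "AKT_f",
         rule = "((mTORC2_c | ILK) & PIP3) & !PPP1CA"),
    list(kind = "remove_edge", source = "CK1_f", target = "FOXO_f")))
  st <- c(AKT_f = 0, CK1_f = 0, FOXO_f = 0, ILK = 1, PIP3 = 1,
          PPP1CA = 0, mTORC2_c = 0)
  expect_equal(evaluate_state(edited, st)[["AKT_f"]], 1)
  expect_false("CK1_f" %in% rule_regulators(edited$rules$FOXO_f))
  expect_false(any(edited$network$edges$source == "CK1_f" &
                     edited$network$edges$target == "FOXO_f"))
  expect_length(edited$edit_log, 2)
  # empty edit list leaves the model unchanged
  expect_equal(apply_edits(m, list()), m)
  # failing edits name their index
  expect_error(apply_edits(m, list(
    list(kind = "set_rule", node = "AKT_f", rule = "PIP3"),
    list(kind = "remove_edge", source = "X", target = "Y"))),
    "edit 2")
})

test_that("rule files round-trip through write_rules/read_rules", {
  b <- shared_bundle()
  path <- withr::local_tempfile(fileext = ".txt")
  write_rules(b$planted_model, path)
  back <- read_rules(path, output_nodes = b$network$output_nodes,
                     drug_targets = b$network$drug_targets)
  expect_setequal(names(back$rules), names(b$planted_model$rules))
  expect_equal(back$max_level, b$planted_model$max_level)
  expect_equal(states_to_matrix(stable_states(back)),
               states_to_matrix(stable_states(b$planted_model)))
})
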