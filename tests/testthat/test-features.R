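make_net <- function(edges_str) {
  # "A->B, B->C" shorthand for positive directed edges
  parts <- trimws(strsplit(edges_str, ",")[[1]])
  st <- do.call(rbind, strsplit(parts, "->", fixed = TRUE))
  regulatory_network(data.frame(source = trimws(st[, 1]), sign = 1L,
                                target = trimws(st[, 2])))
}

test_that("global efficiency on canonical graphs", {
  complete3 <- make_net("A->B, A->C, B->A, B->C, C->A, C->B")
  expect_equal(global_efficiency(complete3), 1)
  edgeless <- regulatory_network(NULL, nodes = c("A", "B", "C"))
  expect_equal(global_efficiency(edgeless), 0)
  path3 <- make_net("A->B, B->C")
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 6)
  expect_error(global_efficiency(regulatory_network(NULL, nodes = "A")),
               "at least 2")
})

test_that("PCI of the middle of a path is 1", {
  path3 <- make_net("A->B, B->C")
  expect_equal(pci(path3, "B"), 1)
  edgeless <- regulatory_network(NULL, nodes = c("A", "B", "C"))
  expect_error(pci(edgeless, "A"), "zero global efficiency")
  expect_error(pci(path3, "Z"), "unknown")
})

test_that("efficiency and PCI match the brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    net <- gen_network(n_nodes = sample(6:10, 1), n_edges = 12,
                       n_cycles = sample(0:2, 1), n_targets = 2,
                       seed = seed)
    expect_equal(global_efficiency(net), oracle_efficiency(net),
                 tolerance = 1e-12)
    for (v in sample(net$nodes, 3)) {
      expect_equal(pci(net, v), oracle_pci(net, v), tolerance = 1e-12)
    }
  }
})

test_that("centralities on canonical graphs", {
  star <- make_net("H->A, H->B, H->C")
  ctr <- centralities(star)
  expect_equal(ctr$betweenness[ctr$node == "H"], 0)
  expect_equal(ctr$out_degree[ctr$node == "H"], 3)
  path3 <- make_net("A->B, B->C")
  ctr2 <- centralities(path3)
  expect_equal(ctr2$betweenness[ctr2$node == "B"], 1)
  expect_equal(ctr2$closeness[ctr2$node == "A"], (1 + 0.5) / 2)
})

test_that("centralities match path-enumeration oracles on random graphs", {
  for (seed in 1:6) {
    net <- gen_network(n_nodes = 8, n_edges = 13, n_cycles = 1,
                       seed = seed)
    ctr <- centralities(net)
    btw <- oracle_betweenness(net)
    cls <- oracle_harmonic_closeness(net)
    expect_equal(ctr$betweenness, unname(btw[ctr$node]),
                 tolerance = 1e-9)
    expect_equal(ctr$closeness, unname(cls[ctr$node]), tolerance = 1e-12)
    outdeg <- vapply(ctr$node, function(v)
      sum(net$edges$source == v), 0L)
    expect_equal(ctr$out_degree, unname(outdeg))
  }
})

test_that("feature table assembles structural columns and labels", {
  net <- gen_network(12, 20, seed = 4)
  labels <- stats::setNames(rep(c(TRUE, FALSE), 6), net$nodes)
  ann <- data.frame(node = net$nodes, oncogene = FALSE)
  tab <- node_feature_table(net, labels = labels, annotations = ann)
  expect_setequal(names(tab), c("node", "out_degree", "betweenness",
                                "closeness", "pci", "label", "oncogene"))
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$betweenness >= 0))
})

test_that("a planted informative feature is ranked first", {
  set.seed(99)
  n <- 160
  signal <- rnorm(n)
  tab <- data.frame(signal = signal,
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    noise3 = sample(c(TRUE, FALSE), n, TRUE))
  labels <- factor(ifelse(signal + rnorm(n, sd = 0.3) > 0,
                          "high", "low"))
  for (balanced in c(TRUE, FALSE)) {
    rk <- importance_ranking(tab, labels, balanced = balanced,
                             seed = 5, n_repeats = 3, ntree = 200)
    expect_equal(rk$feature[1], "signal")
  }
  expect_error(importance_ranking(tab, factor(rep("high", n))),
               "2 classes")
})

test_that("a single feature carries importance 1", {
  set.seed(7)
  x <- rnorm(60)
  labels <- factor(ifelse(x > 0, "a", "b"))
  rk <- importance_ranking(data.frame(x = x), labels, n_repeats = 2,
                           ntree = 100)
  expect_equal(rk$importance, 1)
})

test_that("duplicated features split the original importance", {
  set.seed(21)
  n <- 150
  signal <- rnorm(n)
  labels <- factor(ifelse(signal + rnorm(n, sd = 0.4) > 0, "a", "b"))
  base_tab <- data.frame(signal = signal, noise1 = rnorm(n),
                         noise2 = rnorm(n))
  rk1 <- importance_ranking(base_tab, labels, seed = 2, n_repeats = 5)
  dup_tab <- cbind(base_tab, signal_dup = signal)
  rk2 <- importance_ranking(dup_tab, labels, seed = 2, n_repeats = 5)
  share1 <- rk1$importance[rk1$feature == "signal"]
  share2 <- sum(rk2$importance[rk2$feature %in% c("signal",
                                                  "signal_dup")])
  # the shared share is conserved only approximately: duplicated columns
  # change which splits the noise features win
  expect_lt(abs(share1 - share2), 0.2)
  # and the duplicate pair still dominates the ranking
  expect_setequal(rk2$feature[1:2], c("signal", "signal_dup"))
})

test_that("feature correlations follow the closed form", {
  x <- c(1, 3, 2, 5, 4)
  tab <- data.frame(x = x, neg = -x, y = c(2, 1, 4, 3, 5))
  cm <- feature_correlations(tab)
  expect_equal(cm["x", "x"], 1)
  expect_equal(cm["x", "neg"], -1)
  r_oracle <- sum((x - mean(x)) * (tab$y - mean(tab$y))) /
    sqrt(sum((x - mean(x))^2) * sum((tab$y - mean(tab$y))^2))
  expect_equal(cm["x", "y"], r_oracle, tolerance = 1e-12)
  # zero-variance columns give NA
  cz <- feature_correlations(data.frame(x = x, const = rep(1, 5)))
  expect_true(is.na(cz["x", "const"]))
  expect_error(feature_correlations(data.frame(x = 1:2, y = 2:1)),
               "3 rows")
})
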