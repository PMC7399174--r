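# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

shared_bundle <- function() memo("bundle", function() gen_bundle(seed = 7))

shared_calibration <- function() memo("cal", function() {
  b <- shared_bundle()
  calibrate(b$generic_model, b$profiles$truth)
})

shared_observed <- function() memo("obs", function() {
  score_screen(shared_bundle()$screen)
})

shared_sweep <- function() memo("sweep", function() {
  b <- shared_bundle()
  cal <- shared_calibration()
  influence_sweep(cal$model, b$panel, observed = shared_observed(),
                  wt_state = cal$selected_state)
})

# A three-node p38-style motif: two kinases activating, one phosphatase
# inhibiting a target node.
p38_network <- function() {
  regulatory_network(data.frame(
    source = c("MAP2K3", "MAP2K4", "DUSP1", "IN1", "IN2", "IN3"),
    sign = c(1L, 1L, -1L, 1L, 1L, 1L),
    target = c("MAPK14", "MAPK14", "MAPK14", "MAP2K3", "MAP2K4",
               "DUSP1")))
}

# Random small models for solver property tests: mixed sizes, some with
# feedback cycles, some with OR_NOT operators.
random_model <- function(seed) {
  set.seed(seed)
  n <- sample(7:12, 1)
  extra <- sample(0:4, 1)
  cyc <- sample(0:2, 1)
  gen_model(n_nodes = n, n_edges = min((n - 3) + 4 + extra + cyc,
                                       (n - 2) * (n - 3) / 2 + 4 + cyc),
            frac_inhibitory = 0.35, n_cycles = cyc, frac_or_not = 0.3,
            seed = seed)
}
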