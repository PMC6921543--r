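# Shared designed networks and panels for the test suite.

## 4-node mixed AND/OR/NOT ground truth used for exact-recovery studies
recovery_ground_truth <- function() {
  boolean_network(list(
    A = "B & !C",
    B = "A | D",
    C = "!A",
    D = "C"))
}

## noise-free panel sampling the full 2^4 initial-state fan, densely on the
## 50-point grid, one replicate per group
recovery_panel <- function(noise_sigma = 0, replicates = 1, seed = 3) {
  gt <- recovery_ground_truth()
  grid <- resample_grid()
  combos <- expand.grid(A = 0:1, B = 0:1, C = 0:1, D = 0:1)
  inits <- lapply(seq_len(nrow(combos)), function(i)
    stats::setNames(as.integer(combos[i, ]), gt$nodes))
  names(inits) <- paste0("g", seq_along(inits))
  design <- synthetic_design(proteins = gt$nodes, times = grid,
                             replicates = replicates,
                             groups = c("control", names(inits)),
                             noise_sigma = noise_sigma, seed = seed)
  suppressWarnings(render_panel(gt, design, initial_states = inits))
}

## realistic 7-time-point study design around a small ground truth
small_study_panel <- function(noise_sigma = 0, seed = 11) {
  gt <- boolean_network(list(
    A = "B", B = "!C", C = "A & E", D = "A | !B", E = "D"))
  design <- synthetic_design(proteins = gt$nodes, noise_sigma = noise_sigma,
                             seed = seed)
  inits <- list("LPS" = c(A = 1, B = 1, C = 0, D = 1, E = 0),
                "IL-4" = c(A = 0, B = 1, C = 1, D = 0, E = 1),
                "IL-10" = c(A = 1, B = 0, C = 1, D = 1, E = 1))
  panel <- suppressWarnings(render_panel(gt, design, initial_states = inits))
  list(gt = gt, panel = panel)
}

## exhaustive evaluation of a rule over all parent patterns
rule_outputs_by_bruteforce <- function(rule) {
  k <- length(rule$parents)
  vapply(seq_len(2^k), function(idx) {
    bits <- stats::setNames(cytobool:::pattern_bits(idx, k), rule$parents)
    eval_rule(rule, bits)
  }, numeric(1))
}

## spot-check equivalence on random states (for networks too large to
## enumerate)
networks_equivalent_on_sample <- function(bn1, bn2, n_states = 100, seed = 1) {
  stopifnot(setequal(bn1$nodes, bn2$nodes))
  set.seed(seed)
  for (i in seq_len(n_states)) {
    bits <- stats::setNames(sample(0:1, length(bn1$nodes), TRUE), bn1$nodes)
    s1 <- bn_step(bn1, bits)
    s2 <- bn_step(bn2, bits[bn2$nodes])
    if (!identical(s1[bn1$nodes], s2[bn1$nodes])) return(FALSE)
  }
  TRUE
}

## do two networks over the same nodes perform identical synchronous steps?
networks_equivalent <- function(bn1, bn2) {
  stopifnot(setequal(bn1$nodes, bn2$nodes))
  n <- length(bn1$nodes)
  for (idx in seq_len(2^n)) {
    bits <- stats::setNames(index_to_state(idx, n), bn1$nodes)
    s1 <- bn_step(bn1, bits)
    s2 <- bn_step(bn2, bits[bn2$nodes])
    if (!identical(s1[bn1$nodes], s2[bn1$nodes])) return(FALSE)
  }
  TRUE
}
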