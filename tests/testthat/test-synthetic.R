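test_that("shape kernels evaluate to their closed forms", {
  expect_equal(shape_value(shape_kernel("promotion", c = 10), 0), 0)
  expect_equal(shape_value(shape_kernel("promotion", c = 10), 1), 5)
  ## inhibition asymptote equals the bias
  expect_equal(shape_value(shape_kernel("inhibition", c = 10, bias = 2), 1e9),
               2, tolerance = 1e-6)
  b <- shape_kernel("bell", c = 4, center = 6, width = 2)
  expect_equal(shape_value(b, 6), 4)
  expect_equal(shape_value(b, 8), 4 * exp(-0.5))
  expect_error(shape_kernel("promotion", c = -1))
  expect_error(shape_kernel("bell", c = 1, width = 0))
})

test_that("kernel monotonicity and non-negativity hold on a time grid", {
  t <- seq(0, 24, by = 0.1)
  pro <- shape_value(shape_kernel("promotion", c = 7), t)
  inh <- shape_value(shape_kernel("inhibition", c = 7, bias = 1), t)
  bel <- shape_value(shape_kernel("bell", c = 7), t)
  expect_true(all(diff(pro) >= 0))
  expect_true(all(diff(inh) <= 0))
  expect_true(all(c(pro, inh, bel) >= 0))
})

test_that("ground-truth generator is reproducible and exhaustively correct", {
  ## single node: self-copy, identity transition map
  bn1 <- generate_ground_truth_bn(1)
  ts1 <- transition_matrix(bn1)
  expect_identical(ts1$successor, 1:2)
  ## determinism
  a <- generate_ground_truth_bn(6, max_parents = 3, seed = 77)
  b <- generate_ground_truth_bn(6, max_parents = 3, seed = 77)
  expect_identical(a, b)
  ## every rule's table matches brute-force evaluation over all states
  bn3 <- generate_ground_truth_bn(3, max_parents = 2, seed = 5)
  for (nm in bn3$nodes) {
    r <- bn3$rules[[nm]]
    expect_lte(length(r$parents), 2)
    expect_gt(length(unique(r$outputs)), 1)  # non-constant
    expect_equal(rule_outputs_by_bruteforce(r), as.numeric(r$outputs))
  }
  expect_error(generate_ground_truth_bn(0))
  expect_error(generate_ground_truth_bn(12))
})

test_that("rendered panels honor the study design", {
  gt <- generate_ground_truth_bn(3, seed = 2)
  design <- synthetic_design(proteins = gt$nodes, noise_sigma = 0.1, seed = 9)
  panel <- render_panel(gt, design)
  expect_setequal(unique(panel$time_h), c(0, 0.5, 1, 3, 6, 12, 24))
  expect_equal(length(unique(panel$time_h)), 7)
  expect_equal(max(panel$replicate), 4)
  expect_setequal(unique(panel$group), c("control", "LPS", "IL-4", "IL-10"))
  expect_true(all(panel$value >= 0))
  ## complete grid: one row per protein x group x replicate x time
  expect_equal(nrow(panel), 3 * 4 * 4 * 7)
  ## seed determinism: identical design => bit-identical panel
  again <- render_panel(gt, design)
  expect_identical(panel$value, again$value)
})

test_that("control group renders from the all-low state", {
  gt <- boolean_network(list(A = "A", B = "B"))  # self-copy inputs
  design <- synthetic_design(proteins = gt$nodes, noise_sigma = 0, seed = 1)
  panel <- render_panel(gt, design)
  ctrl <- panel[panel$group == "control", ]
  low_max <- max(kernel_range(kernel_pair()$low))
  expect_true(all(ctrl$value <= low_max))
})

test_that("overlapping high/low kernel ranges raise the separability flag", {
  gt <- boolean_network(list(A = "A"))
  design <- synthetic_design(proteins = "A", noise_sigma = 0, seed = 1)
  bad <- list(A = list(high = shape_kernel("promotion", c = 2),
                       low = shape_kernel("promotion", c = 1)))
  expect_warning(p <- render_panel(gt, design, kernels = bad), "overlap")
  expect_false(attr(p, "separable"))
})

test_that("zero-noise rendering round-trips through fit and binarization", {
  set.seed(21)
  gt <- generate_ground_truth_bn(4, max_parents = 2, seed = 13)
  design <- synthetic_design(proteins = gt$nodes, noise_sigma = 0, seed = 8)
  inits <- list("LPS" = c(1, 0, 1, 0), "IL-4" = c(0, 1, 1, 1),
                "IL-10" = c(1, 1, 0, 0))
  panel <- render_panel(gt, design, initial_states = inits)
  grid <- attr(panel, "grid")
  truth <- attr(panel, "truth")
  for (g in names(inits)) {
    clean <- attr(truth[[g]], "clean_grid")
    for (pr in colnames(clean)) {
      bits_true <- truth[[g]][, pr]
      if (length(unique(bits_true)) < 2) next  # no threshold information
      fit <- fit_smoothing_spline(grid, clean[, pr], p = 1)
      curve <- resample_profile(fit, grid)
      thr <- as.numeric(iterative_kmeans_threshold(curve))
      expect_identical(binarize(curve, thr)$bits, as.integer(bits_true))
    }
  }
})

test_that("binarization mismatches do not decrease with noise in expectation", {
  ## an input-driven cascade whose responder nodes each toggle once;
  ## mismatches are counted at the observation times (where zero-noise
  ## recovery is essentially exact), isolating the noise channel from
  ## transition-smearing effects
  gt <- boolean_network(list(U = bn_rule(character(0), integer(0)),
                             X = "!U", Y = "U", W = "X"))
  grid <- resample_grid()
  mean_mismatch <- function(sigma) {
    total <- 0L
    for (seed in 1:20) {
      design <- synthetic_design(proteins = gt$nodes, noise_sigma = sigma,
                                 groups = c("control", "LPS"), seed = seed)
      panel <- render_panel(gt, design,
                            initial_states = list(LPS = c(U = 1, X = 1,
                                                          Y = 0, W = 1)))
      truth <- attr(panel, "truth")$LPS
      sample_rows <- findInterval(design$times + 1e-9, grid)
      for (pr in c("X", "Y", "W")) {
        s <- panel[panel$group == "LPS" & panel$replicate == 1 &
                     panel$protein == pr, ]
        s <- s[order(s$time_h), ]
        curve <- resample_profile(fit_smoothing_spline(s$time_h, s$value,
                                                       p = 1), grid)
        thr <- as.numeric(iterative_kmeans_threshold(curve))
        total <- total + sum(as.integer(s$value > thr) !=
                               truth[sample_rows, pr])
      }
    }
    total / 20
  }
  m <- vapply(c(0, 0.3, 0.6, 1.0), mean_mismatch, numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("panel CSV dialect round-trips", {
  gt <- generate_ground_truth_bn(2, seed = 3)
  design <- synthetic_design(proteins = gt$nodes, noise_sigma = 0.05, seed = 4)
  panel <- render_panel(gt, design)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)
  expect_equal(back$value, panel$value)
  expect_identical(names(back),
                   c("protein", "group", "replicate", "time_h", "value"))
})
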