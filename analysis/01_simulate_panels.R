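#!/usr/bin/env Rscript

# Stage 1: simulate the study's data. A known 5-node Boolean ground truth
# is rendered into continuous cytokine panels matching the experimental
# design (7 time points over 24 h, 4 replicates, control + 3 stimulated
# groups), once noise-free and once with realistic multiplicative noise.
# Downstream stages re-derive the network from these panels.

suppressPackageStartupMessages(library(cytobool))
dir.create("results/panels", showWarnings = FALSE, recursive = TRUE)

gt <- boolean_network(list(
  A = "B", B = "!C", C = "A & E", D = "A | !B", E = "D"))
cat("Ground-truth network:\n")
print(gt)
write_boolnet(gt, "results/panels/ground_truth.txt")

inits <- list("LPS" = c(A = 1, B = 1, C = 0, D = 1, E = 0),
              "IL-4" = c(A = 0, B = 1, C = 1, D = 0, E = 1),
              "IL-10" = c(A = 1, B = 0, C = 1, D = 1, E = 1))

for (sigma in c(0, 0.2)) {
  design <- synthetic_design(proteins = gt$nodes, noise_sigma = sigma,
                             seed = 11)
  panel <- render_panel(gt, design, initial_states = inits)
  tag <- if (sigma == 0) "clean" else "noisy"
  write_panel_csv(panel, sprintf("results/panels/panel_%s.csv", tag))
  ## ground-truth Boolean trajectories on the 13.5-min grid, per group
  truth <- attr(panel, "truth")
  for (g in names(truth)) {
    utils::write.csv(truth[[g]],
                     sprintf("results/panels/truth_%s_%s.csv", tag,
                             gsub("[^A-Za-z0-9]", "", g)),
                     row.names = FALSE)
  }
  cat(sprintf("panel_%s.csv: %d rows (sigma = %.1f)\n", tag, nrow(panel),
              sigma))
}
cat("Stage 1 done: panels under results/panels/\n")
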