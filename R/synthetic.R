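#' Temporal shape kernels
#'
#' Three archetypal cytokine profile shapes: promotion `c * t / (1 + t)`
#' (non-decreasing, saturating at `c`), inhibition `c / (1 + t) + bias`
#' (non-increasing, decaying to `bias`) and a Gaussian bell
#' `c * exp(-(t - center)^2 / (2 * width^2))`. Time is in hours,
#' amplitudes in expression units; all kernels are non-negative for
#' `t >= 0`.
#'
#' @param kind one of `"promotion"`, `"inhibition"`, `"bell"`.
#' @param c amplitude (expression units, >= 0).
#' @param bias offset (inhibition only, >= 0).
#' @param center,width bell location and scale in hours (width > 0).
#' @export
shape_kernel <- function(kind = c("promotion", "inhibition", "bell"),
                         c = 1, bias = 0, center = 6, width = 2) {
  kind <- match.arg(kind)
  if (c < 0) stop("negative amplitude c")
  if (bias < 0) stop("negative bias")
  if (kind == "bell" && width <= 0) stop("width must be positive")
  structure(list(kind = kind, c = c, bias = bias,
                 center = center, width = width),
            class = "shape_kernel")
}

#' Evaluate a shape kernel
#'
#' @param kernel a [shape_kernel()].
#' @param t time(s) in hours, `t >= 0`.
#' @export
shape_value <- function(kernel, t) {
  stopifnot(all(t >= 0))
  switch(kernel$kind,
         promotion = kernel$c * t / (1 + t),
         inhibition = kernel$c / (1 + t) + kernel$bias,
         bell = kernel$c * exp(-(t - kernel$center)^2 / (2 * kernel$width^2)))
}

## attainable value range of a kernel over t >= 0
kernel_range <- function(kernel) {
  switch(kernel$kind,
         promotion = c(0, kernel$c),
         inhibition = c(kernel$bias, kernel$c + kernel$bias),
         bell = c(kernel$c * exp(-(kernel$center)^2 / (2 * kernel$width^2)),
                  kernel$c))
}

#' Default high/low kernel pair for rendering a Boolean node
#'
#' The high-state kernel is an inhibition shape decaying from `1.2 * high`
#' to a plateau at `high`; the low-state kernel is a promotion shape
#' saturating at `low`. With `low < high` the two value ranges are
#' disjoint, so a threshold between them recovers the Boolean state at
#' every time point - the identifiable regime the binarization stage
#' assumes. The within-state drift (20% of the plateau) is kept well below
#' the gap between states so that the globally optimal two-clustering
#' splits at the gap even when one state is visited only briefly.
#'
#' @param high,low plateau expression levels of the active/inactive state.
#' @export
kernel_pair <- function(high = 10, low = 1) {
  stopifnot(high > low)
  list(high = shape_kernel("inhibition", c = 0.2 * high, bias = high),
       low = shape_kernel("promotion", c = low))
}

#' Synthetic study design
#'
#' Mirrors the experimental design the pipeline targets: a cytokine panel
#' measured at 7 time points over 24 h with 4 replicates in a control group
#' and one group per stimulus. Noise is multiplicative lognormal (sdlog
#' `noise_sigma`) with an additive detection floor.
#'
#' @param proteins character vector of protein names.
#' @param times measurement times in hours, strictly increasing from 0.
#' @param replicates replicates per group (>= 1).
#' @param groups group labels; the first is the control.
#' @param noise_sigma lognormal sdlog of the multiplicative noise.
#' @param noise_floor detection floor in expression units.
#' @param seed integer seed; fully determines the rendered panel.
#' @export
synthetic_design <- function(proteins,
                             times = c(0, 0.5, 1, 3, 6, 12, 24),
                             replicates = 4,
                             groups = c("control", "LPS", "IL-4", "IL-10"),
                             noise_sigma = 0.2,
                             noise_floor = 1e-3,
                             seed = 1L) {
  stopifnot(length(times) >= 2, times[1] == 0, all(diff(times) > 0),
            replicates >= 1, length(groups) >= 2)
  structure(list(proteins = proteins, times = times, replicates = replicates,
                 groups = groups, noise_sigma = noise_sigma,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "synthetic_design")
}

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random ground-truth Boolean network
#'
#' Test-harness generator for parameter-recovery studies: every node gets a
#' non-constant rule over at most `max_parents` randomly chosen parents,
#' with every listed parent essential (the rule depends on it). With
#' `n_nodes = 1` the single node is a self-copy (identity dynamics).
#'
#' @param n_nodes number of nodes (1 to 11).
#' @param max_parents maximum in-degree (<= 3).
#' @param seed integer seed; the result is reproducible.
#' @export
generate_ground_truth_bn <- function(n_nodes, max_parents = 2, seed = 1L) {
  if (n_nodes < 1 || n_nodes > 11) stop("n_nodes must be in [1, 11]")
  if (max_parents > 3) stop("max_parents must be <= 3")
  nodes <- paste0("P", seq_len(n_nodes))
  if (n_nodes == 1) {
    return(boolean_network(stats::setNames(list(bn_rule(nodes, c(0L, 1L))), nodes)))
  }
  with_seed(seed, {
    rules <- stats::setNames(vector("list", n_nodes), nodes)
    for (i in seq_len(n_nodes)) {
      k <- sample.int(min(max_parents, n_nodes - 1), 1)
      parents <- sample(setdiff(nodes, nodes[i]), k)
      repeat {
        outputs <- sample(c(0L, 1L), 2^k, replace = TRUE)
        if (length(unique(outputs)) < 2) next
        fn <- make_boolean_function(parents,
                                    qm_primes(which(outputs == 1L) - 1L, k))
        if (!any(function_unateness(fn) == "absent")) break
      }
      rules[[i]] <- bn_rule(parents, outputs)
    }
    boolean_network(rules)
  })
}

#' Render a Boolean network into a noisy continuous cytokine panel
#'
#' The network is simulated synchronously on the 50-point resampling grid
#' (one update per 13.5-min step in the first segment); each protein's
#' continuous level at time `t` is its high- or low-state kernel evaluated
#' at the time elapsed since that protein's last Boolean switch (the kernel
#' clock resets at each switch). The control group is rendered from the
#' all-low state; each stimulated group from its own initial state.
#' Replicates differ only by noise. Measurements are taken at the design
#' times.
#'
#' @param bn a [boolean_network()] whose nodes name the proteins.
#' @param design a [synthetic_design()] with `proteins == bn$nodes`.
#' @param kernels named list (per protein) of `list(high=, low=)` kernel
#'   pairs; default [kernel_pair()] for every protein.
#' @param initial_states named list mapping each non-control group to an
#'   initial bit vector; defaults to seed-derived random states.
#' @param grid resampling grid from [resample_grid()].
#' @return a data.frame (`protein`, `group`, `replicate`, `time_h`,
#'   `value`) with attributes `truth` (list per group: bits matrix on the
#'   grid), `grid`, `design`, and `separable` (FALSE if any protein's
#'   kernel ranges overlap, flagged with a warning).
#' @export
render_panel <- function(bn, design, kernels = NULL, initial_states = NULL,
                         grid = resample_grid()) {
  proteins <- bn$nodes
  stopifnot(identical(sort(proteins), sort(design$proteins)))
  if (is.null(kernels)) {
    kernels <- stats::setNames(replicate(length(proteins), kernel_pair(),
                                         simplify = FALSE), proteins)
  }
  separable <- TRUE
  for (nm in proteins) {
    hi <- kernel_range(kernels[[nm]]$high)
    lo <- kernel_range(kernels[[nm]]$low)
    if (hi[1] <= lo[2]) separable <- FALSE
  }
  if (!separable) {
    warning("high/low kernel ranges overlap for some protein; ",
            "binarization may not be identifiable")
  }
  stim_groups <- design$groups[-1]
  with_seed(design$seed, {
    if (is.null(initial_states)) {
      initial_states <- stats::setNames(lapply(stim_groups, function(g)
        stats::setNames(sample(c(0L, 1L), length(proteins), replace = TRUE),
                        proteins)), stim_groups)
    }
    truth <- list()
    rows <- list()
    for (g in design$groups) {
      init <- if (g == design$groups[1]) {
        stats::setNames(rep(0L, length(proteins)), proteins)
      } else {
        v <- initial_states[[g]]
        if (is.null(names(v))) names(v) <- proteins
        as.integer(v[proteins])
      }
      sim <- bn_simulate(bn, init, steps = length(grid) - 1)
      truth[[g]] <- sim
      ## per protein: kernel clock = time since last bit flip on the grid
      clean <- function(t_query) {
        vals <- matrix(0, nrow = length(t_query), ncol = length(proteins),
                       dimnames = list(NULL, proteins))
        for (j in seq_along(proteins)) {
          bits <- sim[, j]
          flips <- c(1L, which(diff(bits) != 0) + 1L)
          for (qi in seq_along(t_query)) {
            t <- t_query[qi]
            gi <- max(which(grid <= t + 1e-9))
            last_flip <- max(flips[flips <= gi])
            clock <- t - grid[last_flip]
            kern <- if (bits[gi] == 1L) kernels[[proteins[j]]]$high
                    else kernels[[proteins[j]]]$low
            vals[qi, j] <- shape_value(kern, max(clock, 0))
          }
        }
        vals
      }
      noiseless <- clean(design$times)
      for (r in seq_len(design$replicates)) {
        noise <- matrix(stats::rlnorm(length(noiseless), 0, design$noise_sigma),
                        nrow = nrow(noiseless))
        obs <- pmax(noiseless * noise, design$noise_floor)
        rows[[length(rows) + 1]] <- data.frame(
          protein = rep(proteins, each = length(design$times)),
          group = g, replicate = r,
          time_h = rep(design$times, times = length(proteins)),
          value = as.vector(obs))
      }
      ## dense noiseless rendering on the grid, for round-trip checks
      attr(truth[[g]], "clean_grid") <- clean(grid)
    }
    panel <- do.call(rbind, rows)
    attr(panel, "truth") <- truth
    attr(panel, "grid") <- grid
    attr(panel, "design") <- design
    attr(panel, "separable") <- separable
    panel
  })
}

#' Write / read the tidy panel CSV dialect
#'
#' Columns: `protein`, `group`, `replicate`, `time_h`, `value`; one row per
#' measurement.
#'
#' @param panel a panel data.frame.
#' @param path CSV path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel[, c("protein", "group", "replicate", "time_h", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "group", "replicate", "time_h", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("panel CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (any(df$value < 0, na.rm = TRUE)) stop("negative expression values")
  df[need]
}
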