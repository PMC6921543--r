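#' Pipeline configuration
#'
#' Collects every tunable of the inference pipeline with defaults matching
#' the published workflow: smoothing parameter selected by generalized
#' cross-validation with unit error weights, the 50-point grid with
#' 13.5-min first-segment spacing, iterative K-means from 8 down to 2
#' clusters, LP penalties `gamma = 100` with a fixed slack penalty by
#' default (`lambda = "cv"` enables 5-fold cross-validation), the 70%
#' contribution pruning rule, KS screen at `alpha = 0.01`, and escalation
#' below 85% transition agreement.
#'
#' @param control control group label (default `"control"`).
#' @param p smoothing parameter, NULL for GCV.
#' @param grid_convention `"interval"` or `"inclusive"` (see
#'   [resample_grid()]).
#' @param k_start initial cluster count for binarization.
#' @param gamma LP bias penalty.
#' @param lambda LP slack penalty: numeric, or `"cv"`.
#' @param prune_fraction contribution fraction for pruning.
#' @param alpha KS screen significance level.
#' @param agreement_threshold Boolean-function escalation threshold.
#' @param max_parents cap on parents per child in logic inference.
#' @param max_dynamics_nodes largest network for which the `2^n` state
#'   space is enumerated.
#' @param pool_groups treat all stimulated groups as replicate experiments
#'   of one shared network and infer a single model from their pooled
#'   samples (appropriate for synthetic panels rendered from one ground
#'   truth); default FALSE infers one network per stimulus, as in the
#'   published study.
#' @param candidates `"lp"` (default): the pruned LP network supplies each
#'   child's candidate parents; `"all"`: every other protein is a
#'   candidate (panels of at most 6 proteins), letting the truth-table
#'   minimization drop non-essential parents itself - the validation mode
#'   used for exact recovery studies on small synthetic ground truths.
#' @param seed integer seed for any randomized step.
#' @param out_dir optional directory for per-stage artifact files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(control = "control", p = NULL,
                            grid_convention = "interval", k_start = 8,
                            gamma = 100, lambda = 1, prune_fraction = 0.7,
                            alpha = 0.01, agreement_threshold = 0.85,
                            max_parents = 5, max_dynamics_nodes = 11,
                            pool_groups = FALSE, candidates = c("lp", "all"),
                            seed = 1L, out_dir = NULL) {
  candidates <- match.arg(candidates)
  cfg <- list(control = control, p = p, grid_convention = grid_convention,
              k_start = k_start, gamma = gamma, lambda = lambda,
              prune_fraction = prune_fraction, alpha = alpha,
              agreement_threshold = agreement_threshold,
              max_parents = max_parents,
              max_dynamics_nodes = max_dynamics_nodes,
              pool_groups = pool_groups, candidates = candidates,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

## average replicate values per (protein, time) within one group
average_group <- function(panel, group) {
  sub <- panel[panel$group == group, ]
  agg <- stats::aggregate(value ~ protein + time_h, data = sub, FUN = mean)
  agg[order(agg$protein, agg$time_h), ]
}

## fit + resample one series; returns list(fit, curve)
fit_and_resample <- function(times, values, p, grid) {
  fit <- fit_smoothing_spline(times, values, p = p)
  list(fit = fit, curve = resample_profile(fit, grid))
}

#' Run the full inference pipeline on a cytokine panel
#'
#' Stages, per stimulus group: (1) fit smoothing splines to the averaged
#' and per-replicate profiles and resample them on the 50-point grid;
#' (2) screen proteins by the two-sample KS test against the control's
#' fitted profile; (3) determine per-protein activation thresholds by
#' iterative K-means on the averaged curve and binarize averaged and
#' replicate curves; (4) infer the weighted network by the per-child
#' sparse LP over all replicate samples and prune it with the contribution
#' rule; (5) determine Boolean update rules by truth-table minimization
#' with LP-sign consistency checks and per-replicate escalation;
#' (6) enumerate the state-transition system and its attractors, and
#' reduce the network to its core.
#'
#' @param panel tidy panel data.frame (`protein`, `group`, `replicate`,
#'   `time_h`, `value`) or a path to its CSV.
#' @param config a [pipeline_config()].
#' @return a named list (one element per stimulus group) of stage bundles:
#'   `curves`, `screen`, `thresholds`, `bits`, `network` (pruned weighted
#'   network), `boolean_network`, `transitions`, `attractors`, `core`,
#'   `metrics`, plus a top-level `log` attribute.
#' @export
run_pipeline <- function(panel, config = pipeline_config()) {
  if (is.character(panel)) panel <- read_panel_csv(panel)
  stopifnot(inherits(config, "pipeline_config"))
  groups <- unique(panel$group)
  if (!config$control %in% groups) {
    stop("control group '", config$control, "' absent from the panel")
  }
  stims <- setdiff(groups, config$control)
  proteins <- sort(unique(panel$protein))
  grid <- resample_grid(config$grid_convention)
  log <- list(seed = config$seed, groups = groups, proteins = proteins)

  ## control: averaged fitted curves for the KS screen
  ctrl_avg <- average_group(panel, config$control)
  ctrl_curves <- list()
  for (pr in proteins) {
    s <- ctrl_avg[ctrl_avg$protein == pr, ]
    ctrl_curves[[pr]] <- fit_and_resample(s$time_h, s$value, config$p, grid)$curve
  }

  ## per-group stage data: fitted curves, screen, thresholds, bits
  stage <- list()
  for (g in stims) {
    avg <- average_group(panel, g)
    reps <- sort(unique(panel$replicate[panel$group == g]))
    curves <- list(); fits <- list()
    rep_curves <- stats::setNames(vector("list", length(reps)), reps)
    for (pr in proteins) {
      s <- avg[avg$protein == pr, ]
      fr <- fit_and_resample(s$time_h, s$value, config$p, grid)
      curves[[pr]] <- fr$curve
      fits[[pr]] <- fr$fit
      for (r in reps) {
        sub <- panel[panel$group == g & panel$replicate == r &
                       panel$protein == pr, ]
        sub <- sub[order(sub$time_h), ]
        rep_curves[[as.character(r)]][[pr]] <-
          fit_and_resample(sub$time_h, sub$value, config$p, grid)$curve
      }
    }
    screen <- data.frame(protein = proteins, statistic = NA_real_,
                         p_value = NA_real_, keep = NA)
    for (i in seq_along(proteins)) {
      ks <- ks_screen(curves[[proteins[i]]], ctrl_curves[[proteins[i]]],
                      alpha = config$alpha)
      screen$statistic[i] <- ks$statistic
      screen$p_value[i] <- ks$p_value
      screen$keep[i] <- ks$keep
    }
    kept <- screen$protein[screen$keep]
    if (length(kept) < 2) {
      warning("group ", g, ": fewer than two proteins pass the KS screen; ",
              "keeping all proteins")
      kept <- proteins
    }
    stage[[g]] <- list(curves = curves, fits = fits, rep_curves = rep_curves,
                       screen = screen, kept = kept)
  }

  ## inference units: one per stimulus, or one pooled over all stimuli
  units <- if (isTRUE(config$pool_groups)) {
    list(pooled = stims)
  } else {
    stats::setNames(as.list(stims), stims)
  }
  results <- list()
  for (u in names(units)) {
    member <- units[[u]]
    kept <- sort(unique(unlist(lapply(stage[member], `[[`, "kept"))))
    ## pooled LP samples: every member group x replicate x grid point
    expr <- do.call(rbind, unlist(lapply(stage[member], function(st)
      lapply(st$rep_curves, function(rc) do.call(cbind, rc[kept]))),
      recursive = FALSE))
    colnames(expr) <- kept
    ## thresholds from the pooled samples of each protein
    thresholds <- stats::setNames(numeric(length(kept)), kept)
    for (pr in kept) {
      thresholds[pr] <- as.numeric(
        iterative_kmeans_threshold(expr[, pr], k_start = config$k_start))
    }
    ## binarize averaged curves (per member group) and replicate curves
    avg_bits <- lapply(stage[member], function(st) {
      m <- matrix(0L, nrow = length(grid), ncol = length(kept),
                  dimnames = list(NULL, kept))
      for (pr in kept) m[, pr] <- as.integer(st$curves[[pr]] > thresholds[pr])
      m
    })
    sens <- stats::setNames(numeric(length(kept)), kept)
    for (pr in kept) {
      st1 <- stage[[member[1]]]
      bz <- binarize(st1$curves[[pr]], thresholds[pr],
                     fit_error = st1$fits[[pr]]$mean_abs_error)
      sens[pr] <- bz$sensitive_fraction
    }
    rep_bits <- unlist(lapply(stage[member], function(st)
      lapply(st$rep_curves, function(rc) {
        m <- matrix(0L, nrow = length(grid), ncol = length(kept),
                    dimnames = list(NULL, kept))
        for (pr in kept) m[, pr] <- as.integer(rc[[pr]] > thresholds[pr])
        m
      })), recursive = FALSE)
    if (identical(config$candidates, "all")) {
      if (length(kept) > 6) {
        stop("candidates = \"all\" supports at most 6 proteins")
      }
      links <- do.call(rbind, lapply(kept, function(ch)
        data.frame(parent = setdiff(kept, ch), child = ch,
                   weight = NA_real_)))
      wn <- structure(list(nodes = kept, links = links,
                           biases = stats::setNames(rep(0, length(kept)), kept),
                           provenance = list(candidates = "all")),
                      class = "weighted_network")
      pruned <- wn
    } else {
      wn <- infer_network(expr, thresholds, gamma = config$gamma,
                          lambda = config$lambda)
      pruned <- prune_network(wn, colMeans(expr),
                              fraction = config$prune_fraction)
    }
    bn <- infer_boolean_network(
      pruned, lapply(avg_bits, function(m) m[, pruned$nodes, drop = FALSE]),
      rep_bits = lapply(rep_bits, function(m) m[, pruned$nodes, drop = FALSE]),
      agreement_threshold = config$agreement_threshold,
      max_parents = config$max_parents)
    ts <- NULL; att <- NULL
    if (length(bn$nodes) <= config$max_dynamics_nodes && length(bn$nodes) > 0) {
      ts <- transition_matrix(bn)
      att <- find_attractors(ts)
    }
    core <- if (length(bn$nodes) > 0) reduce_core(bn) else NULL
    metrics <- network_metrics(pruned,
                               attractors = if (is.null(att)) NA_integer_
                                            else length(att$attractors))
    results[[u]] <- list(curves = stage[[member[1]]]$curves,
                         rep_curves = stage[[member[1]]]$rep_curves,
                         screen = stage[[member[1]]]$screen,
                         thresholds = thresholds,
                         sensitive_fraction = sens,
                         bits = list(average = avg_bits, replicates = rep_bits),
                         network = pruned, full_network = wn,
                         boolean_network = bn, transitions = ts,
                         attractors = att, core = core, metrics = metrics)
    inf <- attr(bn, "inference")
    log[[u]] <- list(kept = kept,
                     n_links = nrow(pruned$links),
                     escalated = inf$node[inf$escalated])
    if (!is.null(config$out_dir)) {
      write_pipeline_artifacts(results[[u]], u, config$out_dir)
    }
  }
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  attr(results, "log") <- log
  results
}

## per-stage artifact files for one stimulus group
write_pipeline_artifacts <- function(res, group, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- gsub("[^A-Za-z0-9._-]", "_", group)
  curves <- do.call(cbind, res$curves)
  utils::write.csv(curves, file.path(out_dir, paste0(tag, "_curves.csv")),
                   row.names = FALSE)
  utils::write.csv(res$bits$average[[1]],
                   file.path(out_dir, paste0(tag, "_bits.csv")),
                   row.names = FALSE)
  utils::write.csv(res$screen, file.path(out_dir, paste0(tag, "_screen.csv")),
                   row.names = FALSE)
  utils::write.csv(res$metrics, file.path(out_dir, paste0(tag, "_metrics.csv")),
                   row.names = FALSE)
  write_sif(res$network, file.path(out_dir, paste0(tag, "_network.sif")))
  write_network_graphml(res$network,
                        file.path(out_dir, paste0(tag, "_network.graphml")))
  write_boolnet(res$boolean_network,
                file.path(out_dir, paste0(tag, "_rules.txt")))
  if (!is.null(res$transitions)) {
    write_transition_csv(res$transitions,
                         file.path(out_dir, paste0(tag, "_transitions.csv")))
    export_evolution_map(res$transitions,
                         path = file.path(out_dir, paste0(tag, "_evolution.dot")))
  }
  if (!is.null(res$core)) {
    write_boolnet(res$core$network,
                  file.path(out_dir, paste0(tag, "_core.txt")))
    sidecar <- list(
      core_nodes = res$core$network$nodes,
      outputs = lapply(res$core$outputs, function(r)
        list(node = r$node, round = r$round)),
      collapsed = lapply(res$core$collapsed, function(r)
        list(node = r$node, parent = r$parent, child = r$child,
             parity = r$parity, delay = r$delay)),
      clamped = lapply(res$core$clamped, function(r)
        list(node = r$node, value = r$value)))
    jsonlite::write_json(sidecar,
                         file.path(out_dir, paste0(tag, "_core.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' Shape-classification summary of a panel
#'
#' Fits and resamples every (protein, group, replicate) profile and
#' classifies it as promotion / inhibition / bell over the requested
#' windows, returning the per-group counts.
#'
#' @param panel tidy panel data.frame.
#' @param windows evaluation horizons in hours (default 6, 9, 24).
#' @param p smoothing parameter (NULL for GCV).
#' @param grid resampling grid.
#' @return data.frame with columns `group`, `window_h`, `bell`,
#'   `promotion`, `inhibition`.
#' @export
shape_summary <- function(panel, windows = c(6, 9, 24), p = NULL,
                          grid = resample_grid()) {
  groups <- unique(panel$group)
  rows <- list()
  for (g in groups) {
    sub <- panel[panel$group == g, ]
    combos <- unique(sub[, c("protein", "replicate")])
    labels <- matrix("", nrow = nrow(combos), ncol = length(windows))
    for (i in seq_len(nrow(combos))) {
      s <- sub[sub$protein == combos$protein[i] &
                 sub$replicate == combos$replicate[i], ]
      s <- s[order(s$time_h), ]
      curve <- fit_and_resample(s$time_h, s$value, p, grid)$curve
      for (w in seq_along(windows)) {
        labels[i, w] <- classify_shape(curve, grid, window = windows[w])
      }
    }
    for (w in seq_along(windows)) {
      rows[[length(rows) + 1]] <- data.frame(
        group = g, window_h = windows[w],
        bell = sum(labels[, w] == "bell"),
        promotion = sum(labels[, w] == "promotion"),
        inhibition = sum(labels[, w] == "inhibition"))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
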