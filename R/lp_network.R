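#' Sparse linear-programming inference of one child's regulators
#'
#' For child protein `i` with candidate parents `j`, solves the linear
#' program
#' `min sum_j |w_j| * xbar_j + (1/gamma) * w0 + (1/lambda) * sum_l zeta_l`
#' subject to, for every sample `m` where the child is active
#' (`x_i,m >= delta_i`): `w0 + sum_j w_j x_j,m >= delta_i`, and for every
#' inactive sample: `w0 + sum_j w_j x_j,m <= zeta_l` with slack
#' `zeta_l >= 0`. `xbar_j` is the mean of parent `j` over all samples, so
#' the first term prices each link by its mean contribution. Absolute
#' values are handled by splitting each weight into non-negative positive
#' and negative parts; the bias `w0` is non-negative. Identical sample
#' rows are collapsed (slack coefficients keep their multiplicity), which
#' leaves the optimum unchanged.
#'
#' @param x_parents numeric matrix (samples x candidate parents, named
#'   columns) of parent expression levels.
#' @param x_child numeric vector of the child's expression per sample.
#' @param delta_child the child's activation threshold.
#' @param gamma bias penalty weight (default 100: links are penalized much
#'   more than the bias).
#' @param lambda slack penalty weight (> 0).
#' @return list with `weights` (named, positive = promotion, negative =
#'   inhibition), `bias`, `slacks`, `objective`, `status` (0 = optimal).
#' @export
solve_child_lp <- function(x_parents, x_child, delta_child,
                           gamma = 100, lambda = 1) {
  stopifnot(is.matrix(x_parents), nrow(x_parents) == length(x_child),
            !is.null(colnames(x_parents)), lambda > 0, gamma > 0)
  parents <- colnames(x_parents)
  J <- length(parents)
  xbar <- colMeans(x_parents)
  active <- x_child >= delta_child
  ## collapse duplicate rows within each activity class
  key <- apply(cbind(round(x_parents, 12), active), 1, paste, collapse = "\r")
  first <- !duplicated(key)
  mult <- as.vector(table(key)[key[first]])
  Xu <- x_parents[first, , drop = FALSE]
  act_u <- active[first]
  n_act <- sum(act_u)
  n_inact <- sum(!act_u)
  ## rescale parent columns to unit maximum: the simplex tableau of the raw
  ## problem is badly conditioned when expression scales differ
  sc <- apply(Xu, 2, max)
  sc[sc <= 0] <- 1
  Xs <- sweep(Xu, 2, sc, "/")
  ## variables: w+ (J), w- (J), w0, zeta (n_inact); weights in scaled units
  nv <- 2 * J + 1 + n_inact
  a <- c(xbar / sc, xbar / sc, 1 / gamma, mult[!act_u] / lambda)
  A2 <- NULL; b2 <- NULL
  if (n_act > 0) {
    Xa <- Xs[act_u, , drop = FALSE]
    A2 <- cbind(Xa, -Xa, 1, matrix(0, n_act, n_inact))
    b2 <- rep(delta_child, n_act)
  }
  A1 <- NULL; b1 <- NULL
  if (n_inact > 0) {
    Xi <- Xs[!act_u, , drop = FALSE]
    A1 <- cbind(Xi, -Xi, 1, -diag(n_inact))
    b1 <- rep(0, n_inact)
  }
  if (is.null(A1) && is.null(A2)) {
    sol <- rep(0, nv)
    status <- 0L
  } else {
    fit <- tryCatch(
      boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    maxi = FALSE, n.iter = 50 * (nv + nrow(Xu))),
      error = function(e) list(solved = -2L))
    if (!isTRUE(fit$solved == 1)) {
      return(list(weights = stats::setNames(rep(NA_real_, J), parents),
                  bias = NA_real_, slacks = NULL, objective = NA_real_,
                  status = as.integer(fit$solved)))
    }
    sol <- fit$soln
    status <- 0L
  }
  w <- (sol[1:J] - sol[(J + 1):(2 * J)]) / sc
  names(w) <- parents
  list(weights = w, bias = unname(sol[2 * J + 1]),
       slacks = if (n_inact > 0) sol[(2 * J + 2):nv] else numeric(0),
       objective = sum(a * sol), status = status)
}

#' Select the slack penalty by k-fold cross-validation
#'
#' Grid-searches `lambda` over a log-spaced grid capped at
#' `L * var(x_parents)` (L = number of inactive samples) and returns the
#' value minimizing the mean squared error of the linear predictor
#' `w0 + sum_j w_j x_j` against the child's expression on held-out folds.
#'
#' @inheritParams solve_child_lp
#' @param folds number of cross-validation folds (default 5).
#' @param grid_size number of lambda values on the grid (default 6).
#' @param lambda_grid optional explicit grid overriding the default.
#' @param seed seed for the fold assignment.
#' @return the selected lambda; attribute `cv` holds the per-lambda MSEs.
#' @export
select_lambda <- function(x_parents, x_child, delta_child, gamma = 100,
                          folds = 5, grid_size = 6, lambda_grid = NULL,
                          seed = 1L) {
  n <- length(x_child)
  stopifnot(n >= folds)
  if (is.null(lambda_grid)) {
    L <- sum(x_child < delta_child)
    cap <- L * stats::var(as.vector(x_parents))
    if (!is.finite(cap) || cap <= 0) cap <- 1
    lambda_grid <- cap * 10^seq(-(grid_size - 1), 0)
  }
  if (length(lambda_grid) == 1) return(lambda_grid)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  mse <- vapply(lambda_grid, function(lam) {
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(tr) < 2 || sum(!tr) < 1) { errs[f] <- NA; next }
      sol <- solve_child_lp(x_parents[tr, , drop = FALSE], x_child[tr],
                            delta_child, gamma = gamma, lambda = lam)
      if (sol$status != 0) { errs[f] <- NA; next }
      pred <- sol$bias + as.vector(x_parents[!tr, , drop = FALSE] %*% sol$weights)
      errs[f] <- mean((x_child[!tr] - pred)^2)
    }
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- lambda_grid[which.min(mse)]
  attr(best, "cv") <- data.frame(lambda = lambda_grid, mse = mse)
  best
}

#' Infer the weighted regulatory network over a resampled panel
#'
#' Runs [solve_child_lp()] once per child over all other proteins as
#' candidate parents. Samples are the resampled grid points of every
#' replicate.
#'
#' @param expr numeric matrix (samples x proteins, named columns) of
#'   resampled expression levels.
#' @param thresholds named vector of per-protein activation thresholds.
#' @param gamma bias penalty (default 100).
#' @param lambda slack penalty: a single value, a named per-child vector,
#'   or `"cv"` to select per child by [select_lambda()].
#' @param weight_tol weights with `|w| <= weight_tol` are treated as
#'   absent links (default 1e-8).
#' @return a `weighted_network`: list with `nodes`, `links` (data.frame
#'   parent/child/weight), `biases`, `provenance`.
#' @export
infer_network <- function(expr, thresholds, gamma = 100, lambda = 1,
                          weight_tol = 1e-8) {
  proteins <- colnames(expr)
  stopifnot(all(proteins %in% names(thresholds)))
  links <- list()
  biases <- stats::setNames(numeric(length(proteins)), proteins)
  lambdas <- stats::setNames(numeric(length(proteins)), proteins)
  for (child in proteins) {
    cand <- setdiff(proteins, child)
    xp <- expr[, cand, drop = FALSE]
    lam <- if (identical(lambda, "cv")) {
      as.numeric(select_lambda(xp, expr[, child], thresholds[child], gamma = gamma))
    } else if (length(lambda) > 1) {
      lambda[[child]]
    } else {
      lambda
    }
    sol <- solve_child_lp(xp, expr[, child], thresholds[child],
                          gamma = gamma, lambda = lam)
    if (sol$status != 0) {
      warning("LP not solved for child ", child, " (status ", sol$status, ")")
      next
    }
    keep <- which(abs(sol$weights) > weight_tol)
    if (length(keep)) {
      links[[child]] <- data.frame(parent = names(sol$weights)[keep],
                                   child = child,
                                   weight = unname(sol$weights[keep]))
    }
    biases[child] <- sol$bias
    lambdas[child] <- lam
  }
  links <- if (length(links)) do.call(rbind, c(links, make.row.names = FALSE))
           else data.frame(parent = character(0), child = character(0),
                           weight = numeric(0))
  structure(list(nodes = proteins, links = links, biases = biases,
                 provenance = list(gamma = gamma, lambda = lambdas)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted network:", length(x$nodes), "nodes,", nrow(x$links), "links\n")
  invisible(x)
}

#' Prune a weighted network by the contribution rule
#'
#' For each child, a link's contribution is `|w_j| * xbar_j` with `xbar_j`
#' the parent's mean expression over all samples; links whose contribution
#' falls below `fraction` of the largest contribution into that child are
#' removed. Orphan nodes (no remaining links in either direction) are
#' dropped unless listed in `keep_nodes`.
#'
#' @param network a `weighted_network`.
#' @param mean_expr named vector of per-protein mean expression.
#' @param fraction contribution fraction in (0, 1] (default 0.7).
#' @param keep_nodes nodes never dropped even if orphaned.
#' @return the pruned `weighted_network`.
#' @export
prune_network <- function(network, mean_expr, fraction = 0.7,
                          keep_nodes = character(0)) {
  stopifnot(fraction > 0, fraction <= 1)
  links <- network$links
  if (nrow(links)) {
    contrib <- abs(links$weight) * mean_expr[links$parent]
    keep <- logical(nrow(links))
    for (ch in unique(links$child)) {
      idx <- which(links$child == ch)
      keep[idx] <- contrib[idx] >= fraction * max(contrib[idx])
    }
    links <- links[keep, , drop = FALSE]
  }
  connected <- union(links$parent, links$child)
  nodes <- intersect(network$nodes, union(connected, keep_nodes))
  prov <- network$provenance
  prov$prune_fraction <- fraction
  structure(list(nodes = nodes, links = links,
                 biases = network$biases[intersect(names(network$biases), nodes)],
                 provenance = prov),
            class = "weighted_network")
}

#' Countable properties of a weighted network
#'
#' @param network a `weighted_network` (or a list with `nodes` and a
#'   `links` data.frame with parent/child/weight).
#' @param attractors optional attractor count to report.
#' @return a one-row data.frame: `n_nodes`, `n_links`, `density`
#'   (links/nodes), `n_promotion`, `n_inhibition`, `n_input_nodes`,
#'   `n_output_nodes`, `nodes_ge4_parents`, `n_attractors`.
#' @export
network_metrics <- function(network, attractors = NA_integer_) {
  nodes <- network$nodes
  links <- network$links
  n_nodes <- length(nodes)
  n_links <- nrow(links)
  parents_per <- table(factor(links$child, levels = nodes))
  children_per <- table(factor(links$parent, levels = nodes))
  data.frame(
    n_nodes = n_nodes,
    n_links = n_links,
    density = if (n_nodes > 0) n_links / n_nodes else 0,
    n_promotion = sum(links$weight > 0, na.rm = TRUE),
    n_inhibition = sum(links$weight < 0, na.rm = TRUE),
    n_input_nodes = sum(parents_per == 0),
    n_output_nodes = sum(children_per == 0),
    nodes_ge4_parents = sum(parents_per >= 4),
    n_attractors = attractors)
}

#' Write a network as a SIF (simple interaction format) file
#'
#' Lines are `parent <sign> child` with sign `promotes` / `inhibits`.
#'
#' @param network a `weighted_network`.
#' @param path output path.
#' @export
write_sif <- function(network, path) {
  links <- network$links
  sign <- ifelse(links$weight >= 0, "promotes", "inhibits")
  writeLines(paste(links$parent, sign, links$child, sep = "\t"), path)
  invisible(path)
}

#' Write a network as GraphML with weight and bias attributes
#'
#' @param network a `weighted_network`.
#' @param path output path.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$links, directed = TRUE,
                                     vertices = data.frame(name = network$nodes))
  bias <- network$biases[network$nodes]
  bias[is.na(bias)] <- 0
  g <- igraph::set_vertex_attr(g, "bias", value = unname(bias))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
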