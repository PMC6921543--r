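#' Iterative K-means binarization threshold
#'
#' One-dimensional K-means under the absolute-deviation objective
#' `J = sum_j sum_{i in cluster j} |x_i - C_j|` (cluster centroids are
#' therefore medians), started at `k_start` clusters and reduced one
#' cluster at a time: at each stage the two closest centroids are merged
#' and the clustering is re-fitted by Lloyd iterations, which keeps the
#' whole cascade deterministic (centroids are initialized at quantiles).
#' Because one-dimensional clusters are contiguous in sorted order, the
#' final two-cluster stage is refined by exhaustive split-point search, so
#' the returned 2-clustering is the global optimum of its objective.
#' The activation threshold is the average of the two final cluster
#' centroids (the midpoint reading); a dispersion-based alternative -
#' the average of the within-cluster mean absolute deviations - is
#' available via `threshold_rule = "dispersion"`. A zero threshold is
#' replaced by the detection floor.
#'
#' @param values non-negative resampled expression values (typically 50).
#' @param k_start initial number of clusters (default 8).
#' @param k_end final number of clusters (fixed at 2).
#' @param centroid `"median"` (the L1 objective's minimizer; default) or
#'   `"mean"`.
#' @param threshold_rule `"midpoint"` (default) or `"dispersion"`.
#' @param floor detection floor replacing a zero threshold (default 1e-6).
#' @return the threshold (scalar); attributes `centroids` (final two) and
#'   `J` (final objective value).
#' @export
iterative_kmeans_threshold <- function(values, k_start = 8, k_end = 2,
                                       centroid = c("median", "mean"),
                                       threshold_rule = c("midpoint", "dispersion"),
                                       floor = 1e-6) {
  centroid <- match.arg(centroid)
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(k_start >= k_end, k_end == 2, all(values >= 0))
  x <- as.numeric(values)
  n <- length(x)
  stopifnot(n >= k_start || length(unique(x)) <= k_start)
  cent_fun <- if (centroid == "median") stats::median else mean
  ## initial centroids: quantiles of the data, deduplicated
  centers <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k_start),
                                    names = FALSE, type = 1))
  fit <- kmeans1d(x, centers, cent_fun)
  while (length(fit$centers) > k_end) {
    cs <- sort(fit$centers)
    gaps <- diff(cs)
    j <- which.min(gaps)           # merge the two closest centroids
    merged <- cent_fun(x[fit$assign %in% which(fit$centers %in% cs[j:(j + 1)])])
    centers <- c(setdiff(fit$centers, cs[j:(j + 1)]), merged)
    fit <- kmeans1d(x, centers, cent_fun)
  }
  ## global refinement of the final two-cluster stage
  if (length(unique(x)) > 1) {
    best <- best_split_l1(x, cent_fun)
    xs <- sort(x)
    boundary <- (xs[best$split] + xs[best$split + 1]) / 2
    fit <- list(centers = best$centers,
                assign = ifelse(x <= boundary, 1L, 2L),
                J = best$J)
  }
  cs <- sort(fit$centers)
  if (length(cs) < 2) cs <- c(cs, cs)  # fully degenerate (constant) data
  thr <- if (threshold_rule == "midpoint") {
    mean(cs[c(1, length(cs))])
  } else {
    mean(vapply(seq_along(fit$centers), function(j) {
      pts <- x[fit$assign == j]
      if (length(pts) == 0) 0 else mean(abs(pts - fit$centers[j]))
    }, numeric(1)))
  }
  if (thr <= 0) thr <- floor
  structure(thr, centroids = cs[c(1, length(cs))], J = fit$J)
}

## Lloyd iterations for 1-D K-means under L1 (or L2) distance; empty
## clusters are dropped. Returns centers, assignment and objective trace.
kmeans1d <- function(x, centers, cent_fun = stats::median, max_iter = 100) {
  centers <- sort(unique(centers))
  J_trace <- numeric(0)
  assign <- NULL
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    assign <- max.col(-d, ties.method = "first")
    keep <- sort(unique(assign))
    centers <- centers[keep]
    assign <- match(assign, keep)
    new_centers <- vapply(seq_along(centers), function(j)
      cent_fun(x[assign == j]), numeric(1))
    J <- sum(abs(x - new_centers[assign]))
    J_trace <- c(J_trace, J)
    if (isTRUE(all.equal(new_centers, centers, tolerance = 1e-12))) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  list(centers = centers, assign = assign, J = utils::tail(J_trace, 1),
       J_trace = J_trace)
}

#' Globally optimal 1-D two-clustering by exhaustive split search
#'
#' One-dimensional optimal clusters are contiguous in sorted order, so the
#' global two-cluster optimum is found by scanning all split points. Used
#' both to refine the cascade's final stage and as its independent test
#' oracle (the oracle recomputes costs from scratch).
#'
#' @param values numeric vector.
#' @param cent_fun centroid function: `median` (L1 objective, default) or
#'   `mean` (L2).
#' @export
best_split_l1 <- function(values, cent_fun = stats::median) {
  x <- sort(values)
  n <- length(x)
  l2 <- identical(cent_fun, mean)
  best <- NULL
  for (s in 1:(n - 1)) {
    lo <- x[1:s]; hi <- x[(s + 1):n]
    cl <- cent_fun(lo); ch <- cent_fun(hi)
    J <- if (l2) sum((lo - cl)^2) + sum((hi - ch)^2)
         else sum(abs(lo - cl)) + sum(abs(hi - ch))
    if (is.null(best) || J < best$J - 1e-12) {
      best <- list(J = J, split = s, centers = c(cl, ch))
    }
  }
  best
}

#' Plain two-cluster K-means threshold (L2, single run)
#'
#' The non-iterative baseline: standard Lloyd K-means with two clusters
#' initialized at the data extremes; threshold is the midpoint of the two
#' cluster means. Kept for comparison with the iterative cascade.
#'
#' @param values numeric vector.
#' @export
plain_kmeans_threshold <- function(values) {
  x <- as.numeric(values)
  km <- kmeans1d(x, centers = range(x), cent_fun = mean)
  cs <- sort(km$centers)
  if (length(cs) < 2) return(cs[1])
  mean(cs[c(1, length(cs))])
}

#' Binarize a profile against an activation threshold
#'
#' A value strictly above the threshold maps to 1; a value equal to or
#' below it maps to 0. When the mean absolute fit error is supplied, an
#' error band `threshold +/- error` is recorded along with the fraction of
#' points strictly inside it (the binarization-sensitive points).
#'
#' @param values resampled profile values.
#' @param threshold activation threshold (> 0).
#' @param fit_error mean absolute fit error (optional).
#' @return a `binarized_profile`: list with `bits`, `threshold`, `band`,
#'   `sensitive_fraction`.
#' @export
binarize <- function(values, threshold, fit_error = NULL) {
  stopifnot(threshold > 0)
  bits <- as.integer(values > threshold)
  band <- NULL
  sens <- 0
  if (!is.null(fit_error)) {
    band <- c(threshold - fit_error, threshold + fit_error)
    sens <- mean(values > band[1] & values < band[2])
  }
  structure(list(bits = bits, threshold = threshold, band = band,
                 sensitive_fraction = sens),
            class = "binarized_profile")
}

#' Flag a binarization as sensitive to fit error
#'
#' Fails when more than `tolerance` of the resampled points lie inside the
#' threshold error band (possible false binarization).
#'
#' @param profile a `binarized_profile` with a band.
#' @param tolerance maximum acceptable sensitive fraction (default 0.05).
#' @return TRUE (pass) or FALSE (fail).
#' @export
sensitivity_flag <- function(profile, tolerance = 0.05) {
  profile$sensitive_fraction <= tolerance
}
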