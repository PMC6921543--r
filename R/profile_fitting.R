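#' Penalized smoothing-spline fit of a temporal profile
#'
#' Minimizes the weighted penalized least-squares criterion
#' `p * sum_i a_i (x_i - s(t_i))^2 + (1 - p) * integral (s'')^2 dt`
#' over natural cubic splines with knots at the data points. `p = 1` gives
#' the interpolating spline; `p = 0` the weighted least-squares straight
#' line; `p = NULL` (default) selects `p` by generalized cross-validation.
#' Fitted values are computed by the Reinsch/Green-Silverman linear solve
#' `(p W + (1 - p) K) yhat = p W x` with `K = Q R^-1 Q'`, and the fitted
#' function is the natural cubic interpolant of `(t, yhat)`, clamped at 0
#' on evaluation (no negative expression values).
#'
#' @param times strictly increasing time points (>= 4).
#' @param values non-negative expression values.
#' @param p smoothing parameter in `[0, 1]`, or NULL for GCV.
#' @param weights per-point error weights `a_i` (default all 1).
#' @return a `spline_fit`: list with `times`, `values`, `fitted`, `p`,
#'   `weights`, `r_squared`, `mean_abs_error`, and `fun(t)` evaluating the
#'   clamped fit.
#' @export
fit_smoothing_spline <- function(times, values, p = NULL, weights = NULL) {
  n <- length(times)
  stopifnot(n >= 4, length(values) == n)
  if (anyDuplicated(times)) stop("duplicate time points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("negative expression values")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  K <- curvature_matrix(times)
  solve_p <- function(p) {
    if (p >= 1) return(values)
    if (p <= 0) {
      ## curvature penalty dominates: weighted least-squares line
      fit <- stats::lm.wfit(cbind(1, times), values, w = weights)
      return(as.vector(cbind(1, times) %*% fit$coefficients))
    }
    A <- p * diag(weights) + (1 - p) * K
    as.vector(solve(A, p * weights * values))
  }
  if (is.null(p)) {
    p <- select_p_gcv(times, values, weights, K)
  }
  stopifnot(p >= 0, p <= 1)
  yhat <- solve_p(p)
  f <- stats::splinefun(times, yhat, method = "natural")
  fun <- function(t) pmax(f(t), 0)
  resid <- values - yhat
  sst <- sum(weights * (values - stats::weighted.mean(values, weights))^2)
  r2 <- if (sst > 0) 1 - sum(weights * resid^2) / sst else 1
  structure(list(times = times, values = values, fitted = yhat, p = p,
                 weights = weights, r_squared = r2,
                 mean_abs_error = mean(abs(resid)), fun = fun, K = K),
            class = "spline_fit")
}

## K = Q R^-1 Q' of Green & Silverman: yhat' K yhat is the integrated
## squared second derivative of the natural cubic interpolant of yhat.
curvature_matrix <- function(times) {
  n <- length(times)
  h <- diff(times)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    col <- j - 1
    Q[j - 1, col] <- 1 / h[j - 1]
    Q[j, col] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, col] <- 1 / h[j]
    R[col, col] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) {
      R[col, col + 1] <- R[col + 1, col] <- h[j] / 6
    }
  }
  Q %*% solve(R, t(Q))
}

#' Evaluate the Eq.-style penalized criterion for candidate fitted values
#'
#' `p * sum a_i (x_i - yhat_i)^2 + (1 - p) * yhat' K yhat`, the objective
#' whose minimizer [fit_smoothing_spline()] returns. Exposed so optimality
#' can be verified numerically.
#'
#' @param fit a `spline_fit`.
#' @param yhat candidate fitted values at `fit$times` (default the fit's own).
#' @export
spline_objective <- function(fit, yhat = fit$fitted) {
  p <- fit$p
  p * sum(fit$weights * (fit$values - yhat)^2) +
    (1 - p) * as.numeric(t(yhat) %*% fit$K %*% yhat)
}

select_p_gcv <- function(times, values, weights, K) {
  n <- length(times)
  W <- diag(weights)
  gcv <- function(p) {
    A <- p * W + (1 - p) * K
    S <- solve(A, p * W)
    yhat <- as.vector(S %*% values)
    df <- sum(diag(S))
    if (n - df < 1e-8) return(Inf)
    n * sum(weights * (values - yhat)^2) / (n - df)^2
  }
  grid <- 1 / (1 + 10^seq(4, -4, length.out = 33))  # p from ~1e-4 to ~1
  scores <- vapply(grid, gcv, numeric(1))
  grid[which.min(scores)]
}

#' The 50-point resampling grid
#'
#' 40 samples over the first 9 h plus 10 over (9, 24] h. Under the default
#' `"interval"` convention the first segment uses exact 13.5-min (0.225 h)
#' steps covering `[0, 9)` and the second segment is 10 evenly spaced
#' points from 9 to 24 h; under `"inclusive"` the first 40 points span
#' `[0, 9]` inclusive (spacing 540/39 min) and the last 10 span `(9, 24]`.
#'
#' @param convention `"interval"` (13.5-min steps; default) or
#'   `"inclusive"`.
#' @return strictly increasing numeric vector of 50 times in hours.
#' @export
resample_grid <- function(convention = c("interval", "inclusive")) {
  convention <- match.arg(convention)
  if (convention == "interval") {
    c(0.225 * (0:39), seq(9, 24, length.out = 10))
  } else {
    c(seq(0, 9, length.out = 40), seq(9, 24, length.out = 11)[-1])
  }
}

#' Resample a fitted profile on the 50-point grid
#'
#' @param fit a `spline_fit` covering `[0, 24]` h.
#' @param grid times from [resample_grid()].
#' @return numeric vector of `s(t)` on the grid, clamped at 0.
#' @export
resample_profile <- function(fit, grid = resample_grid()) {
  if (min(grid) < min(fit$times) - 1e-9 || max(grid) > max(fit$times) + 1e-9)
    stop("grid extends outside the fitted support")
  fit$fun(grid)
}

#' Classify a resampled profile as promotion, inhibition or bell
#'
#' Promotion if the final level (at the window end) is more than twice the
#' initial level, inhibition if less than half, bell otherwise. A zero
#' initial level is replaced by the detection floor so the ratio is
#' defined.
#'
#' @param values resampled profile values.
#' @param times matching times in hours (default the 50-point grid).
#' @param window evaluation horizon in hours (6, 9 or 24).
#' @param floor detection floor used when the initial value is 0.
#' @return character label.
#' @export
classify_shape <- function(values, times = resample_grid(), window = 24,
                           floor = 1e-6) {
  stopifnot(length(values) == length(times), length(values) > 0)
  initial <- max(values[1], floor)
  final <- values[max(which(times <= window + 1e-9))]
  ratio <- final / initial
  if (ratio > 2) "promotion" else if (ratio < 0.5) "inhibition" else "bell"
}

#' Two-sample Kolmogorov-Smirnov screen against the control profile
#'
#' Applies the two-sample KS test to the fitted stimulated profile versus
#' the fitted control profile; the protein is kept when `p < alpha`. Note
#' the resampled points of a fitted curve are autocorrelated, so the
#' nominal p-value is approximate; the screen is implemented exactly as
#' described in the source procedure.
#'
#' @param stim,ctrl resampled series (length 50 each).
#' @param alpha significance level (default 0.01).
#' @return list with `statistic` (D), `p_value`, `keep`.
#' @export
ks_screen <- function(stim, ctrl, alpha = 0.01) {
  stopifnot(length(stim) == length(ctrl))
  if (identical(stim, ctrl) || (stats::sd(stim) == 0 && stats::sd(ctrl) == 0 &&
                                stim[1] == ctrl[1])) {
    return(list(statistic = 0, p_value = 1, keep = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(stim, ctrl))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       keep = kt$p.value < alpha)
}
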