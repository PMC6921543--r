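#' Semi-tensor-product state representation
#'
#' A joint Boolean state of `n` nodes is represented as a canonical unit
#' vector ("delta state") of dimension `2^n`. The delta index of a bit
#' vector is `1 + v` where `v` is the integer value of the complemented
#' bits, first-listed node most significant: the all-ones state has index 1
#' and the all-zeros state has index `2^n`. This is the standard indexing
#' that the semi-tensor product `x1 |x| x2 |x| ... |x| xn` induces when a
#' single node's 1 maps to `(1,0)'` and its 0 to `(0,1)'`.
#'
#' @param bits integer/logical vector of node values, first node most
#'   significant.
#' @return delta index in `[1, 2^n]`.
#' @examples
#' state_to_index(c(1, 1, 0, 1, 0, 1))  # 11
#' @export
state_to_index <- function(bits) {
  n <- length(bits)
  1L + as.integer(sum((1L - as.integer(bits > 0)) * 2^((n - 1):0)))
}

#' @rdname state_to_index
#' @param index delta index in `[1, 2^n]`.
#' @param n number of nodes.
#' @return integer bit vector of length `n`.
#' @export
index_to_state <- function(index, n) {
  if (index < 1 || index > 2^n) stop("index out of [1, 2^n]")
  1L - pattern_bits(as.integer(index), n)
}

#' Semi-tensor product of two matrices
#'
#' `stp(A, B) = (A kron I_{t/a}) %*% (B kron I_{t/b})` where `a = ncol(A)`,
#' `b = nrow(B)` and `t = lcm(a, b)`; it reduces to the ordinary product
#' when `a == b`.
#'
#' @param A,B numeric matrices (vectors are treated as columns).
#' @export
stp <- function(A, B) {
  if (is.vector(A)) A <- matrix(A, ncol = 1)
  if (is.vector(B)) B <- matrix(B, ncol = 1)
  a <- ncol(A); b <- nrow(B)
  g <- gcd_int(a, b)
  t <- a / g * b
  (A %x% diag(t / a)) %*% (B %x% diag(t / b))
}

gcd_int <- function(x, y) {
  while (y != 0) { r <- x %% y; x <- y; y <- r }
  x
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' For logical matrices this composes per-node structure matrices into the
#' joint state-transition matrix: column `j` of the result is
#' `A[, j] kron B[, j]`.
#'
#' @param A,B matrices with the same number of columns.
#' @export
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow = nrow(A) * nrow(B), ncol = ncol(A))
  for (j in seq_len(ncol(A))) out[, j] <- A[, j] %x% B[, j]
  out
}

## 2 x 2^n matrix extracting variable j from the joint delta state
var_extractor <- function(j, n) {
  left <- matrix(1, nrow = 1, ncol = 2^(j - 1))
  right <- matrix(1, nrow = 1, ncol = 2^(n - j))
  left %x% diag(2) %x% right
}

## 2 x 2^k structure matrix of a rule on its own parents: column r holds
## delta_2^1 if the rule outputs 1 on the parent state with delta index r.
## Parent delta index r corresponds to truth-table row 2^k + 1 - r.
rule_structure_matrix <- function(rule) {
  k <- length(rule$parents)
  m <- matrix(0, nrow = 2, ncol = 2^k)
  for (r in seq_len(2^k)) {
    v <- rule$outputs[2^k + 1L - r]
    if (is.na(v)) stop("cannot build structure matrix: rule has don't-care rows")
    m[2L - v, r] <- 1
  }
  m
}

#' State-transition system of a Boolean network
#'
#' Builds the `2^n x 2^n` logical transition matrix `M` of the synchronous
#' dynamics `X(k+1) = M |x| X(k)` (every column a unit vector), together
#' with the equivalent successor array. Two constructions are available:
#' `"stp"` composes per-node structure matrices algebraically with
#' Khatri-Rao products of variable-extraction operators, never evaluating
#' the network state by state; `"enumeration"` evaluates [bn_step()] on all
#' `2^n` states. They must agree; tests cross-check them.
#'
#' @param bn a [boolean_network()]; input nodes hold their value.
#' @param method `"stp"` (default) or `"enumeration"`.
#' @param max_nodes guard for the `2^n` state space (default 11).
#' @return a `transition_system`: list with `nodes`, `successor` (integer
#'   vector of length `2^n`), and `M` (the logical matrix).
#' @export
transition_matrix <- function(bn, method = c("stp", "enumeration"),
                              max_nodes = 11) {
  method <- match.arg(method)
  n <- length(bn$nodes)
  if (n > max_nodes) stop("network has ", n, " nodes; limit is ", max_nodes)
  N <- 2^n
  if (method == "stp") {
    Mi <- vector("list", n)
    for (i in seq_len(n)) {
      r <- bn$rules[[bn$nodes[i]]]
      if (inherits(r, "bn_constant")) {
        Mi[[i]] <- matrix(c(r$outputs[1], 1 - r$outputs[1]), 2, 2^n)
      } else if (length(r$parents) == 0) {
        Mi[[i]] <- var_extractor(i, n)  # input node: x' = x
      } else {
        S <- Reduce(khatri_rao,
                    lapply(match(r$parents, bn$nodes), var_extractor, n = n))
        Mi[[i]] <- rule_structure_matrix(r) %*% S
      }
    }
    M <- Reduce(khatri_rao, Mi)
    successor <- apply(M, 2, which.max)
  } else {
    successor <- integer(N)
    for (idx in seq_len(N)) {
      successor[idx] <- state_to_index(bn_step(bn, index_to_state(idx, n)))
    }
    M <- matrix(0, N, N)
    M[cbind(successor, seq_len(N))] <- 1
  }
  structure(list(nodes = bn$nodes, successor = as.integer(successor), M = M),
            class = "transition_system")
}

#' @export
print.transition_system <- function(x, ...) {
  cat("Transition system on", length(x$nodes), "nodes (",
      length(x$successor), "states )\n")
  invisible(x)
}

#' Enumerate attractors and basins of a transition system
#'
#' Fixed points are states mapping to themselves; longer cycles are found
#' by iterative traversal with coloring (no recursion). Every state is
#' assigned to exactly one attractor's basin.
#'
#' @param ts a `transition_system` from [transition_matrix()].
#' @return list with `attractors` (list of integer state-index vectors, in
#'   cycle order; length-1 vectors are fixed points) and `basin` (integer
#'   vector mapping each state to its attractor's position in `attractors`).
#' @export
find_attractors <- function(ts) {
  succ <- ts$successor
  N <- length(succ)
  basin <- integer(N)            # 0 = unassigned
  attractors <- list()
  for (start in seq_len(N)) {
    if (basin[start] != 0L) next
    path <- integer(0)
    mark <- integer(N)           # position on the current path
    s <- start
    while (basin[s] == 0L && mark[s] == 0L) {
      path <- c(path, s)
      mark[s] <- length(path)
      s <- succ[s]
    }
    if (basin[s] != 0L) {
      aid <- basin[s]
    } else {
      cyc <- path[mark[s]:length(path)]
      attractors[[length(attractors) + 1]] <- cyc
      aid <- length(attractors)
    }
    basin[path] <- aid
  }
  list(attractors = attractors, basin = basin)
}

#' Iterate a Boolean network from an initial state
#'
#' Applies synchronous updates until a state repeats or `max_steps` is
#' reached, and returns the visited delta-index sequence (including the
#' first repeated state, so a fixed point appears twice at the end).
#'
#' @param bn a [boolean_network()].
#' @param init initial state: a named/ordered bit vector or a delta index.
#' @param max_steps maximum number of updates (default `2^n + 1`).
#' @return integer vector of delta indices.
#' @export
bn_trajectory <- function(bn, init, max_steps = NULL) {
  n <- length(bn$nodes)
  if (length(init) == 1 && is.numeric(init) && is.null(names(init))) {
    idx <- as.integer(init)
  } else {
    if (is.null(names(init))) names(init) <- bn$nodes
    idx <- state_to_index(as.integer(init[bn$nodes] > 0))
  }
  if (is.null(max_steps)) max_steps <- 2^n + 1
  stopifnot(max_steps >= 1)
  seen <- rep(FALSE, 2^n)
  out <- idx
  seen[idx] <- TRUE
  for (s in seq_len(max_steps)) {
    idx <- state_to_index(bn_step(bn, index_to_state(idx, n)))
    out <- c(out, idx)
    if (seen[idx]) break
    seen[idx] <- TRUE
  }
  out
}

#' Export a state-evolution map as a graph document
#'
#' One node per delta state, one edge per transition; states listed in
#' `highlight` (typically the experimentally observed trajectory) carry a
#' `highlight` attribute. Node ordering is deterministic (delta index).
#'
#' @param ts a `transition_system`.
#' @param highlight integer vector of delta indices to mark.
#' @param path optional output file; format from extension (`.dot`,
#'   `.graphml`) or the `format` argument.
#' @param format `"dot"` or `"graphml"` (default from `path` extension).
#' @return the [igraph::graph] object, invisibly if written to file.
#' @export
export_evolution_map <- function(ts, highlight = integer(0), path = NULL,
                                 format = NULL) {
  N <- length(ts$successor)
  n <- length(ts$nodes)
  labels <- vapply(seq_len(N), function(i)
    paste0("e", N, "_", i), character(1))
  g <- igraph::make_empty_graph(n = N, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  g <- igraph::set_vertex_attr(g, "bits", value = vapply(seq_len(N), function(i)
    paste(index_to_state(i, n), collapse = ""), character(1)))
  g <- igraph::set_vertex_attr(g, "highlight",
                               value = as.integer(seq_len(N) %in% highlight))
  g <- igraph::add_edges(g, rbind(seq_len(N), ts$successor))
  if (!is.null(path)) {
    if (is.null(format)) {
      format <- if (grepl("\\.graphml$", path)) "graphml" else "dot"
    }
    igraph::write_graph(g, path, format = format)
    return(invisible(g))
  }
  g
}

#' Write a transition system as CSV
#'
#' Columns: `state_index`, `successor_index`, `attractor_id`.
#'
#' @param ts a `transition_system`.
#' @param path output CSV path.
#' @export
write_transition_csv <- function(ts, path) {
  att <- find_attractors(ts)
  df <- data.frame(state_index = seq_along(ts$successor),
                   successor_index = ts$successor,
                   attractor_id = att$basin)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
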