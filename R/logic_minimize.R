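#' Truth tables and two-level logic minimization
#'
#' The published workflow determines each child's update rule by filling a
#' truth table from observed state transitions and reading a minimal
#' sum-of-products off a Karnaugh map. The automated equivalent implemented
#' here is Quine-McCluskey minimization with free use of don't-care rows.
#'
#' @name logic_minimization
NULL

#' Build a truth table from binarized transitions
#'
#' Each transition (parent bits at step k, child bit at step k+1) increments
#' its row's vote. Rows never observed stay don't-care. Conflicting rows are
#' resolved by majority vote with the conflict count retained; an exact tie
#' leaves the row don't-care (equal evidence leaves it unconstrained).
#'
#' @param parents character vector of parent node names (at most 5).
#' @param child child node name.
#' @param bits an integer matrix (time points x nodes, named columns, values
#'   0/1) or a list of such matrices (e.g. one per replicate or stimulus
#'   group); transitions are taken within each matrix only.
#' @return a `truth_table`: list with `parents`, `child`, `outputs`
#'   (0/1/NA per row), `votes1`, `votes0` (per-row counts), `conflicts`
#'   (rows with both votes), `n_transitions`.
#' @export
build_truth_table <- function(parents, child, bits) {
  if (length(parents) > 5) stop("at most 5 parents are supported")
  if (is.matrix(bits)) bits <- list(bits)
  k <- length(parents)
  nrows <- 2^k
  votes1 <- votes0 <- integer(nrows)
  n_tr <- 0L
  for (b in bits) {
    stopifnot(is.matrix(b), all(c(parents, child) %in% colnames(b)))
    nt <- nrow(b) - 1L
    if (nt < 1) next
    for (s in seq_len(nt)) {
      idx <- pattern_index(as.integer(b[s, parents] > 0))
      if (b[s + 1L, child] > 0) votes1[idx] <- votes1[idx] + 1L
      else votes0[idx] <- votes0[idx] + 1L
    }
    n_tr <- n_tr + nt
  }
  outputs <- rep(NA_integer_, nrows)
  outputs[votes1 > votes0] <- 1L
  outputs[votes0 > votes1] <- 0L
  ## ties (votes1 == votes0 > 0) stay NA
  structure(list(parents = parents, child = child, outputs = outputs,
                 votes1 = votes1, votes0 = votes0,
                 conflicts = which(votes1 > 0 & votes0 > 0),
                 n_transitions = n_tr),
            class = "truth_table")
}

## implicant: list(mask, value) on k bits; bit j (1 = first parent) is cared
## about iff mask has that bit set; minterm numbering uses first parent as MSB.
imp_covers <- function(mask, value, minterm) {
  bitwAnd(minterm, mask) == value
}

#' Minimize a truth table to a sum-of-products Boolean function
#'
#' Quine-McCluskey with don't-cares used freely: the result covers every
#' 1-row, excludes every 0-row, and is free on NA rows. The cover is chosen
#' as essential primes plus an exhaustive minimal completion (exact for the
#' sizes arising with at most 5 parents); ties between equally small covers
#' break deterministically by lexicographic implicant order. An all
#' don't-care (or empty) table minimizes to the constant 0.
#'
#' @param table a `truth_table` from [build_truth_table()], or any list with
#'   `parents` and `outputs`.
#' @return a `boolean_function`: list with `parents`, `implicants` (each a
#'   `(mask, value)` pair), `expr` (SOP string), `outputs` (the completed
#'   0/1 table the expression realizes), and `rule` (a [bn_rule()]).
#' @export
minimize_sop <- function(table) {
  parents <- table$parents
  k <- length(parents)
  outputs <- table$outputs
  nrows <- 2^k
  stopifnot(length(outputs) == nrows)
  ones <- which(outputs == 1L) - 1L
  dcs <- which(is.na(outputs)) - 1L
  if (length(ones) == 0) {
    return(make_boolean_function(parents, list(), constant = 0L))
  }
  if (length(ones) + length(dcs) == nrows) {
    if (length(ones) == nrows || k == 0) {
      return(make_boolean_function(parents, list(list(mask = 0L, value = 0L)),
                                   constant = 1L))
    }
  }
  primes <- qm_primes(c(ones, dcs), k)
  ## cover selection over the 1-rows only
  cover_tbl <- vapply(primes, function(pr)
    vapply(ones, function(m) imp_covers(pr$mask, pr$value, m), logical(1)),
    logical(length(ones)))
  cover_tbl <- matrix(cover_tbl, nrow = length(ones))
  chosen <- qm_select_cover(cover_tbl)
  make_boolean_function(parents, primes[chosen])
}

## combine minterms into prime implicants (classic QM pairing)
qm_primes <- function(care_minterms, k) {
  if (k == 0) return(list(list(mask = 0L, value = 0L)))
  full_mask <- 2L^k - 1L
  current <- unique(lapply(sort(care_minterms), function(m)
    list(mask = full_mask, value = as.integer(m))))
  primes <- list()
  repeat {
    n <- length(current)
    combined <- logical(n)
    nxt <- list()
    seen <- character(0)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- current[[i]]; b <- current[[j]]
          if (a$mask != b$mask) next
          d <- bitwXor(a$value, b$value)
          if (d != 0 && bitwAnd(d, d - 1L) == 0L) {  # single-bit difference
            combined[i] <- combined[j] <- TRUE
            nm <- list(mask = bitwAnd(a$mask, bitwNot(d)),
                       value = bitwAnd(a$value, bitwNot(d)))
            key <- paste(nm$mask, nm$value)
            if (!key %in% seen) { nxt[[length(nxt) + 1]] <- nm; seen <- c(seen, key) }
          }
        }
      }
    }
    primes <- c(primes, current[!combined])
    if (length(nxt) == 0) break
    current <- nxt
  }
  ## deterministic order: wider implicants (fewer literals) first, then value
  ord <- order(vapply(primes, function(p) sum(pattern_bits(p$mask + 1L, k)), numeric(1)),
               vapply(primes, function(p) as.numeric(p$mask), numeric(1)),
               vapply(primes, function(p) as.numeric(p$value), numeric(1)))
  primes[ord]
}

## minimal cover: essential primes, then exhaustive search over the rest
qm_select_cover <- function(cover_tbl) {
  n_primes <- ncol(cover_tbl)
  uncovered <- rep(TRUE, nrow(cover_tbl))
  chosen <- integer(0)
  ## essential primes: a 1-row covered by exactly one prime
  repeat {
    counts <- rowSums(cover_tbl[, setdiff(seq_len(n_primes), chosen), drop = FALSE])
    ess <- FALSE
    for (r in which(uncovered)) {
      covering <- which(cover_tbl[r, ])
      covering <- setdiff(covering, chosen)
      if (length(covering) == 1) {
        chosen <- c(chosen, covering)
        uncovered <- uncovered & !cover_tbl[, covering]
        ess <- TRUE
        break
      }
    }
    if (!ess) break
  }
  if (!any(uncovered)) return(sort(chosen))
  remaining <- setdiff(which(colSums(cover_tbl[uncovered, , drop = FALSE]) > 0),
                       chosen)
  ## exhaustive search for the smallest completion (sizes here are tiny)
  for (size in seq_along(remaining)) {
    combos <- utils::combn(remaining, size, simplify = FALSE)
    for (cb in combos) {
      if (all(rowSums(cover_tbl[uncovered, cb, drop = FALSE]) > 0)) {
        return(sort(c(chosen, cb)))
      }
    }
  }
  stop("internal error: no cover found")  # cannot happen: minterms cover themselves
}

make_boolean_function <- function(parents, implicants, constant = NULL) {
  k <- length(parents)
  nrows <- 2^k
  if (!is.null(constant)) {
    outputs <- rep(as.integer(constant), nrows)
    expr <- as.character(constant)
    implicants <- if (constant == 1L) list(list(mask = 0L, value = 0L)) else list()
  } else {
    outputs <- integer(nrows)
    for (idx in seq_len(nrows)) {
      m <- idx - 1L
      outputs[idx] <- as.integer(any(vapply(implicants, function(pr)
        imp_covers(pr$mask, pr$value, m), logical(1))))
    }
    expr <- sop_string(parents, implicants)
  }
  structure(list(parents = parents, implicants = implicants, expr = expr,
                 outputs = outputs,
                 rule = bn_rule(parents, outputs, expr = expr)),
            class = "boolean_function")
}

sop_string <- function(parents, implicants) {
  k <- length(parents)
  terms <- vapply(implicants, function(pr) {
    lits <- character(0)
    for (j in seq_len(k)) {
      bit <- 2L^(k - j)
      if (bitwAnd(pr$mask, bit) != 0) {
        lits <- c(lits, if (bitwAnd(pr$value, bit) != 0) parents[j]
                  else paste0("!", parents[j]))
      }
    }
    if (length(lits) == 0) "1" else paste(lits, collapse = " & ")
  }, character(1))
  paste(sort(terms), collapse = " | ")
}

#' @export
print.boolean_function <- function(x, ...) {
  cat(x$expr, "\n")
  invisible(x)
}

#' Evaluate a Boolean function on parent bits
#'
#' @param fn a `boolean_function`.
#' @param bits integer vector (or matrix with one row per case) of parent
#'   values in `fn$parents` order.
#' @export
eval_boolean_function <- function(fn, bits) {
  if (is.matrix(bits)) {
    return(apply(bits, 1, function(b) fn$outputs[pattern_index(as.integer(b > 0))]))
  }
  fn$outputs[pattern_index(as.integer(bits > 0))]
}

#' Semantic unateness of a Boolean function in each parent
#'
#' @param fn a `boolean_function`.
#' @return character vector, one of `"positive"`, `"negative"`, `"mixed"`,
#'   `"absent"` per parent. Positive means flipping the parent from 0 to 1
#'   never decreases the output (a promotion link); negative the converse.
#' @export
function_unateness <- function(fn) {
  k <- length(fn$parents)
  res <- character(k)
  for (j in seq_len(k)) {
    bit <- 2L^(k - j)
    up <- down <- FALSE
    for (m in 0:(2^k - 1)) {
      if (bitwAnd(m, bit) != 0) next
      lo <- fn$outputs[m + 1L]
      hi <- fn$outputs[bitwOr(m, bit) + 1L]
      if (hi > lo) up <- TRUE
      if (hi < lo) down <- TRUE
    }
    res[j] <- if (up && down) "mixed" else if (up) "positive" else if (down) "negative" else "absent"
  }
  stats::setNames(res, fn$parents)
}
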