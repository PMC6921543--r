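#' Check a Boolean function against data and LP link signs
#'
#' Two agreement checks drive the escalation decision: (1) the fraction of
#' observed transitions where the function's prediction equals the child's
#' next bit, and (2) whether each parent's LP sign (promotion/inhibition)
#' matches the function's semantic unateness in that variable (a positive
#' unate parent corresponds to a promotion link). A function that is
#' non-unate (mixed) in some parent always triggers escalation.
#'
#' @param fn a `boolean_function` from [minimize_sop()].
#' @param lp_signs named character vector per parent: `"promotion"` or
#'   `"inhibition"` (parents absent from the vector are skipped).
#' @param bits binarized sample matrix/list as in [build_truth_table()],
#'   used to score predictions; NULL skips the agreement score.
#' @param child child node name (needed when `bits` is supplied).
#' @param agreement_threshold minimum agreement before escalation
#'   (default 0.85).
#' @return list with `agreement`, `sign_check` (per parent: `"match"`,
#'   `"mismatch"`, `"mixed"`, `"absent"`), `escalate`.
#' @export
check_consistency <- function(fn, lp_signs = NULL, bits = NULL, child = NULL,
                              agreement_threshold = 0.85) {
  unate <- function_unateness(fn)
  sign_check <- stats::setNames(rep(NA_character_, length(fn$parents)), fn$parents)
  for (p in fn$parents) {
    u <- unate[[p]]
    if (u == "mixed") { sign_check[p] <- "mixed"; next }
    if (u == "absent") { sign_check[p] <- "absent"; next }
    if (is.null(lp_signs) || !p %in% names(lp_signs) ||
        is.na(lp_signs[[p]])) next
    expected <- if (lp_signs[[p]] == "promotion") "positive" else "negative"
    sign_check[p] <- if (u == expected) "match" else "mismatch"
  }
  agreement <- NA_real_
  if (!is.null(bits)) {
    stopifnot(!is.null(child))
    if (is.matrix(bits)) bits <- list(bits)
    hits <- 0L; total <- 0L
    for (b in bits) {
      nt <- nrow(b) - 1L
      if (nt < 1) next
      for (s in seq_len(nt)) {
        pred <- fn$outputs[pattern_index(as.integer(b[s, fn$parents] > 0))]
        hits <- hits + as.integer(pred == b[s + 1L, child])
        total <- total + 1L
      }
    }
    agreement <- if (total > 0) hits / total else NA_real_
  }
  escalate <- any(sign_check %in% c("mismatch", "mixed"), na.rm = TRUE) ||
    (!is.na(agreement) && agreement < agreement_threshold)
  list(agreement = agreement, sign_check = sign_check, escalate = escalate)
}

#' Re-determine a Boolean function from per-replicate transitions
#'
#' Escalation path: instead of the averaged profile's 49 transitions, all
#' replicates' transitions are pooled into one truth table (supports
#' summed, 4 x 49 = 196 transitions in the reference design) and minimized
#' as usual. For children whose binarized profile stays constantly high,
#' self-regulation (the child as its own parent) is admitted as a
#' candidate and selected when it strictly improves the transition
#' agreement.
#'
#' @param parents candidate parent names.
#' @param child child node name.
#' @param bits list of per-replicate binarized matrices (time x nodes).
#' @param consider_self admit the child itself as an extra parent when its
#'   profile is constantly high (default TRUE).
#' @return a `boolean_function`; attribute `self_regulation` records
#'   whether the self-loop variant was selected.
#' @export
refit_per_replicate <- function(parents, child, bits, consider_self = TRUE) {
  if (is.matrix(bits)) bits <- list(bits)
  tt <- build_truth_table(parents, child, bits)
  fn <- minimize_sop(tt)
  chosen_self <- FALSE
  child_bits <- unlist(lapply(bits, function(b) b[, child]))
  if (consider_self && !child %in% parents && all(child_bits == 1L)) {
    tt_self <- build_truth_table(c(parents, child), child, bits)
    fn_self <- minimize_sop(tt_self)
    a0 <- check_consistency(fn, bits = bits, child = child)$agreement
    a1 <- check_consistency(fn_self, bits = bits, child = child)$agreement
    if (!is.na(a1) && (is.na(a0) || a1 > a0)) {
      fn <- fn_self
      chosen_self <- TRUE
    }
  }
  attr(fn, "self_regulation") <- chosen_self
  fn
}

#' Infer every node's Boolean update rule from binarized profiles
#'
#' For each child with parents in the (pruned) weighted network, builds the
#' truth table from the averaged binarized transitions, minimizes it, and
#' checks agreement and LP-sign consistency; children failing either check
#' are re-fitted from the pooled per-replicate transitions.
#'
#' @param network a `weighted_network` (pruned); link signs provide the
#'   promotion/inhibition labels.
#' @param avg_bits binarized matrix (grid x proteins) of the averaged
#'   profiles, or a list of such matrices (one per stimulus group).
#' @param rep_bits list of per-replicate binarized matrices for
#'   escalation; NULL disables escalation.
#' @param agreement_threshold escalation threshold (default 0.85).
#' @param max_parents cap on parents per child (default 5).
#' @return a [boolean_network()]; attribute `inference` is a data.frame
#'   recording agreement, escalation and the final expression per node.
#' @export
infer_boolean_network <- function(network, avg_bits, rep_bits = NULL,
                                  agreement_threshold = 0.85,
                                  max_parents = 5) {
  if (is.matrix(avg_bits)) avg_bits <- list(avg_bits)
  nodes <- network$nodes
  links <- network$links
  rules <- stats::setNames(vector("list", length(nodes)), nodes)
  log <- list()
  for (child in nodes) {
    lk <- links[links$child == child, , drop = FALSE]
    if (nrow(lk) == 0) {
      rules[[child]] <- bn_rule(character(0), integer(0))  # input node
      log[[child]] <- data.frame(node = child, parents = "", agreement = NA,
                                 escalated = FALSE, expr = "<input>")
      next
    }
    if (nrow(lk) > max_parents) {
      ## keep the strongest parents by |weight|
      lk <- lk[order(-abs(lk$weight)), , drop = FALSE][seq_len(max_parents), ]
    }
    parents <- lk$parent
    signs <- stats::setNames(ifelse(lk$weight > 0, "promotion", "inhibition"),
                             parents)
    tt <- build_truth_table(parents, child, avg_bits)
    fn <- minimize_sop(tt)
    chk <- check_consistency(fn, lp_signs = signs, bits = avg_bits,
                             child = child,
                             agreement_threshold = agreement_threshold)
    escalated <- FALSE
    if (chk$escalate && !is.null(rep_bits)) {
      fn <- refit_per_replicate(parents, child, rep_bits)
      escalated <- TRUE
    }
    rules[[child]] <- fn$rule
    log[[child]] <- data.frame(node = child,
                               parents = paste(fn$parents, collapse = ","),
                               agreement = chk$agreement,
                               escalated = escalated, expr = fn$expr)
  }
  bn <- if (length(rules)) boolean_network(rules)
        else structure(list(nodes = character(0), rules = list()),
                       class = "boolean_network")
  attr(bn, "inference") <-
    if (length(log)) do.call(rbind, c(log, make.row.names = FALSE))
    else data.frame(node = character(0), parents = character(0),
                    agreement = numeric(0), escalated = logical(0),
                    expr = character(0))
  bn
}
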