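#' Boolean networks
#'
#' A Boolean network is a set of named nodes, each carrying a synchronous
#' update rule over a (possibly empty) set of parent nodes. Rules are stored
#' as explicit truth tables so that evaluation, minimization and the
#' semi-tensor-product machinery all operate on one canonical form.
#'
#' Rule truth tables are indexed with the first parent as the most
#' significant bit: the row for parent bits `b` is `1 + sum(b * 2^(k-1:0))`.
#' A node with no parents is an input node; under synchronous update an
#' input node holds its value (`x' = x`) unless clamped.
#'
#' @param rules named list; each element is a rule created by [bn_rule()]
#'   or a character scalar parsed by [parse_rule()].
#' @param nodes character vector of node names; defaults to `names(rules)`.
#' @return an object of class `boolean_network`.
#' @examples
#' bn <- boolean_network(list(a = "b", b = "!a"))
#' bn_step(bn, c(a = 1, b = 1))
#' @export
boolean_network <- function(rules, nodes = names(rules)) {
  stopifnot(is.list(rules), !is.null(names(rules)), all(nzchar(names(rules))))
  if (anyDuplicated(nodes)) stop("duplicate node names")
  rules <- lapply(rules, function(r) {
    if (is.character(r)) parse_rule(r) else r
  })
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (!inherits(r, "bn_rule")) stop("rule for ", nm, " is not a bn_rule")
    missing <- setdiff(r$parents, nodes)
    if (length(missing)) {
      stop("rule for ", nm, " references unknown node(s): ",
           paste(missing, collapse = ", "))
    }
  }
  extra <- setdiff(nodes, names(rules))
  for (nm in extra) rules[[nm]] <- bn_rule(character(0), integer(0))
  structure(list(nodes = nodes, rules = rules[nodes]),
            class = "boolean_network")
}

#' Construct a Boolean update rule from a truth table
#'
#' @param parents character vector of parent node names (first parent is the
#'   most significant bit of the row index).
#' @param outputs integer vector of length `2^length(parents)` with values in
#'   `{0, 1}` (NA marks a don't-care row); length 0 marks an input node.
#' @param expr optional human-readable sum-of-products string.
#' @export
bn_rule <- function(parents, outputs, expr = NULL) {
  parents <- as.character(parents)
  k <- length(parents)
  if (k > 0) {
    stopifnot(length(outputs) == 2^k)
    outputs <- as.integer(outputs)
    stopifnot(all(outputs %in% c(0L, 1L) | is.na(outputs)))
  } else {
    outputs <- integer(0)
  }
  structure(list(parents = parents, outputs = outputs, expr = expr),
            class = "bn_rule")
}

#' @export
print.bn_rule <- function(x, ...) {
  if (length(x$parents) == 0) {
    cat("<input node>\n")
  } else {
    cat(rule_to_string(x), "\n")
  }
  invisible(x)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$nodes), "nodes\n")
  for (nm in x$nodes) {
    r <- x$rules[[nm]]
    rhs <- if (length(r$parents) == 0) "<input>" else rule_to_string(r)
    cat(" ", nm, "<-", rhs, "\n")
  }
  invisible(x)
}

pattern_index <- function(bits) {
  k <- length(bits)
  if (k == 0) return(1L)
  1L + as.integer(sum(bits * 2^((k - 1):0)))
}

pattern_bits <- function(idx, k) {
  v <- idx - 1L
  bits <- integer(k)
  for (j in k:1) {
    bits[j] <- v %% 2L
    v <- v %/% 2L
  }
  bits
}

#' Evaluate a rule on a named state vector
#'
#' @param rule a [bn_rule()].
#' @param state named numeric/logical vector of node values (0/1).
#' @return 0 or 1 (NA on a don't-care row).
#' @export
eval_rule <- function(rule, state) {
  if (length(rule$parents) == 0) stop("input node has no update rule")
  bits <- as.integer(state[rule$parents] > 0)
  rule$outputs[pattern_index(bits)]
}

#' Synchronous update of a Boolean network
#'
#' Every node's rule is evaluated on the current state simultaneously.
#' Input nodes hold their value.
#'
#' @param bn a [boolean_network()].
#' @param bits named vector of current node values (0/1), or an unnamed
#'   vector in `bn$nodes` order.
#' @return named integer vector of next-state values in `bn$nodes` order.
#' @export
bn_step <- function(bn, bits) {
  if (is.null(names(bits))) {
    stopifnot(length(bits) == length(bn$nodes))
    names(bits) <- bn$nodes
  }
  state <- as.integer(bits[bn$nodes] > 0)
  names(state) <- bn$nodes
  nxt <- state
  for (nm in bn$nodes) {
    r <- bn$rules[[nm]]
    if (inherits(r, "bn_constant")) {
      nxt[nm] <- r$outputs[1]
    } else if (length(r$parents) > 0) {
      v <- r$outputs[pattern_index(state[r$parents])]
      if (is.na(v)) stop("rule for ", nm, " is undefined (don't-care) at the current state")
      nxt[nm] <- v
    }
  }
  nxt
}

#' Simulate a Boolean network
#'
#' @inheritParams bn_step
#' @param steps number of synchronous updates.
#' @return integer matrix with `steps + 1` rows (including the initial
#'   state) and one column per node.
#' @export
bn_simulate <- function(bn, bits, steps) {
  if (is.null(names(bits))) names(bits) <- bn$nodes
  out <- matrix(NA_integer_, nrow = steps + 1, ncol = length(bn$nodes),
                dimnames = list(NULL, bn$nodes))
  state <- as.integer(bits[bn$nodes] > 0)
  names(state) <- bn$nodes
  out[1, ] <- state
  for (s in seq_len(steps)) {
    state <- bn_step(bn, state)
    out[s + 1, ] <- state
  }
  out
}

## parent -> children adjacency
bn_children <- function(bn) {
  ch <- stats::setNames(vector("list", length(bn$nodes)), bn$nodes)
  for (nm in bn$nodes) {
    for (p in bn$rules[[nm]]$parents) ch[[p]] <- c(ch[[p]], nm)
  }
  lapply(ch, unique)
}

bn_parents <- function(bn) {
  lapply(bn$rules, function(r) r$parents)
}

## ------------------------------------------------------------------
## Rule expression parsing: tokens are node names ([A-Za-z0-9._-]+),
## '!', '&', '|', parentheses.  Grammar: or := and ('|' and)*;
## and := unary ('&' unary)*; unary := '!' unary | '(' or ')' | name.
## ------------------------------------------------------------------

tokenize_rule <- function(text) {
  pat <- "[A-Za-z0-9._-]+|[!&|()]"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("cannot tokenize rule: ", text)
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  rest <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", rest)) stop("unexpected characters in rule: ", text)
  toks
}

parse_rule_ast <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    lhs <- parse_and()
    while (!is.na(peek()) && peek() == "|") {
      take()
      lhs <- list(op = "|", args = list(lhs, parse_and()))
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_unary()
    while (!is.na(peek()) && peek() == "&") {
      take()
      lhs <- list(op = "&", args = list(lhs, parse_unary()))
    }
    lhs
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of rule")
    if (t == "!") { take(); return(list(op = "!", args = list(parse_unary()))) }
    if (t == "(") {
      take()
      e <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("missing closing parenthesis")
      take()
      return(e)
    }
    if (t %in% c("&", "|", ")")) stop("unexpected token: ", t)
    take()
    list(op = "var", name = t)
  }
  ast <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in rule: ",
                                paste(toks[pos:length(toks)], collapse = " "))
  ast
}

ast_vars <- function(ast) {
  if (ast$op == "var") return(ast$name)
  unique(unlist(lapply(ast$args, ast_vars)))
}

ast_eval <- function(ast, env) {
  switch(ast$op,
         var = env[[ast$name]],
         "!" = 1L - ast_eval(ast$args[[1]], env),
         "&" = ast_eval(ast$args[[1]], env) * ast_eval(ast$args[[2]], env),
         "|" = max(ast_eval(ast$args[[1]], env), ast_eval(ast$args[[2]], env)))
}

#' Parse a Boolean rule string into a truth-table rule
#'
#' Understands `!` (negation), `&`, `|` and parentheses; node names may
#' contain letters, digits, `.`, `_` and `-`. `"0"` and `"1"` are the
#' constant rules.
#'
#' @param text rule string, e.g. `"IL-10 & !MIP-1b"`.
#' @param parents optional explicit parent ordering (superset of the
#'   variables appearing in `text`).
#' @return a [bn_rule()].
#' @export
parse_rule <- function(text, parents = NULL) {
  toks <- tokenize_rule(text)
  ast <- parse_rule_ast(toks)
  vars <- ast_vars(ast)
  const <- intersect(vars, c("0", "1"))
  if (length(const) && length(vars) > 1)
    stop("constants cannot be mixed with variables in a rule")
  if (identical(vars, "0") || identical(vars, "1")) {
    if (is.null(parents) || length(parents) == 0)
      stop("constant rule needs explicit parents to size its table; use bn_rule()")
    vars <- character(0)
  }
  if (is.null(parents)) parents <- vars
  stopifnot(all(vars %in% parents) || length(vars) == 0)
  k <- length(parents)
  outputs <- integer(2^k)
  for (idx in seq_len(2^k)) {
    bits <- pattern_bits(idx, k)
    env <- as.list(stats::setNames(as.integer(bits), parents))
    if (identical(ast$op, "var") && ast$name %in% c("0", "1")) {
      outputs[idx] <- as.integer(ast$name)
    } else {
      outputs[idx] <- ast_eval(ast, env)
    }
  }
  bn_rule(parents, outputs, expr = text)
}

#' Render a rule as a sum-of-products string
#'
#' The string is rebuilt from the truth table (don't-cares are treated as
#' zeros), so it always matches the stored table.
#'
#' @param rule a [bn_rule()].
#' @param minimize logical; minimize before printing (default TRUE).
#' @export
rule_to_string <- function(rule, minimize = TRUE) {
  k <- length(rule$parents)
  if (k == 0) return("<input>")
  if (minimize) {
    tt <- list(parents = rule$parents, outputs = rule$outputs)
    fn <- minimize_sop(tt)
    return(fn$expr)
  }
  ones <- which(rule$outputs == 1L)
  if (length(ones) == 0) return("0")
  terms <- vapply(ones, function(idx) {
    bits <- pattern_bits(idx, k)
    lits <- ifelse(bits == 1L, rule$parents, paste0("!", rule$parents))
    paste(lits, collapse = " & ")
  }, character(1))
  paste(terms, collapse = " | ")
}

## ------------------------------------------------------------------
## BoolNet-style "targets, factors" serialization
## ------------------------------------------------------------------

#' Write a Boolean network in BoolNet's targets/factors text format
#'
#' @param bn a [boolean_network()].
#' @param path output file path.
#' @export
write_boolnet <- function(bn, path) {
  lines <- "targets, factors"
  for (nm in bn$nodes) {
    r <- bn$rules[[nm]]
    rhs <- if (length(r$parents) == 0) nm else rule_to_string(r)
    lines <- c(lines, paste0(nm, ", ", rhs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Boolean network from BoolNet's targets/factors text format
#'
#' A line whose factor expression is just the target itself is read back as
#' an input node when the node appears in no other rule as written, i.e.
#' self-copy rules are preserved literally.
#'
#' @param path input file path.
#' @export
read_boolnet <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!grepl("^targets[[:space:]]*,[[:space:]]*factors$", lines[1]))
    stop("not a BoolNet targets/factors file")
  lines <- lines[-1]
  rules <- list()
  for (ln in lines) {
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma == -1) stop("malformed line: ", ln)
    target <- trimws(substr(ln, 1, comma - 1))
    factor <- trimws(substr(ln, comma + 1, nchar(ln)))
    rules[[target]] <- parse_rule(factor)
  }
  boolean_network(rules)
}
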