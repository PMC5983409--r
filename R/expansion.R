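# Condensed-to-expanded formula algebra: expression trees, level-r
# expansion by simultaneous substitution, operand sets and their
# convergence, closed formulas and symbol counting.

expr_leaf <- function(name) structure(name, class = "si_expression")

expr_node <- function(left, right)
  structure(list(left, right), class = "si_expression")

is_expr_leaf <- function(e) is.character(e)

#' @export
print.si_expression <- function(x, ...) {
  cat(format_expression(x), "\n")
  invisible(x)
}

#' Level-0 formula of an internal element
#'
#' The condensed synthesis formula of `x`: a two-leaf expression matching
#' the binary operator of `x`'s row.
#'
#' @param si a valid `synthesis_interactome`.
#' @param x an internal element name (a product of some row).
#' @return An `si_expression` with two leaves.
#' @examples
#' format_expression(base_formula(toy_si(), "i"))  # "<a,b>"
#' @export
base_formula <- function(si, x) {
  rows <- si_rows(si)
  i <- match(x, rows$product)
  if (is.na(i))
    stop(sprintf("no synthesis information for element %s", sQuote(x)),
         call. = FALSE)
  expr_node(expr_leaf(rows$operand_a[i]), expr_leaf(rows$operand_b[i]))
}

#' Expand a synthesis formula to a given level
#'
#' Applies `r` rounds of simultaneous substitution: at each round, every
#' leaf naming an internal element is replaced by that element's level-0
#' formula; external leaves are left untouched.  Formulas of recursive
#' elements grow without bound, so the expansion is guarded by a size cap
#' on the number of leaves.
#'
#' @param si a valid `synthesis_interactome`.
#' @param x an internal element name.
#' @param r number of substitution rounds (`r >= 0`).
#' @param size_cap maximum number of leaves the tree may reach
#'   (default `1e6`).
#' @return An `si_expression`.
#' @examples
#' format_expression(expand_to_level(toy_si(), "a", 2))  # "<<<b,c>,d>,c>"
#' @export
expand_to_level <- function(si, x, r, size_cap = 1e6) {
  stopifnot(length(r) == 1L, r >= 0)
  rows <- si_rows(si)
  expr <- base_formula(si, x)
  if (r == 0) return(expr)
  internal <- rows$product
  substitute_once <- function(e) {
    if (is_expr_leaf(e)) {
      nm <- unclass(e)
      if (nm %in% internal) base_formula(si, nm) else e
    } else {
      expr_node(substitute_once(e[[1L]]), substitute_once(e[[2L]]))
    }
  }
  for (level in seq_len(r)) {
    expr <- substitute_once(expr)
    n_leaves <- symbol_count(expr, "leaves")
    if (n_leaves > size_cap)
      stop(sprintf(
        "expansion exceeded size cap of %g leaves at level %d (of %d requested)",
        size_cap, level, r), call. = FALSE)
  }
  expr
}

#' Set of operands of an expression
#'
#' The set of distinct element names appearing as leaves of the formula
#' (duplicates collapse).
#'
#' @param expr an `si_expression`.
#' @return Sorted character vector of leaf names.
#' @examples
#' formula_operands(parse_expression("<<a,d>,c>"))  # "a" "c" "d"
#' @export
formula_operands <- function(expr) {
  leaves <- function(e) {
    if (is_expr_leaf(e)) unclass(e) else c(leaves(e[[1L]]), leaves(e[[2L]]))
  }
  sort(unique(leaves(expr)))
}

# Level-r operand sets computed without materializing trees: the leaves of
# the level r+1 formula are the external leaves of level r plus the
# operands of each internal leaf of level r.  As *sets* this recursion is
# exact, which is what makes operand-set convergence cap-free.
level_operand_sets <- function(si, x, r_max) {
  rows <- si_rows(si)
  internal <- rows$product
  current <- sort(row_operands(si, x))
  out <- vector("list", r_max + 1L)
  out[[1L]] <- current
  if (r_max >= 1L) {
    for (r in seq_len(r_max)) {
      int <- intersect(current, internal)
      ext <- setdiff(current, internal)
      nxt <- ext
      if (length(int) > 0L)
        nxt <- union(nxt, unlist(lapply(int, function(m) row_operands(si, m))))
      current <- sort(unique(nxt))
      out[[r + 1L]] <- current
    }
  }
  out
}

#' Cumulative operand set up to a level
#'
#' The union of the level operand sets for levels `0..r`; monotonically
#' non-decreasing in `r` and bounded by the element set `S`.
#'
#' @param si a valid `synthesis_interactome`.
#' @param x an internal element name.
#' @param r maximum level (`r >= 0`).
#' @return Sorted character vector.
#' @examples
#' cumulative_operand_set(toy_si(), "a", 1)  # "a" "b" "c" "d"
#' @export
cumulative_operand_set <- function(si, x, r) {
  stopifnot(length(r) == 1L, r >= 0)
  sets <- level_operand_sets(si, x, r)
  sort(unique(unlist(sets)))
}

#' Complete operand set of an element, with its convergence trace
#'
#' Iterates the cumulative operand sets until two consecutive levels are
#' equal.  Because the cumulative sets grow monotonically and are bounded
#' by `S`, the iteration always converges within fewer than `|S|` rounds.
#' The converged set is the complete operand set: every element that
#' appears, at any depth, in the synthesis of `x`.  It equals the ancestor
#' set of `x` in the synthesis digraph.
#'
#' @param si a valid `synthesis_interactome`.
#' @param x an internal element name.
#' @return An object of class `operand_trace`: a list with `element`,
#'   `levels` (a data-frame-free list, one entry per level, each holding
#'   `level_operands` and `cumulative_operands`), `converged_at` (the
#'   smallest `u` with equal cumulative sets at `u` and `u+1`) and
#'   `complete` (the converged set).
#' @examples
#' complete_operand_set(toy_si(), "i")$complete  # "a" "b" "c" "d"
#' @export
complete_operand_set <- function(si, x) {
  part <- element_partition(si, check = FALSE)
  r_cap <- length(part$S)  # convergence is guaranteed strictly below |S|
  sets <- level_operand_sets(si, x, r_cap)
  levels <- vector("list", r_cap + 1L)
  cumulative <- character(0)
  converged_at <- NA_integer_
  for (r in 0:r_cap) {
    new_cum <- sort(union(cumulative, sets[[r + 1L]]))
    levels[[r + 1L]] <- list(level = r,
                             level_operands = sets[[r + 1L]],
                             cumulative_operands = new_cum)
    if (r > 0L && setequal(new_cum, cumulative) && is.na(converged_at))
      converged_at <- r - 1L
    cumulative <- new_cum
  }
  if (is.na(converged_at))
    converged_at <- r_cap  # unreachable for well-formed SIs; defensive
  structure(list(element = x,
                 levels = levels[seq_len(converged_at + 2L)],
                 converged_at = converged_at,
                 complete = levels[[converged_at + 1L]]$cumulative_operands),
            class = "operand_trace")
}

#' @export
print.operand_trace <- function(x, ...) {
  cat(sprintf("Operand trace for %s (converged at level %d)\n",
              sQuote(x$element), x$converged_at))
  for (lv in x$levels)
    cat(sprintf("  r=%d  O_r={%s}  O*_r={%s}\n", lv$level,
                paste(lv$level_operands, collapse = ","),
                paste(lv$cumulative_operands, collapse = ",")))
  cat(sprintf("  complete O* = {%s}\n", paste(x$complete, collapse = ",")))
  invisible(x)
}

#' Closed expanded formula of an element, if one exists
#'
#' A closed formula `E*(x)` is a level-`r` expansion whose operands are all
#' external; further substitution leaves it unchanged.  It exists exactly
#' when no ancestor of `x` (including `x` itself) lies on a directed cycle
#' of the synthesis digraph, so existence is decided through the digraph
#' first and the formula is only materialized when the search is known to
#' terminate.
#'
#' @param si a valid `synthesis_interactome`.
#' @param x an internal element name.
#' @param size_cap passed to [expand_to_level()] when materializing.
#' @return The closed `si_expression` (at the smallest such level), or
#'   `NULL` when every expansion level still contains internal operands.
#' @examples
#' format_expression(closed_expanded_formula(toy_si(), "g"))  # "<<e,h>,<e,h>>"
#' is.null(closed_expanded_formula(toy_si(), "a"))            # TRUE
#' @export
closed_expanded_formula <- function(si, x, size_cap = 1e6) {
  part <- element_partition(si, check = FALSE)
  if (!x %in% part$S_i)
    stop(sprintf("no synthesis information for element %s", sQuote(x)),
         call. = FALSE)
  g <- build_synthesis_digraph(si)
  anc <- ancestor_set(g, x)
  sub_nodes <- union(x, anc)
  sub <- igraph::induced_subgraph(g, vids = sub_nodes)
  if (!igraph::is_dag(sub)) return(NULL)
  # acyclic ancestry: level operand sets reach an all-external state
  r <- 0L
  repeat {
    o_r <- level_operand_sets(si, x, r)[[r + 1L]]
    if (length(intersect(o_r, part$S_i)) == 0L) break
    r <- r + 1L
  }
  expand_to_level(si, x, r, size_cap = size_cap)
}

#' Count the symbols of an expression
#'
#' Two conventions are offered: `"tokens"` counts every leaf name, bracket
#' and comma as one symbol (a two-leaf formula `<a,b>` has 5 tokens);
#' `"leaves"` counts leaves only.
#'
#' @param expr an `si_expression`.
#' @param convention `"tokens"` or `"leaves"`.
#' @return Integer count.
#' @examples
#' symbol_count(parse_expression("<a,b>"), "tokens")  # 5
#' @export
symbol_count <- function(expr, convention = c("tokens", "leaves")) {
  convention <- match.arg(convention)
  n_leaves <- function(e) {
    if (is_expr_leaf(e)) 1L else n_leaves(e[[1L]]) + n_leaves(e[[2L]])
  }
  n <- n_leaves(expr)
  switch(convention,
         leaves = n,
         # each of the n-1 internal nodes contributes '<', ',' and '>'
         tokens = n + 3L * (n - 1L))
}
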