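# Graph-theoretic view of a synthesis interactome, built on igraph.  This
# module is deliberately independent of the operand-set algebra: recursion
# is re-derived here as membership in a directed closed walk, and ancestor
# sets as reverse reachability, so the two routes cross-validate each
# other.

element_types <- function(si) {
  rows <- si_rows(si)
  elements <- sort(unique(c(rows$product, rows$operand_a, rows$operand_b)))
  type <- rep(NA_character_, length(elements))
  names(type) <- elements
  pick <- function(el, val) {
    if (!is.na(val) && is.na(type[[el]])) type[[el]] <<- val
  }
  for (i in seq_len(nrow(rows))) pick(rows$product[i], rows$type_name[i])
  for (i in seq_len(nrow(rows))) {
    pick(rows$operand_a[i], rows$type_a[i])
    pick(rows$operand_b[i], rows$type_b[i])
  }
  type
}

#' Build the synthesis digraph of an interactome
#'
#' Nodes are the elements of `S`; each row contributes directed edges from
#' its operands to its product.  A repeated operand (`<a,a> => c`) is
#' stored as a single edge with `multiplicity` 2, which leaves cycle and
#' reachability semantics untouched while keeping simple-graph exports
#' clean.  External and genomic nodes have in-degree 0; every internal
#' node receives exactly two in-edge slots (the sum of incoming edge
#' multiplicities).
#'
#' Node attributes: `set_of_origin` (`"Si"`, `"Se"` or `"G"`), `type`
#' (free text, possibly `NA`), `recursive` (lies on a directed closed
#' walk) and `essential` (recursive, or an ancestor of a recursive node)
#' -- the last two computed purely graph-side.
#'
#' @param si a valid `synthesis_interactome`.
#' @return An `igraph` directed graph.
#' @examples
#' g <- build_synthesis_digraph(toy_si())
#' igraph::vcount(g)  # 9
#' @export
build_synthesis_digraph <- function(si) {
  assert_valid_si(si)
  rows <- si_rows(si)
  part <- element_partition(si, check = FALSE)
  elements <- part$S

  from <- character(0); to <- character(0); mult <- integer(0)
  for (i in seq_len(nrow(rows))) {
    a <- rows$operand_a[i]; b <- rows$operand_b[i]; p <- rows$product[i]
    if (a == b) {
      from <- c(from, a); to <- c(to, p); mult <- c(mult, 2L)
    } else {
      from <- c(from, a, b); to <- c(to, p, p); mult <- c(mult, 1L, 1L)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, multiplicity = mult,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = elements, stringsAsFactors = FALSE))

  origin <- ifelse(elements %in% part$S_i, "Si",
                   ifelse(elements %in% part$G, "G", "Se"))
  types <- element_types(si)
  igraph::V(g)$set_of_origin <- origin
  igraph::V(g)$type <- unname(types[elements])

  rec <- cycle_nodes(g)
  igraph::V(g)$recursive <- elements %in% rec
  ess <- rec
  for (x in rec) ess <- union(ess, ancestor_set(g, x))
  igraph::V(g)$essential <- elements %in% ess
  g
}

#' Build the undirected binding graph of an interactome
#'
#' The binding relation links the two operands of every row (a self-loop
#' when the operands coincide); the product is recorded as an edge
#' attribute.
#'
#' @param si a valid `synthesis_interactome`.
#' @return An `igraph` undirected graph with one edge per row.
#' @examples
#' igraph::ecount(build_binding_graph(pol_si()))  # 12
#' @export
build_binding_graph <- function(si) {
  assert_valid_si(si)
  rows <- si_rows(si)
  part <- element_partition(si, check = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rows$operand_a, to = rows$operand_b,
               product = rows$product, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = part$S, stringsAsFactors = FALSE))
  origin <- ifelse(part$S %in% part$S_i, "Si",
                   ifelse(part$S %in% part$G, "G", "Se"))
  igraph::V(g)$set_of_origin <- origin
  igraph::V(g)$type <- unname(element_types(si)[part$S])
  g
}

# nodes lying on some directed closed walk: members of a strongly
# connected component of size >= 2, or bearing a self-loop
cycle_nodes <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  multi <- names(comp$membership)[comp$csize[comp$membership] >= 2L]
  loop_edges <- igraph::E(g)[igraph::which_loop(g)]
  loops <- if (length(loop_edges) > 0L)
    unique(igraph::ends(g, loop_edges, names = TRUE)[, 1L]) else character(0)
  sort(unique(c(multi, loops)))
}

#' Ancestors of a node in the synthesis digraph
#'
#' All nodes with a directed path of length >= 1 ending at `x`.  `x`
#' itself is included exactly when it lies on a closed walk through
#' itself.  For internal elements this set coincides with the complete
#' operand set computed by formula expansion.
#'
#' @param g a synthesis digraph from [build_synthesis_digraph()].
#' @param x a node name.
#' @return Sorted character vector of node names.
#' @examples
#' ancestor_set(build_synthesis_digraph(toy_si()), "i")  # "a" "b" "c" "d"
#' @export
ancestor_set <- function(g, x) {
  if (!x %in% igraph::V(g)$name)
    stop(sprintf("unknown node %s", sQuote(x)), call. = FALSE)
  anc <- setdiff(names(igraph::subcomponent(g, x, mode = "in")), x)
  if (x %in% cycle_nodes(g)) anc <- union(anc, x)
  sort(anc)
}

#' Internal elements lying on a directed closed walk
#'
#' The graph-side characterization of recursion: an internal element has a
#' recursive synthesis formula exactly when the digraph contains a closed
#' walk through it (a strongly connected component of size >= 2, or a
#' self-loop).
#'
#' @param g a synthesis digraph from [build_synthesis_digraph()].
#' @return Sorted character vector of internal node names.
#' @examples
#' recursive_elements_via_cycles(build_synthesis_digraph(toy_si()))  # "a" "b"
#' @export
recursive_elements_via_cycles <- function(g) {
  internal <- igraph::V(g)$name[igraph::V(g)$set_of_origin == "Si"]
  sort(intersect(cycle_nodes(g), internal))
}

#' A shortest closed walk through an internal element
#'
#' Returns one explicit closed walk `x -> ... -> x` witnessing the
#' recursion of `x`, or `NULL` when none exists.  The walk is shortest,
#' with lexicographic tie-breaking over the successors of `x`; walks
#' reported elsewhere for the same element need not be shortest, but any
#' valid closed walk certifies recursion equally.
#'
#' @param g a synthesis digraph from [build_synthesis_digraph()].
#' @param x an internal node name (externals have in-degree 0 and cannot
#'   close a walk; passing one is an error).
#' @return Character vector of node names starting and ending at `x`, or
#'   `NULL`.
#' @examples
#' cycle_for_element(build_synthesis_digraph(pol_si()), "o")
#' # "o" "pol" "t.o" "o"
#' @export
cycle_for_element <- function(g, x) {
  if (!x %in% igraph::V(g)$name)
    stop(sprintf("unknown node %s", sQuote(x)), call. = FALSE)
  if (igraph::V(g)$set_of_origin[match(x, igraph::V(g)$name)] != "Si")
    stop(sprintf("%s is external: external elements have in-degree 0 and cannot lie on a closed walk",
                 sQuote(x)), call. = FALSE)
  succ <- setdiff(sort(unique(names(igraph::neighbors(g, x, mode = "out")))), x)
  if (x %in% names(igraph::neighbors(g, x, mode = "out")))
    return(c(x, x))  # self-loop: shortest possible closed walk
  best <- NULL
  for (s in succ) {
    sp <- suppressWarnings(igraph::shortest_paths(g, from = s, to = x,
                                                  mode = "out"))
    path <- sp$vpath[[1L]]
    if (length(path) == 0L) next
    walk <- c(x, names(path))
    if (is.null(best) || length(walk) < length(best)) best <- walk
  }
  best
}
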