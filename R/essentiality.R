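# Essentiality by recursion: the monotone operand-set fixpoint with frozen
# marking, the recursion rule (an internal element needed for its own
# synthesis is essential), the propagation rule (all operands of an
# essential element are essential), minimal-SI reduction and the
# interactome-size estimator.

#' Complete operand sets for every internal element, by fixpoint iteration
#'
#' Starts each internal element's set at the operands of its own row and
#' repeatedly merges, into each set, the current sets of its internal
#' members, until no set changes.  Sets only grow and are bounded by the
#' element set `S`, so the iteration terminates in at most `|S|` rounds.
#'
#' Elements found to contain themselves are marked *frozen* (detected
#' recursive) the first time this is observed; the order of detection is
#' reported.  Merging continues through frozen members: a set frozen early
#' may still be incomplete at that moment, and consumers of it must keep
#' receiving its later additions for every set to reach the true complete
#' operand set.  Termination never depends on freezing -- it follows from
#' monotonicity alone (see the methods vignette for the degenerate case
#' that motivates this).
#'
#' @param si a valid `synthesis_interactome`.
#' @return Named list mapping each internal element to its complete operand
#'   set (sorted character vectors), with attribute `frozen_order`: a
#'   `data.frame` with columns `iteration` (0 = detected at
#'   initialization) and `element`.
#' @examples
#' fixpoint_operand_sets(toy_si())[["g"]]  # "e" "f" "h"
#' @export
fixpoint_operand_sets <- function(si) {
  assert_valid_si(si)
  rows <- si_rows(si)
  internal <- rows$product
  k <- length(internal)
  current <- lapply(seq_len(k), function(i)
    unique(c(rows$operand_a[i], rows$operand_b[i])))
  names(current) <- internal
  frozen <- logical(k)
  names(frozen) <- internal
  frozen_order <- list()
  iteration <- 0L

  update_frozen <- function() {
    for (i in seq_len(k)) {
      if (!frozen[i] && internal[i] %in% current[[i]]) {
        frozen[i] <<- TRUE
        frozen_order[[length(frozen_order) + 1L]] <<- data.frame(
          iteration = iteration, element = internal[i],
          stringsAsFactors = FALSE)
      }
    }
  }

  update_frozen()
  repeat {
    new <- current
    for (i in seq_len(k)) {
      members <- current[[i]]
      pull <- intersect(members, internal)
      if (length(pull) > 0L)
        new[[i]] <- unique(c(members, unlist(current[pull], use.names = FALSE)))
    }
    stable <- all(vapply(seq_len(k), function(i)
      setequal(new[[i]], current[[i]]), logical(1)))
    current <- new
    iteration <- iteration + 1L
    update_frozen()
    if (stable) break
  }

  out <- lapply(current, sort)
  attr(out, "frozen_order") <- if (length(frozen_order) > 0L)
    do.call(rbind, frozen_order) else
    data.frame(iteration = integer(), element = character(),
               stringsAsFactors = FALSE)
  out
}

#' Is an internal element recursive?
#'
#' An internal element is recursive when it belongs to its own complete
#' operand set: it is needed, at some depth, for its own synthesis.
#' Recursion is defined only for internal elements.
#'
#' @param si a valid `synthesis_interactome`.
#' @param x an internal element name.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_recursive(toy_si(), "a")  # TRUE
#' is_recursive(toy_si(), "i")  # FALSE
#' @export
is_recursive <- function(si, x) {
  part <- element_partition(si)
  if (!x %in% part$S_i)
    stop(sprintf("recursion is defined only for internal elements; %s is not a product",
                 sQuote(x)), call. = FALSE)
  x %in% complete_operand_set(si, x)$complete
}

#' Recursive (hence essential) internal elements
#'
#' The set of internal elements that are members of their own complete
#' operand set.  By the recursion rule these elements cannot be synthesized
#' de novo in their own absence and are therefore essential.
#'
#' @param si a valid `synthesis_interactome`.
#' @return Sorted character vector (possibly empty).
#' @examples
#' essential_internal(toy_si())  # "a" "b"
#' @export
essential_internal <- function(si) {
  sets <- fixpoint_operand_sets(si)
  sort(names(sets)[vapply(names(sets), function(x) x %in% sets[[x]],
                          logical(1))])
}

#' Full essentiality report
#'
#' Combines the recursion rule with the propagation rule: every operand in
#' the complete operand set of a recursive element is itself essential.
#' The essential set is the union of the complete operand sets of all
#' recursive elements; it may be empty (no recursion anywhere in the SI)
#' or cover all of `S`.  Elements of the genome-replication machinery are
#' outside the scope of these two rules -- their essentiality only becomes
#' observable at replication and must be established experimentally.
#'
#' @param si a valid `synthesis_interactome`.
#' @return An object of class `essentiality_report`: a list with
#'   `recursive_elements`, `essential_set`, `operand_sets` (named list,
#'   one complete operand set per internal element), `frozen_order`
#'   (detection order of recursive elements) and `note` (the
#'   replication-machinery caveat).
#' @examples
#' essential_set(toy_si())$essential_set  # "a" "b" "c" "d"
#' @export
essential_set <- function(si) {
  sets <- fixpoint_operand_sets(si)
  recursive <- sort(names(sets)[vapply(names(sets), function(x)
    x %in% sets[[x]], logical(1))])
  ess <- if (length(recursive) > 0L)
    sort(unique(unlist(sets[recursive], use.names = FALSE))) else character(0)
  structure(list(
    recursive_elements = recursive,
    essential_set = ess,
    operand_sets = sets[order(names(sets))],
    frozen_order = attr(sets, "frozen_order"),
    note = paste("Genome-replication machinery is not classified here:",
                 "its essentiality is experimental, not algorithmic.")),
    class = "essentiality_report")
}

#' @export
print.essentiality_report <- function(x, ...) {
  cat(sprintf("Essentiality report: %d internal element(s)\n",
              length(x$operand_sets)))
  cat(sprintf("  recursive (essential by recursion): {%s}\n",
              paste(x$recursive_elements, collapse = ",")))
  cat(sprintf("  essential set E: {%s}\n", paste(x$essential_set, collapse = ",")))
  cat(" ", x$note, "\n")
  invisible(x)
}

#' Tabulate an essentiality report
#'
#' One row per element of the interactome, suitable for TSV export.
#'
#' @param x an `essentiality_report`.
#' @param si the `synthesis_interactome` the report was computed from.
#' @param ... unused.
#' @return `data.frame` with columns `element`, `in_Si`, `recursive`,
#'   `essential`, `operand_set_size` (`NA` for external elements, which
#'   have no formula).
#' @export
as.data.frame.essentiality_report <- function(x, si, ...) {
  part <- element_partition(si)
  elements <- part$S
  data.frame(
    element = elements,
    in_Si = elements %in% part$S_i,
    recursive = elements %in% x$recursive_elements,
    essential = elements %in% x$essential_set,
    operand_set_size = vapply(elements, function(e)
      if (e %in% names(x$operand_sets)) length(x$operand_sets[[e]])
      else NA_integer_, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Reduce an interactome to its essential core
#'
#' Keeps exactly the rows whose product is essential; rows involved only in
#' the synthesis of non-essential elements are deleted.  The surviving SI
#' is well-formed and yields the same essential set as the original.
#'
#' @param si a valid `synthesis_interactome`.
#' @return A `synthesis_interactome`, or `NULL` when no row survives
#'   (the essential set is empty).
#' @examples
#' si_size(minimal_si(toy_si()))  # 2
#' @export
minimal_si <- function(si) {
  report <- essential_set(si)
  keep <- which(si_rows(si)$product %in% report$essential_set)
  if (length(keep) == 0L) return(NULL)
  subset_si(si, keep)
}

#' Estimate the minimum number of binary operators for a complete SI
#'
#' A linear extrapolation from an integrated interactome in which the ratio
#' of binary operators to genes is close to 3: the minimum number of
#' operators needed to describe the synthesis of all elements of a species
#' is estimated as three times its gene count.  The estimate is coarse and
#' likely an underestimate for large genomes.
#'
#' @param n_genes non-negative gene count.
#' @return Integer estimate `3 * n_genes`.
#' @examples
#' estimate_min_operators(4685)  # 14055 (E. coli scale)
#' @export
estimate_min_operators <- function(n_genes) {
  stopifnot(length(n_genes) == 1L, is.finite(n_genes))
  if (n_genes < 0) stop("n_genes must be non-negative", call. = FALSE)
  as.integer(round(3 * n_genes))
}
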