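# Core data model: synthesis interactomes as tables of commutative binary
# operators <operand_a, operand_b> => product.

SI_COLUMNS <- c("product", "operand_a", "operand_b",
                "set_a", "set_b", "type_name", "type_a", "type_b")

# Characters that would break the round-tripping of expression strings.
BAD_NAME_PATTERN <- "[<>,〈〉〈〉[:space:]]"

#' Construct a synthesis interactome
#'
#' A synthesis interactome (SI) is a table with one row per internally
#' synthesized element: the element (`product`) and the two elements whose
#' binding yields it (`operand_a`, `operand_b`).  The binding operation is
#' commutative, so `<a,b>` and `<b,a>` denote the same operator.  Optional
#' annotations record, per operand, the set the element belongs to (`"Si"`
#' for internally synthesized, `"Se"` for external, `"G"` for genomic) and
#' free-text element types.
#'
#' Element names are case-sensitive tokens; they may not be empty or contain
#' whitespace, `<`, `>` or `,` (nor their angle-bracket Unicode variants),
#' so that expression strings round-trip unambiguously.
#'
#' The constructor enforces name syntax only; structural rules (distinct
#' products, distinct commutative operators) are checked by
#' [validate_si()], which most algorithms call before running.
#'
#' @param product character vector of synthesized element names (one per row).
#' @param operand_a,operand_b character vectors of operand names.
#' @param set_a,set_b optional per-operand set labels (`"Si"`, `"Se"`, `"G"`).
#' @param type_name,type_a,type_b optional free-text type labels.
#'
#' @return An object of class `synthesis_interactome`.
#' @examples
#' si <- si_table(product   = c("a", "b", "f", "g", "i"),
#'                operand_a = c("b", "a", "e", "f", "a"),
#'                operand_b = c("c", "d", "h", "f", "b"))
#' validate_si(si)$is_valid
#' @export
si_table <- function(product, operand_a, operand_b,
                     set_a = NA_character_, set_b = NA_character_,
                     type_name = NA_character_, type_a = NA_character_,
                     type_b = NA_character_) {
  product   <- as.character(product)
  operand_a <- as.character(operand_a)
  operand_b <- as.character(operand_b)
  k <- length(product)
  if (k == 0L) stop("empty interactome", call. = FALSE)
  if (length(operand_a) != k || length(operand_b) != k)
    stop("product, operand_a and operand_b must have equal length", call. = FALSE)
  rows <- data.frame(
    product   = product,
    operand_a = operand_a,
    operand_b = operand_b,
    set_a     = rep_len(as.character(set_a), k),
    set_b     = rep_len(as.character(set_b), k),
    type_name = rep_len(as.character(type_name), k),
    type_a    = rep_len(as.character(type_a), k),
    type_b    = rep_len(as.character(type_b), k),
    stringsAsFactors = FALSE
  )
  bad <- bad_names(c(rows$product, rows$operand_a, rows$operand_b))
  if (length(bad) > 0L)
    stop("invalid element name(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  structure(list(rows = rows), class = "synthesis_interactome")
}

bad_names <- function(x) {
  unique(x[is.na(x) | !nzchar(x) | grepl(BAD_NAME_PATTERN, x)])
}

is_si <- function(x) inherits(x, "synthesis_interactome")

#' Rows of a synthesis interactome
#'
#' @param si a `synthesis_interactome`.
#' @return The underlying `data.frame`, one row per binary operator.
#' @export
si_rows <- function(si) {
  stopifnot(is_si(si))
  si$rows
}

#' @export
as.data.frame.synthesis_interactome <- function(x, ...) x$rows

#' Number of operator rows of an interactome
#' @param si a `synthesis_interactome`.
#' @return integer row count `k` (equals the number of internal elements).
#' @export
si_size <- function(si) nrow(si_rows(si))

#' @export
print.synthesis_interactome <- function(x, ...) {
  rows <- si_rows(x)
  part <- element_partition(x, check = FALSE)
  cat(sprintf("Synthesis interactome: %d operator row(s), %d element(s)\n",
              nrow(rows), length(part$S_i) + length(part$S_e)))
  cat(sprintf("  internal (S_i): %d   external (S_e): %d   genomic (G): %d\n",
              length(part$S_i), length(part$S_e), length(part$G)))
  op <- sprintf("<%s,%s> => %s", rows$operand_a, rows$operand_b, rows$product)
  show <- utils::head(op, 12L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (nrow(rows) > 12L) cat(sprintf("  ... and %d more row(s)\n", nrow(rows) - 12L))
  invisible(x)
}

canonical_operator <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Validate an interactome against the well-formedness rules
#'
#' A well-formed SI must have (ii) pairwise-distinct products and (iii)
#' pairwise-distinct commutative operand pairs (`<a,b>` equals `<b,a>`).
#' Elements annotated as genomic (`"G"`) are additionally required to be
#' operand-only: the genome is treated as static, so a G element may not
#' appear as a product.  Name syntax is enforced at construction, but files
#' read through lenient paths are re-checked here.
#'
#' @param si a `synthesis_interactome`.
#' @return A list of class `si_validation` with `is_valid` (logical) and
#'   `violations`, a `data.frame` with columns `rule`
#'   (`duplicate_product`, `duplicate_operator`, `bad_name`,
#'   `genome_as_product`), `rows` (comma-separated offending row numbers)
#'   and `detail`.
#' @examples
#' validate_si(toy_si())$is_valid
#' @export
validate_si <- function(si) {
  rows <- si_rows(si)
  violations <- list()
  add <- function(rule, idx, detail) {
    violations[[length(violations) + 1L]] <<- data.frame(
      rule = rule, rows = paste(idx, collapse = ","), detail = detail,
      stringsAsFactors = FALSE)
  }

  bad <- bad_names(c(rows$product, rows$operand_a, rows$operand_b))
  for (nm in bad) {
    idx <- which(rows$product == nm | rows$operand_a == nm | rows$operand_b == nm)
    add("bad_name", idx, sprintf("invalid element name %s", sQuote(nm)))
  }

  dup_prod <- unique(rows$product[duplicated(rows$product)])
  for (nm in dup_prod) {
    idx <- which(rows$product == nm)
    add("duplicate_product", idx,
        sprintf("product %s defined by more than one row", sQuote(nm)))
  }

  ops <- canonical_operator(rows$operand_a, rows$operand_b)
  dup_op <- unique(ops[duplicated(ops)])
  for (op in dup_op) {
    idx <- which(ops == op)
    add("duplicate_operator", idx,
        sprintf("operator <%s,%s> used by more than one row",
                rows$operand_a[idx[1L]], rows$operand_b[idx[1L]]))
  }

  g <- genomic_elements(rows)
  g_prod <- intersect(g, rows$product)
  for (nm in g_prod) {
    idx <- which(rows$product == nm)
    add("genome_as_product", idx,
        sprintf("genomic element %s appears as a product", sQuote(nm)))
  }

  violations <- if (length(violations) > 0L) do.call(rbind, violations) else
    data.frame(rule = character(), rows = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(is_valid = nrow(violations) == 0L, violations = violations),
            class = "si_validation")
}

#' @export
print.si_validation <- function(x, ...) {
  if (x$is_valid) {
    cat("Well-formed synthesis interactome (no violations)\n")
  } else {
    cat(sprintf("Invalid synthesis interactome: %d violation(s)\n",
                nrow(x$violations)))
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] rows %s: %s\n", x$violations$rule[i],
                  x$violations$rows[i], x$violations$detail[i]))
  }
  invisible(x)
}

genomic_elements <- function(rows) {
  sort(unique(c(rows$operand_a[!is.na(rows$set_a) & rows$set_a == "G"],
                rows$operand_b[!is.na(rows$set_b) & rows$set_b == "G"])))
}

assert_valid_si <- function(si) {
  v <- validate_si(si)
  if (!v$is_valid)
    stop("invalid synthesis interactome: ",
         paste(v$violations$detail, collapse = "; "), call. = FALSE)
  invisible(si)
}

#' Partition the elements of an interactome
#'
#' Derives the element sets induced by the table: the internal elements
#' `S_i` (products, exactly one per row), the external elements
#' `S_e = S - S_i` (operand-only elements, for which the SI carries no
#' synthesis information) and the genomic elements `G` (the subset of
#' `S_e` annotated `"G"`).  The genomic label is semantic only -- every
#' algorithm in the package treats G members exactly like other externals.
#'
#' @param si a `synthesis_interactome`.
#' @param check validate the SI first (default `TRUE`).
#' @return A list with sorted character vectors `S_i`, `S_e`, `G` and the
#'   full element set `S`.
#' @examples
#' element_partition(toy_si())$S_i   # "a" "b" "f" "g" "i"
#' @export
element_partition <- function(si, check = TRUE) {
  if (check) assert_valid_si(si)
  rows <- si_rows(si)
  s_i <- sort(unique(rows$product))
  s   <- sort(unique(c(rows$product, rows$operand_a, rows$operand_b)))
  s_e <- setdiff(s, s_i)
  g   <- intersect(genomic_elements(rows), s_e)
  list(S_i = s_i, S_e = s_e, G = g, S = s)
}

#' Select a subset of rows as a new interactome
#'
#' Any non-empty subset of rows of a well-formed SI is itself well-formed.
#' The induced partition is recomputed: elements whose defining row is
#' dropped migrate from `S_i` to `S_e`.
#'
#' @param si a `synthesis_interactome`.
#' @param rows integer or logical row selector, or a character vector of
#'   product names to keep.
#' @return A new `synthesis_interactome`.
#' @examples
#' subset_si(toy_si(), rows = 3)   # keeps only <e,h> => f
#' @export
subset_si <- function(si, rows) {
  tab <- si_rows(si)
  if (is.character(rows)) rows <- which(tab$product %in% rows)
  if (is.logical(rows)) rows <- which(rows)
  rows <- as.integer(rows)
  if (length(rows) == 0L) stop("empty row selection", call. = FALSE)
  if (any(rows < 1L | rows > nrow(tab)))
    stop("row selector out of range", call. = FALSE)
  out <- si
  out$rows <- tab[rows, , drop = FALSE]
  rownames(out$rows) <- NULL
  out
}

#' Operands of a row's binary operator
#' @param si a `synthesis_interactome`.
#' @param x an internal element name.
#' @return Character vector of the (deduplicated) operands of `x`'s row.
#' @keywords internal
row_operands <- function(si, x) {
  rows <- si_rows(si)
  i <- match(x, rows$product)
  if (is.na(i))
    stop(sprintf("no synthesis information for element %s", sQuote(x)),
         call. = FALSE)
  unique(c(rows$operand_a[i], rows$operand_b[i]))
}
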