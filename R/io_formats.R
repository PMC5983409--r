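# Readers and writers: expression strings, the canonical tab-separated SI
# dialect, graph export and report serialization.

#' Parse an expression string into an expression tree
#'
#' Accepts the ASCII form `<a,b>` and the Unicode angle-bracket form on
#' input; output through [format_expression()] is canonical.  A bare
#' element name parses to a leaf.
#'
#' @param text a single character string.
#' @return An `si_expression`; parse errors report the failing position.
#' @examples
#' parse_expression("<<b,c>,<a,d>>")
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # normalize the Unicode angle brackets to ASCII before scanning
  text <- chartr("〈〉〈〉", "<><>", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  pos <- 1L
  n <- length(chars)
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg),
                             call. = FALSE)
  peek <- function() if (pos <= n) chars[pos] else NA_character_
  parse_one <- function() {
    if (is.na(peek())) fail("unexpected end of input")
    if (peek() == "<") {
      pos <<- pos + 1L
      left <- parse_one()
      if (is.na(peek()) || peek() != ",") fail("expected ','")
      pos <<- pos + 1L
      right <- parse_one()
      if (is.na(peek()) || peek() != ">") fail("expected '>' (unbalanced brackets)")
      pos <<- pos + 1L
      expr_node(left, right)
    } else {
      start <- pos
      while (!is.na(peek()) && !peek() %in% c("<", ">", ",")) pos <<- pos + 1L
      name <- trimws(paste(chars[start:(pos - 1L)], collapse = ""))
      if (pos == start || !nzchar(name)) fail("empty operand")
      expr_leaf(name)
    }
  }
  out <- parse_one()
  if (!is.na(peek())) fail(sprintf("stray character '%s' after expression", peek()))
  out
}

#' Serialize an expression tree
#'
#' @param expr an `si_expression`.
#' @param style `"ascii"` (`<a,b>`, canonical) or `"unicode"` (angle
#'   brackets).
#' @return A character string; `parse_expression(format_expression(e))`
#'   reproduces `e`.
#' @examples
#' format_expression(parse_expression("〈e,h〉"))  # "<e,h>"
#' @export
format_expression <- function(expr, style = c("ascii", "unicode")) {
  style <- match.arg(style)
  br <- if (style == "ascii") c("<", ">") else c("〈", "〉")
  fmt <- function(e) {
    if (is_expr_leaf(e)) unclass(e)
    else paste0(br[1L], fmt(e[[1L]]), ",", fmt(e[[2L]]), br[2L])
  }
  fmt(expr)
}

#' Read a synthesis interactome from a tab-separated table
#'
#' The canonical dialect is UTF-8, tab-delimited, `#` comments, with
#' header columns `name`, `operand_a`, `operand_b` and optional annotation
#' columns `set_a`, `set_b`, `type_name`, `type_a`, `type_b`.  A dialect
#' with a single `binary_operator` column holding `<a,b>` strings (ASCII
#' or Unicode brackets) is also accepted; the two operand encodings are
#' mutually exclusive.  Column names are matched case-insensitively and
#' `product` is accepted as a synonym for `name`.
#'
#' @param path file path.
#' @param validate stop on well-formedness violations (default `TRUE`);
#'   violations are reported with their row numbers.
#' @return A `synthesis_interactome`.
#' @export
read_si_table <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8",
                           check.names = FALSE)
  names(tab) <- tolower(trimws(names(tab)))
  if ("product" %in% names(tab) && !"name" %in% names(tab))
    names(tab)[names(tab) == "product"] <- "name"
  if (!"name" %in% names(tab))
    stop("SI table must have a 'name' (or 'product') column", call. = FALSE)

  has_ops  <- all(c("operand_a", "operand_b") %in% names(tab))
  has_bop  <- "binary_operator" %in% names(tab)
  if (has_ops && has_bop)
    stop("SI table may have either operand columns or a 'binary_operator' column, not both",
         call. = FALSE)
  if (!has_ops && !has_bop)
    stop("SI table needs 'operand_a'/'operand_b' columns or a 'binary_operator' column",
         call. = FALSE)

  if (has_bop) {
    ops <- lapply(seq_along(tab$binary_operator), function(i) {
      e <- tryCatch(parse_expression(tab$binary_operator[i]),
                    error = function(err)
                      stop(sprintf("row %d: malformed operator string: %s",
                                   i, conditionMessage(err)), call. = FALSE))
      if (is_expr_leaf(e) || !is_expr_leaf(e[[1L]]) || !is_expr_leaf(e[[2L]]))
        stop(sprintf("row %d: operator must be a flat pair '<a,b>'", i),
             call. = FALSE)
      c(unclass(e[[1L]]), unclass(e[[2L]]))
    })
    tab$operand_a <- vapply(ops, `[`, character(1), 1L)
    tab$operand_b <- vapply(ops, `[`, character(1), 2L)
  }

  get <- function(col) if (col %in% names(tab)) {
    v <- trimws(tab[[col]])
    ifelse(nzchar(v), v, NA_character_)
  } else NA_character_

  si <- si_table(product   = trimws(tab$name),
                 operand_a = trimws(tab$operand_a),
                 operand_b = trimws(tab$operand_b),
                 set_a = get("set_a"), set_b = get("set_b"),
                 type_name = get("type_name"),
                 type_a = get("type_a"), type_b = get("type_b"))
  if (validate) {
    v <- validate_si(si)
    if (!v$is_valid)
      stop(sprintf("invalid SI in %s: %s", path,
                   paste(sprintf("[%s] rows %s: %s", v$violations$rule,
                                 v$violations$rows, v$violations$detail),
                         collapse = "; ")), call. = FALSE)
  }
  si
}

#' Write a synthesis interactome in the canonical dialect
#'
#' Tab-separated UTF-8 with header `name operand_a operand_b set_a set_b
#' type_name type_a type_b`; missing annotations are written as empty
#' fields.  Reading the file back reproduces the SI exactly.
#'
#' @param si a `synthesis_interactome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_si_table <- function(si, path) {
  rows <- si_rows(si)
  out <- data.frame(name = rows$product,
                    operand_a = rows$operand_a,
                    operand_b = rows$operand_b,
                    set_a = rows$set_a, set_b = rows$set_b,
                    type_name = rows$type_name,
                    type_a = rows$type_a, type_b = rows$type_b,
                    stringsAsFactors = FALSE)
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- ""
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a graph to GraphML, DOT or an edge-list TSV
#'
#' GraphML and DOT are written through igraph and carry the node
#' attributes (`set_of_origin`, `type`, `recursive`, `essential`) present
#' on the graph.  The edge-list TSV has columns `source`, `target`,
#' `role` and `multiplicity` (`role` is `"synthesis"` for directed
#' graphs, `"binding"` for undirected ones).
#'
#' @param g an `igraph` graph from [build_synthesis_digraph()] or
#'   [build_binding_graph()].
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot", "edgelist")) {
  if (!inherits(g, "igraph")) stop("g must be an igraph graph", call. = FALSE)
  format <- match.arg(format)
  if (format %in% c("graphml", "dot")) {
    gg <- g
    # DOT output chokes on NA values and downgrades logicals noisily;
    # normalize the attributes before writing
    if (!is.null(igraph::V(gg)$type))
      igraph::V(gg)$type <- ifelse(is.na(igraph::V(gg)$type), "",
                                   igraph::V(gg)$type)
    if (format == "dot") {
      for (at in igraph::vertex_attr_names(gg)) {
        v <- igraph::vertex_attr(gg, at)
        if (is.logical(v)) gg <- igraph::set_vertex_attr(gg, at,
                                                         value = as.integer(v))
      }
    }
    igraph::write_graph(gg, file = path, format = format)
  } else {
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    mult <- igraph::E(g)$multiplicity
    if (is.null(mult)) mult <- rep(1L, nrow(ends))
    out <- data.frame(source = ends[, 1L], target = ends[, 2L],
                      role = if (igraph::is_directed(g)) "synthesis" else "binding",
                      multiplicity = mult, stringsAsFactors = FALSE)
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write an essentiality report as TSV or JSON
#'
#' The TSV has one row per element (`element`, `in_Si`, `recursive`,
#' `essential`, `operand_set_size`); the JSON additionally carries the
#' complete operand sets and the freeze order.
#'
#' @param report an `essentiality_report` from [essential_set()].
#' @param si the interactome the report was computed from.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_essentiality_report <- function(report, si, path,
                                      format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- as.data.frame(report, si)
  if (format == "tsv") {
    utils::write.table(tab, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    payload <- list(
      recursive_elements = report$recursive_elements,
      essential_set = report$essential_set,
      operand_sets = report$operand_sets,
      frozen_order = report$frozen_order,
      elements = tab,
      note = report$note)
    jsonlite::write_json(payload, path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}
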