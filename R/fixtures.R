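# Built-in interactomes and a seeded random-SI generator with planted
# cycles, so every algorithm is testable without external data.

#' A five-row worked-example interactome
#'
#' A small SI with one mutually recursive pair (`a` and `b` each need the
#' other), one element with a closed formula (`f`, from externals only),
#' one element built from a repeated operand (`g` from `<f,f>`) and one
#' non-recursive product of the recursive pair (`i`).
#'
#' @return A `synthesis_interactome` with
#'   `S_i = {a,b,f,g,i}` and `S_e = {c,d,e,h}`.
#' @examples
#' essential_internal(toy_si())  # "a" "b"
#' @export
toy_si <- function() {
  si_table(product   = c("a", "b", "f", "g", "i"),
           operand_a = c("b", "a", "e", "f", "a"),
           operand_b = c("c", "d", "h", "f", "b"))
}

#' The RNA polymerase synthesis interactome
#'
#' Twelve rows describing the synthesis of a simplified bacterial RNA
#' polymerase (`pol` = 2-alpha beta beta-prime omega; Greek subunit names
#' are transliterated: `a`, `b`, `bp`, `o`): subunit complexes assemble
#' stepwise into `pol`, each subunit is translated by the ribosome (`rib`)
#' from its transcript, and each transcript is transcribed from its gene
#' by `pol` itself.  That last dependency makes every internal element
#' recursive -- to synthesize `pol` you must already have `pol`.
#'
#' Annotations mark the four genes (`g.a`, `g.b`, `g.bp`, `g.o`) as
#' genomic and the ribosome as the single non-genomic external element:
#' this SI is "rooted" at the ribosome.
#'
#' @return A 12-row `synthesis_interactome`.
#' @examples
#' length(essential_internal(pol_si()))  # 12
#' @export
pol_si <- function() {
  si_table(
    product   = c("bpb", "2a", "ba", "pol",
                  "t.bp", "t.b", "t.a", "t.o",
                  "bp", "b", "a", "o"),
    operand_a = c("bp", "a", "bpb", "o",
                  "g.bp", "g.b", "g.a", "g.o",
                  "t.bp", "t.b", "t.a", "t.o"),
    operand_b = c("b", "a", "2a", "ba",
                  "pol", "pol", "pol", "pol",
                  "rib", "rib", "rib", "rib"),
    set_a     = c("Si", "Si", "Si", "Si", "G", "G", "G", "G",
                  "Si", "Si", "Si", "Si"),
    set_b     = c("Si", "Si", "Si", "Si", "Si", "Si", "Si", "Si",
                  "Se", "Se", "Se", "Se"),
    type_name = c("protein complex", "protein complex", "protein complex",
                  "enzyme", "transcript", "transcript", "transcript",
                  "transcript", "peptide", "peptide", "peptide", "peptide"),
    type_a    = c("peptide", "peptide", "protein complex", "peptide",
                  "gene", "gene", "gene", "gene",
                  "transcript", "transcript", "transcript", "transcript"),
    type_b    = c("peptide", "peptide", "protein complex", "protein complex",
                  "enzyme", "enzyme", "enzyme", "enzyme",
                  "ribosome", "ribosome", "ribosome", "ribosome"))
}

#' The partial RNA polymerase interactome (transcription rows removed)
#'
#' [pol_si()] with the four transcript-defining rows deleted.  The
#' transcripts become external, every dependency chain opens up, and no
#' internal element is recursive any more: the same molecules, described
#' with less synthesis information, can no longer be recognized as
#' essential.
#'
#' @return An 8-row `synthesis_interactome`.
#' @examples
#' essential_internal(partial_pol_si())  # character(0)
#' @export
partial_pol_si <- function() {
  full <- pol_si()
  keep <- which(!startsWith(si_rows(full)$product, "t."))
  subset_si(full, keep)
}

#' Generate a random interactome with planted cycles
#'
#' Builds a well-formed SI whose ground-truth recursive set is known by
#' construction.  Planted cycles use minimal wiring: cycle member
#' `x_(j+1)`'s row takes `x_j` as one operand (and the last member closes
#' back to the first), with the second operand drawn from the externals;
#' a cycle of length 1 yields a directly self-recursive row.  All other
#' internal elements form a DAG layer: their operands are drawn only from
#' earlier-indexed DAG internals and externals, so they can neither lie on
#' nor feed into a cycle, and are provably non-recursive.
#'
#' Elements are named `iNNN` (internal), `eNNN` (external) and `gNNN`
#' (genomic, annotated `"G"` and treated as external).  The same seed
#' always yields the identical interactome.
#'
#' @param n_internal number of internal elements (`>= 1`); the first
#'   `sum(planted_cycle_sizes)` of them form the cycles.
#' @param n_external number of external elements (`>= 1`).
#' @param planted_cycle_sizes integer vector of cycle lengths; their sum
#'   may not exceed `n_internal`.
#' @param n_genomic number of genomic elements added to the external pool.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A `synthesis_interactome`.
#' @examples
#' si <- random_si(5, 3, planted_cycle_sizes = 3, seed = 7)
#' essential_internal(si)  # the three planted cycle members
#' @export
random_si <- function(n_internal, n_external, planted_cycle_sizes = integer(0),
                      n_genomic = 0, seed = 1) {
  n_internal <- as.integer(n_internal)
  n_external <- as.integer(n_external)
  n_genomic  <- as.integer(n_genomic)
  planted_cycle_sizes <- as.integer(planted_cycle_sizes)
  if (n_internal < 1L) stop("n_internal must be >= 1", call. = FALSE)
  if (n_external < 1L) stop("n_external must be >= 1", call. = FALSE)
  if (n_genomic < 0L) stop("n_genomic must be >= 0", call. = FALSE)
  if (any(planted_cycle_sizes < 1L))
    stop("planted cycle sizes must be >= 1", call. = FALSE)
  n_cyc <- sum(planted_cycle_sizes)
  if (n_cyc > n_internal)
    stop("sum of planted cycle sizes exceeds n_internal", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  internal <- sprintf("i%03d", seq_len(n_internal))
  external <- sprintf("e%03d", seq_len(n_external))
  genomic  <- if (n_genomic > 0L) sprintf("g%03d", seq_len(n_genomic)) else character(0)
  ext_pool <- c(external, genomic)

  used_ops <- character(0)
  product <- operand_a <- operand_b <- character(0)
  add_row <- function(p, a, b) {
    key <- canonical_operator(a, b)
    if (key %in% used_ops) return(FALSE)
    used_ops <<- c(used_ops, key)
    product   <<- c(product, p)
    operand_a <<- c(operand_a, a)
    operand_b <<- c(operand_b, b)
    TRUE
  }
  draw <- function(pool) pool[sample.int(length(pool), 1L)]

  idx <- 0L
  for (m in planted_cycle_sizes) {
    members <- internal[idx + seq_len(m)]
    idx <- idx + m
    for (j in seq_len(m)) {
      prev <- members[if (j == 1L) m else j - 1L]
      placed <- FALSE
      for (try in seq_len(100L)) {
        if (add_row(members[j], prev, draw(ext_pool))) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place a unique operator for a cycle row; increase n_external",
             call. = FALSE)
    }
  }

  dag <- internal[idx + seq_len(n_internal - n_cyc)]
  for (j in seq_along(dag)) {
    pool <- c(dag[seq_len(j - 1L)], ext_pool)
    placed <- FALSE
    for (try in seq_len(100L)) {
      if (add_row(dag[j], draw(pool), draw(pool))) { placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place a unique operator for a DAG row; increase n_external",
           call. = FALSE)
  }

  set_label <- function(x) ifelse(x %in% internal, "Si",
                                  ifelse(x %in% genomic, "G", "Se"))
  si_table(product = product, operand_a = operand_a, operand_b = operand_b,
           set_a = set_label(operand_a), set_b = set_label(operand_b))
}
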