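# Shared helpers: independent oracles and case generators.

# Brute-force ancestor set by repeated relaxation over the raw edge list;
# independent of both the fixpoint algebra and the igraph-backed module.
brute_ancestors <- function(si, x) {
  rows <- si_rows(si)
  edges <- unique(rbind(
    data.frame(from = rows$operand_a, to = rows$product, stringsAsFactors = FALSE),
    data.frame(from = rows$operand_b, to = rows$product, stringsAsFactors = FALSE)))
  anc <- character(0)
  frontier <- x
  repeat {
    preds <- unique(edges$from[edges$to %in% frontier])
    new <- setdiff(preds, anc)
    if (length(new) == 0L) break
    anc <- union(anc, new)
    frontier <- new
  }
  sort(anc)
}

# a walk is valid when every consecutive pair is a directed edge
expect_valid_closed_walk <- function(g, walk, x) {
  expect_gte(length(walk), 2L)
  expect_identical(walk[1L], x)
  expect_identical(walk[length(walk)], x)
  for (i in seq_len(length(walk) - 1L)) {
    expect_true(igraph::are_adjacent(g, walk[i], walk[i + 1L]),
                label = sprintf("edge %s -> %s exists", walk[i], walk[i + 1L]))
  }
}

# deterministic sweep of generator configurations for property tests
random_case_configs <- function(n, seed_offset = 0L) {
  lapply(seq_len(n), function(i) {
    set.seed(10000L + seed_offset + i)
    n_int <- sample(2:10, 1L)
    n_ext <- sample(1:6, 1L)
    sizes <- integer(0)
    budget <- n_int
    while (budget >= 1L && runif(1) < 0.6) {
      s <- sample(seq_len(min(4L, budget)), 1L)
      sizes <- c(sizes, s)
      budget <- budget - s
    }
    list(n_internal = n_int, n_external = n_ext,
         planted_cycle_sizes = sizes,
         n_genomic = sample(0:2, 1L), seed = 555L + seed_offset + i)
  })
}

random_expression_string <- function(depth, pool = letters[1:6]) {
  if (depth <= 0L || runif(1) < 0.3)
    return(sample(pool, 1L))
  paste0("<", random_expression_string(depth - 1L, pool), ",",
         random_expression_string(depth - 1L, pool), ">")
}
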