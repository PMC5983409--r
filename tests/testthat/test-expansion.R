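toy <- toy_si()

test_that("level-0 formulas reproduce each row's operator", {
  expect_identical(format_expression(base_formula(toy, "i")), "<a,b>")
  expect_identical(format_expression(base_formula(toy, "f")), "<e,h>")
  expect_error(base_formula(toy, "c"), "no synthesis information")
})

test_that("simultaneous substitution reproduces the worked expansion traces", {
  # element i: both operands re-substituted at every level
  expect_identical(format_expression(expand_to_level(toy, "i", 1)),
                   "<<b,c>,<a,d>>")
  expect_identical(format_expression(expand_to_level(toy, "i", 2)),
                   "<<<a,d>,c>,<<b,c>,d>>")
  # element a: the recursive pair a/b alternates through the levels
  expect_identical(format_expression(expand_to_level(toy, "a", 0)), "<b,c>")
  expect_identical(format_expression(expand_to_level(toy, "a", 1)), "<<a,d>,c>")
  expect_identical(format_expression(expand_to_level(toy, "a", 2)),
                   "<<<b,c>,d>,c>")
  expect_identical(format_expression(expand_to_level(toy, "a", 3)),
                   "<<<<a,d>,c>,d>,c>")
  # element f: already closed, expansion is a fixed point
  expect_identical(format_expression(expand_to_level(toy, "f", 5)), "<e,h>")
})

test_that("the size cap stops unbounded recursive expansions with a level report", {
  expect_error(expand_to_level(toy, "a", 50, size_cap = 10),
               "size cap.*at level")
})

test_that("operand sets collapse duplicates and match the printed traces", {
  expect_identical(formula_operands(parse_expression("<<a,d>,c>")),
                   c("a", "c", "d"))
  expect_identical(formula_operands(parse_expression("<a,a>")), "a")
  expect_identical(formula_operands(expand_to_level(toy, "i", 2)),
                   c("a", "b", "c", "d"))
})

test_that("cumulative operand sets are the monotone union over levels", {
  expect_identical(cumulative_operand_set(toy, "a", 0), c("b", "c"))
  expect_identical(cumulative_operand_set(toy, "a", 1), c("a", "b", "c", "d"))
  expect_identical(cumulative_operand_set(toy, "f", 3), c("e", "h"))
})

test_that("complete operand sets converge with a recorded trace", {
  tr_i <- complete_operand_set(toy, "i")
  expect_identical(tr_i$complete, c("a", "b", "c", "d"))
  expect_identical(tr_i$converged_at, 1L)

  tr_f <- complete_operand_set(toy, "f")
  expect_identical(tr_f$complete, c("e", "h"))
  expect_identical(tr_f$converged_at, 0L)

  # derived by the independent reachability oracle
  expect_identical(complete_operand_set(toy, "g")$complete,
                   brute_ancestors(toy, "g"))
  expect_identical(complete_operand_set(toy, "g")$complete, c("e", "f", "h"))
})

test_that("closed expanded formulas exist exactly for acyclic ancestries", {
  expect_identical(format_expression(closed_expanded_formula(toy, "f")), "<e,h>")
  expect_identical(format_expression(closed_expanded_formula(toy, "g")),
                   "<<e,h>,<e,h>>")
  expect_null(closed_expanded_formula(toy, "a"))
  expect_null(closed_expanded_formula(toy, "i"))  # i sits on top of the a/b cycle
  expect_error(closed_expanded_formula(toy, "e"), "no synthesis information")
})

test_that("symbol counting supports token and leaf conventions", {
  e <- parse_expression("<a,b>")
  expect_identical(symbol_count(e, "tokens"), 5L)
  expect_identical(symbol_count(e, "leaves"), 2L)
  expect_identical(symbol_count(expand_to_level(toy, "i", 1), "tokens"), 13L)
  expect_error(symbol_count(e, "runes"))
})

test_that("token growth of the open formula for i is linear: 5 + 8r", {
  for (r in 0:10)
    expect_identical(symbol_count(expand_to_level(toy, "i", r), "tokens"),
                     5L + 8L * r)
})

test_that("cumulative sets are monotone and converge below |S| on random SIs", {
  for (cfg in random_case_configs(15, seed_offset = 100L)) {
    si <- do.call(random_si, cfg)
    part <- element_partition(si)
    for (x in part$S_i) {
      tr <- complete_operand_set(si, x)
      expect_lt(tr$converged_at, length(part$S))
      cums <- lapply(tr$levels, `[[`, "cumulative_operands")
      for (j in seq_len(length(cums) - 1L))
        expect_true(all(cums[[j]] %in% cums[[j + 1L]]))
      expect_true(all(tr$complete %in% part$S))
    }
  }
})
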