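toy <- toy_si()
pol <- pol_si()

test_that("the fixpoint yields the complete operand sets of the worked example", {
  sets <- fixpoint_operand_sets(toy)
  expect_identical(sets[["a"]], c("a", "b", "c", "d"))
  expect_identical(sets[["b"]], c("a", "b", "c", "d"))
  expect_identical(sets[["i"]], c("a", "b", "c", "d"))
  expect_identical(sets[["f"]], c("e", "h"))
  expect_identical(sets[["g"]], c("e", "f", "h"))
  fo <- attr(sets, "frozen_order")
  expect_setequal(fo$element, c("a", "b"))

  single <- si_table("f", "e", "h")
  s1 <- fixpoint_operand_sets(single)
  expect_identical(s1[["f"]], c("e", "h"))
  expect_identical(nrow(attr(s1, "frozen_order")), 0L)
})

test_that("in the polymerase SI every internal element needs all 17 elements", {
  sets <- fixpoint_operand_sets(pol)
  all17 <- element_partition(pol)$S
  expect_length(all17, 17L)
  for (x in names(sets)) expect_identical(sets[[x]], all17)
})

test_that("a set frozen early still propagates its later additions", {
  # a and b freeze while c has only seen a's partial set; c's complete set
  # must nevertheless pick up y through the continued merge
  si <- si_table(product = c("a", "b", "c"),
                 operand_a = c("b", "a", "a"),
                 operand_b = c("x", "y", "z"))
  sets <- fixpoint_operand_sets(si)
  expect_identical(sets[["c"]], sort(c("a", "b", "x", "y", "z")))
  expect_identical(sets[["c"]], brute_ancestors(si, "c"))
})

test_that("recursion is membership in one's own complete operand set", {
  expect_true(is_recursive(toy, "a"))
  expect_false(is_recursive(toy, "i"))
  expect_true(is_recursive(pol, "pol"))
  expect_error(is_recursive(toy, "c"), "internal")
})

test_that("recursive internal elements match the worked examples", {
  expect_length(essential_internal(pol), 12L)
  expect_identical(essential_internal(partial_pol_si()), character(0))
  expect_identical(essential_internal(toy), c("a", "b"))
})

test_that("the essential set is the union of complete sets over recursive elements", {
  rep_toy <- essential_set(toy)
  expect_identical(rep_toy$recursive_elements, c("a", "b"))
  expect_identical(rep_toy$essential_set, c("a", "b", "c", "d"))

  rep_pol <- essential_set(pol)
  expect_identical(rep_pol$essential_set, element_partition(pol)$S)

  dag <- subset_si(toy, 3)  # <e,h> => f alone: no recursion anywhere
  expect_identical(essential_set(dag)$essential_set, character(0))

  # report invariants
  expect_true(all(rep_toy$recursive_elements %in% rep_toy$essential_set))
  expect_true(all(rep_toy$recursive_elements %in% names(rep_toy$operand_sets)))
})

test_that("report tabulation lists every element with its classification", {
  tab <- as.data.frame(essential_set(toy), toy)
  expect_identical(tab$element, element_partition(toy)$S)
  expect_identical(tab$recursive, tab$element %in% c("a", "b"))
  expect_identical(tab$essential, tab$element %in% c("a", "b", "c", "d"))
  expect_true(all(is.na(tab$operand_set_size[!tab$in_Si])))
})

test_that("minimal reduction keeps exactly the essential rows", {
  m <- minimal_si(toy)
  expect_identical(si_size(m), 2L)
  expect_setequal(si_rows(m)$product, c("a", "b"))

  m_pol <- minimal_si(pol)
  expect_identical(si_rows(m_pol), si_rows(pol))

  expect_null(minimal_si(subset_si(toy, 3)))

  # idempotence: reducing again changes nothing
  expect_identical(essential_set(m)$essential_set,
                   essential_set(toy)$essential_set)
  expect_identical(si_rows(minimal_si(m)), si_rows(m))
})

test_that("deleting rows from the polymerase SI only shrinks the recursive set", {
  full <- essential_internal(pol)
  expect_length(full, 12L)
  expect_length(essential_internal(partial_pol_si()), 0L)
  dropped <- subset_si(pol, setdiff(1:12, 4))  # remove the pol-assembly row
  expect_true(all(essential_internal(dropped) %in% full))
})

test_that("the operator-count estimator is three times the gene count", {
  expect_identical(estimate_min_operators(4685), 14055L)
  expect_identical(estimate_min_operators(6294), 18882L)
  expect_identical(estimate_min_operators(0), 0L)
  expect_error(estimate_min_operators(-1), "non-negative")
})
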