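test_that("well-formedness validation accepts the worked example and flags rule breaks", {
  expect_true(validate_si(toy_si())$is_valid)

  # commutative duplicate: <b,c> and <c,b> are the same operator
  dup_op <- si_table(product = c("a", "d"),
                     operand_a = c("b", "c"),
                     operand_b = c("c", "b"))
  v <- validate_si(dup_op)
  expect_false(v$is_valid)
  expect_true("duplicate_operator" %in% v$violations$rule)
  expect_identical(v$violations$rows[v$violations$rule == "duplicate_operator"], "1,2")

  dup_prod <- si_table(product = c("a", "a"),
                       operand_a = c("b", "c"),
                       operand_b = c("c", "d"))
  v2 <- validate_si(dup_prod)
  expect_false(v2$is_valid)
  expect_true("duplicate_product" %in% v2$violations$rule)

  # a genomic element may never be a product
  g_prod <- si_table(product = c("g1", "x"),
                     operand_a = c("u", "g1"),
                     operand_b = c("v", "w"),
                     set_a = c(NA, "G"))
  v3 <- validate_si(g_prod)
  expect_false(v3$is_valid)
  expect_true("genome_as_product" %in% v3$violations$rule)
})

test_that("element names are case-sensitive tokens without metacharacters", {
  expect_error(si_table("a", "b<", "c"), "invalid element name")
  expect_error(si_table("a", "b c", "d"), "invalid element name")
  expect_error(si_table("", "b", "c"), "invalid element name")
  expect_error(si_table(character(0), character(0), character(0)),
               "empty interactome")
  si <- si_table(c("A", "a"), c("x", "y"), c("y", "z"))
  expect_true(validate_si(si)$is_valid)  # A and a are distinct
})

test_that("element partition splits products from externals and genomic annotations", {
  p <- element_partition(toy_si())
  expect_identical(p$S_i, c("a", "b", "f", "g", "i"))
  expect_identical(p$S_e, c("c", "d", "e", "h"))
  expect_identical(p$G, character(0))

  pp <- element_partition(pol_si())
  expect_length(pp$S_i, 12L)
  expect_identical(pp$G, c("g.a", "g.b", "g.bp", "g.o"))
  expect_identical(setdiff(pp$S_e, pp$G), "rib")

  single <- si_table("f", "e", "h")
  ps <- element_partition(single)
  expect_identical(ps$S_i, "f")
  expect_identical(ps$S_e, c("e", "h"))

  # conservation: |S_i| = k and S_i, S_e partition S
  expect_length(pp$S_i, si_size(pol_si()))
  expect_identical(sort(c(pp$S_i, pp$S_e)), pp$S)
  expect_length(intersect(pp$S_i, pp$S_e), 0L)
})

test_that("row subsets stay well-formed and the partition is recomputed", {
  partial <- subset_si(pol_si(), setdiff(1:12, 5:8))
  expect_identical(si_size(partial), 8L)
  p <- element_partition(partial)
  expect_true(all(c("t.a", "t.b", "t.bp", "t.o") %in% p$S_e))

  expect_identical(si_rows(subset_si(toy_si(), 1:5)), si_rows(toy_si()))

  one <- subset_si(toy_si(), 3)
  p1 <- element_partition(one)
  expect_identical(p1$S_i, "f")
  expect_identical(p1$S_e, c("e", "h"))

  expect_error(subset_si(toy_si(), integer(0)), "empty row selection")
  expect_error(subset_si(toy_si(), 99), "out of range")
})

test_that("row order is irrelevant to everything downstream", {
  set.seed(42)
  for (si in list(toy_si(), pol_si())) {
    perm <- subset_si(si, sample(seq_len(si_size(si))))
    expect_identical(element_partition(perm), element_partition(si))
    expect_identical(essential_internal(perm), essential_internal(si))
    sets_a <- fixpoint_operand_sets(si)
    sets_b <- fixpoint_operand_sets(perm)
    expect_identical(sets_b[order(names(sets_b))], sets_a[order(names(sets_a))],
                     ignore_attr = TRUE)
  }
})

test_that("every non-empty row subset of a valid SI validates", {
  for (cfg in random_case_configs(12)) {
    si <- do.call(random_si, cfg)
    set.seed(cfg$seed)
    keep <- sample(seq_len(si_size(si)),
                   size = sample(seq_len(si_size(si)), 1L))
    expect_true(validate_si(subset_si(si, keep))$is_valid)
  }
})
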