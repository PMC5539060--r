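test_that("planted order classes are recovered from the coordinates", {
  f <- make_disorder_fixture(12, double_at = c(3, 9), missing_at = 5,
                             high_b_at = 11)
  led <- classify_residues(f)
  expect_identical(led$label, attr(f, "expected"))
  expect_equal(led$n_altloc[3], 2L)
  expect_match(led$missing[5], "CB")
  expect_gt(led$max_b_sc[11], 2 * stats::median(f$atom$b))
})

test_that("the ledger is a pure function of its inputs", {
  f <- make_disorder_fixture(8, double_at = 2)
  expect_identical(classify_residues(f), classify_residues(f))
})

test_that("self-correspondence is fully concordant", {
  f <- make_disorder_fixture(10, double_at = 4, missing_at = 7)
  led <- classify_residues(f)
  cc <- correspondence(led, led, c(A = "A"))
  expect_equal(cc$agreement, 1)
  expect_equal(nrow(cc$discordant), 0)
  expect_equal(sum(cc$table), 10)
})

test_that("planted discordances appear off the diagonal, one each", {
  for (k in c(1, 3)) {
    f1 <- make_disorder_fixture(10)
    f2 <- make_disorder_fixture(10, double_at = seq_len(k) * 2)
    cc <- correspondence(classify_residues(f1), classify_residues(f2),
                         c(A = "A"))
    expect_equal(nrow(cc$discordant), k)
    expect_equal(sum(cc$table) - sum(diag(cc$table)), k)
    expect_equal(cc$agreement, (10 - k) / 10)
  }
})

test_that("mapping chains of unequal length is an error", {
  l1 <- classify_residues(make_disorder_fixture(10))
  l2 <- classify_residues(make_disorder_fixture(8, chain = "C"))
  expect_error(correspondence(l1, l2, c(A = "C")), "different residue counts")
})

test_that("activity flags intersect heterogeneity with the rank table", {
  empty <- classify_residues(make_helix("alpha", 4))[0, ]
  expect_equal(nrow(flag_activity_overlap(empty)), 0)

  # A2 is activity-ranked; plant a double conformation there only
  f <- make_disorder_fixture(21, double_at = 2)
  out <- flag_activity_overlap(classify_residues(f))
  expect_equal(nrow(out), 1)
  expect_equal(out$resno, 2)
  expect_identical(out$rank, "alpha")

  # the sequence-identical copy (chain C) maps onto chain A positions
  fc <- make_disorder_fixture(21, double_at = 2, chain = "C")
  outc <- flag_activity_overlap(classify_residues(fc))
  expect_equal(nrow(outc), 1)
  expect_identical(outc$chain, "C")
})

test_that("an ordered residue at a ranked position is not flagged", {
  f <- make_disorder_fixture(21)
  expect_equal(nrow(flag_activity_overlap(classify_residues(f))), 0)
})
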