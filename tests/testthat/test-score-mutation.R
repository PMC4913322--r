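mk_mut <- function(gene, variant_class, pos, sample_id = NULL) {
  mutation_table(data.frame(
    gene = gene,
    sample_id = if (is.null(sample_id)) sprintf("S%03d", seq_along(pos))
                else sample_id,
    variant_class = variant_class, chrom = "1", pos = pos,
    ref = "A", alt = "T", stringsAsFactors = FALSE))
}

test_that("variant classes map onto the 20/20 dichotomy", {
  expect_identical(
    classify_mutation(c("missense", "in_frame_del", "in_frame_ins")),
    rep("oncogene", 3))
  expect_identical(
    classify_mutation(c("nonsense", "splice_site", "frame_shift_ins",
                        "frame_shift_del")),
    rep("tumor_suppressor", 4))
  expect_identical(classify_mutation("other"), "other")
  expect_error(classify_mutation("stopgain"), "stopgain")
})

test_that("mutation rates follow the distinct/total formulas", {
  # 8 copies of one missense + 2 distinct nonsense
  tb <- mk_mut("G1", c(rep("missense", 8), rep("nonsense", 2)),
               c(rep(100L, 8), 200L, 201L))
  r <- mutation_rates(tb)
  expect_equal(r$ogmr, 0.9)   # 1 - 1/10
  expect_equal(r$tsmr, 0.2)   # 2/10
  expect_equal(r$n_og, 8L)
  expect_equal(r$n_ts_distinct, 2L)

  # all-distinct nonsense: TSMR 1 and, by the formula, OGMR 1 as well
  r2 <- mutation_rates(mk_mut("G1", rep("nonsense", 6), 1:6))
  expect_equal(r2$tsmr, 1)
  expect_equal(r2$ogmr, 1)

  # 20 identical missense
  r3 <- mutation_rates(mk_mut("G1", rep("missense", 20), rep(7L, 20)))
  expect_equal(r3$ogmr, 0.95)
  expect_equal(r3$tsmr, 0)

  # 'other' records inflate the denominator
  r4 <- mutation_rates(mk_mut("G1", c(rep("missense", 8), rep("other", 2)),
                              c(rep(5L, 8), 900L, 901L)))
  expect_equal(r4$ogmr, 0.9)

  expect_error(mutation_rates(mk_mut("G1", "missense", 1L)[0, ]), "no mutation")
})

test_that("the 20/20 thresholds and the minimum-of-five gate decide the flags", {
  # 20 identical missense: OGMR 0.95 > 0.2, TSMR 0 < 0.05, n_og 20 >= 5
  act <- score_mutations(mk_mut("G1", rep("missense", 20), rep(7L, 20)))
  expect_true(act$activating)
  expect_false(act$inactivating)

  # TS clause fires on the rates but n_ts = 2 < 5: no flag at all
  none <- score_mutations(mk_mut(
    "G1", c(rep("missense", 8), rep("nonsense", 2)),
    c(rep(100L, 8), 200L, 201L)))
  expect_false(none$activating || none$inactivating)

  # 6 distinct nonsense: TSMR 1 > 0.2, n_ts 6 >= 5
  inact <- score_mutations(mk_mut("G1", rep("nonsense", 6), 1:6))
  expect_true(inact$inactivating)
  expect_false(inact$activating)
})

test_that("mutation flags are mutually exclusive and order-invariant on random tables", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(1:60, 1)
    tb <- mk_mut("G1",
                 sample(variant_classes(), n, replace = TRUE),
                 sample(1:12, n, replace = TRUE),
                 sample_id = sprintf("S%03d", sample(1:20, n, replace = TRUE)))
    calls <- score_mutations(tb)
    expect_false(calls$activating && calls$inactivating)
    perm <- score_mutations(tb[sample(n), ])
    expect_identical(perm$activating, calls$activating)
    expect_identical(perm$inactivating, calls$inactivating)
  }
})

test_that("duplicating an existing oncogene-class mutation raises OGMR", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    tb <- mk_mut("G1", sample(c("missense", "nonsense", "other"), n,
                              replace = TRUE),
                 sample(1:10, n, replace = TRUE))
    og_rows <- which(classify_mutation(tb$variant_class) == "oncogene")
    if (!length(og_rows)) next
    before <- mutation_rates(tb)$ogmr
    dup <- rbind(as.data.frame(tb), as.data.frame(tb)[og_rows[1], ])
    after <- mutation_rates(mutation_table(dup))$ogmr
    expect_gt(after, before)
  }
})
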