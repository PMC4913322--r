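mk_screen <- function(values, n_type = 20L, genes = "G1",
                      solutions = NULL) {
  lines <- sprintf("L%03d", seq_along(values))
  viab <- matrix(values, length(genes), length(values), byrow = TRUE,
                 dimnames = list(genes, lines))
  if (is.null(solutions)) solutions <- setNames(rep(1L, length(genes)), genes)
  shrna_screen(omics_matrix(viab, "shrna"), solutions,
               setNames(rep(c("TYPEA", "OTHER"),
                            c(n_type, length(values) - n_type)), lines))
}

test_that("multi-solution genes are filtered out", {
  lines <- sprintf("L%03d", 1:4)
  viab <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("A", "B", "C"), lines))
  screen <- shrna_screen(omics_matrix(viab, "shrna"),
                         c(A = 1L, B = 2L, C = 1L),
                         setNames(rep("TYPEA", 4), lines))
  flt <- filter_single_solution(screen)
  expect_setequal(feature_ids(flt$viability), c("A", "C"))

  # everything multi-solution: empty screen
  screen2 <- shrna_screen(omics_matrix(viab, "shrna"),
                          c(A = 2L, B = 3L, C = 2L),
                          setNames(rep("TYPEA", 4), lines))
  expect_equal(nrow(filter_single_solution(screen2)$viability$values), 0L)
})

test_that("the quarter-beyond-the-quartile rules decide the flags", {
  # 100 lines, viability 1..100, global Q1 = 25.75; the type's 20 lines
  # hold values 1..5 (below Q1) and 26..40 (between the quartiles)
  s5 <- mk_screen(c(1:5, 26:40, setdiff(1:100, c(1:5, 26:40))))
  calls <- score_shrna(s5, "TYPEA")
  expect_true(calls$activating)    # 5/20 = 25% is inclusive
  expect_false(calls$inactivating)

  # only 4 of 20 below Q1: 20% < 25%
  s4 <- mk_screen(c(1:4, 26:41, setdiff(1:100, c(1:4, 26:41))))
  expect_false(score_shrna(s4, "TYPEA")$activating)

  # both extremes occupied: both flags
  sboth <- mk_screen(c(1:10, 91:100, setdiff(1:100, c(1:10, 91:100))))
  both <- score_shrna(sboth, "TYPEA")
  expect_true(both$activating && both$inactivating)

  expect_error(score_shrna(s5, "NOSUCHTYPE"), "no cell lines")
})

test_that("scores ignore cell-line ordering and missing-type genes are unavailable", {
  vals <- c(1:5, 26:40, setdiff(1:100, c(1:5, 26:40)))
  base <- score_shrna(mk_screen(vals), "TYPEA")
  # permute line labels within the matrix (keeping each line's type)
  s <- mk_screen(vals)
  set.seed(61)
  perm <- sample(ncol(s$viability$values))
  s$viability <- omics_matrix(
    s$viability$values[, perm, drop = FALSE], "shrna")
  permuted <- score_shrna(s, "TYPEA")
  expect_identical(permuted$activating, base$activating)
  expect_identical(permuted$inactivating, base$inactivating)

  # gene missing in all of the type's lines
  s2 <- mk_screen(vals)
  s2$viability$values[1, 1:20] <- NA
  calls <- score_shrna(s2, "TYPEA")
  expect_false(calls$available)
  expect_false(calls$activating || calls$inactivating)
})
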