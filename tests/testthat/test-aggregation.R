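test_that("combine_scores sums flags into the four scores", {
  calls <- list(
    mk_calls("G1", "expression", act = TRUE),
    mk_calls("G1", "cna", act = TRUE),
    mk_calls("G1", "methylation", inact = TRUE),
    mk_calls("G1", "shrna", act = TRUE),
    mk_calls("G1", "mutation"))
  cards <- combine_scores(calls, "BRCA")
  expect_equal(cards$og_score, 3L)
  expect_equal(cards$ts_score, 1L)
  expect_equal(cards$overall_score, 2L)
  expect_equal(cards$aberration_score, 4L)
  expect_equal(cards$n_data_types_available, 5L)

  # no flags anywhere
  zero <- combine_scores(list(mk_calls("G1", "expression")), "BRCA")
  expect_true(all(c(zero$og_score, zero$ts_score, zero$overall_score,
                    zero$aberration_score) == 0L))

  # each additional activating flag raises og and overall by exactly 1
  grow <- lapply(c("expression", "cna", "methylation"), function(tp) {
    mk_calls("G1", tp, act = TRUE)
  })
  for (k in 1:3) {
    ck <- combine_scores(grow[seq_len(k)], "BRCA")
    expect_equal(ck$og_score, k)
    expect_equal(ck$overall_score, k)
  }

  expect_error(
    combine_scores(list(mk_calls("G1", "cna"), mk_calls("G2", "cna"))),
    "duplicate call set")
})

test_that("genes absent from a data type lose availability, not validity", {
  calls <- list(
    mk_calls(c("G1", "G2"), "expression", act = c(TRUE, FALSE)),
    mk_calls("G1", "mutation"))
  cards <- combine_scores(calls, "X")
  expect_equal(cards$n_data_types_available[cards$gene == "G2"], 1L)
  expect_true(is.na(cards$mutation_call[cards$gene == "G2"]))
  expect_silent(validate_cards(cards))
})

test_that("rank_genes sorts deterministically with alphabetical ties", {
  cards <- combine_scores(list(
    mk_calls(c("B", "A", "C"), "expression",
             act = c(TRUE, TRUE, FALSE))), "X")
  expect_identical(rank_genes(cards, "og"), c("A", "B", "C"))
  # overall = og - ts discriminates differently than og
  calls2 <- list(
    mk_calls(c("P", "Q"), "expression", act = c(TRUE, TRUE)),
    mk_calls(c("P", "Q"), "cna", act = c(TRUE, TRUE)),
    mk_calls(c("P", "Q"), "methylation",
             act = c(FALSE, TRUE), inact = c(FALSE, TRUE)),
    mk_calls(c("P", "Q"), "mutation", inact = c(FALSE, TRUE)),
    mk_calls(c("P", "Q"), "shrna", inact = c(FALSE, TRUE)))
  cards2 <- combine_scores(calls2, "X")
  expect_identical(rank_genes(cards2, "overall")[1], "P")
  expect_identical(rank_genes(cards2, "aberration")[1], "Q")
})

test_that("dual-role genes need both roles in different cancer types", {
  card <- function(gene, ct, og, ts) {
    data.frame(gene = gene, cancer_type = ct, og_score = og, ts_score = ts,
               overall_score = og - ts, aberration_score = og + ts,
               n_data_types_available = 5L, stringsAsFactors = FALSE)
  }
  cards <- rbind(
    card("G1", "A", 2L, 0L), card("G1", "B", 0L, 2L),  # dual role
    card("G2", "A", 2L, 2L), card("G2", "B", 0L, 0L),  # same type only
    card("G3", "A", 2L, 0L), card("G3", "B", 0L, 1L))  # ts side too weak
  expect_identical(dual_role_genes(cards, min_data_types = 2L), "G1")
  expect_error(dual_role_genes(cards[cards$cancer_type == "A", ]),
               "two cancer types")
})

test_that("pathway scores average overall scores of covered members", {
  calls <- list(
    mk_calls(c("A", "B", "C"), "expression",
             act = c(TRUE, FALSE, FALSE), inact = c(FALSE, TRUE, FALSE)),
    mk_calls(c("A", "B", "C"), "cna", act = c(TRUE, FALSE, FALSE)))
  cards <- combine_scores(calls, "X")   # overall: A=2, B=-1, C=0
  ps <- pathway_scores(cards, list(P1 = c("A", "B", "C"),
                                   P2 = c("A"),
                                   P3 = c("Z1", "Z2")))
  expect_equal(ps$mean_overall[ps$pathway_id == "P1"], 1 / 3)
  # singleton pathway equals the gene's own overall score
  expect_equal(ps$mean_overall[ps$pathway_id == "P2"], 2)
  expect_true(is.na(ps$mean_overall[ps$pathway_id == "P3"]))
  expect_equal(ps$n_genes_scored[ps$pathway_id == "P3"], 0L)
  expect_equal(ps$n_missing[ps$pathway_id == "P3"], 2L)
})

test_that("affected fractions use the strict one-SD rule", {
  fx <- boundary_fixture("affected_sd")
  af <- affected_fractions(fx$tumor, fx$normal, fx$pairs)
  # differences (-2,-1,0,1,2): sd = sqrt(2.5), only the extremes exceed it
  expect_equal(af$frac_up[af$gene == "G_spread"], 0.2)
  expect_equal(af$frac_down[af$gene == "G_spread"], 0.2)
  # samples exactly at mean +/- sd are NOT affected
  expect_equal(af$frac_up[af$gene == "G_boundary"], 0)
  # constant differences: sd 0, nobody affected
  expect_equal(af$frac_up[af$gene == "G_flat"] +
                 af$frac_down[af$gene == "G_flat"], 0)
  expect_true(all(af$frac_up + af$frac_down <= 1, na.rm = TRUE))
})

test_that("unpaired affected fractions subtract the normal mean", {
  tum <- omics_matrix(matrix(c(0, 0, 0, 5, -5), 1, 5,
                             dimnames = list("G", paste0("T", 1:5))),
                      "expression")
  nor <- omics_matrix(matrix(c(1, 3), 1, 2,
                             dimnames = list("G", c("N1", "N2"))),
                      "expression")
  af <- affected_fractions(tum, nor)
  # differences: (-2,-2,-2,3,-7); mean -2, sd sqrt(12.5)
  expect_equal(af$frac_up, 0.2)
  expect_equal(af$frac_down, 0.2)
})

test_that("cohort comparison is plain Pearson over shared pathways", {
  ps <- function(ids, v) data.frame(pathway_id = ids, mean_overall = v,
                                    n_genes_scored = 1L,
                                    stringsAsFactors = FALSE)
  a <- ps(c("P1", "P2", "P3"), c(1, 2, 3))
  expect_equal(compare_cohorts(a, a), 1)
  expect_equal(compare_cohorts(a, ps(c("P1", "P2", "P3"), c(3, 2, 1))), -1)
  set.seed(71)
  va <- rnorm(10); vb <- rnorm(10)
  ids <- sprintf("P%02d", 1:10)
  expect_equal(compare_cohorts(ps(ids, va), ps(ids, vb)),
               oracle_pearson(va, vb))
  expect_error(compare_cohorts(a[1:2, ], a[1:2, ]), "at least 3")
})
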