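# one gene, configurable probes; tumor betas coupled to expression
meth_fixture <- function(probes, n = 30, seed = 31) {
  # probes: data.frame(probe_id, region, shift, couple) where couple is the
  # sign of the beta-expression association among tumors
  set.seed(seed)
  tum_s <- sprintf("T%02d", seq_len(n))
  nor_s <- sprintf("N%02d", seq_len(n))
  expr <- 8 + rnorm(n)
  z <- as.vector(scale(expr))
  tum <- t(vapply(seq_len(nrow(probes)), function(i) {
    plogis(qlogis(0.4 + probes$shift[i]) +
             probes$couple[i] * 1.2 * z + rnorm(n, 0, 0.2))
  }, numeric(n)))
  nor <- t(vapply(seq_len(nrow(probes)), function(i) {
    plogis(qlogis(0.4) + rnorm(n, 0, 0.2))
  }, numeric(n)))
  dimnames(tum) <- list(probes$probe_id, tum_s)
  dimnames(nor) <- list(probes$probe_id, nor_s)
  expr_m <- matrix(expr, 1, n, dimnames = list("G1", tum_s))
  list(tumor = omics_matrix(tum, "methylation"),
       normal = omics_matrix(nor, "methylation"),
       annot = probe_annotation(data.frame(
         probe_id = probes$probe_id, gene = "G1", region = probes$region,
         stringsAsFactors = FALSE)),
       expr = omics_matrix(expr_m, "expression"))
}

test_that("a hypermethylated body probe with positive coupling activates the gene", {
  fx <- meth_fixture(data.frame(
    probe_id = c("p_hit", "p_null"), region = c("Body", "Body"),
    shift = c(0.25, 0), couple = c(1, 0), stringsAsFactors = FALSE))
  calls <- score_methylation(fx$tumor, fx$normal, fx$annot, fx$expr)
  expect_true(calls$activating[calls$gene == "G1"])
  expect_false(calls$inactivating[calls$gene == "G1"])
  expect_identical(calls$probe_act[calls$gene == "G1"], "p_hit")
})

test_that("a hypermethylated promoter probe with negative coupling inactivates the gene", {
  fx <- meth_fixture(data.frame(
    probe_id = "p_prom", region = "TSS200", shift = 0.25, couple = -1,
    stringsAsFactors = FALSE))
  calls <- score_methylation(fx$tumor, fx$normal, fx$annot, fx$expr)
  expect_false(calls$activating)
  expect_true(calls$inactivating)
})

test_that("independent probes can set both flags on one gene", {
  fx <- meth_fixture(data.frame(
    probe_id = c("p_body", "p_prom"), region = c("Body", "TSS1500"),
    shift = c(0.25, 0.25), couple = c(1, -1), stringsAsFactors = FALSE))
  calls <- score_methylation(fx$tumor, fx$normal, fx$annot, fx$expr)
  expect_true(calls$activating && calls$inactivating)
})

test_that("the beta gate and coupling direction both guard the call", {
  # shift below the 0.1 gate: significant p but no eligibility
  fx <- meth_fixture(data.frame(
    probe_id = "p_small", region = "Body", shift = 0.05, couple = 1,
    stringsAsFactors = FALSE), n = 60)
  calls <- score_methylation(fx$tumor, fx$normal, fx$annot, fx$expr)
  expect_false(any(calls$activating | calls$inactivating))

  # body probe higher in tumors but negatively coupled: no call either
  fx2 <- meth_fixture(data.frame(
    probe_id = "p_wrongdir", region = "Body", shift = 0.25, couple = -1,
    stringsAsFactors = FALSE))
  calls2 <- score_methylation(fx2$tumor, fx2$normal, fx2$annot, fx2$expr)
  expect_false(any(calls2$activating | calls2$inactivating))
})

test_that("probes without annotation or expression are skipped gracefully", {
  fx <- meth_fixture(data.frame(
    probe_id = "p_hit", region = "Body", shift = 0.25, couple = 1,
    stringsAsFactors = FALSE))
  # annotation points at a gene absent from the expression matrix
  annot2 <- probe_annotation(data.frame(
    probe_id = "p_hit", gene = "ABSENT", region = "Body",
    stringsAsFactors = FALSE))
  calls <- score_methylation(fx$tumor, fx$normal, annot2, fx$expr)
  expect_equal(nrow(calls), 0L)
})
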