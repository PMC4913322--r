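test_that("signed-rank test handles the textbook cases", {
  # all-positive differences 1..5: P(W >= 15) = 1/32, doubled
  r <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(r$p_two_sided, 0.0625)
  expect_identical(r$direction, 1L)

  # identical pairs degenerate to p = 1, direction 0
  r0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p_two_sided, 1)
  expect_identical(r0$direction, 0L)
  expect_identical(r0$n_effective, 0L)

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("signed-rank p matches the sign-enumeration oracle for n <= 12", {
  set.seed(42)
  for (i in 1:150) {
    n <- sample(2:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 3 == 0) {                       # force ties in |differences|
      x <- y + sample(c(-2, -1, 1, 2), n, replace = TRUE)
    }
    expect_equal(wilcoxon_signed_rank(x, y)$p_two_sided,
                 oracle_signed_rank_p(x, y),
                 info = sprintf("instance %d (n=%d)", i, n))
  }
})

test_that("rank-sum test handles the textbook cases", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_two_sided, 1 / 3)

  # identical multisets are perfectly symmetric
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))$p_two_sided, 1)

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p matches the group-assignment oracle for small n", {
  set.seed(43)
  for (i in 1:150) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    x <- rnorm(nx)
    y <- rnorm(ny)
    if (i %% 3 == 0) {
      x <- round(x)
      y <- round(y)
    }
    expect_equal(wilcoxon_rank_sum(x, y)$p_two_sided,
                 oracle_rank_sum_p(x, y),
                 info = sprintf("instance %d (%d vs %d)", i, nx, ny))
  }
})

test_that("exact and approximate paths agree near the crossover size", {
  set.seed(44)
  worst <- 0
  for (i in 1:200) {
    x <- rnorm(49)
    y <- rnorm(49)
    pe <- wilcoxon_signed_rank(x, y, exact_limit = 49L)$p_two_sided
    pa <- wilcoxon_signed_rank(x, y, exact_limit = 0L)$p_two_sided
    worst <- max(worst, abs(pe - pa))
    a <- rnorm(25)
    b <- rnorm(25)
    pe <- wilcoxon_rank_sum(a, b, exact_limit = 49L)$p_two_sided
    pa <- wilcoxon_rank_sum(a, b, exact_limit = 0L)$p_two_sided
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.02)
})

test_that("bh_adjust follows the step-up formula and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")

  # NA pass-through does not inflate the test count
  withna <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(withna[2]))
  expect_equal(withna[c(1, 3)], bh_adjust(c(0.01, 0.04)))

  set.seed(45)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("spearman_cor computes rank correlations and exact p-values", {
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)

  # invariant under replacing values by their ranks
  set.seed(46)
  x <- rnorm(10); y <- rnorm(10)
  expect_identical(spearman_cor(x, y)$rho,
                   spearman_cor(rank(x), rank(y))$rho)

  # constant input is degenerate, not an error
  d <- spearman_cor(rep(2, 5), 1:5)
  expect_true(d$degenerate)
  expect_true(is.na(d$rho))

  expect_error(spearman_cor(1:2, 2:1), "at least 3")

  for (i in 1:60) {
    n <- sample(4:6, 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else x + rnorm(n, sd = 0.5)
    expect_equal(spearman_cor(x, y)$p_two_sided, oracle_spearman_p(x, y),
                 info = paste("instance", i))
  }
})

test_that("quantile_linear interpolates and honors the boundaries", {
  expect_equal(quantile_linear(1:100, 0.25), 25.75)
  expect_equal(quantile_linear(c(7, 3, 9), 0), 3)
  expect_equal(quantile_linear(c(7, 3, 9), 1), 9)
  expect_equal(quantile_linear(rep(4.2, 10), 0.37), 4.2)
  expect_error(quantile_linear(numeric(0), 0.5), "empty")
  expect_error(quantile_linear(1:5, 1.2), "\\[0, 1\\]")
})
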