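#' Rank-based tests used by the scorers
#'
#' Self-contained paired signed-rank and unpaired rank-sum tests.  Both
#' use the exact (conditional-on-ties) permutation distribution, computed
#' by a shift-distribution dynamic program over doubled mid-ranks, for up
#' to `exact_limit` effective observations per group, and a tie-corrected
#' normal approximation above that.  The crossover of 49 matches the
#' convention of `stats::wilcox.test`, under which small cohorts (a few
#' dozen tumor/normal pairs) still get exact p-values: with, say, 20
#' uniformly positive paired differences the exact two-sided p is
#' 2^-19 ~ 1.9e-6 whereas the normal approximation saturates near 1e-4,
#' a difference that decides borderline FDR calls in genome-wide runs.
#'
#' Two-sided p-values are `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#' Zero paired differences are dropped before ranking (Wilcoxon
#' convention); if all differences are zero the test is degenerate and
#' returns p = 1 with direction 0.
#'
#' @param x,y Numeric vectors; for the signed-rank test they are paired
#'   and must have equal length.
#' @param exact_limit Largest number of effective observations (nonzero
#'   pairs, or per-group sizes for the rank-sum test) for which the exact
#'   permutation distribution is used.
#' @return A list of class `rank_test` with elements `statistic` (W, the
#'   sum of positive-difference ranks or of the first group's ranks),
#'   `p_two_sided`, `n_effective` and `direction` (-1, 0, +1; the sign of
#'   the location shift of `x` relative to `y`).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 49L) {
  if (length(x) != length(y)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- x - y
  d <- d[!is.na(d)]
  if (!length(d)) stop("need at least one non-missing pair", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(rank_test(statistic = 0, p = 1, n_effective = 0L, direction = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  direction <- sign_int(W - mu)
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, W)
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  rank_test(statistic = W, p = p, n_effective = n, direction = direction)
}

#' @rdname wilcoxon_signed_rank
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 49L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  direction <- sign_int(W - mu)
  if (nx <= exact_limit && ny <= exact_limit) {
    p <- rank_sum_exact_p(r, nx, W)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  rank_test(statistic = W, p = p, n_effective = N, direction = direction)
}

rank_test <- function(statistic, p, n_effective, direction) {
  structure(list(statistic = statistic, p_two_sided = p,
                 n_effective = as.integer(n_effective),
                 direction = as.integer(direction)),
            class = "rank_test")
}

sign_int <- function(v) {
  if (isTRUE(all.equal(v, 0)) || v == 0) 0L else if (v > 0) 1L else -1L
}

# Exact permutation distribution of the signed-rank statistic conditional
# on the observed |d| mid-ranks.  Doubling the mid-ranks makes them
# integers, so the 2^n equally likely sign assignments can be counted with
# a subset-sum DP; counts stay below 2^53 for n <= 49, hence exact.
signed_rank_exact_p <- function(r, W) {
  w <- as.integer(round(2 * r))
  total <- sum(w)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), counts[seq_len(total + 1L - wi)])
    counts <- counts + shifted
  }
  denom <- 2^length(w)
  W2 <- as.integer(round(2 * W))
  p_le <- sum(counts[seq_len(W2 + 1L)]) / denom
  p_ge <- sum(counts[seq.int(W2 + 1L, total + 1L)]) / denom
  min(1, 2 * min(p_le, p_ge))
}

# Number of size-nx subsets of the (doubled) combined ranks attaining each
# rank sum; gives the exact conditional distribution of the rank-sum
# statistic under the null that group labels are exchangeable.
rank_sum_exact_p <- function(r, nx, W) {
  w <- as.integer(round(2 * r))
  total <- sum(w)
  counts <- matrix(0, nrow = nx + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (wi in w) {
    kmax <- nx
    for (k in seq.int(kmax, 1L)) {
      src <- counts[k, seq_len(total + 1L - wi)]
      counts[k + 1L, seq.int(wi + 1L, total + 1L)] <-
        counts[k + 1L, seq.int(wi + 1L, total + 1L)] + src
    }
  }
  dist <- counts[nx + 1L, ]
  denom <- sum(dist)
  W2 <- as.integer(round(2 * W))
  p_le <- sum(dist[seq_len(W2 + 1L)]) / denom
  p_ge <- sum(dist[seq.int(W2 + 1L, total + 1L)]) / denom
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), with validation and
#' `NA` pass-through: missing entries stay missing and do not count
#' towards the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted q-values, order-preserving with the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Spearman rank correlation with small-n exact p-values
#'
#' rho is the Pearson correlation of mid-ranks.  The two-sided p-value is
#' obtained by full enumeration of the n! orderings for `n <= exact_limit`
#' and by the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` above.  A
#' constant input vector makes rho undefined; the result is flagged
#' degenerate (`rho` and `p` are `NA`), which downstream scoring treats as
#' "no significant correlation".
#'
#' @param x,y Equal-length numeric vectors; pairs with any missing value
#'   are dropped, at least 3 complete pairs are required.
#' @param exact_limit Largest n for which the permutation distribution is
#'   enumerated exactly.
#' @return List with elements `rho`, `p_two_sided`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y, exact_limit = 8L) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_two_sided = NA_real_, n = n,
                degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # rho under every reordering of y's ranks
    rho_perm <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) /
      denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p_two_sided = p, n = n, degenerate = FALSE)
}

# all permutations of 1..n as an (n!) x n index matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- matrix(rest[sub], nrow = nrow(sub))
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, block)
    row <- row + nrow(sub)
  }
  out
}

#' Linear-interpolation quantile
#'
#' The "type 7" rule: position `1 + q * (n - 1)` on the sorted vector,
#' linearly interpolated.  Missing values are dropped.
#'
#' @param values Non-empty numeric vector.
#' @param q Fraction in \[0, 1\].
#' @return The quantile value.
#' @export
quantile_linear <- function(values, q) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty vector", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}
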