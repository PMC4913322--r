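# Independent brute-force oracles for the rank statistics.  These
# enumerate the permutation spaces directly (sign patterns, group
# assignments, orderings) and share no code with the package's
# shift-distribution DP / approximation paths.

oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & (x - y) != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  w <- sum(r[d > 0])
  min(1, 2 * min(mean(W_all <= w), mean(W_all >= w)))
}

oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  combos <- utils::combn(length(r), nx)
  W_all <- colSums(matrix(r[combos], nrow = nx))
  w <- sum(r[seq_len(nx)])
  min(1, 2 * min(mean(W_all <= w), mean(W_all >= w)))
}

# all permutations, written independently of the package's generator
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

oracle_spearman_p <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  ry <- rank(y)
  rho_all <- vapply(oracle_perms(length(y)), function(p) {
    stats::cor(rank(x), ry[p])
  }, numeric(1L))
  mean(abs(rho_all) >= abs(rho) - 1e-12)
}

# literal step-up formula: q_i = min over j with p_(j) >= p_i of
# p_(j) * n / rank(j), capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- sorted[sorted >= p[i]] * n / which(sorted >= p[i])
    q[i] <- min(1, min(cand))
  }
  q
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small builders -----------------------------------------------------------

mk_map <- function(n_pairs, cancer_type = "T1", dedup = TRUE) {
  patients <- sprintf("P%03d", seq_len(n_pairs))
  m <- sample_map(data.frame(
    patient_id = rep(patients, 2L),
    sample_id = c(paste0(patients, "-T"), paste0(patients, "-N")),
    sample_class = rep(c("tumor_primary", "normal"), each = n_pairs),
    cancer_type = cancer_type, stringsAsFactors = FALSE))
  if (dedup) deduplicate_samples(m) else m
}

mk_paired <- function(tum, nor, tag = "expression") {
  n <- ncol(tum)
  patients <- sprintf("P%03d", seq_len(n))
  colnames(tum) <- paste0(patients, "-T")
  colnames(nor) <- paste0(patients, "-N")
  paired_cohort(omics_matrix(tum, tag), omics_matrix(nor, tag), mk_map(n))
}

mk_calls <- function(gene, data_type, act = FALSE, inact = FALSE,
                     avail = TRUE) {
  aberration_calls(gene, data_type,
                   rep_len(act, length(gene)),
                   rep_len(inact, length(gene)),
                   rep_len(avail, length(gene)))
}
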