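#' Deterministic fixtures probing each scoring threshold
#'
#' Small, fully determined input bundles that place a single gene exactly
#' at (and on both sides of) each published decision boundary: the +1
#' score unit, the 0.1 copy-number and methylation effect gates, the 0.2
#' OGMR / TSMR cut-offs, the minimum of five class mutations, the
#' 25%-beyond-the-quartile shRNA rules, and the one-SD affected-sample
#' rule.  Shifted values at the 0.1 gates are built from exact binary
#' fractions so that the group mean equals the nominal shift bit-exactly
#' and the strict ">" comparison is well defined at the boundary.
#'
#' @param case_id One of `"unit_score"`, `"cn_gate"`, `"beta_gate"`,
#'   `"ogmr_gate"`, `"tsmr_gate"`, `"min_five"`, `"shrna_quartile"`,
#'   `"shrna_percentile"`, `"affected_sd"`.
#' @param seed Seed for the one fixture (`unit_score`) that draws noise
#'   for its null genes; all other fixtures are noise-free.
#' @return A list; contents depend on the case, see Details.
#'
#' @details
#' * `unit_score`: 20 tumor/normal pairs, 1000 genes; gene `G0001` has
#'   tumor = normal + 2, the rest are null.  Elements: `expr_tumor`,
#'   `expr_normal`, `sample_map`.
#' * `cn_gate` / `beta_gate`: per shift d in {0.05, 0.10, 0.15}, a bundle
#'   with the shifted gene/probe, constant-zero (resp. 0.4) normals,
#'   deterministic zero-mean jitter of amplitude ~0.01, and tumor
#'   expression perfectly monotone in the shifted values.
#' * `ogmr_gate`: 20 missense mutations with d = 20..14 distinct sites
#'   (OGMR sweeping 0..0.3 on a 0.05 grid).
#' * `tsmr_gate`: 40 all-distinct mutations, k = 5..12 nonsense and the
#'   rest missense (TSMR = OGMR = k/40, a 0.025 grid).
#' * `min_five`: m = 1..10 distinct nonsense mutations in one gene.
#' * `shrna_quartile`: 100-line screen with viability 1..100; one 20-line
#'   type holds k = 1..20 lines at values 1..k (below the global lower
#'   quartile), the rest mid-range.
#' * `shrna_percentile`: same screen; 5 of the type's lines sit just
#'   above the global {50, 75, 90}th percentile in separate sub-bundles.
#' * `affected_sd`: paired difference vectors probing the strict one-SD
#'   rule, including a sample exactly at mean + SD.
#' @export
boundary_fixture <- function(case_id, seed = 20L) {
  valid <- c("unit_score", "cn_gate", "beta_gate", "ogmr_gate",
             "tsmr_gate", "min_five", "shrna_quartile",
             "shrna_percentile", "affected_sd")
  if (!is.character(case_id) || length(case_id) != 1L ||
      !(case_id %in% valid)) {
    stop("unknown case_id; valid ids: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  switch(case_id,
         unit_score = fixture_unit_score(seed),
         cn_gate = fixture_shift_gate("cna"),
         beta_gate = fixture_shift_gate("methylation"),
         ogmr_gate = fixture_ogmr_gate(),
         tsmr_gate = fixture_tsmr_gate(),
         min_five = fixture_min_five(),
         shrna_quartile = fixture_shrna_quartile(),
         shrna_percentile = fixture_shrna_percentile(),
         affected_sd = fixture_affected_sd())
}

fixture_map <- function(n_pairs) {
  patients <- sprintf("P%03d", seq_len(n_pairs))
  deduplicate_samples(sample_map(data.frame(
    patient_id = rep(patients, 2L),
    sample_id = c(paste0(patients, "-T"), paste0(patients, "-N")),
    sample_class = rep(c("tumor_primary", "normal"), each = n_pairs),
    cancer_type = "FIX", stringsAsFactors = FALSE)))
}

fixture_unit_score <- function(seed) {
  set.seed(seed)
  n_pairs <- 20L
  n_genes <- 1000L
  genes <- sprintf("G%04d", seq_len(n_genes))
  map <- fixture_map(n_pairs)
  tum_s <- paste0(sprintf("P%03d", seq_len(n_pairs)), "-T")
  nor_s <- paste0(sprintf("P%03d", seq_len(n_pairs)), "-N")
  nor <- matrix(stats::rnorm(n_genes * n_pairs, 8, 1), n_genes, n_pairs,
                dimnames = list(genes, nor_s))
  tum <- nor + matrix(stats::rnorm(n_genes * n_pairs, 0, 1),
                      n_genes, n_pairs)
  # the probe gene: a uniform +2 shift over its (distinct) normal values
  tum["G0001", ] <- nor["G0001", ] + 2
  dimnames(tum) <- list(genes, tum_s)
  list(expr_tumor = omics_matrix(tum, "expression"),
       expr_normal = omics_matrix(nor, "expression"),
       sample_map = map)
}

# zero-mean, pairwise-negating jitter of amplitude ~0.01 whose values are
# exact multiples of 2^-20, so adding it to a shift < 0.51 is exact
exact_jitter <- function(n) {
  m <- 2L * seq_len(n) - (n + 1L)      # symmetric integers, sum 0
  scale <- floor(0.01 * 2^20 / max(abs(m)))
  (m * scale) / 2^20
}

fixture_shift_gate <- function(kind) {
  n <- if (kind == "cna") 200L else 100L
  base <- if (kind == "cna") 0 else 0.4
  shifts <- c(0.05, 0.10, 0.15)
  jit <- exact_jitter(n)
  map <- fixture_map(n)
  tum_s <- paste0(sprintf("P%03d", seq_len(n)), "-T")
  nor_s <- paste0(sprintf("P%03d", seq_len(n)), "-N")
  feature <- if (kind == "cna") "G1" else "P1"
  bundles <- lapply(shifts, function(d) {
    tum <- matrix(base + d + jit, 1L, n, dimnames = list(feature, tum_s))
    nor <- matrix(base, 1L, n, dimnames = list(feature, nor_s))
    expr <- matrix(10 * as.vector(tum), 1L, n,
                   dimnames = list("G1", tum_s))
    out <- list(tumor = omics_matrix(tum, kind),
                normal = omics_matrix(nor, kind),
                expr_tumor = omics_matrix(expr, "expression"),
                sample_map = map)
    if (kind == "methylation") {
      out$probe_annotation <- probe_annotation(data.frame(
        probe_id = "P1", gene = "G1", region = "Body",
        stringsAsFactors = FALSE))
    }
    out
  })
  names(bundles) <- sprintf("%.2f", shifts)
  list(shifts = shifts, bundles = bundles)
}

one_gene_maf <- function(gene, variant_class, pos, ref = "A", alt = "T") {
  mutation_table(data.frame(
    gene = gene, sample_id = sprintf("S%03d", seq_along(pos)),
    variant_class = variant_class, chrom = "1", pos = pos,
    ref = ref, alt = alt, stringsAsFactors = FALSE))
}

fixture_ogmr_gate <- function() {
  d_values <- 20:14
  tables <- lapply(d_values, function(d) {
    # 20 missense total over d distinct sites: surplus copies re-hit site 1
    pos <- c(seq_len(d), rep(1L, 20L - d))
    one_gene_maf("G1", "missense", pos)
  })
  names(tables) <- as.character(d_values)
  list(d_values = d_values, ogmr = 1 - d_values / 20, tables = tables)
}

fixture_tsmr_gate <- function() {
  k_values <- 5:12
  tables <- lapply(k_values, function(k) {
    cls <- c(rep("nonsense", k), rep("missense", 40L - k))
    one_gene_maf("G1", cls, seq_len(40L))
  })
  names(tables) <- as.character(k_values)
  list(k_values = k_values, tsmr = k_values / 40, tables = tables)
}

fixture_min_five <- function() {
  m_values <- 1:10
  tables <- lapply(m_values, function(m) {
    one_gene_maf("G1", "nonsense", seq_len(m))
  })
  names(tables) <- as.character(m_values)
  list(m_values = m_values, tables = tables)
}

# screen layout shared by the two shRNA fixtures: 100 lines, viability a
# permutation of 1..100, first 20 lines form the probed cancer type
shrna_fixture_screen <- function(type_values) {
  lines <- sprintf("L%03d", 1:100)
  type_lines <- lines[1:20]
  rest <- setdiff(1:100, type_values)
  viab <- matrix(c(type_values, rest), 1L, 100L,
                 dimnames = list("G1", lines))
  shrna_screen(omics_matrix(viab, "shrna"),
               stats::setNames(1L, "G1"),
               stats::setNames(rep(c("TYPEA", "OTHER"), c(20L, 80L)),
                               lines))
}

fixture_shrna_quartile <- function() {
  k_values <- 1:20
  screens <- lapply(k_values, function(k) {
    # k lines below the global lower quartile (25.75), rest mid-range
    shrna_fixture_screen(c(seq_len(k), 25L + seq_len(20L - k)))
  })
  names(screens) <- as.character(k_values)
  list(k_values = k_values, cancer_type = "TYPEA", screens = screens)
}

fixture_shrna_percentile <- function() {
  candidates <- c(50, 75, 90)
  screens <- lapply(candidates, function(p) {
    # 5 lines just above the p-th percentile of 1..100, 15 mid-range
    above <- p + seq_len(5L)
    shrna_fixture_screen(c(above, 25L + seq_len(15L)))
  })
  names(screens) <- as.character(candidates)
  list(candidates = candidates, cancer_type = "TYPEA", screens = screens)
}

fixture_affected_sd <- function() {
  samples <- sprintf("S%d", 1:5)
  tum <- matrix(c(-2, -1, 0, 1, 2,      # mu 0, sd sqrt(2.5): two affected
                  -1, -1, 0, 1, 1,      # samples exactly at mu +/- sd
                  3, 3, 3, 3, 3),       # sd 0: nobody affected
                nrow = 3L, byrow = TRUE,
                dimnames = list(c("G_spread", "G_boundary", "G_flat"),
                                samples))
  nor <- matrix(0, 3L, 5L,
                dimnames = list(rownames(tum), paste0(samples, "n")))
  pairs <- data.frame(tumor_sample = samples,
                      normal_sample = paste0(samples, "n"),
                      stringsAsFactors = FALSE)
  list(tumor = omics_matrix(tum, "expression"),
       normal = omics_matrix(nor, "expression"),
       pairs = pairs)
}
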