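#' Specification for a synthetic multi-omics cohort
#'
#' Describes a cohort with planted oncogenes and tumor suppressors whose
#' effects are engineered to satisfy every scorer's criteria, plus
#' exchangeable null genes.  The defaults define the validation cohort
#' used throughout the package's tests: 1000 genes, 50 tumor/normal
#' pairs, 20 planted genes per role with large effects in four data types
#' (expression, copy number, methylation, mutations); an shRNA screen
#' across four cell-line types is generated as well when
#' `n_lines_per_type > 0`.
#'
#' Effect sizes, in the units of each data type: `expr_shift` in noise-SD
#' units of log2 expression (default 2), `cn_shift` in log-ratio units
#' (default 0.5, well beyond the 0.1 gate), `beta_shift` in beta units
#' (default 0.25), `mut_recurrent` identical missense mutations for
#' planted oncogenes (default 10), `mut_truncating` distinct nonsense
#' mutations for planted suppressors (default 8), `viability_shift` in
#' viability-SD units (default 3).  Tumor-side copy number and
#' methylation are coupled to tumor expression so the correlation stages
#' see strong positive associations.
#'
#' @param n_genes,n_pairs Cohort dimensions (`n_pairs >= 3`).
#' @param n_oncogenes,n_tumor_suppressors Planted genes per role.
#' @param n_probes_per_gene Methylation probes per gene (first is a
#'   gene-body probe, the rest promoter/"other").
#' @param n_extra_tumors Unpaired tumor samples (expression/CN only).
#' @param n_line_types,n_lines_per_type shRNA screen layout; the first
#'   type is the cohort's own cancer type.
#' @param expr_shift,cn_shift,beta_shift,viability_shift,mut_recurrent,mut_truncating
#'   Planted effect sizes (see above).
#' @param expr_sd,cn_sd,cn_tumor_sd,beta_logit_sd Noise SDs: expression
#'   noise, normal-sample CN noise, tumor-side CN dispersion of planted
#'   genes, and the latent-logit SD of the beta noise (beta values are
#'   logit-normal, clipped to \[0, 1\] by construction).
#' @param mut_background Poisson mean of background mutations per gene.
#' @param cancer_type Label of the cohort.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_genes = 1000L, n_pairs = 50L,
                        n_oncogenes = 20L, n_tumor_suppressors = 20L,
                        n_probes_per_gene = 2L, n_extra_tumors = 0L,
                        n_line_types = 4L, n_lines_per_type = 25L,
                        expr_shift = 2, cn_shift = 0.5, beta_shift = 0.25,
                        viability_shift = 3,
                        mut_recurrent = 10L, mut_truncating = 8L,
                        expr_sd = 1, cn_sd = 0.05, cn_tumor_sd = 0.3,
                        beta_logit_sd = 0.3, mut_background = 0.3,
                        cancer_type = "SYNTH", seed = 1L) {
  if (n_pairs < 3L) stop("n_pairs must be >= 3", call. = FALSE)
  if (n_oncogenes + n_tumor_suppressors > n_genes) {
    stop("more planted genes than genes", call. = FALSE)
  }
  if (n_probes_per_gene < 1L) stop("need >= 1 probe per gene", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with known truth
#'
#' Draws the full input bundle for [score_cohort()] from a
#' [cohort_spec()]: sample map, paired expression / copy-number /
#' methylation matrices, probe annotation, mutation table, shRNA screen,
#' and a truth table recording each gene's planted role.  Planted
#' oncogenes are up-regulated, copy-gained (gain correlated with
#' expression), body-probe hypermethylated (beta correlated with
#' expression), recurrently missense-mutated and drop viability upon
#' knock-down in the target type's cell lines; tumor suppressors carry
#' the mirrored effects.  Null genes are exchangeable noise.  The same
#' seed reproduces the bundle exactly; `dir`, if given, writes every
#' input in its external text format.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for the file bundle.
#' @return List with the inputs named as the [score_cohort()] arguments,
#'   plus `truth` (data frame `gene`, `role`) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  planted <- sample(genes, spec$n_oncogenes + spec$n_tumor_suppressors)
  og_genes <- planted[seq_len(spec$n_oncogenes)]
  ts_genes <- setdiff(planted, og_genes)
  role <- ifelse(genes %in% og_genes, "oncogene",
                 ifelse(genes %in% ts_genes, "tumor_suppressor", "null"))
  sgn <- ifelse(role == "oncogene", 1, ifelse(role == "tumor_suppressor",
                                              -1, 0))

  patients <- sprintf("P%03d", seq_len(spec$n_pairs))
  tum_s <- paste0(patients, "-T")
  nor_s <- paste0(patients, "-N")
  map <- sample_map(data.frame(
    patient_id = rep(patients, 2L),
    sample_id = c(tum_s, nor_s),
    sample_class = rep(c("tumor_primary", "normal"), each = spec$n_pairs),
    cancer_type = spec$cancer_type, stringsAsFactors = FALSE))

  G <- spec$n_genes
  P <- spec$n_pairs
  mu_g <- stats::rnorm(G, mean = 8, sd = 2)

  # copy number: normals are flat noise; planted tumors carry a shifted,
  # dispersed log-ratio whose per-sample deviation also drives expression
  cn_nor <- matrix(stats::rnorm(G * P, 0, spec$cn_sd), G, P,
                   dimnames = list(genes, nor_s))
  cn_dev <- matrix(0, G, P)
  cn_dev[sgn != 0, ] <- stats::rnorm(sum(sgn != 0) * P, 0, spec$cn_tumor_sd)
  cn_tum <- cn_nor + sgn * spec$cn_shift + cn_dev +
    matrix(stats::rnorm(G * P, 0, spec$cn_sd), G, P)
  dimnames(cn_tum) <- list(genes, tum_s)

  expr_nor <- mu_g + matrix(stats::rnorm(G * P, 0, spec$expr_sd), G, P)
  dimnames(expr_nor) <- list(genes, nor_s)
  expr_noise_sd <- ifelse(sgn != 0, spec$expr_sd / 2, spec$expr_sd)
  expr_tum <- mu_g + sgn * spec$expr_shift * spec$expr_sd + 2 * cn_dev +
    matrix(stats::rnorm(G * P, 0, 1), G, P) * expr_noise_sd
  dimnames(expr_tum) <- list(genes, tum_s)

  if (spec$n_extra_tumors > 0L) {
    extra_p <- sprintf("X%03d", seq_len(spec$n_extra_tumors))
    extra_s <- paste0(extra_p, "-T")
    map <- sample_map(rbind(as.data.frame(map), data.frame(
      patient_id = extra_p, sample_id = extra_s,
      sample_class = "tumor_primary", cancer_type = spec$cancer_type,
      stringsAsFactors = FALSE)))
    dev_x <- matrix(0, G, spec$n_extra_tumors)
    dev_x[sgn != 0, ] <- stats::rnorm(sum(sgn != 0) * spec$n_extra_tumors,
                                      0, spec$cn_tumor_sd)
    cn_x <- sgn * spec$cn_shift + dev_x +
      matrix(stats::rnorm(G * spec$n_extra_tumors, 0, spec$cn_sd),
             G, spec$n_extra_tumors)
    ex_x <- mu_g + sgn * spec$expr_shift * spec$expr_sd + 2 * dev_x +
      matrix(stats::rnorm(G * spec$n_extra_tumors, 0, 1),
             G, spec$n_extra_tumors) * expr_noise_sd
    dimnames(cn_x) <- dimnames(ex_x) <- list(genes, extra_s)
    cn_tum <- cbind(cn_tum, cn_x)
    expr_tum <- cbind(expr_tum, ex_x)
  }

  # methylation: logit-normal betas around 0.4; planted genes shift their
  # body probe by +/- beta_shift with the latent logit tied to the gene's
  # standardized tumor expression
  n_probes <- G * spec$n_probes_per_gene
  probe_ids <- paste0(rep(genes, each = spec$n_probes_per_gene), "_p",
                      rep(seq_len(spec$n_probes_per_gene), times = G))
  probe_gene <- rep(genes, each = spec$n_probes_per_gene)
  probe_region <- rep(c("body", rep("other", spec$n_probes_per_gene - 1L)),
                      times = G)
  annot <- probe_annotation(data.frame(
    probe_id = probe_ids, gene = probe_gene, region = probe_region,
    stringsAsFactors = FALSE))

  base_logit <- stats::qlogis(0.4)
  meth_nor <- stats::plogis(
    base_logit + matrix(stats::rnorm(n_probes * P, 0, spec$beta_logit_sd),
                        n_probes, P))
  dimnames(meth_nor) <- list(probe_ids, nor_s)
  z_expr <- t(scale(t(expr_tum[, tum_s, drop = FALSE])))
  probe_sgn <- sgn[match(probe_gene, genes)] *
    as.integer(probe_region == "body")
  target <- stats::plogis(base_logit) + probe_sgn * spec$beta_shift
  lat <- stats::qlogis(pmin(pmax(target, 0.02), 0.98)) +
    0.8 * (probe_sgn != 0) * z_expr[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(n_probes * P, 0, spec$beta_logit_sd), n_probes, P)
  meth_tum <- stats::plogis(lat)
  dimnames(meth_tum) <- list(probe_ids, tum_s)

  # mutations: recurrent missense for oncogenes, distinct nonsense for
  # suppressors, sparse distinct background elsewhere
  mut_rows <- list()
  for (i in seq_len(G)) {
    g <- genes[i]
    base_pos <- i * 10000L
    if (role[i] == "oncogene") {
      smp <- sample(tum_s, min(spec$mut_recurrent, P))
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        gene = g, sample_id = smp, variant_class = "missense",
        chrom = "1", pos = base_pos, ref = "A", alt = "T",
        stringsAsFactors = FALSE)
    } else if (role[i] == "tumor_suppressor") {
      k <- min(spec$mut_truncating, P)
      smp <- sample(tum_s, k)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        gene = g, sample_id = smp, variant_class = "nonsense",
        chrom = "1", pos = base_pos + seq_len(k), ref = "C", alt = "G",
        stringsAsFactors = FALSE)
    }
    k_bg <- stats::rpois(1L, spec$mut_background)
    if (k_bg > 0L) {
      cls <- sample(c("missense", "other", "nonsense"), k_bg,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        gene = g, sample_id = sample(tum_s, k_bg, replace = TRUE),
        variant_class = cls, chrom = "1",
        pos = base_pos + 1000L + seq_len(k_bg), ref = "G", alt = "A",
        stringsAsFactors = FALSE)
    }
  }
  mutations <- mutation_table(do.call(rbind, mut_rows))

  screen <- NULL
  if (spec$n_line_types > 0L && spec$n_lines_per_type > 0L) {
    types <- c(spec$cancer_type,
               sprintf("OTHER%d", seq_len(max(spec$n_line_types - 1L, 0L))))
    lines <- sprintf("CL%03d", seq_len(spec$n_line_types *
                                         spec$n_lines_per_type))
    line_type <- stats::setNames(rep(types, each = spec$n_lines_per_type),
                                 lines)
    viab <- matrix(stats::rnorm(G * length(lines)), G, length(lines),
                   dimnames = list(genes, lines))
    target_lines <- lines[line_type == spec$cancer_type]
    viab[og_genes, target_lines] <-
      viab[og_genes, target_lines] - spec$viability_shift
    viab[ts_genes, target_lines] <-
      viab[ts_genes, target_lines] + spec$viability_shift
    screen <- shrna_screen(omics_matrix(viab, "shrna"),
                           stats::setNames(rep(1L, G), genes), line_type)
  }

  truth <- data.frame(gene = genes, role = role, stringsAsFactors = FALSE)
  bundle <- list(cancer_type = spec$cancer_type, sample_map = map,
                 expr_tumor = omics_matrix(expr_tum, "expression"),
                 expr_normal = omics_matrix(expr_nor, "expression"),
                 cn_tumor = omics_matrix(cn_tum, "cna"),
                 cn_normal = omics_matrix(cn_nor, "cna"),
                 meth_tumor = omics_matrix(meth_tum, "methylation"),
                 meth_normal = omics_matrix(meth_nor, "methylation"),
                 probe_annotation = annot,
                 mutations = mutations,
                 screen = screen,
                 truth = truth, spec = spec)
  if (!is.null(dir)) write_cohort(bundle, dir)
  bundle
}

#' Write a generated cohort as its external file formats
#'
#' @param bundle Output of [generate_cohort()].
#' @param dir Directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  write_matrix(bundle$expr_tumor, file.path(dir, "expr_tumor.tsv"), "gene")
  write_matrix(bundle$expr_normal, file.path(dir, "expr_normal.tsv"), "gene")
  write_matrix(bundle$cn_tumor, file.path(dir, "cn_tumor.tsv"), "gene")
  write_matrix(bundle$cn_normal, file.path(dir, "cn_normal.tsv"), "gene")
  write_matrix(bundle$meth_tumor, file.path(dir, "meth_tumor.tsv"),
               "probe_id")
  write_matrix(bundle$meth_normal, file.path(dir, "meth_normal.tsv"),
               "probe_id")
  w(as.data.frame(bundle$sample_map), "sample_map.tsv")
  w(as.data.frame(bundle$probe_annotation), "probe_annotation.tsv")
  maf <- data.frame(
    Hugo_Symbol = bundle$mutations$gene,
    Tumor_Sample_Barcode = bundle$mutations$sample_id,
    Variant_Classification = maf_label(bundle$mutations$variant_class),
    Chromosome = bundle$mutations$chrom,
    Start_Position = bundle$mutations$pos,
    Reference_Allele = bundle$mutations$ref,
    Tumor_Seq_Allele2 = bundle$mutations$alt,
    stringsAsFactors = FALSE)
  w(maf, "mutations.maf")
  if (!is.null(bundle$screen)) {
    write_matrix(bundle$screen$viability, file.path(dir, "viability.tsv"),
                 "gene")
    w(data.frame(gene = names(bundle$screen$gene_solution_count),
                 n_solutions = unname(bundle$screen$gene_solution_count)),
      "gene_solutions.tsv")
    w(data.frame(cell_line = names(bundle$screen$line_type),
                 cancer_type = unname(bundle$screen$line_type)),
      "line_types.tsv")
  }
  w(bundle$truth, "truth.tsv")
  invisible(dir)
}

# inverse of the MAF -> vocabulary mapping, for writing MAF files
maf_label <- function(variant_class) {
  rev_map <- stats::setNames(names(maf_class_map), unname(maf_class_map))
  out <- unname(rev_map[variant_class])
  out[is.na(out)] <- "Silent"
  out
}
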