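#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: an LD-block
#' reference panel (one independent block per gene), GWAS summary statistics
#' for two traits with planted associations at shared causal genes, and
#' case-control expression studies with planted log2 fold changes.
#'
#' Defaults describe the conditions used throughout the package's
#' validation: a 503-individual panel (the size of the 1000 Genomes
#' European reference the method emulates), 200 genes of 10 SNPs with
#' strong within-block LD (latent AR(1) rho = 0.8), minor-allele
#' frequencies Uniform(0.05, 0.5), five shared causal genes at per-SNP
#' noncentrality 4, and four expression studies sized like typical
#' case-control series (12/15, 10/10, 39/24, 69/23) with sigma = 0.5 and
#' planted logFC = 1 at the causal genes.
#'
#' @param seed Master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_individuals Panel size.
#' @param n_genes Number of gene blocks.
#' @param snps_per_gene SNPs per block.
#' @param ld_rho Latent AR(1) correlation of adjacent SNPs within a block,
#'   in \[0, 1).
#' @param maf_range Range of allele frequencies, drawn uniformly per SNP.
#' @param causal_genes Genes causal in both traits.
#' @param causal_lambda Per-SNP noncentrality (mean of the association
#'   z-score) at causal genes.
#' @param expression_design List of per-study designs, each a list with
#'   `study_id`, `disease`, `n_case`, `n_control`, `sigma`.
#' @param planted_logfc Named numeric vector of log2 fold changes planted in
#'   every expression study (default: 1 at each causal gene).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_individuals = 503,
                       n_genes = 200,
                       snps_per_gene = 10,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       causal_genes = gene_symbols(min(5, n_genes)),
                       causal_lambda = 4,
                       expression_design = default_expression_design(),
                       planted_logfc = setNames(rep(1, length(causal_genes)),
                                                causal_genes)) {
  stopifnot(ld_rho >= 0, ld_rho < 1, n_individuals >= 1, n_genes >= 1,
            snps_per_gene >= 1, causal_lambda >= 0,
            all(causal_genes %in% gene_symbols(n_genes)))
  structure(list(seed = seed, n_individuals = n_individuals,
                 n_genes = n_genes, snps_per_gene = snps_per_gene,
                 ld_rho = ld_rho, maf_range = maf_range,
                 causal_genes = causal_genes, causal_lambda = causal_lambda,
                 expression_design = expression_design,
                 planted_logfc = planted_logfc),
            class = "sim_config")
}

gene_symbols <- function(n) sprintf("G%03d", seq_len(n))

default_expression_design <- function(sigma = 0.5) {
  list(
    list(study_id = "STUDY_MS1", disease = "MS", n_case = 12,
         n_control = 15, sigma = sigma),
    list(study_id = "STUDY_MS2", disease = "MS", n_case = 10,
         n_control = 10, sigma = sigma),
    list(study_id = "STUDY_IS1", disease = "IS", n_case = 39,
         n_control = 24, sigma = sigma),
    list(study_id = "STUDY_IS2", disease = "IS", n_case = 69,
         n_control = 23, sigma = sigma)
  )
}

ar1_chol <- function(n, rho) {
  if (n == 1) return(matrix(1, 1, 1))
  chol(rho^abs(outer(seq_len(n), seq_len(n), "-")))
}

#' Generate an LD-structured reference panel and gene annotation
#'
#' Haplotypes are drawn per gene block from an AR(1) Gaussian copula with
#' parameter `ld_rho`, thresholded at per-SNP allele frequencies drawn from
#' `maf_range`, and summed into diploid dosages. Blocks are mutually
#' independent; each gene interval covers exactly its block's SNP positions.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (default `config$seed`).
#' @return List with `panel` (a [ref_panel()], whose map carries a `block`
#'   column naming each SNP's gene) and `genes` (annotation tibble).
#' @export
make_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$snps_per_gene
  L <- ar1_chol(s, config$ld_rho)
  with_seed(gene_seed(seed, "panel"), {
    blocks <- lapply(seq_len(config$n_genes), function(g) {
      freq <- runif(s, config$maf_range[1], config$maf_range[2])
      thr <- qnorm(1 - freq)
      hap <- function() {
        z <- matrix(rnorm(config$n_individuals * s),
                    config$n_individuals, s) %*% L
        sweep(z, 2, thr, ">") * 1
      }
      hap() + hap()
    })
    dosages <- do.call(cbind, blocks)
  })
  genes <- gene_symbols(config$n_genes)
  pos <- as.integer(outer(seq_len(s) * 1000L, (seq_len(config$n_genes) - 1L) *
                            1000000L, "+"))
  map <- tibble::tibble(
    rsid = sprintf("rs%d", seq_len(config$n_genes * s)),
    chrom = "1", pos = pos, block = rep(genes, each = s)
  )
  anno <- map |>
    dplyr::group_by(gene = .data$block) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$pos),
                     end = max(.data$pos), .groups = "drop")
  list(panel = ref_panel(dosages, map), genes = anno)
}

#' Generate GWAS summary statistics from a panel
#'
#' Per block, association z-scores are drawn from MVN(lambda, Sigma), where
#' Sigma is the block's realised dosage correlation matrix and lambda is the
#' per-SNP noncentrality (0 at non-causal genes). P-values are two-sided
#' normal tails, matching the summary-statistic abstraction the gene test
#' consumes: under the null they are uniform and LD-correlated exactly as
#' the panel dictates.
#'
#' @param panel_set A `list(panel, genes)` from [make_panel()].
#' @param config A [sim_config()].
#' @param seed Seed for this trait's draw (use different seeds for
#'   different traits).
#' @return Tibble of `rsid`, `chrom`, `pos`, `pvalue`.
#' @export
make_gwas <- function(panel_set, config, seed = config$seed) {
  panel <- panel_set$panel
  map <- panel$map
  stopifnot("block" %in% names(map))
  blocks <- split(seq_len(nrow(map)), map$block)
  z <- numeric(nrow(map))
  for (g in names(blocks)) {
    idx <- blocks[[g]]
    sigma <- suppressWarnings(ld_matrix(panel, map$rsid[idx]))
    lam <- if (g %in% config$causal_genes) config$causal_lambda else 0
    kept <- match(colnames(sigma), map$rsid)
    L <- chol(sigma)
    zg <- with_seed(gene_seed(seed, g, salt = 7L),
                    as.vector(rnorm(ncol(sigma)) %*% L) + lam)
    z[kept] <- zg
    dropped <- setdiff(idx, kept)
    if (length(dropped) > 0) {
      z[dropped] <- with_seed(gene_seed(seed, g, salt = 11L),
                              rnorm(length(dropped))) + lam
    }
  }
  tibble::tibble(rsid = map$rsid, chrom = map$chrom, pos = map$pos,
                 pvalue = 2 * pnorm(-abs(z)))
}

#' Generate case-control expression studies with planted fold changes
#'
#' Log2 expression values are Normal(mu_gene, sigma^2) with per-gene
#' baselines Normal(8, 2); case samples are shifted by the planted logFC.
#' Noise is independent across studies.
#'
#' @param config A [sim_config()]; uses `expression_design` and
#'   `planted_logfc`.
#' @param seed Seed override (default `config$seed`).
#' @return List of [expression_study()] objects.
#' @export
make_expression <- function(config, seed = config$seed) {
  genes <- gene_symbols(config$n_genes)
  logfc <- setNames(rep(0, length(genes)), genes)
  pl <- config$planted_logfc
  logfc[names(pl)] <- pl
  baseline <- with_seed(gene_seed(seed, "baseline"),
                        rnorm(length(genes), mean = 8, sd = 2))
  lapply(config$expression_design, function(d) {
    n <- d$n_case + d$n_control
    mat <- with_seed(gene_seed(seed, d$study_id), {
      noise <- matrix(rnorm(length(genes) * n, sd = d$sigma),
                      length(genes), n)
      baseline + noise
    })
    groups <- rep(c("case", "control"), c(d$n_case, d$n_control))
    mat[, groups == "case"] <- mat[, groups == "case"] + logfc
    rownames(mat) <- genes
    colnames(mat) <- sprintf("%s_S%02d", d$study_id, seq_len(n))
    expression_study(mat, groups, study_id = d$study_id, disease = d$disease)
  })
}

#' Generate every input the pipeline needs
#'
#' Convenience wrapper producing one reference panel with annotation, two
#' trait GWAS (independent draws sharing the panel LD and the causal-gene
#' truth), the expression studies, and the generating truth.
#'
#' @param config A [sim_config()].
#' @return List: `panel`, `genes`, `gwas_a`, `gwas_b`, `studies`, `truth`
#'   (list of `causal_genes` and `planted_logfc`).
#' @export
sim_pipeline_inputs <- function(config = sim_config()) {
  ps <- make_panel(config)
  list(panel = ps$panel, genes = ps$genes,
       gwas_a = make_gwas(ps, config, seed = gene_seed(config$seed, "traitA")),
       gwas_b = make_gwas(ps, config, seed = gene_seed(config$seed, "traitB")),
       studies = make_expression(config),
       truth = list(causal_genes = config$causal_genes,
                    planted_logfc = config$planted_logfc))
}
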