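#' Run the full shared-gene discovery pipeline
#'
#' Chains the three stages: gene-based tests for both traits, Fisher
#' cross-trait meta-analysis with the layered Bonferroni filter, and (when
#' expression studies are supplied) the differential-expression concordance
#' stage restricted to the meta-significant genes.
#'
#' @param gwas_a,gwas_b Summary-statistic tibbles (`rsid`, `pvalue`).
#' @param genes Gene annotation tibble.
#' @param panel A [ref_panel()].
#' @param studies Optional list of [expression_study()] objects (two
#'   diseases); when `NULL` the expression stage is skipped.
#' @param alpha Nominal and family-wise level used at every stage.
#' @param bonferroni_factor Extra layer for the combined-p threshold.
#' @param seed Master seed for the simulation nulls.
#' @param ... Passed on to [run_gene_test()] (e.g. `max_sims`, `stages`,
#'   `padding_bp`, `r2_link`).
#' @return List: `scan_a`, `scan_b` (per-trait `pleio_gene_scan`), `meta`
#'   (`pleio_meta`), `shared_genes` (meta-significant symbols), `de`
#'   (`pleio_de` or `NULL`), `final_genes` (shared-significant at the
#'   expression stage, or `NULL`).
#' @export
run_pipeline <- function(gwas_a, gwas_b, genes, panel, studies = NULL,
                         alpha = 0.05, bonferroni_factor = 2, seed = 1, ...) {
  scan_a <- run_gene_test(gwas_a, genes, panel,
                          seed = gene_seed(seed, "traitA"), ...)
  scan_b <- run_gene_test(gwas_b, genes, panel,
                          seed = gene_seed(seed, "traitB"), ...)
  meta <- run_meta(scan_a, scan_b, alpha = alpha,
                   bonferroni_factor = bonferroni_factor)
  shared_genes <- meta$gene[meta$significant]
  de <- NULL
  final <- NULL
  if (!is.null(studies) && length(shared_genes) > 0) {
    de <- run_de(studies, genes = shared_genes, alpha = alpha)
    final <- de$shared$gene[de$shared$shared_significant]
  }
  list(scan_a = scan_a, scan_b = scan_b, meta = meta,
       shared_genes = shared_genes, de = de, final_genes = final)
}
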