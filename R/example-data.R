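#' Paths to bundled example data
#'
#' The package ships three small plain-text tables of published multiple
#' sclerosis (MS) / ischemic stroke (IS) shared-gene results, used in the
#' vignette, the tests and the acceptance script:
#'
#' * `ms_is_shared_genes.tsv` — the 24 genes nominally associated with both
#'   traits: per-trait gene-based p-values (from VEGAS2-style analyses of
#'   large MS and IS GWAS), SNP counts, top SNPs, and the published
#'   Fisher-combined p-value.
#' * `ms_is_expression_pvalues.tsv` — differential-expression p-values for
#'   those 24 genes across four GEO case-control series (two MS, two IS);
#'   `NA` marks genes absent from a platform.
#' * `ms_is_shared_expression.tsv` — p-value / logFC pairs for the five
#'   genes significant in at least one study of each disease.
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' pleio_example()
#' readr::read_tsv(pleio_example("ms_is_shared_genes.tsv"),
#'                 show_col_types = FALSE)
pleio_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pleioscan")))
  }
  path <- system.file("extdata", file, package = "pleioscan")
  if (path == "") stop("no such example file: ", file, call. = FALSE)
  path
}
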