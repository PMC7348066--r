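# Fixture builders shared across test files. Everything is generated in code;
# no binary data.

# Panel with explicitly supplied dosage columns.
panel_from_dosages <- function(..., chrom = "1") {
  cols <- list(...)
  mat <- do.call(cbind, cols)
  map <- tibble::tibble(rsid = names(cols), chrom = chrom,
                        pos = seq_along(cols) * 100L)
  ref_panel(mat, map)
}

# Panel of independent binomial(2, maf) SNPs.
random_panel <- function(n_ind, mafs, seed = 1, pos = seq_along(mafs) * 100L,
                         chrom = "1") {
  mat <- pleioscan:::with_seed(seed, {
    vapply(mafs, function(f) stats::rbinom(n_ind, 2, f), numeric(n_ind))
  })
  colnames(mat) <- sprintf("snp%d", seq_along(mafs))
  ref_panel(mat, tibble::tibble(rsid = colnames(mat), chrom = chrom,
                                pos = as.integer(pos)))
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Published shared-gene tables bundled with the package.
shared_gene_table <- function() {
  readr::read_tsv(pleio_example("ms_is_shared_genes.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

expression_p_long <- function() {
  wide <- readr::read_tsv(pleio_example("ms_is_expression_pvalues.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  long <- tidyr::pivot_longer(wide, -gene, names_to = "study_id",
                              values_to = "pvalue")
  long$disease <- ifelse(long$study_id %in% c("GSE21942", "GSE43591"),
                         "MS", "IS")
  long
}

# Expression study from case/control value matrices (genes in rows).
study_from_groups <- function(case, ctrl, study_id = "S1", disease = "D1",
                              genes = sprintf("g%d", seq_len(nrow(case)))) {
  mat <- cbind(case, ctrl)
  rownames(mat) <- genes
  colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  expression_study(mat, rep(c("case", "control"), c(ncol(case), ncol(ctrl))),
                   study_id = study_id, disease = disease)
}
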