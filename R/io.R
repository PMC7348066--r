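#' Read GWAS summary statistics (rsID + p-value)
#'
#' Parses a whitespace- or tab-delimited table of per-SNP association
#' results. Two to four columns are accepted: `rsid`, `pvalue` and optionally
#' `chrom`, `pos`. A header line is auto-detected (the second field of the
#' first line is non-numeric). Duplicated rsIDs keep their first occurrence;
#' p-values of exactly zero are clamped to `p_floor` because the downstream
#' 1-df chi-square quantile diverges at zero.
#'
#' @param path Path to the summary-statistic file.
#' @param p_floor Positive floor applied to p-values of exactly 0.
#' @return A tibble with columns `rsid`, `pvalue` and, when present in the
#'   file, `chrom` and `pos`.
#' @export
read_gwas_summary <- function(path, p_floor = 1e-300) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) stop("empty GWAS summary file: ", path, call. = FALSE)

  toks <- strsplit(trimws(lines), "\\s+")
  ncol1 <- length(toks[[1]])
  if (ncol1 < 2 || ncol1 > 4) {
    stop("expected 2-4 columns (rsid, p[, chrom, pos]); line 1 has ",
         ncol1, call. = FALSE)
  }
  has_header <- is.na(suppressWarnings(as.numeric(toks[[1]][2])))
  if (has_header) {
    toks <- toks[-1]
    line_no <- line_no[-1]
    if (length(toks) == 0) stop("GWAS summary file has a header but no data: ",
                                path, call. = FALSE)
  }

  nfield <- lengths(toks)
  if (any(nfield != ncol1)) {
    bad <- which(nfield != ncol1)[1]
    stop("line ", line_no[bad], ": expected ", ncol1, " fields, found ",
         nfield[bad], call. = FALSE)
  }
  mat <- matrix(unlist(toks), ncol = ncol1, byrow = TRUE)

  p <- suppressWarnings(as.numeric(mat[, 2]))
  if (any(is.na(p))) {
    bad <- which(is.na(p))[1]
    stop("line ", line_no[bad], ": unparseable p-value '", mat[bad, 2], "'",
         call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    bad <- which(p < 0 | p > 1)[1]
    stop("line ", line_no[bad], ": p-value ", p[bad], " outside [0, 1]",
         call. = FALSE)
  }
  n_zero <- sum(p == 0)
  if (n_zero > 0) {
    warning(n_zero, " p-value(s) of exactly 0 clamped to ", p_floor,
            call. = FALSE)
    p[p == 0] <- p_floor
  }

  out <- tibble::tibble(rsid = mat[, 1], pvalue = p)
  if (ncol1 >= 3) out$chrom <- mat[, 3]
  if (ncol1 == 4) {
    pos <- suppressWarnings(as.integer(mat[, 4]))
    if (any(is.na(pos))) {
      bad <- which(is.na(pos))[1]
      stop("line ", line_no[bad], ": unparseable position '", mat[bad, 4], "'",
           call. = FALSE)
    }
    out$pos <- pos
  }

  dup <- duplicated(out$rsid)
  if (any(dup)) {
    warning(sum(dup), " duplicated rsID(s) dropped (first occurrence kept)",
            call. = FALSE)
    out <- out[!dup, ]
  }
  out
}

#' Read a gene annotation table
#'
#' Accepts either BED (`chrom start end gene`, 0-based half-open) or a
#' 1-based inclusive dialect with the same column order. Intervals are
#' stored 1-based inclusive.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` (0-based half-open) or `"onebased"` (1-based
#'   inclusive).
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, dialect = c("onebased", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty annotation file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  if (is.na(suppressWarnings(as.numeric(toks[[1]][2])))) toks <- toks[-1]
  if (any(lengths(toks) < 4)) {
    stop("annotation rows need 4 fields: chrom start end gene", call. = FALSE)
  }
  mat <- matrix(unlist(lapply(toks, `[`, 1:4)), ncol = 4, byrow = TRUE)
  start <- as.numeric(mat[, 2])
  end <- as.numeric(mat[, 3])
  if (dialect == "bed") start <- start + 1
  if (any(is.na(start) | is.na(end))) {
    stop("unparseable interval coordinates in ", path, call. = FALSE)
  }
  if (any(start > end)) {
    bad <- which(start > end)[1]
    stop("gene ", mat[bad, 4], ": start ", start[bad], " > end ", end[bad],
         call. = FALSE)
  }
  if (anyDuplicated(mat[, 4])) {
    stop("duplicated gene symbol(s): ",
         paste(unique(mat[duplicated(mat[, 4]), 4]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(gene = mat[, 4], chrom = mat[, 1],
                 start = as.integer(start), end = as.integer(end))
}

#' Construct an expression study
#'
#' Bundles a genes x samples matrix of log2 expression with case/control
#' labels and study metadata. Expression is assumed already log2-scaled and
#' normalised upstream.
#'
#' @param mat Numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param groups Character or factor of `"case"`/`"control"`, one per sample
#'   column (named vectors are matched to column names).
#' @param study_id Study label, e.g. a GEO series accession.
#' @param disease Trait label the study belongs to.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(mat, groups, study_id, disease) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat))) {
    stop("gene identifiers must be unique", call. = FALSE)
  }
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing) > 0) {
      stop("sample(s) without a group label: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    groups <- groups[colnames(mat)]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    stop("one group label per sample column required", call. = FALSE)
  }
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'", call. = FALSE)
  }
  if (any(table(factor(groups, c("case", "control"))) < 2)) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  all_na <- rowSums(!is.na(mat)) == 0
  if (any(all_na)) {
    stop("all-missing gene row(s): ",
         paste(head(rownames(mat)[all_na], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(study_id = study_id, disease = disease, matrix = mat,
         groups = groups,
         incomplete_genes = rownames(mat)[rowSums(is.na(mat)) > 0]),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", x$study_id, " (", x$disease, "): ",
      nrow(x$matrix), " genes x ", ncol(x$matrix), " samples (",
      sum(x$groups == "case"), " case / ", sum(x$groups == "control"),
      " control)\n", sep = "")
  invisible(x)
}

#' Read a genes x samples expression matrix
#'
#' Tab-separated, first column gene identifiers, remaining columns samples.
#' Duplicated gene identifiers are disambiguated with a numeric suffix (GEO
#' probes map many-to-one onto symbols); rows with missing values are kept
#' and flagged on the returned study.
#'
#' @param path Path to the TSV file.
#' @param labels Named character vector mapping every sample column to
#'   `"case"` or `"control"`.
#' @inheritParams expression_study
#' @return An [expression_study()].
#' @export
read_expression_matrix <- function(path, labels, study_id = basename(path),
                                   disease = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  missing <- setdiff(names(labels), colnames(mat))
  if (length(missing) > 0) {
    stop("labelled sample(s) absent from header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unlabelled <- setdiff(colnames(mat), names(labels))
  if (length(unlabelled) > 0) {
    stop("sample column(s) without labels: ",
         paste(unlabelled, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)),
            " duplicated gene identifier(s) suffix-disambiguated",
            call. = FALSE)
    genes <- make.unique(genes, sep = ".")
  }
  rownames(mat) <- genes
  expression_study(mat, labels, study_id = study_id, disease = disease)
}

#' Write a results table with formatted p-values
#'
#' Writes a TSV in which every p-value column (names matching `p`/`pvalue`
#' conventions) is rendered in scientific notation at three significant
#' figures; all other columns are written untouched. Reading such a file
#' back reproduces p-values to the printed precision.
#'
#' @param df Results tibble.
#' @param path Output path.
#' @return `df`, invisibly.
#' @export
write_results_table <- function(df, path) {
  is_p <- grepl("(^|_)p($|_)|pvalue|p_value", names(df), ignore.case = TRUE) &
    vapply(df, is.numeric, logical(1))
  out <- df
  out[is_p] <- lapply(df[is_p], format_pvalue)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(df)
}
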