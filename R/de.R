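#' Case-control differential expression for one study
#'
#' Per gene: logFC = mean(case) - mean(control) on the log2 scale, plus a
#' two-sided two-sample test. The default is the pooled-variance t-test
#' (the unmoderated core of the standard microarray linear-model workflow);
#' `welch_t` relaxes equal variances; `moderated_t` applies empirical-Bayes
#' variance shrinkage via limma. Missing values are handled complete-case
#' within each group; a gene with fewer than two usable samples in either
#' group gets an NA result and is flagged.
#'
#' @param study An [expression_study()].
#' @param genes Genes to test (default: all genes in the study).
#' @param method `"pooled_t"`, `"welch_t"` or `"moderated_t"`.
#' @return Tibble with one row per gene: `gene`, `study_id`, `disease`,
#'   `logfc`, `t_stat`, `df`, `pvalue`, `flagged`.
#' @export
de_test <- function(study, genes = NULL,
                    method = c("pooled_t", "welch_t", "moderated_t")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  mat <- study$matrix
  if (!is.null(genes)) {
    mat <- mat[rownames(mat) %in% genes, , drop = FALSE]
  }
  case <- mat[, study$groups == "case", drop = FALSE]
  ctrl <- mat[, study$groups == "control", drop = FALSE]

  if (method == "moderated_t") {
    res <- moderated_de(case, ctrl)
  } else {
    n1 <- rowSums(!is.na(case))
    n2 <- rowSums(!is.na(ctrl))
    m1 <- rowMeans(case, na.rm = TRUE)
    m2 <- rowMeans(ctrl, na.rm = TRUE)
    v1 <- row_var(case, n1, m1)
    v2 <- row_var(ctrl, n2, m2)
    d <- m1 - m2
    if (method == "pooled_t") {
      df <- n1 + n2 - 2
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    } else {
      a <- v1 / n1
      b <- v2 / n2
      se <- sqrt(a + b)
      df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    }
    t_stat <- ifelse(se == 0 & d == 0, 0, d / se)
    p <- 2 * pt(-abs(t_stat), df)
    p <- pmin(pmax(p, 1e-300), 1)
    res <- tibble::tibble(gene = rownames(mat), logfc = unname(d),
                          t_stat = unname(t_stat), df = unname(df),
                          pvalue = unname(p))
    bad <- n1 < 2 | n2 < 2
    res$logfc[bad] <- NA_real_
    res$t_stat[bad] <- NA_real_
    res$pvalue[bad] <- NA_real_
    res$flagged <- bad
  }
  res$study_id <- study$study_id
  res$disease <- study$disease
  dplyr::relocate(res, "study_id", "disease", .after = "gene")
}

row_var <- function(x, n, m) {
  ss <- rowSums(x^2, na.rm = TRUE)
  pmax(ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_), 0)
}

# Empirical-Bayes moderated t via limma on a two-group design.
moderated_de <- function(case, ctrl) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop("method 'moderated_t' needs the limma package", call. = FALSE)
  }
  mat <- cbind(case, ctrl)
  design <- cbind(intercept = 1,
                  case = rep(c(1, 0), c(ncol(case), ncol(ctrl))))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  n1 <- rowSums(!is.na(case))
  n2 <- rowSums(!is.na(ctrl))
  bad <- n1 < 2 | n2 < 2
  tibble::tibble(gene = rownames(mat),
                 logfc = unname(fit$coefficients[, "case"]),
                 t_stat = unname(fit$t[, "case"]),
                 df = unname(fit$df.total),
                 pvalue = unname(pmin(pmax(fit$p.value[, "case"], 1e-300), 1)),
                 flagged = unname(bad))
}

#' Classify genes as shared-significant across two diseases
#'
#' Applies the Bonferroni threshold `alpha / n_genes` (strict `<`) to a long
#' table of per-gene, per-study differential-expression p-values. A gene is
#' `any_significant` if it clears the threshold in at least one study, and
#' `shared_significant` if it does so in at least one study of *each*
#' disease. NA p-values (gene absent or untestable in a study) are ignored
#' in the minima; a gene absent from every study of a disease cannot be
#' shared-significant.
#'
#' @param de_tbl Tibble with columns `gene`, `study_id`, `disease`,
#'   `pvalue` (e.g. bound rows of [de_test()] results).
#' @param n_genes Bonferroni denominator G; defaults to the number of
#'   distinct genes in `de_tbl`.
#' @param alpha Family-wise error rate.
#' @return A `pleio_shared` tibble with one row per gene: `gene`, one
#'   `min_p_<disease>` column per disease, `min_p`, `any_significant`,
#'   `shared_significant`. Attributes `threshold`, `n_genes`.
#' @export
classify_shared <- function(de_tbl, n_genes = NULL, alpha = 0.05) {
  de_tbl <- tibble::as_tibble(de_tbl)
  stopifnot(all(c("gene", "disease", "pvalue") %in% names(de_tbl)))
  diseases <- sort(unique(de_tbl$disease))
  if (length(diseases) != 2) {
    stop("exactly two diseases required, found: ",
         paste(diseases, collapse = ", "), call. = FALSE)
  }
  if (is.null(n_genes)) n_genes <- dplyr::n_distinct(de_tbl$gene)
  thr <- alpha / n_genes

  safe_min <- function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) NA_real_ else min(p)
  }
  wide <- de_tbl |>
    dplyr::group_by(.data$gene, .data$disease) |>
    dplyr::summarise(min_p = safe_min(.data$pvalue), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "disease", values_from = "min_p",
                       names_prefix = "min_p_")
  cols <- paste0("min_p_", diseases)
  per_dis <- as.matrix(wide[, cols])
  sig <- !is.na(per_dis) & per_dis < thr
  out <- wide |>
    dplyr::mutate(
      min_p = suppressWarnings(apply(per_dis, 1, safe_min)),
      any_significant = rowSums(sig) > 0,
      shared_significant = rowSums(sig) == 2
    ) |>
    dplyr::arrange(.data$gene)
  structure(out, threshold = thr, n_genes = as.integer(n_genes),
            alpha = alpha, diseases = diseases,
            class = c("pleio_shared", class(out)))
}

#' Differential-expression stage of the pipeline
#'
#' Runs [de_test()] for every study, classifies genes with
#' [classify_shared()], and reports, per gene and disease, the study with
#' the smallest p-value (the representative result carried forward for a
#' shared gene).
#'
#' @param studies List of [expression_study()] objects covering exactly two
#'   diseases, at least one study per disease.
#' @param genes Genes to test (default: genes present in any study).
#' @param alpha Family-wise error rate for the Bonferroni threshold
#'   `alpha / G`, where G is the number of genes under test.
#' @param method Test passed to [de_test()].
#' @return A `pleio_de` list: `de` (long per-gene x study results),
#'   `shared` (the [classify_shared()] verdicts), `best` (per gene and
#'   disease, the smallest-p study row), `threshold`.
#' @export
run_de <- function(studies, genes = NULL, alpha = 0.05,
                   method = c("pooled_t", "welch_t", "moderated_t")) {
  method <- match.arg(method)
  stopifnot(length(studies) >= 2,
            all(vapply(studies, inherits, logical(1), "expression_study")))
  if (length(unique(vapply(studies, `[[`, character(1), "disease"))) != 2) {
    stop("studies must cover exactly two diseases", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(studies,
                                       function(s) rownames(s$matrix)))))
  }
  de <- purrr::map_dfr(studies, de_test, genes = genes, method = method)
  shared <- classify_shared(de, n_genes = length(genes), alpha = alpha)
  best <- de |>
    dplyr::filter(!is.na(.data$pvalue)) |>
    dplyr::group_by(.data$gene, .data$disease) |>
    dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene, .data$disease)
  structure(list(de = de, shared = shared, best = best,
                 threshold = attr(shared, "threshold")),
            class = "pleio_de")
}

#' @export
print.pleio_de <- function(x, ...) {
  cat("<pleio_de> ", dplyr::n_distinct(x$de$gene), " genes x ",
      dplyr::n_distinct(x$de$study_id), " studies; threshold ",
      format_pvalue(x$threshold), "; ",
      sum(x$shared$shared_significant), " shared-significant gene(s)\n",
      sep = "")
  invisible(x)
}
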