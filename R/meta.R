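#' Fisher's combined probability test
#'
#' Combines k independent p-values via the statistic
#' x^2 = -2 * sum(ln p_i), referred to a chi-square distribution with 2k
#' degrees of freedom.
#'
#' @param p Numeric vector of k >= 1 p-values in (0, 1\].
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' fisher_combine(c(8.34e-4, 1.39e-3))
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1)
  stopifnot_prob(p, "p")
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  pc <- max(pchisq(x2, df = df, lower.tail = FALSE), .Machine$double.xmin)
  tibble::tibble(statistic = x2, df = df, p_value = pc)
}

#' Genes nominally significant in both traits
#'
#' @param results_a,results_b Per-gene result tables with a `gene` column
#'   and a p-value column (`empirical_p`, `p_value`, `pvalue` or `p`).
#' @param alpha Nominal level; strict `<` on both sides.
#' @return Character vector of overlapping gene symbols, sorted.
#' @export
nominal_overlap <- function(results_a, results_b, alpha = 0.05) {
  pick <- function(df) {
    p <- df[[find_p_column(df)]]
    df$gene[!is.na(p) & p < alpha]
  }
  sort(intersect(pick(results_a), pick(results_b)))
}

#' Layered Bonferroni threshold
#'
#' `alpha / (factor * n_tests)`; the factor-2 layer implements the
#' two-trait family correction applied to combined p-values.
#'
#' @param n_tests Number of tests in the family.
#' @param factor Extra multiplicity layer (1 or 2).
#' @param alpha Family-wise error rate.
#' @return One-row tibble: `n_tests`, `factor`, `alpha`, `threshold`.
#' @export
#' @examples
#' bonferroni_layer(14811)$threshold    # 3.38e-06
#' bonferroni_layer(108, factor = 2)$threshold
bonferroni_layer <- function(n_tests, factor = 1, alpha = 0.05) {
  stopifnot(n_tests >= 1, factor %in% c(1, 2))
  tibble::tibble(n_tests = as.integer(n_tests), factor = as.integer(factor),
                 alpha = alpha, threshold = alpha / (factor * n_tests))
}

#' Cross-trait meta-analysis of per-gene p-values
#'
#' Intersects the genes nominally significant in both traits, combines each
#' overlapping gene's two p-values by Fisher's method, and flags genes whose
#' combined p-value falls (strictly) below the layered Bonferroni threshold
#' `alpha / (bonferroni_factor * n_overlap)`.
#'
#' @inheritParams nominal_overlap
#' @param bonferroni_factor Extra multiplicity layer applied on top of the
#'   overlap count (default 2, one layer per trait).
#' @param n_overlap Override for the Bonferroni denominator, e.g. when the
#'   supplied tables are a pre-filtered subset of a larger overlap set.
#'   Defaults to the number of overlapping genes.
#' @return A `pleio_meta` tibble with one row per overlapping gene: `gene`,
#'   `p_a`, `p_b`, additional per-trait columns suffixed `_a`/`_b` when
#'   present, `fisher_x2`, `df`, `p_combined`, `significant`. Attributes
#'   `threshold`, `n_overlap`, `alpha`, `bonferroni_factor`.
#' @export
run_meta <- function(results_a, results_b, alpha = 0.05,
                     bonferroni_factor = 2, n_overlap = NULL) {
  overlap <- nominal_overlap(results_a, results_b, alpha)
  if (is.null(n_overlap)) n_overlap <- length(overlap)
  empty <- tibble::tibble(gene = character(), p_a = double(),
                          p_b = double(), fisher_x2 = double(),
                          df = integer(), p_combined = double(),
                          significant = logical())
  if (length(overlap) == 0) {
    warning("no gene is nominally significant in both traits", call. = FALSE)
    return(new_meta(empty, NA_real_, 0L, alpha, bonferroni_factor))
  }

  side <- function(df, suffix) {
    pcol <- find_p_column(df)
    df <- tibble::as_tibble(df)[df$gene %in% overlap, ]
    keep <- setdiff(names(df), c("gene", "chrom", pcol))
    out <- df[, c("gene", pcol, keep)]
    names(out) <- c("gene", paste0("p", suffix),
                    if (length(keep)) paste0(keep, suffix))
    out
  }
  tab <- dplyr::inner_join(side(results_a, "_a"), side(results_b, "_b"),
                           by = "gene") |>
    dplyr::arrange(.data$gene)

  comb <- purrr::map2_dfr(tab$p_a, tab$p_b,
                          function(a, b) fisher_combine(c(a, b)))
  thr <- bonferroni_layer(n_overlap, factor = bonferroni_factor,
                          alpha = alpha)$threshold
  tab$fisher_x2 <- comb$statistic
  tab$df <- comb$df
  tab$p_combined <- comb$p_value
  tab$significant <- tab$p_combined < thr
  new_meta(tab, thr, n_overlap, alpha, bonferroni_factor)
}

new_meta <- function(df, threshold, n_overlap, alpha, factor) {
  structure(df, threshold = threshold, n_overlap = n_overlap, alpha = alpha,
            bonferroni_factor = factor,
            class = c("pleio_meta", class(df)))
}
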