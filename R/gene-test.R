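#' Convert a p-value to an upper-tail 1-df chi-square statistic
#'
#' Returns the value q such that the upper-tail probability of a chi-square
#' distribution with one degree of freedom at q equals `p`. This is the
#' per-SNP building block of the gene statistic.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Non-negative chi-square statistics.
#' @export
#' @examples
#' chisq_from_p(c(1, 0.05))
chisq_from_p <- function(p) {
  stopifnot_prob(p, "p")
  qchisq(p, df = 1, lower.tail = FALSE)
}

#' Observed gene statistic: sum of per-SNP 1-df chi-squares
#'
#' @param p P-values of the gene's member SNPs.
#' @return The summed chi-square statistic.
#' @export
gene_statistic <- function(p) {
  sum(chisq_from_p(p))
}

#' Assign SNPs to genes by position and LD linkage
#'
#' A SNP becomes a member of a gene if (a) its position lies within
#' `[start - padding_bp, end + padding_bp]` on the gene's chromosome
#' (boundaries inclusive), or (b) its squared dosage correlation with any
#' rule-(a) member exceeds `r2_link`. Rule (b) recruits SNPs on the same
#' chromosome only; LD against positional members is estimated from the
#' reference panel. SNPs absent from the panel are dropped (counted in a
#' message) because no LD can be estimated for them.
#'
#' @param snps Tibble of summary statistics with columns `rsid`, `pvalue`
#'   (positions are taken from the panel map).
#' @param genes Gene annotation tibble (`gene`, `chrom`, `start`, `end`).
#' @param panel A [ref_panel()].
#' @param padding_bp Symmetric window, in base pairs, added to each gene.
#' @param r2_link Squared-correlation threshold (strict `>`) for LD
#'   recruitment of outside SNPs.
#' @return Tibble with one row per (gene, member SNP): columns `gene`,
#'   `rsid`, `chrom`, `pos`, `pvalue`, `inside` (TRUE for rule-(a) members).
#'   Genes with no members simply have no rows.
#' @export
assign_snps_to_genes <- function(snps, genes, panel, padding_bp = 0,
                                 r2_link = 0.8) {
  stopifnot(inherits(panel, "ref_panel"))
  snps <- tibble::as_tibble(snps)
  in_panel <- snps$rsid %in% panel$map$rsid
  if (any(!in_panel)) {
    message(sum(!in_panel), " SNP(s) absent from the reference panel dropped")
    snps <- snps[in_panel, ]
  }
  if (nrow(snps) == 0) {
    return(tibble::tibble(gene = character(), rsid = character(),
                          chrom = character(), pos = integer(),
                          pvalue = double(), inside = logical()))
  }
  info <- dplyr::inner_join(snps[, c("rsid", "pvalue")],
                            panel$map[, c("rsid", "chrom", "pos")],
                            by = "rsid")

  # standardised dosages once, for all rule-(b) correlation lookups
  z <- impute_dosages(panel$dosages[, info$rsid, drop = FALSE])
  z <- scale(z)
  z[is.na(z)] <- 0  # monomorphic columns contribute zero correlation
  n_ind <- nrow(z)

  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    on_chrom <- info$chrom == g$chrom
    inside <- on_chrom & info$pos >= (g$start - padding_bp) &
      info$pos <= (g$end + padding_bp)
    linked <- rep(FALSE, nrow(info))
    if (any(inside) && any(on_chrom & !inside)) {
      cand <- which(on_chrom & !inside)
      r <- crossprod(z[, cand, drop = FALSE],
                     z[, which(inside), drop = FALSE]) / (n_ind - 1)
      linked[cand] <- apply(r^2, 1, max) > r2_link
    }
    keep <- inside | linked
    if (!any(keep)) return(NULL)
    tibble::tibble(gene = g$gene, rsid = info$rsid[keep],
                   chrom = info$chrom[keep], pos = info$pos[keep],
                   pvalue = info$pvalue[keep], inside = inside[keep])
  })
}

#' Simulate the LD-aware null distribution of the gene statistic
#'
#' Each replicate draws z ~ MVN(0, sigma) via the Cholesky factor of the
#' (PSD-repaired) LD matrix and returns the sum of squared components. The
#' stream is fully determined by `seed`; draws are generated in chunks to
#' bound memory.
#'
#' @param sigma LD correlation matrix (see [ld_matrix()]).
#' @param m Number of simulations.
#' @param seed RNG seed for this stream.
#' @return Numeric vector of `m` null statistics.
#' @export
simulate_null <- function(sigma, m, seed = 1) {
  sigma <- as.matrix(sigma)
  n <- nrow(sigma)
  stopifnot(m >= 1, n >= 1)
  L <- chol(sigma)  # upper-triangular; rows of Z %*% L are MVN(0, sigma)
  out <- numeric(m)
  with_seed(seed, {
    done <- 0L
    chunk <- 250000L
    while (done < m) {
      k <- min(chunk, m - done)
      zz <- matrix(rnorm(k * n), k, n) %*% L
      out[(done + 1):(done + k)] <- rowSums(zz^2)
      done <- done + k
    }
  })
  out
}

#' Empirical p-value from null simulations
#'
#' `(r + 1) / (m + 1)` where r counts null statistics strictly exceeding
#' the observed one (ties do not count as surpassing).
#'
#' @param observed Observed gene statistic.
#' @param nulls Vector of simulated null statistics.
#' @return The empirical p-value, in `[1/(m+1), 1]`.
#' @export
empirical_p <- function(observed, nulls) {
  (sum(nulls > observed) + 1) / (length(nulls) + 1)
}

#' Gene-based association test for one gene
#'
#' Converts member-SNP p-values to 1-df chi-squares, sums them, and compares
#' the sum against a multivariate-normal null with the panel LD matrix as
#' covariance. Simulation effort escalates adaptively through `stages`
#' (stopping once at least `min_exceed` null draws surpass the observed
#' statistic) so small p-values get proportionally more resolution.
#'
#' @param members Tibble of member SNPs (`rsid`, `pos`, `pvalue`), e.g. one
#'   gene's rows from [assign_snps_to_genes()].
#' @param panel A [ref_panel()].
#' @param stages Increasing simulation sizes for the adaptive schedule.
#' @param max_sims Cap on the simulation size; stages above it are dropped.
#' @param seed Seed for this gene's simulation stream.
#' @param min_exceed Exceedance count at which escalation stops.
#' @return One-row tibble: `gene` (if present in `members`), `n_snps`,
#'   `statistic`, `empirical_p`, `n_sims`, `n_exceed`, `top_snp`,
#'   `top_snp_p`. Untestable genes (all members monomorphic) yield NA
#'   statistic and p.
#' @export
test_gene <- function(members, panel, stages = c(1e3, 1e4, 1e5, 1e6),
                      max_sims = 1e6, seed = 1, min_exceed = 10) {
  members <- tibble::as_tibble(members)
  stopifnot(nrow(members) >= 1, !anyDuplicated(members$rsid))
  # canonical member order: results must not depend on SNP input order
  members <- members[order(members$pos, members$rsid), ]
  gene <- if ("gene" %in% names(members)) members$gene[[1]] else NA_character_

  sigma <- withCallingHandlers(
    ld_matrix(panel, members$rsid),
    warning = function(w) invokeRestart("muffleWarning")
  )
  na_row <- tibble::tibble(
    gene = gene, n_snps = 0L, statistic = NA_real_, empirical_p = NA_real_,
    n_sims = 0L, n_exceed = NA_integer_,
    top_snp = NA_character_, top_snp_p = NA_real_
  )
  if (is.null(sigma)) return(na_row)
  members <- members[members$rsid %in% colnames(sigma), ]

  stat <- gene_statistic(members$pvalue)
  ord <- order(members$pvalue, members$pos)
  top <- members[ord[1], ]

  stages <- sort(unique(pmin(stages, max_sims)))
  r <- NA_integer_
  m <- NA_integer_
  for (s in seq_along(stages)) {
    m <- as.integer(stages[s])
    nulls <- simulate_null(sigma, m, seed = gene_seed(seed, "stage", s))
    r <- sum(nulls > stat)
    if (r >= min_exceed) break
  }

  tibble::tibble(
    gene = gene, n_snps = nrow(members), statistic = stat,
    empirical_p = (r + 1) / (m + 1), n_sims = m, n_exceed = as.integer(r),
    top_snp = top$rsid, top_snp_p = top$pvalue
  )
}

#' Run the gene-based test across all genes
#'
#' Assigns SNPs to genes ([assign_snps_to_genes()]) and tests each gene with
#' at least one member ([test_gene()]). Per-gene simulation seeds are derived
#' from a stable hash of (seed, gene symbol), so results do not depend on
#' gene order.
#'
#' @inheritParams assign_snps_to_genes
#' @inheritParams test_gene
#' @param seed Global seed; per-gene streams are derived from it.
#' @return A `pleio_gene_scan` tibble with one row per tested gene: `gene`,
#'   `chrom`, `n_snps`, `statistic`, `empirical_p`, `n_sims`, `n_exceed`,
#'   `top_snp`, `top_snp_p`. Genes with zero members are reported in the
#'   `untested` attribute.
#' @export
run_gene_test <- function(snps, genes, panel, padding_bp = 0, r2_link = 0.8,
                          stages = c(1e3, 1e4, 1e5, 1e6), max_sims = 1e6,
                          seed = 1, min_exceed = 10) {
  assignments <- assign_snps_to_genes(snps, genes, panel,
                                      padding_bp = padding_bp,
                                      r2_link = r2_link)
  if (nrow(assignments) == 0) {
    warning("no SNP could be assigned to any gene", call. = FALSE)
    out <- tibble::tibble(gene = character(), chrom = character(),
                          n_snps = integer(), statistic = double(),
                          empirical_p = double(), n_sims = integer(),
                          n_exceed = integer(), top_snp = character(),
                          top_snp_p = double())
    return(new_gene_scan(out, genes$gene, seed))
  }
  res <- assignments |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(mem) {
      test_gene(mem, panel, stages = stages, max_sims = max_sims,
                seed = gene_seed(seed, mem$gene[[1]]),
                min_exceed = min_exceed)
    })
  res <- dplyr::left_join(res, genes[, c("gene", "chrom")], by = "gene") |>
    dplyr::relocate("chrom", .after = "gene") |>
    dplyr::arrange(.data$gene)
  new_gene_scan(res, setdiff(genes$gene, res$gene), seed)
}

new_gene_scan <- function(df, untested, seed) {
  structure(df, untested = untested, seed = seed,
            class = c("pleio_gene_scan", class(df)))
}
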