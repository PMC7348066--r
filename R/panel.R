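#' Construct a reference genotype panel
#'
#' A reference panel supplies the linkage-disequilibrium (LD) structure for
#' the gene-based test: pairwise Pearson correlations between SNP dosage
#' vectors stand in for the LD (r) matrix of, e.g., 1000 Genomes Europeans.
#'
#' @param dosages Individuals x SNPs numeric matrix of allele dosages in
#'   \[0, 2\]; `NA` allowed (mean-imputed when correlations are computed).
#' @param map Tibble/data frame with columns `rsid`, `chrom`, `pos`
#'   describing the SNP columns in order; extra columns are kept.
#' @return An object of class `ref_panel`.
#' @export
ref_panel <- function(dosages, map) {
  map <- tibble::as_tibble(map)
  stopifnot(is.matrix(dosages), all(c("rsid", "chrom", "pos") %in% names(map)))
  if (ncol(dosages) != nrow(map)) {
    stop("dosage columns (", ncol(dosages), ") != map rows (", nrow(map), ")",
         call. = FALSE)
  }
  if (anyDuplicated(map$rsid)) stop("duplicated rsIDs in map", call. = FALSE)
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  colnames(dosages) <- map$rsid
  structure(list(dosages = dosages, map = map), class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel> ", nrow(x$dosages), " individuals x ", ncol(x$dosages),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read a reference panel from a dosage matrix and SNP map
#'
#' The dosage file is a TSV with one header row of rsIDs and one row per
#' individual; the sidecar map is a TSV with columns `rsid`, `chrom`, `pos`.
#'
#' @param dosage_path Path to the individuals x SNPs dosage TSV.
#' @param map_path Path to the SNP map TSV.
#' @return A [ref_panel()].
#' @export
read_reference_panel <- function(dosage_path, map_path) {
  dos <- readr::read_tsv(dosage_path, show_col_types = FALSE, progress = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(dos)
  storage.mode(mat) <- "double"
  map <- map[match(colnames(mat), map$rsid), ]
  if (any(is.na(map$rsid))) {
    stop("dosage column(s) missing from SNP map", call. = FALSE)
  }
  ref_panel(mat, map)
}

# Mean-impute missing dosages per SNP; returns the matrix.
impute_dosages <- function(x) {
  for (j in which(colSums(is.na(x)) > 0)) {
    v <- x[, j]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    x[, j] <- v
  }
  x
}

# SNPs with < 2 distinct observed dosage values.
monomorphic_snps <- function(panel) {
  x <- panel$dosages
  mono <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    length(unique(v[!is.na(v)])) < 2
  }, logical(1))
  panel$map$rsid[mono]
}

#' LD correlation matrix for a set of SNPs
#'
#' Signed Pearson correlations between dosage vectors, with missing dosages
#' mean-imputed per SNP. Because finite panels can yield numerically
#' indefinite matrices, the result is repaired by clipping eigenvalues at
#' `eps` and renormalising the diagonal to 1, so a Cholesky factorisation
#' always exists for the simulation null.
#'
#' @param panel A [ref_panel()].
#' @param members Character vector of member rsIDs.
#' @param eps Eigenvalue floor for the positive-semi-definite repair.
#' @return Correlation matrix with rsID dimnames, or `NULL` when every
#'   member is monomorphic (gene untestable). Monomorphic members are
#'   dropped with a warning.
#' @export
ld_matrix <- function(panel, members, eps = 1e-8) {
  stopifnot(inherits(panel, "ref_panel"))
  missing <- setdiff(members, panel$map$rsid)
  if (length(missing) > 0) {
    stop("SNP(s) absent from panel: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- panel$dosages[, members, drop = FALSE]
  x <- impute_dosages(x)
  sds <- apply(x, 2, sd)
  mono <- sds == 0 | is.na(sds)
  if (all(mono)) {
    warning("all member SNPs monomorphic; gene untestable", call. = FALSE)
    return(NULL)
  }
  if (any(mono)) {
    warning(sum(mono), " monomorphic member SNP(s) dropped: ",
            paste(head(members[mono], 5), collapse = ", "), call. = FALSE)
    x <- x[, !mono, drop = FALSE]
  }
  r <- cor(x)
  repair_correlation(r, eps)
}

# Clip eigenvalues at eps, rebuild, renormalise diagonal to exactly 1.
repair_correlation <- function(r, eps = 1e-8) {
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < eps) {
    vals <- pmax(e$values, eps)
    r2 <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(r2))
    r2 <- r2 / tcrossprod(d)
    dimnames(r2) <- dimnames(r)
    r <- (r2 + t(r2)) / 2
    diag(r) <- 1
  }
  r
}
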