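# Internal helpers shared across modules.

# Deterministic 31-bit seed from a global seed plus a gene symbol (or any
# label), so per-gene simulation streams do not depend on iteration order.
gene_seed <- function(seed, label, salt = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483563
  }
  as.integer((h + as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %%
               2147483563)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

#' Format p-values in scientific notation at three significant figures
#'
#' Matches the conventional presentation of gene-based and expression
#' p-values (e.g. `1.70E-05`).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector; `NA` elements stay `NA`.
#' @export
#' @examples
#' format_pvalue(c(1.7e-5, 0.05, NA))
format_pvalue <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- sprintf("%.2E", p[ok])
  out
}

# First matching p-value column in a results table.
find_p_column <- function(df, prefer = c("empirical_p", "p_combined",
                                         "p_value", "pvalue", "p")) {
  hit <- intersect(prefer, names(df))
  if (length(hit) == 0) {
    stop("no p-value column found (looked for: ",
         paste(prefer, collapse = ", "), ")", call. = FALSE)
  }
  hit[[1]]
}

stopifnot_prob <- function(p, what = "p", open_zero = TRUE) {
  if (any(is.na(p))) stop(what, " contains NA", call. = FALSE)
  bad <- if (open_zero) p <= 0 | p > 1 else p < 0 | p > 1
  if (any(bad)) {
    stop(what, " must lie in ", if (open_zero) "(0, 1]" else "[0, 1]",
         "; offending value: ", format(p[bad][1]), call. = FALSE)
  }
  invisible(p)
}
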