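#' Tidy and summarise pipeline results
#'
#' broom-style accessors: `tidy()` returns the per-gene rows as a plain
#' tibble; `glance()` returns a one-row summary of the stage.
#'
#' @param x A `pleio_gene_scan`, `pleio_meta`, `pleio_shared` or `pleio_de`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name pleio_tidiers
NULL

strip_class <- function(x) {
  tibble::as_tibble(unclass(x)[!vapply(unclass(x), is.null, logical(1))])
}

#' @rdname pleio_tidiers
#' @method tidy pleio_gene_scan
#' @export
tidy.pleio_gene_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname pleio_tidiers
#' @method glance pleio_gene_scan
#' @export
glance.pleio_gene_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_untested = length(attr(x, "untested")),
    n_snps_used = sum(x$n_snps, na.rm = TRUE),
    n_nominal = sum(x$empirical_p < 0.05, na.rm = TRUE),
    median_p = stats::median(x$empirical_p, na.rm = TRUE)
  )
}

#' @rdname pleio_tidiers
#' @method tidy pleio_meta
#' @export
tidy.pleio_meta <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname pleio_tidiers
#' @method glance pleio_meta
#' @export
glance.pleio_meta <- function(x, ...) {
  tibble::tibble(
    n_overlap = attr(x, "n_overlap"),
    threshold = attr(x, "threshold"),
    alpha = attr(x, "alpha"),
    bonferroni_factor = attr(x, "bonferroni_factor"),
    n_significant = sum(x$significant)
  )
}

#' @rdname pleio_tidiers
#' @method tidy pleio_shared
#' @export
tidy.pleio_shared <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname pleio_tidiers
#' @method glance pleio_shared
#' @export
glance.pleio_shared <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    threshold = attr(x, "threshold"),
    n_any_significant = sum(x$any_significant),
    n_shared_significant = sum(x$shared_significant)
  )
}

#' @rdname pleio_tidiers
#' @method tidy pleio_de
#' @export
tidy.pleio_de <- function(x, ...) {
  tibble::as_tibble(x$de)
}

#' @rdname pleio_tidiers
#' @method glance pleio_de
#' @export
glance.pleio_de <- function(x, ...) {
  glance(x$shared)
}
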