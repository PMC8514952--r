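#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a locus report into one row per gene
#'
#' @param x a `tr_locus_report`.
#' @param ... unused.
#' @return the annotation tibble (gene-level rows) with the locus name added.
#' @method tidy tr_locus_report
#' @export
tidy.tr_locus_report <- function(x, ...) {
  x$annotations |> mutate(locus = x$locus_name, .before = 1L)
}

#' One-row summary of a locus report
#'
#' @param x a `tr_locus_report`.
#' @param ... unused.
#' @return tibble with locus name, span, per-type gene counts, functionality
#'   counts and the V subgroup count.
#' @method glance tr_locus_report
#' @export
glance.tr_locus_report <- function(x, ...) {
  g <- x$annotations
  cnt <- function(tp) sum(g$type == tp)
  fun <- function(cl) sum(g$functionality == cl, na.rm = TRUE)
  tibble(
    locus = x$locus_name, span_kb = x$span_kb,
    n_genes = nrow(g),
    n_v = cnt("V"), n_d = cnt("D"), n_j = cnt("J"), n_c = cnt("C"),
    n_f = fun("F"), n_orf = fun("ORF"), n_p = fun("P"),
    n_v_subgroups = if (is.null(x$subgroups)) NA_integer_ else
      length(unique(x$subgroups$subgroup)),
    organization = x$organization
  )
}

#' Tidy a synthetic locus into its truth table
#'
#' @param x a `tr_synthetic_locus`.
#' @param ... unused.
#' @return the planted-gene truth tibble.
#' @method tidy tr_synthetic_locus
#' @export
tidy.tr_synthetic_locus <- function(x, ...) x$genes

#' One-row summary of a synthetic locus
#'
#' @param x a `tr_synthetic_locus`.
#' @param ... unused.
#' @return tibble with sequence length, gene counts and defect totals.
#' @method glance tr_synthetic_locus
#' @export
glance.tr_synthetic_locus <- function(x, ...) {
  g <- x$genes
  tibble(
    seq_id = names(x$sequence), length_nt = nchar(x$sequence),
    n_genes = nrow(g),
    n_v = sum(g$type == "V"), n_d = sum(g$type == "D"),
    n_j = sum(g$type == "J"), n_c = sum(g$type == "C"),
    n_defective = sum(!is.na(g$defects)),
    seed = x$params$seed
  )
}
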