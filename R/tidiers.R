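# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a divergence summary into its pair table
#'
#' @param x A `divergence_summary` from [partition_divergence()].
#' @param ... Unused.
#' @return The long pair tibble (one row per accession pair).
#' @method tidy divergence_summary
#' @export
tidy.divergence_summary <- function(x, ...) x$pairs

#' One-row summary of a divergence partition
#'
#' @inheritParams tidy.divergence_summary
#' @method glance divergence_summary
#' @export
glance.divergence_summary <- function(x, ...) x$summary

#' Tidy a recovery report into its per-species table
#'
#' @param x A `recovery_report` from [species_recovery()].
#' @param ... Unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$per_species

#' One-row summary of a recovery report
#'
#' @inheritParams tidy.recovery_report
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) x$summary

#' Tidy PCoA coordinates
#'
#' @param x A `pcoa_result` from [pcoa_bands()].
#' @param ... Unused.
#' @return Tibble of accession coordinates on the positive axes.
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' One-row summary of a PCoA
#'
#' @inheritParams tidy.pcoa_result
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coordinates),
    n_positive_axes = length(x$pct_variance),
    n_negative_eigenvalues = x$n_negative_eigenvalues,
    pct_axis_1 = x$pct_variance[1],
    pct_axis_2 = if (length(x$pct_variance) >= 2) x$pct_variance[2] else NA_real_,
    pct_axis_3 = if (length(x$pct_variance) >= 3) x$pct_variance[3] else NA_real_
  )
}

#' One-row summaries of evaluation bundles
#'
#' @param x A `barcode_eval` or `aflp_eval` object.
#' @param ... Unused.
#' @method glance barcode_eval
#' @export
glance.barcode_eval <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$locus_summary),
    best_recovery_pct = max(x$recovery$pct_recovered),
    best_recovery_locus = x$recovery$locus[which.max(x$recovery$pct_recovered)]
  )
}

#' @rdname glance.barcode_eval
#' @method glance aflp_eval
#' @export
glance.aflp_eval <- function(x, ...) {
  tot <- x$polymorphism[x$polymorphism$primer == "overall", ]
  tibble::tibble(
    n_accessions = nrow(x$jaccard),
    n_bands = tot$n_bands,
    pct_polymorphic = tot$pct_polymorphic,
    n_unique_bands = nrow(x$unique_bands),
    cophenetic_r = x$cophenetic_r,
    mantel_r = if (!is.null(x$mantel)) x$mantel$r else NA_real_,
    mantel_p = if (!is.null(x$mantel)) x$mantel$p_value else NA_real_
  )
}
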