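# End-to-end report bundles: the full barcode-locus evaluation and the
# AFLP diversity analysis.

#' Run the full barcode-locus evaluation
#'
#' For each locus: site statistics, K2P distances under complete deletion,
#' intra/interspecific divergence partitioning, per-species gap statistics
#' with the strict discrimination criterion, the barcoding-gap t-test,
#' NJ/UPGMA trees with bootstrap consensus support, and monophyletic
#' species recovery. With more than one locus, the loci are concatenated
#' over their common accessions and the multilocus alignment is evaluated
#' the same way. Diagnostic characters are searched where a reference is
#' supplied.
#'
#' @param alignments Named list of [locus_alignment] objects.
#' @param species_map Species map covering every accession.
#' @param methods Tree methods to score, subset of `c("nj", "upgma")`.
#' @param n_bootstrap Bootstrap replicates for consensus support (500 is
#'   the conventional number; 0 skips the bootstrap).
#' @param consensus_rule `"majority50"` or `"strict"`.
#' @param diagnostics Optional named list (by locus) of lists with
#'   `reference_id`, `origin_offset` (default 1), `min_accessions`
#'   (default 3) and `k_max` (default 3) controlling the diagnostic
#'   character search.
#' @param multilocus Whether to add the concatenated analysis.
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `barcode_eval` with tibbles `locus_summary`,
#'   `gap_stats`, `gap_tests`, `recovery`, `diagnostics`, plus lists
#'   `trees`, `consensus` (per locus and method), `divergence` (per-locus
#'   `divergence_summary`), and `seed`.
#' @export
run_barcode_eval <- function(alignments, species_map,
                             methods = c("nj", "upgma"), n_bootstrap = 500,
                             consensus_rule = "majority50",
                             diagnostics = NULL, multilocus = TRUE,
                             seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(alignments))) {
    names(alignments) <- vapply(alignments, locus_name_or, character(1))
  }
  if (multilocus && length(alignments) > 1) {
    alignments <- c(alignments,
                    stats::setNames(list(concatenate_loci(alignments)),
                                    paste(names(alignments), collapse = "+")))
  }
  locus_summary <- list(); gap_stats <- list(); gap_tests <- list()
  recovery <- list(); trees <- list(); consensus <- list()
  divergence <- list(); diag_tbl <- list()
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    species_of(rownames(aln), species_map)   # fail fast on unmapped accessions
    stats_row <- site_statistics(aln)
    stats_row$locus <- locus
    dm <- k2p_matrix(aln, deletion = "complete")
    part <- partition_divergence(dm, species_map)
    divergence[[locus]] <- part
    locus_summary[[locus]] <- dplyr::bind_cols(
      stats_row, part$summary[, c("mean_inter", "sd_inter", "mean_intra",
                                  "sd_intra", "n_undefined")])
    gs <- species_gap_stats(dm, species_map)
    gs$locus <- locus
    gap_stats[[locus]] <- gs
    gap_tests[[locus]] <- tryCatch({
      gt <- barcode_gap_test(gs)
      gt$locus <- locus
      gt
    }, error = function(e) NULL)
    if (anyNA(dm)) {
      stop("undefined K2P distances in locus ", shQuote(locus),
           "; remove saturated accessions before tree building",
           call. = FALSE)
    }
    for (m in methods) {
      tree <- if (m == "nj") nj_tree(dm) else upgma_tree(dm)
      trees[[locus]][[m]] <- tree
      rec <- species_recovery(tree, species_map, method = m)
      row <- rec$summary
      row$locus <- locus
      recovery[[paste(locus, m)]] <- row
      if (n_bootstrap > 0) {
        bt <- bootstrap_trees(aln, method = m, n_replicates = n_bootstrap,
                              seed = seed)
        consensus[[locus]][[m]] <- consensus_tree(bt, rule = consensus_rule)
      }
    }
    dspec <- diagnostics[[locus]]
    if (!is.null(dspec)) {
      refmap <- map_to_reference(aln, dspec$reference_id,
                                 origin_offset = dspec$origin_offset %||% 1)
      min_acc <- dspec$min_accessions %||% 3
      simple <- find_simple_diagnostics(aln, species_map, refmap,
                                        min_accessions = min_acc)
      compound <- find_compound_diagnostics(aln, species_map, refmap,
                                            k_max = dspec$k_max %||% 3,
                                            min_accessions = min_acc)
      found <- dplyr::bind_rows(
        simple[, c("species", "kind", "label", "support")],
        compound[, c("species", "kind", "label", "support")])
      if (nrow(found) > 0) found$locus <- locus
      diag_tbl[[locus]] <- found
    }
  }
  structure(list(
    locus_summary = dplyr::bind_rows(locus_summary),
    gap_stats = dplyr::bind_rows(gap_stats),
    gap_tests = dplyr::bind_rows(gap_tests),
    recovery = dplyr::bind_rows(recovery),
    diagnostics = dplyr::bind_rows(diag_tbl),
    trees = trees, consensus = consensus, divergence = divergence,
    seed = seed
  ), class = "barcode_eval")
}

#' @export
print.barcode_eval <- function(x, ...) {
  cat("<barcode_eval> ", nrow(x$locus_summary), " locus set(s)\n", sep = "")
  print(x$locus_summary[, c("locus", "n_sequences", "pct_variable",
                            "pct_pic", "mean_inter", "mean_intra")])
  cat("\nSpecies recovery:\n")
  print(x$recovery[, c("locus", "method", "n_species", "pct_recovered")])
  invisible(x)
}

#' Run the AFLP diversity analysis
#'
#' Summarises a binary band matrix (polymorphism per primer pair, unique
#' bands, per-species band distribution), builds the Jaccard distance
#' matrix and its UPGMA phenogram with cophenetic correlation, runs PCoA,
#' and — when GPS coordinates are available — the Mantel test of genetic
#' against WGS84 geographic distance.
#'
#' @param bands A [band_matrix].
#' @param species_map Species map covering the accessions (with `lat`,
#'   `lon` for the Mantel test).
#' @param n_permutations Mantel permutations.
#' @param seed Integer seed for the Mantel permutations.
#' @return A list of class `aflp_eval`: tibbles `polymorphism`,
#'   `unique_bands`, `band_distribution`, `mantel`; `phenogram` (`phylo`),
#'   `cophenetic_r`, `pcoa` ([pcoa_bands()] result), `jaccard` and `geo`
#'   distance matrices, and `seed`.
#' @export
run_aflp_eval <- function(bands, species_map, n_permutations = 999,
                          seed = 1) {
  if (length(bands) == 0 || all(bands == 0)) {
    stop("degenerate band matrix: no bands present", call. = FALSE)
  }
  species_of(rownames(bands), species_map)
  poly <- polymorphism_summary(bands)
  uniq <- unique_bands(bands, species_map)
  dist_tbl <- species_band_distribution(bands, species_map)
  dm <- jaccard_distance(bands)
  if (anyNA(dm)) stop("accession pairs with no scored bands", call. = FALSE)
  phen <- upgma_tree(dm)
  coph <- cophenetic_correlation(phen, dm)
  ord <- pcoa_bands(dm)
  mantel <- NULL; geo <- NULL
  has_gps <- all(rownames(bands) %in%
                   species_map$accession_id[!is.na(species_map$lat) &
                                              !is.na(species_map$lon)])
  if (has_gps) {
    geo <- geo_distance_matrix(
      species_map[species_map$accession_id %in% rownames(bands), ])
    mantel <- mantel_test(dm, geo, n_permutations = n_permutations,
                          seed = seed)
  } else {
    message("GPS coordinates incomplete; Mantel test skipped")
  }
  structure(list(polymorphism = poly, unique_bands = uniq,
                 band_distribution = dist_tbl, phenogram = phen,
                 cophenetic_r = coph, pcoa = ord, mantel = mantel,
                 jaccard = dm, geo = geo, seed = seed),
            class = "aflp_eval")
}

#' @export
print.aflp_eval <- function(x, ...) {
  tot <- x$polymorphism[x$polymorphism$primer == "overall", ]
  cat("<aflp_eval> ", nrow(x$jaccard), " accessions, ", tot$n_bands,
      " bands (", tot$pct_polymorphic, "% polymorphic), ",
      nrow(x$unique_bands), " unique band(s)\n", sep = "")
  cat("cophenetic r = ", round(x$cophenetic_r, 3), sep = "")
  if (!is.null(x$mantel)) {
    cat("; Mantel r = ", round(x$mantel$r, 3), " (p = ",
        signif(x$mantel$p_value, 3), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every tabular component as CSV (full precision), trees as
#' Newick, and for AFLP results the PCoA coordinates/eigenvalues and the
#' Mantel result.
#'
#' @param x A `barcode_eval` or `aflp_eval` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  if (inherits(x, "barcode_eval")) {
    wcsv(x$locus_summary, "locus_summary")
    wcsv(x$gap_stats, "gap_stats")
    if (nrow(x$gap_tests)) wcsv(x$gap_tests, "gap_tests")
    wcsv(x$recovery, "recovery")
    if (nrow(x$diagnostics)) wcsv(x$diagnostics, "diagnostics")
    for (locus in names(x$trees)) {
      for (m in names(x$trees[[locus]])) {
        ape::write.tree(x$trees[[locus]][[m]], file.path(
          dir, paste0("tree_", gsub("[^A-Za-z0-9]+", "_", locus), "_", m,
                      ".nwk")))
      }
    }
  } else if (inherits(x, "aflp_eval")) {
    wcsv(x$polymorphism, "aflp_polymorphism")
    wcsv(x$unique_bands, "aflp_unique_bands")
    wcsv(x$band_distribution, "aflp_band_distribution")
    wcsv(x$pcoa$coordinates, "aflp_pcoa_coordinates")
    wcsv(tibble::tibble(axis = seq_along(x$pcoa$eigenvalues),
                        eigenvalue = x$pcoa$eigenvalues),
         "aflp_pcoa_eigenvalues")
    if (!is.null(x$mantel)) wcsv(x$mantel, "aflp_mantel")
    ape::write.tree(x$phenogram, file.path(dir, "aflp_phenogram.nwk"))
  } else {
    stop("unsupported report object", call. = FALSE)
  }
  invisible(dir)
}
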