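# AFLP binary-marker analysis: band accounting, Jaccard similarity,
# phenograms, cophenetic correlation, PCoA, Mantel test, geographic
# distances.

#' Construct an AFLP band matrix
#'
#' Binary presence/absence matrix of AFLP bands: rows are accessions,
#' columns are bands named `"primer:band"` so the primer pair each band
#' came from is recoverable. Band scoring itself (fragment sizing) is
#' upstream of this package.
#'
#' @param values A 0/1 matrix (or data frame) with accession rownames and
#'   band colnames in the form `primer:band`.
#' @return An object of class `band_matrix` (integer matrix).
#' @export
band_matrix <- function(values) {
  mat <- as.matrix(values)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("band matrix needs accession rownames and band colnames",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) stop("band IDs must be unique", call. = FALSE)
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L))) {
    stop("band matrix entries must be 0 or 1", call. = FALSE)
  }
  structure(mat, class = c("band_matrix", "matrix", "array"))
}

#' Read a band matrix from CSV
#'
#' @param path CSV with accession IDs in the first column and one 0/1
#'   column per band (`primer:band` column names).
#' @return A [band_matrix].
#' @export
read_band_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  band_matrix(df)
}

band_primers <- function(bm) {
  sub(":.*$", "", colnames(bm))
}

#' Polymorphism summary of a band matrix
#'
#' A band is polymorphic when it is neither present in every accession nor
#' absent from all of them. Reported per primer pair and overall, with
#' percentages to one decimal.
#'
#' @param bm A [band_matrix].
#' @param by_primer If `TRUE` (default), include per-primer rows.
#' @return A tibble: `primer` (`"overall"` for the total row), `n_bands`,
#'   `n_polymorphic`, `pct_polymorphic`.
#' @export
polymorphism_summary <- function(bm, by_primer = TRUE) {
  if (length(bm) == 0) stop("empty band matrix", call. = FALSE)
  pres <- colSums(bm)
  poly <- pres > 0 & pres < nrow(bm)
  per <- tibble::tibble(primer = band_primers(bm), polymorphic = poly)
  out <- if (by_primer) {
    dplyr::summarise(dplyr::group_by(per, .data$primer),
                     n_bands = dplyr::n(),
                     n_polymorphic = sum(.data$polymorphic),
                     .groups = "drop")
  } else {
    tibble::tibble(primer = character(), n_bands = integer(),
                   n_polymorphic = integer())
  }
  out <- dplyr::bind_rows(out, tibble::tibble(
    primer = "overall", n_bands = ncol(bm), n_polymorphic = sum(poly)))
  out$pct_polymorphic <- round(100 * out$n_polymorphic / out$n_bands, 1)
  out
}

#' Bands unique to a single species
#'
#' A band is unique to a species when it is present in at least one of its
#' accessions and absent from every accession of every other species.
#'
#' @param bm A [band_matrix].
#' @param species_map Species map covering the accessions.
#' @return A tibble: `band`, `primer`, `species`, `n_carriers`.
#' @export
unique_bands <- function(bm, species_map) {
  sp <- species_of(rownames(bm), species_map)
  rows <- list()
  for (j in seq_len(ncol(bm))) {
    carriers <- rownames(bm)[bm[, j] == 1L]
    if (length(carriers) == 0) next
    carrier_sp <- unique(unname(sp[carriers]))
    if (length(carrier_sp) == 1) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        band = colnames(bm)[j], primer = band_primers(bm)[j],
        species = carrier_sp, n_carriers = length(carriers))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(band = character(), primer = character(),
                          species = character(), n_carriers = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Distribution of bands across species and primer pairs
#'
#' Counts, for each species and primer pair, the bands present in at least
#' one accession of the species.
#'
#' @inheritParams unique_bands
#' @return A tibble in wide form: `species` plus one column per primer.
#' @export
species_band_distribution <- function(bm, species_map) {
  sp <- species_of(rownames(bm), species_map)
  primers <- band_primers(bm)
  long <- purrr::map_dfr(sort(unique(unname(sp))), function(s) {
    members <- rownames(bm)[sp == s]
    present <- colSums(bm[members, , drop = FALSE]) > 0
    tibble::tibble(species = s, primer = primers, present = present)
  })
  counts <- dplyr::summarise(
    dplyr::group_by(long, .data$species, .data$primer),
    n_bands = sum(.data$present), .groups = "drop")
  tidyr::pivot_wider(counts, names_from = "primer", values_from = "n_bands")
}

#' Jaccard similarity between two binary profiles
#'
#' `S = a11 / (a11 + a10 + a01)`: shared presences over bands present in at
#' least one profile; joint absences are ignored, as appropriate for
#' dominant markers. Returns `NA` when both profiles are all-zero.
#'
#' @param x,y Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`, or `NA` if undefined.
#' @export
jaccard_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length", call. = FALSE)
  a11 <- sum(x == 1 & y == 1)
  denom <- a11 + sum(x == 1 & y == 0) + sum(x == 0 & y == 1)
  if (denom == 0) return(NA_real_)
  a11 / denom
}

#' Jaccard distance matrix for a band matrix
#'
#' Pairwise `1 - S` over all accessions, computed over all bands pooled
#' across primer pairs (a single fingerprint per accession).
#'
#' @param bm A [band_matrix].
#' @return A symmetric distance matrix with accession dimnames; pairs of
#'   all-zero profiles are `NA`.
#' @export
jaccard_distance <- function(bm) {
  x <- matrix(as.numeric(bm), nrow = nrow(bm), dimnames = dimnames(bm))
  a11 <- tcrossprod(x)
  a10 <- tcrossprod(x, 1 - x)
  denom <- a11 + a10 + t(a10)
  d <- 1 - a11 / denom
  d[denom == 0] <- NA_real_
  diag(d) <- 0
  d
}

#' Cophenetic correlation between a dendrogram and a distance matrix
#'
#' Pearson correlation between the tree's cophenetic distances and the
#' original distances over all off-diagonal pairs — the usual check that a
#' UPGMA phenogram faithfully summarises its input matrix.
#'
#' @param tree A `phylo` tree (or `hclust`) whose tips match the matrix
#'   labels.
#' @param dm The original distance matrix.
#' @return The correlation coefficient.
#' @export
cophenetic_correlation <- function(tree, dm) {
  coph <- if (inherits(tree, "hclust")) as.matrix(stats::cophenetic(tree))
          else ape::cophenetic.phylo(tree)
  labels <- rownames(dm)
  if (!setequal(labels, rownames(coph))) {
    stop("tree tips and matrix labels differ", call. = FALSE)
  }
  coph <- coph[labels, labels]
  i <- upper.tri(dm)
  x <- coph[i]; y <- dm[i]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in distances; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-D^2/2` followed by
#' eigendecomposition. Axes are ordered by eigenvalue; negative eigenvalues
#' (possible for non-Euclidean distances such as Jaccard) are reported but
#' not corrected, and percent variance is computed over the positive
#' eigenvalues only.
#'
#' @param dm A labeled symmetric distance matrix.
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (tibble: `accession`, `axis_1` ... ), `eigenvalues`, `pct_variance`
#'   (per positive axis), `n_negative_eigenvalues`.
#' @export
pcoa_bands <- function(dm) {
  check_dm(dm)
  n <- nrow(dm)
  if (all(dm == 0)) {
    warning("all-zero distance matrix; PCoA is degenerate", call. = FALSE)
  }
  # cmdscale warns when it cannot return n-1 positive axes; negative
  # eigenvalues are expected for Jaccard distances, so silence that
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = max(n - 1, 1), eig = TRUE))
  eig <- sc$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  coords <- sc$points
  k_pos <- min(ncol(coords), sum(pos))
  coords <- coords[, seq_len(k_pos), drop = FALSE]
  coord_tbl <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(coord_tbl) <- paste0("axis_", seq_len(ncol(coord_tbl)))
  coord_tbl <- dplyr::bind_cols(tibble::tibble(accession = rownames(dm)),
                                coord_tbl)
  structure(list(
    coordinates = coord_tbl,
    eigenvalues = eig,
    pct_variance = 100 * eig[pos][seq_len(k_pos)] / sum(eig[pos]),
    n_negative_eigenvalues = sum(eig < -sqrt(.Machine$double.eps) *
                                   max(abs(eig), 1))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$coordinates), " points, first axes explain ",
      paste(round(utils::head(x$pct_variance, 3), 1), collapse = ", "),
      "% of positive variance\n", sep = "")
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Permutation test of the Pearson correlation between corresponding
#' off-diagonal elements of two distance matrices (typically Jaccard
#' genetic distance versus geographic distance). One matrix's rows and
#' columns are permuted jointly; the one-sided p-value for positive
#' association is `(number of permuted r >= observed r + 1) /
#' (n_permutations + 1)`.
#'
#' @param dm1,dm2 Labeled symmetric matrices over the same accessions
#'   (order is matched by label).
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `mantel_result`: one-row tibble with `r`,
#'   `p_value`, `n_permutations`, `n`, `seed`.
#' @export
mantel_test <- function(dm1, dm2, n_permutations = 999, seed = 1) {
  if (!setequal(rownames(dm1), rownames(dm2))) {
    stop("matrices must be over the same accessions", call. = FALSE)
  }
  dm2 <- dm2[rownames(dm1), rownames(dm1)]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(dm1), stats::as.dist(dm2),
                       method = "pearson", permutations = n_permutations)
  out <- tibble::tibble(r = unname(fit$statistic), p_value = fit$signif,
                        n_permutations = n_permutations, n = nrow(dm1),
                        seed = seed)
  class(out) <- c("mantel_result", class(out))
  out
}

#' Geographic distance matrix on the WGS84 ellipsoid
#'
#' Pairwise geodesic distances (in km) between accession collection sites,
#' computed with Karney's algorithm on the WGS84 ellipsoid
#' ([geosphere::distGeo()]). Accessions with missing coordinates are
#' dropped with a warning.
#'
#' @param species_map Species map with `accession_id`, `lat`, `lon`
#'   (decimal degrees).
#' @return A symmetric matrix of distances in km, accession dimnames.
#' @export
geo_distance_matrix <- function(species_map) {
  ok <- !is.na(species_map$lat) & !is.na(species_map$lon)
  if (any(!ok)) {
    warning(sum(!ok), " accession(s) without coordinates excluded",
            call. = FALSE)
  }
  sm <- species_map[ok, ]
  if (nrow(sm) < 2) stop("need at least 2 accessions with coordinates",
                         call. = FALSE)
  if (any(abs(sm$lat) > 90) || any(abs(sm$lon) > 180)) {
    stop("coordinates out of range (decimal degrees expected)", call. = FALSE)
  }
  coords <- cbind(sm$lon, sm$lat)
  d <- geosphere::distm(coords, fun = geosphere::distGeo) / 1000
  dimnames(d) <- list(sm$accession_id, sm$accession_id)
  d
}
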