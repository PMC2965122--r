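# Kimura two-parameter distances, complete deletion, intra/interspecific
# divergence partitioning, discrimination and barcoding-gap statistics.

#' Remove alignment columns with gaps or ambiguity in any sequence
#'
#' Complete-deletion handling of indels and missing data: every column in
#' which any sequence carries a gap or an ambiguity code is removed before
#' distance calculation, so all sequences are compared over the same set of
#' unambiguous sites. The original column indices of the retained sites are
#' kept in the `kept_columns` attribute.
#'
#' @param aln A [locus_alignment] with at least 2 sequences.
#' @return A [locus_alignment], possibly with fewer columns.
#' @export
complete_deletion <- function(aln) {
  if (nrow(aln) < 2) stop("need at least 2 sequences", call. = FALSE)
  mat <- unclass(aln)
  keep <- colSums(matrix(mat %in% BASES, nrow = nrow(mat))) == nrow(mat)
  if (!any(keep)) {
    stop("complete deletion removed every column; alignment is degenerate",
         call. = FALSE)
  }
  out <- locus_alignment(mat[, keep, drop = FALSE],
                         locus_name = locus_name(aln))
  attr(out, "kept_columns") <- which(keep)
  out
}

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(w1 > 0 & w2 > 0, -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                0.25 * log(pmax(w2, .Machine$double.xmin)), NA_real_)
  d
}

#' Kimura two-parameter distance between two sequences
#'
#' Computes the K2P (K80) distance
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' where `P` and `Q` are the proportions of sites differing by a transition
#' (A/G, C/T) and a transversion, respectively. Sites where either sequence
#' has a gap or an ambiguity code are excluded from the comparison. When the
#' log arguments are non-positive the estimator is undefined and `d` is
#' returned as `NA` with `defined = FALSE` rather than raising an error.
#'
#' @param a,b Equal-length nucleotide strings or character vectors.
#' @return A one-row tibble: `d`, `P`, `Q`, `n_sites`, `defined`.
#' @examples
#' # 2 transitions + 1 transversion over 20 sites: P = 0.10, Q = 0.05
#' k2p_distance(strrep("A", 20), paste0(strrep("A", 17), "GGT"))
#' @export
k2p_distance <- function(a, b) {
  av <- if (length(a) == 1) strsplit(toupper(a), "")[[1]] else toupper(a)
  bv <- if (length(b) == 1) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(av) != length(bv)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  ok <- av %in% BASES & bv %in% BASES
  n <- sum(ok)
  if (n == 0) stop("no comparable (unambiguous) sites", call. = FALSE)
  av <- av[ok]; bv <- bv[ok]
  diff <- av != bv
  purine_a <- av %in% c("A", "G")
  purine_b <- bv %in% c("A", "G")
  ts <- sum(diff & (purine_a == purine_b))
  tv <- sum(diff & (purine_a != purine_b))
  P <- ts / n
  Q <- tv / n
  d <- k2p_from_pq(P, Q)
  tibble::tibble(d = d, P = P, Q = Q, n_sites = n, defined = !is.na(d))
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Computes all pairwise K2P distances. Under `deletion = "complete"` (the
#' default) gapped/ambiguous columns are removed alignment-wide first; under
#' `"pairwise"` each pair is compared over its own unambiguous sites. Pairs
#' for which the K2P estimator is undefined (saturated divergence putting
#' the logarithm out of domain) are `NA` in the result; their count is
#' available as attribute `n_undefined`.
#'
#' @param aln A [locus_alignment] with at least 2 sequences.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return A symmetric numeric matrix (substitutions/site) with accession
#'   IDs as dimnames, zero diagonal, and attributes `n_undefined` and
#'   `n_sites` (columns used; a matrix of per-pair counts for pairwise
#'   deletion).
#' @export
k2p_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (nrow(aln) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (deletion == "complete") aln <- complete_deletion(aln)
  mat <- unclass(aln)
  n <- nrow(mat)
  valid <- matrix(as.numeric(mat %in% BASES), nrow = n)
  n_sites <- tcrossprod(valid)
  match_count <- matrix(0, n, n)
  for (b in BASES) {
    ib <- matrix(as.numeric(mat == b), nrow = n)
    match_count <- match_count + tcrossprod(ib)
  }
  purine <- matrix(as.numeric(mat %in% c("A", "G")), nrow = n) * valid
  tv_count <- tcrossprod(purine, valid - purine) +
    tcrossprod(valid - purine, purine)
  ts_count <- n_sites - match_count - tv_count
  if (any(n_sites[upper.tri(n_sites)] == 0)) {
    stop("some pairs share no comparable sites", call. = FALSE)
  }
  P <- ts_count / n_sites
  Q <- tv_count / n_sites
  d <- matrix(k2p_from_pq(as.vector(P), as.vector(Q)), n, n)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  attr(d, "n_undefined") <- sum(is.na(d[upper.tri(d)]))
  attr(d, "n_sites") <- if (deletion == "complete") ncol(mat) else n_sites
  d
}

pair_table <- function(dm, species_map) {
  labels <- rownames(dm)
  sp <- species_of(labels, species_map)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble::tibble(
    accession_1 = labels[idx[, 1]],
    accession_2 = labels[idx[, 2]],
    species_1 = unname(sp[idx[, 1]]),
    species_2 = unname(sp[idx[, 2]]),
    type = ifelse(sp[idx[, 1]] == sp[idx[, 2]], "intraspecific",
                  "interspecific"),
    d = dm[idx]
  )
}

#' Partition pairwise divergence into intra- and interspecific components
#'
#' Every unordered accession pair is classified as intraspecific (same
#' species) or interspecific, and means and standard deviations are computed
#' over the pairs where the distance estimator is defined. Undefined pairs
#' are excluded and counted, never silently propagated.
#'
#' @param dm A distance matrix from [k2p_matrix()] (or any labeled
#'   symmetric matrix).
#' @param species_map Species map covering every matrix label.
#' @return An object of class `divergence_summary`: a list with `pairs`
#'   (long tibble of all pairs) and `summary` (one-row tibble with
#'   `mean_intra`, `sd_intra`, `n_intra`, `mean_inter`, `sd_inter`,
#'   `n_inter`, `n_undefined`). See [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
partition_divergence <- function(dm, species_map) {
  pairs <- pair_table(dm, species_map)
  def <- pairs[!is.na(pairs$d), ]
  intra <- def$d[def$type == "intraspecific"]
  inter <- def$d[def$type == "interspecific"]
  summary <- tibble::tibble(
    mean_intra = if (length(intra)) mean(intra) else NA_real_,
    sd_intra = if (length(intra) >= 2) stats::sd(intra) else NA_real_,
    n_intra = length(intra),
    mean_inter = if (length(inter)) mean(inter) else NA_real_,
    sd_inter = if (length(inter) >= 2) stats::sd(inter) else NA_real_,
    n_inter = length(inter),
    n_undefined = sum(is.na(pairs$d))
  )
  structure(list(pairs = pairs, summary = summary),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("<divergence_summary>\n")
  print(x$summary)
  invisible(x)
}

#' Per-species barcoding-gap statistics and strict discrimination
#'
#' For each species, computes the maximum intraspecific K2P distance, the
#' minimum interspecific distance over pairs involving that species, and the
#' ratio of the species' mean inter- to mean intraspecific distance.
#' Discrimination follows the CBOL plant working group criterion with a
#' strict inequality: a species is discriminated only if its minimum
#' interspecific distance is strictly larger than its maximum intraspecific
#' distance, so ties fail. Species without intraspecific pairs (single
#' accession) are flagged not evaluable.
#'
#' @inheritParams partition_divergence
#' @return A tibble with one row per species: `species`, `n_accessions`,
#'   `max_intra`, `mean_intra`, `min_inter`, `mean_inter`, `ratio`,
#'   `discriminated`, `evaluable`.
#' @export
species_gap_stats <- function(dm, species_map) {
  pairs <- pair_table(dm, species_map)
  labels <- rownames(dm)
  sp <- species_of(labels, species_map)
  species <- sort(unique(unname(sp)))
  rows <- lapply(species, function(s) {
    involving <- pairs$species_1 == s | pairs$species_2 == s
    intra <- pairs$d[involving & pairs$type == "intraspecific"]
    inter <- pairs$d[involving & pairs$type == "interspecific"]
    intra <- intra[!is.na(intra)]
    inter <- inter[!is.na(inter)]
    max_intra <- if (length(intra)) max(intra) else NA_real_
    mean_intra <- if (length(intra)) mean(intra) else NA_real_
    min_inter <- if (length(inter)) min(inter) else NA_real_
    mean_inter <- if (length(inter)) mean(inter) else NA_real_
    evaluable <- length(intra) > 0 && length(inter) > 0
    tibble::tibble(
      species = s,
      n_accessions = sum(sp == s),
      max_intra = max_intra, mean_intra = mean_intra,
      min_inter = min_inter, mean_inter = mean_inter,
      ratio = if (evaluable && mean_intra > 0) mean_inter / mean_intra else NA_real_,
      discriminated = if (evaluable) min_inter > max_intra else NA,
      evaluable = evaluable
    )
  })
  dplyr::bind_rows(rows)
}

#' Barcoding-gap t-test
#'
#' Tests for a barcoding gap by comparing, across species, the minimum
#' interspecific against the maximum intraspecific K2P distance with a
#' paired two-sided t-test. Only evaluable species (those with both kinds
#' of pairs) enter the test.
#'
#' @param gap_stats Output of [species_gap_stats()].
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n_species`,
#'   `mean_gap` (mean of min_inter - max_intra).
#' @export
barcode_gap_test <- function(gap_stats) {
  ok <- gap_stats$evaluable & !is.na(gap_stats$min_inter) &
    !is.na(gap_stats$max_intra)
  x <- gap_stats$min_inter[ok]
  y <- gap_stats$max_intra[ok]
  if (length(x) < 2) {
    stop("need at least 2 evaluable species for the gap test", call. = FALSE)
  }
  diffs <- x - y
  if (stats::sd(diffs) == 0) {
    # degenerate case t.test() refuses: constant differences
    if (mean(diffs) == 0) {
      return(tibble::tibble(statistic = 0, df = length(x) - 1, p_value = 1,
                            n_species = length(x), mean_gap = 0))
    }
    stop("paired differences are constant and non-zero; t-test undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_species = length(x),
                 mean_gap = mean(diffs))
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Compares divergence levels (e.g. interspecific K2P distances per locus)
#' across groups with a one-way ANOVA followed by all pairwise pooled-
#' variance t-tests whose p-values are Bonferroni adjusted (multiplied by
#' the number of comparisons, capped at 1). Values may be log-transformed
#' first to stabilise variances.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric response and
#'   the grouping variable.
#' @param log_transform If `TRUE`, analyse `log10(value)`; requires
#'   strictly positive values.
#' @return A list with `anova` (one-row tibble: `statistic`, `df_between`,
#'   `df_within`, `p_value`) and `pairwise` (tibble: `group_1`, `group_2`,
#'   `estimate`, `p_value`, `p_adjusted`).
#' @export
anova_bonferroni <- function(data, value = "value", group = "group",
                             log_transform = FALSE) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (is.null(v) || is.null(g)) stop("value/group columns not found", call. = FALSE)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least 2 groups with at least 2 values each", call. = FALSE)
  }
  if (log_transform) {
    if (any(v <= 0)) stop("log transform requires positive values", call. = FALSE)
    v <- log10(v)
  }
  fit <- stats::aov(v ~ factor(g))
  tab <- summary(fit)[[1]]
  anova_row <- tibble::tibble(
    statistic = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
  combos <- utils::combn(sort(names(sizes)), 2)
  pw <- apply(combos, 2, function(pair) {
    a <- v[g == pair[1]]; b <- v[g == pair[2]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    c(estimate = mean(a) - mean(b), p_value = tt$p.value)
  })
  pairwise <- tibble::tibble(
    group_1 = combos[1, ], group_2 = combos[2, ],
    estimate = pw["estimate", ], p_value = pw["p_value", ],
    p_adjusted = pmin(pw["p_value", ] * ncol(combos), 1)
  )
  list(anova = anova_row, pairwise = pairwise)
}

#' Write a distance matrix to disk
#'
#' @param dm Labeled symmetric distance matrix.
#' @param path Output path.
#' @param format `"csv"` (square, with header) or `"phylip"` (lower
#'   triangle).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(dm), path, row.names = TRUE)
  } else {
    n <- nrow(dm)
    lines <- c(as.character(n), vapply(seq_len(n), function(i) {
      vals <- if (i > 1) paste(formatC(dm[i, seq_len(i - 1)], format = "g",
                                       digits = 10), collapse = " ") else ""
      trimws(paste(formatC(rownames(dm)[i], width = -10), vals))
    }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
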