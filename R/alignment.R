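# Aligned sequence data: construction, IO, site statistics, haplotypes,
# locus concatenation and the 5.8S motif screen.

BASES <- c("A", "C", "G", "T")
GAP <- "-"
# IUPAC one-letter codes accepted in input (U folded to T, ? to N on entry)
IUPAC_CODES <- c(BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", GAP)

#' Construct a locus alignment
#'
#' A `locus_alignment` holds equal-length gapped nucleotide sequences for a
#' single barcode locus (e.g. ITS, matK, rbcL, trnH-psbA), one per accession.
#' Internally it is an accessions-by-columns character matrix of upper-case
#' IUPAC codes; `U` is folded to `T` and `?` to `N` on construction.
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   accession IDs), or a character matrix with one row per accession.
#' @param locus_name Name of the locus, carried through all downstream
#'   summaries.
#' @return An object of class `locus_alignment`.
#' @examples
#' aln <- locus_alignment(c(a = "ACGT", b = "AC-T"), "toy")
#' aln_length(aln)
#' @export
locus_alignment <- function(sequences, locus_name = "locus") {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(rownames(mat))) {
      stop("sequence matrix must have accession IDs as rownames", call. = FALSE)
    }
  } else {
    if (length(sequences) == 0) {
      stop("no sequences supplied", call. = FALSE)
    }
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == "")) {
      stop("sequences must be named by accession ID", call. = FALSE)
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop("aligned sequences must all have the same length (got lengths ",
           paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
    }
    if (lens[1] < 1L) stop("alignment has zero columns", call. = FALSE)
    mat <- do.call(rbind, strsplit(as.character(sequences), "", fixed = TRUE))
    rownames(mat) <- names(sequences)
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat[mat == "?"] <- "N"
  bad <- setdiff(unique(as.vector(mat)), IUPAC_CODES)
  if (length(bad) > 0) {
    stop("illegal characters in alignment: ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("accession IDs must be unique", call. = FALSE)
  }
  structure(mat, class = c("locus_alignment", "matrix", "array"),
            locus_name = locus_name)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> locus ", shQuote(attr(x, "locus_name")), ": ",
      nrow(x), " sequences x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' @rdname locus_alignment
#' @param aln A `locus_alignment`.
#' @export
aln_length <- function(aln) ncol(aln)

#' @rdname locus_alignment
#' @export
locus_name <- function(aln) attr(aln, "locus_name")

aln_sequences <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' Accession IDs are taken as the first whitespace-delimited token of each
#' FASTA header. All records must have identical aligned length.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param locus_name Locus label to attach; defaults to the file name
#'   without extension.
#' @return A [locus_alignment].
#' @export
read_aligned_fasta <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no FASTA records in ", path, call. = FALSE)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have the same length (got lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  names(seqs) <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1)
  if (is.null(locus_name)) {
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  }
  locus_alignment(seqs, locus_name = locus_name)
}

#' Write a locus alignment as FASTA
#'
#' @param aln A [locus_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  seqs <- aln_sequences(aln)
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read or build an accession metadata table
#'
#' The species map links each accession to its species and, optionally, a
#' geographic region, WGS84 decimal-degree coordinates and a taxonomic
#' section. The CSV must contain columns `accession_id` and `species`;
#' `region`, `lat`, `lon` and `section` are optional.
#'
#' @param path Path to a CSV (or TSV with `sep = "\t"`) file.
#' @param sep Field separator.
#' @return A tibble with columns `accession_id`, `species`, `region`,
#'   `lat`, `lon`, `section`.
#' @export
read_species_map <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_species_map(df)
}

#' @rdname read_species_map
#' @param df A data frame with at least `accession_id` and `species`.
#' @export
as_species_map <- function(df) {
  need <- c("accession_id", "species")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("species map lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("region", "section")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  for (col in c("lat", "lon")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  out <- tibble::as_tibble(df)[, c("accession_id", "species", "region",
                                   "lat", "lon", "section")]
  out$accession_id <- as.character(out$accession_id)
  out$species <- as.character(out$species)
  if (anyDuplicated(out$accession_id)) {
    stop("duplicate accession_id in species map", call. = FALSE)
  }
  if (any(is.na(out$species) | out$species == "")) {
    stop("species names must be non-empty", call. = FALSE)
  }
  out
}

# accession -> species lookup restricted to the alignment; errors on gaps in
# coverage so downstream partitions can trust complete mapping
species_of <- function(accessions, species_map) {
  idx <- match(accessions, species_map$accession_id)
  if (anyNA(idx)) {
    stop("accessions missing from species map: ",
         paste(accessions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(species_map$species[idx], accessions)
}

#' Alignment-level site statistics
#'
#' Counts variable and parsimony-informative columns. Only the four
#' unambiguous bases are counted as states: gaps and ambiguity codes are
#' treated as missing data, so a column needs at least two distinct
#' unambiguous bases to be variable, and at least two bases each present in
#' at least two sequences to be parsimony-informative. `mean_length` is the
#' mean ungapped sequence length (bp), matching how amplicon lengths are
#' reported for barcode surveys; percentages are over all alignment columns.
#'
#' @param aln A [locus_alignment] with at least 2 sequences.
#' @return A one-row tibble: `locus`, `n_sequences`, `mean_length`,
#'   `n_variable`, `n_parsimony_informative`, `pct_variable`, `pct_pic`.
#' @export
site_statistics <- function(aln) {
  if (nrow(aln) < 2) {
    stop("site statistics need at least 2 sequences", call. = FALSE)
  }
  mat <- unclass(aln)
  counts <- apply(mat, 2, function(col) {
    tab <- table(factor(col[col %in% BASES], levels = BASES))
    c(n_states = sum(tab > 0), n_informative_states = sum(tab >= 2))
  })
  n_var <- sum(counts["n_states", ] >= 2)
  n_pic <- sum(counts["n_states", ] >= 2 & counts["n_informative_states", ] >= 2)
  ungapped <- rowSums(mat != GAP)
  tibble::tibble(
    locus = locus_name(aln),
    n_sequences = nrow(mat),
    mean_length = mean(ungapped),
    n_variable = n_var,
    n_parsimony_informative = n_pic,
    pct_variable = 100 * n_var / ncol(mat),
    pct_pic = 100 * n_pic / ncol(mat)
  )
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences are grouped by exact (case-folded) string identity, so each
#' accession belongs to exactly one haplotype.
#'
#' @param aln A [locus_alignment].
#' @param species_map Optional species map; when given, the species
#'   represented in each haplotype are listed.
#' @return A tibble with one row per haplotype: `haplotype`, `sequence`,
#'   `n_members`, `accessions` (list), and `species` (list) when a map is
#'   supplied. Haplotypes are ordered by first appearance.
#' @export
collapse_haplotypes <- function(aln, species_map = NULL) {
  seqs <- aln_sequences(aln)
  first <- !duplicated(seqs)
  keys <- match(seqs, seqs[first])
  groups <- split(names(seqs), keys)
  out <- tibble::tibble(
    haplotype = paste0("H", seq_along(groups)),
    sequence = unname(seqs[first]),
    n_members = unname(lengths(groups)),
    accessions = unname(groups)
  )
  if (!is.null(species_map)) {
    sp <- species_of(names(seqs), species_map)
    out$species <- lapply(out$accessions, function(a) sort(unique(unname(sp[a]))))
  }
  out
}

#' Screen an ITS sequence for the conserved 5.8S motif
#'
#' Angiosperm nuclear ITS sequences carry the conserved 5.8S motif
#' `GAATTGCAGAATCC`; the variant `GAATTGCAGAATTC` is characteristic of
#' fungal sequences and flags probable fungal contamination of a plant
#' sample. Gaps are removed before searching and only the forward strand is
#' scanned; if both motifs occur, the plant motif takes precedence.
#'
#' @param sequence A single nucleotide string (may contain gaps).
#' @return `"plant"`, `"fungal_variant"`, or `"absent"`.
#' @export
check_58s_motif <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence)) {
    stop("sequence must be a single string", call. = FALSE)
  }
  s <- toupper(gsub("-", "", sequence, fixed = TRUE))
  if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
  if (grepl("GAATTGCAGAATCC", s, fixed = TRUE)) return("plant")
  if (grepl("GAATTGCAGAATTC", s, fixed = TRUE)) return("fungal_variant")
  "absent"
}

#' Concatenate loci over their common accessions
#'
#' Builds a multilocus supermatrix by joining, per accession, the aligned
#' sequences of several loci in the order given. Only accessions present in
#' every input locus are retained (the usual "common accessions" policy for
#' multilocus barcode analysis); the partition boundaries of each locus are
#' recorded in the `partitions` attribute.
#'
#' @param alns A list of [locus_alignment] objects (at least 2).
#' @param locus_name Name for the concatenated alignment.
#' @return A [locus_alignment] whose length is the sum of the input
#'   lengths, with attribute `partitions` (tibble: `locus`, `start`, `end`).
#' @export
concatenate_loci <- function(alns, locus_name = NULL) {
  if (length(alns) < 2) stop("need at least two loci", call. = FALSE)
  common <- Reduce(intersect, lapply(alns, rownames))
  if (length(common) == 0) {
    stop("no accession is present in all loci", call. = FALSE)
  }
  common <- rownames(alns[[1]])[rownames(alns[[1]]) %in% common]
  pieces <- lapply(alns, function(a) unclass(a)[common, , drop = FALSE])
  mat <- do.call(cbind, pieces)
  lens <- vapply(pieces, ncol, integer(1))
  ends <- cumsum(lens)
  if (is.null(locus_name)) {
    locus_name <- paste(vapply(alns, locus_name_or, character(1)), collapse = "+")
  }
  out <- locus_alignment(mat, locus_name = locus_name)
  attr(out, "partitions") <- tibble::tibble(
    locus = vapply(alns, locus_name_or, character(1)),
    start = c(1L, utils::head(ends, -1) + 1L),
    end = ends
  )
  out
}

locus_name_or <- function(a) {
  nm <- attr(a, "locus_name")
  if (is.null(nm)) "locus" else nm
}
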