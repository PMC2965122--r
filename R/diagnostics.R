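# Character-based species identification: reference-anchored position
# numbering, simple and compound diagnostic characters.

#' Map alignment columns to reference sequence positions
#'
#' Diagnostic characters are reported in the coordinate system of a
#' reference sequence included in the alignment: position 1 is placed at
#' `origin_offset` in the ungapped reference (for ITS the start of ITS1,
#' for coding loci the first base of the start codon, for a spacer its
#' first position). Columns where the reference carries a gap, or that lie
#' before the origin, have no reference position.
#'
#' @param aln A [locus_alignment] containing the reference.
#' @param reference_id Accession ID of the reference sequence.
#' @param origin_offset 1-based position in the ungapped reference taken
#'   as coordinate 1.
#' @return A tibble with one row per alignment column: `column`,
#'   `ref_base`, `ref_pos` (`NA` where unmapped), plus attribute
#'   `reference_id`.
#' @export
map_to_reference <- function(aln, reference_id, origin_offset = 1) {
  if (!reference_id %in% rownames(aln)) {
    stop("reference ", shQuote(reference_id), " not in alignment", call. = FALSE)
  }
  ref <- unclass(aln)[reference_id, ]
  nongap <- ref != GAP
  if (origin_offset < 1 || origin_offset > sum(nongap)) {
    stop("origin_offset outside the reference sequence", call. = FALSE)
  }
  pos <- rep(NA_integer_, length(ref))
  pos[nongap] <- cumsum(nongap)[nongap] - as.integer(origin_offset) + 1L
  pos[!is.na(pos) & pos < 1L] <- NA_integer_
  out <- tibble::tibble(column = seq_along(ref), ref_base = unname(ref),
                        ref_pos = pos)
  attr(out, "reference_id") <- reference_id
  out
}

# members per species meeting the accession threshold; reference and other
# excluded accessions never count as members or as "other" accessions
diag_groups <- function(aln, species_map, min_accessions, exclude) {
  acc <- setdiff(rownames(aln), exclude)
  sp <- species_of(acc, species_map)
  groups <- split(acc, unname(sp))
  eligible <- groups[lengths(groups) >= min_accessions]
  skipped <- names(groups)[lengths(groups) < min_accessions]
  if (length(skipped) > 0) {
    message("species below the ", min_accessions, "-accession threshold ",
            "skipped: ", paste(skipped, collapse = ", "))
  }
  list(groups = eligible, accessions = acc)
}

# columns where every member of the species carries the same unambiguous
# base; gaps/ambiguity in any member disqualify the column for that species
fixed_states <- function(mat, members) {
  sub <- mat[members, , drop = FALSE]
  ok <- colSums(matrix(sub %in% BASES, nrow = nrow(sub))) == nrow(sub)
  same <- apply(sub, 2, function(col) all(col == col[1]))
  state <- sub[1, ]
  state[!(ok & same)] <- NA_character_
  state
}

diag_label <- function(ref_pos, states) {
  paste(paste0(ref_pos, "-", states), collapse = "+")
}

#' Find simple diagnostic characters
#'
#' A simple diagnostic character for a species is a single alignment
#' position at which every accession of the species (at least
#' `min_accessions` of them) carries one unambiguous base and no accession
#' of any other species carries that base. Gaps or ambiguity codes within
#' the species disqualify a position; missing data in non-members do not
#' block a diagnostic but are counted. Positions are reported in reference
#' coordinates, so columns without a reference position are skipped.
#'
#' @param aln A [locus_alignment].
#' @param species_map Species map covering the alignment.
#' @param refmap Output of [map_to_reference()].
#' @param min_accessions Minimum accessions a species needs to be
#'   evaluated (3 is the conventional threshold).
#' @param exclude Accession IDs to leave out entirely (typically the
#'   reference sequence).
#' @return A tibble: `species`, `kind` (`"simple"`), `label` (e.g.
#'   `"29-T"`), `ref_pos`, `state`, `support` (member count),
#'   `n_missing_other` (non-members with missing data at the site).
#' @export
find_simple_diagnostics <- function(aln, species_map, refmap,
                                    min_accessions = 3, exclude = NULL) {
  exclude <- union(exclude, attr(refmap, "reference_id"))
  info <- diag_groups(aln, species_map, min_accessions, exclude)
  mat <- unclass(aln)
  mapped <- !is.na(refmap$ref_pos)
  rows <- list()
  for (s in names(info$groups)) {
    members <- info$groups[[s]]
    others <- setdiff(info$accessions, members)
    state <- fixed_states(mat, members)
    for (j in which(!is.na(state) & mapped)) {
      other_states <- mat[others, j]
      if (!any(other_states == state[j])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = s, kind = "simple",
          label = diag_label(refmap$ref_pos[j], state[j]),
          ref_pos = refmap$ref_pos[j], state = state[j],
          support = length(members),
          n_missing_other = sum(!other_states %in% BASES)
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(species = character(), kind = character(),
                          label = character(), ref_pos = integer(),
                          state = character(), support = integer(),
                          n_missing_other = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Find compound diagnostic characters
#'
#' A compound diagnostic character combines states at `k >= 2` positions
#' that are individually shared with other species but whose joint pattern
#' is fixed within the species and occurs in no other accession. Only
#' minimal combinations are reported: positions that are themselves simple
#' diagnostics are excluded from the search, and a k-combination is dropped
#' when one of its sub-combinations is already diagnostic. The search is
#' restricted to species-fixed variable positions and capped by
#' `max_combinations` per species and order; when the cap is hit that order
#' is skipped with a warning and partial results are returned.
#'
#' @inheritParams find_simple_diagnostics
#' @param k_max Largest combination order searched (2 or 3 positions is
#'   the conventional range).
#' @param max_combinations Combinatorial budget per species and order.
#' @return A tibble: `species`, `kind` (`"compound"`), `label` (e.g.
#'   `"78-G+181-G"`), `sites` (list of reference positions), `states`
#'   (list), `n_sites`, `support`.
#' @export
find_compound_diagnostics <- function(aln, species_map, refmap, k_max = 3,
                                      min_accessions = 3, exclude = NULL,
                                      max_combinations = 100000) {
  exclude <- union(exclude, attr(refmap, "reference_id"))
  info <- diag_groups(aln, species_map, min_accessions, exclude)
  mat <- unclass(aln)
  mapped <- !is.na(refmap$ref_pos)
  rows <- list()
  for (s in names(info$groups)) {
    members <- info$groups[[s]]
    others <- setdiff(info$accessions, members)
    state <- fixed_states(mat, members)
    fixed <- which(!is.na(state) & mapped)
    # candidates: fixed but individually non-diagnostic, and variable
    shared <- vapply(fixed, function(j) any(mat[others, j] == state[j]),
                     logical(1))
    variable <- vapply(fixed, function(j) any(mat[others, j] %in% BASES &
                                                mat[others, j] != state[j]),
                       logical(1))
    cand <- fixed[shared & variable]
    # other x candidate matrix of "carries the species state here"
    carries <- matrix(FALSE, length(others), length(cand))
    for (i in seq_along(cand)) {
      carries[, i] <- mat[others, cand[i]] == state[cand[i]]
    }
    found_sets <- list()
    for (k in 2:k_max) {
      if (length(cand) < k) break
      if (choose(length(cand), k) > max_combinations) {
        warning("combination budget exceeded for species ", shQuote(s),
                " at k = ", k, "; returning partial results", call. = FALSE)
        break
      }
      combos <- utils::combn(seq_along(cand), k)
      for (ci in seq_len(ncol(combos))) {
        idx <- combos[, ci]
        has_sub <- any(vapply(found_sets, function(fs) all(fs %in% idx),
                              logical(1)))
        if (has_sub) next
        if (!any(rowSums(carries[, idx, drop = FALSE]) == k)) {
          found_sets[[length(found_sets) + 1]] <- idx
          cols <- cand[idx]
          rows[[length(rows) + 1]] <- tibble::tibble(
            species = s, kind = "compound",
            label = diag_label(refmap$ref_pos[cols], state[cols]),
            sites = list(refmap$ref_pos[cols]),
            states = list(unname(state[cols])),
            n_sites = k, support = length(members)
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(species = character(), kind = character(),
                          label = character(), sites = list(),
                          states = list(), n_sites = integer(),
                          support = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Verify a diagnostic character against an alignment
#'
#' Checks a supplied character (including disjunctive forms like
#' `"36-G+66-T/86-C"`, meaning 36-G and either 66-T or 86-C) against the
#' raw alignment: every accession of the species must satisfy every
#' clause, and no accession of any other species may satisfy all clauses.
#' Clauses are separated by `+`, alternatives within a clause by `/`, and
#' each term is `position-STATE` in reference coordinates.
#'
#' @inheritParams find_simple_diagnostics
#' @param species Species name the character claims to identify.
#' @param character_spec Character string in the notation above.
#' @return A one-row tibble: `species`, `character_spec`, `valid`,
#'   `n_members_failing`, `n_others_matching`.
#' @export
verify_diagnostic <- function(aln, species_map, refmap, species,
                              character_spec, exclude = NULL) {
  exclude <- union(exclude, attr(refmap, "reference_id"))
  acc <- setdiff(rownames(aln), exclude)
  sp <- species_of(acc, species_map)
  members <- acc[sp == species]
  others <- acc[sp != species]
  if (length(members) == 0) stop("no accessions for ", shQuote(species),
                                 call. = FALSE)
  clauses <- strsplit(strsplit(character_spec, "+", fixed = TRUE)[[1]],
                      "/", fixed = TRUE)
  mat <- unclass(aln)
  satisfies <- function(who) {
    vapply(who, function(a) {
      all(vapply(clauses, function(cl) {
        any(vapply(cl, function(term) {
          parts <- strsplit(term, "-", fixed = TRUE)[[1]]
          pos <- as.integer(parts[1])
          col <- refmap$column[match(pos, refmap$ref_pos)]
          if (is.na(col)) stop("reference position ", pos,
                               " not present in mapping", call. = FALSE)
          identical(unname(mat[a, col]), toupper(parts[2]))
        }, logical(1)))
      }, logical(1)))
    }, logical(1))
  }
  member_ok <- satisfies(members)
  other_match <- if (length(others)) satisfies(others) else logical(0)
  tibble::tibble(
    species = species, character_spec = character_spec,
    valid = all(member_ok) && !any(other_match),
    n_members_failing = sum(!member_ok),
    n_others_matching = sum(other_match)
  )
}
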