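# Distance-based tree construction (NJ, UPGMA), bootstrap, consensus,
# monophyly testing and species-recovery scoring.

check_dm <- function(dm) {
  if (is.null(rownames(dm))) stop("distance matrix must be labeled", call. = FALSE)
  if (anyNA(dm)) {
    stop("distance matrix has undefined entries; remove the affected ",
         "accessions or impute before tree building", call. = FALSE)
  }
  invisible(dm)
}

# Kuhner-Felsenstein style cleanup: negative edges are set to zero and the
# deficit is pushed onto the daughter edges of the child node so path
# lengths through the node are approximately preserved; topology unchanged.
clamp_negative_edges <- function(phy) {
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    child <- phy$edge[e, 2]
    daughters <- which(phy$edge[, 1] == child)
    if (length(daughters) > 0) {
      phy$edge.length[daughters] <- pmax(
        phy$edge.length[daughters] + deficit, 0)
    }
  }
  phy
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]). Negative branch lengths,
#' which NJ can produce when the matrix is not additive, are clamped to zero
#' with the deficit transferred to the adjacent daughter edges; the topology
#' is unaffected.
#'
#' @param dm Labeled symmetric distance matrix with no undefined entries
#'   and at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  check_dm(dm)
  if (nrow(dm) < 3) stop("NJ needs at least 3 taxa", call. = FALSE)
  clamp_negative_edges(ape::nj(stats::as.dist(dm)))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering ([stats::hclust()] with
#' `method = "average"`), returned as a rooted ultrametric `phylo` tree.
#' Tip-to-tip path length equals the merge height, so for an ultrametric
#' input the cophenetic distances reproduce the input exactly.
#'
#' @param dm Labeled symmetric distance matrix with no undefined entries
#'   and at least 2 taxa.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  check_dm(dm)
  if (nrow(dm) < 2) stop("UPGMA needs at least 2 taxa", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap trees by resampling alignment columns
#'
#' Standard nonparametric phylogenetic bootstrap: alignment columns (after
#' complete deletion) are resampled with replacement to the original
#' length, the K2P matrix is recomputed and a tree is built for each
#' replicate. Replicates whose resampled matrix contains undefined
#' distances are skipped with a message. Fully seeded and reproducible.
#'
#' @param aln A [locus_alignment].
#' @param method `"nj"` or `"upgma"`.
#' @param n_replicates Number of bootstrap replicates (500 is the
#'   conventional choice for barcode surveys).
#' @param seed Integer seed.
#' @return A list of `phylo` trees of length at most `n_replicates`, with
#'   attribute `n_skipped`.
#' @export
bootstrap_trees <- function(aln, method = c("nj", "upgma"),
                            n_replicates = 500, seed = 1) {
  method <- match.arg(method)
  aln <- complete_deletion(aln)
  mat <- unclass(aln)
  builder <- if (method == "nj") nj_tree else upgma_tree
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  trees <- vector("list", n_replicates)
  skipped <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rep_aln <- locus_alignment(mat[, cols, drop = FALSE],
                               locus_name = locus_name(aln))
    dm <- k2p_matrix(rep_aln, deletion = "pairwise")
    if (anyNA(dm)) {
      skipped <- skipped + 1L
      next
    }
    trees[[r]] <- builder(dm)
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  if (skipped > 0) {
    message(skipped, " bootstrap replicate(s) skipped (undefined distances)")
  }
  class(trees) <- "multiPhylo"
  attr(trees, "n_skipped") <- skipped
  trees
}

#' Consensus of a set of trees
#'
#' Strict consensus keeps only the bipartitions present in every tree;
#' majority-rule keeps those present in more than half. Internal nodes are
#' annotated with the bipartition frequency as a percentage (the usual
#' bootstrap support values).
#'
#' @param trees A list/`multiPhylo` of trees over the same leaf set.
#' @param rule `"strict"` or `"majority50"`.
#' @return A `phylo` tree with `node.label` holding support percentages.
#' @export
consensus_tree <- function(trees, rule = c("strict", "majority50")) {
  rule <- match.arg(rule)
  if (length(trees) == 0) stop("no trees supplied", call. = FALSE)
  tip_sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(tip_sets)) != 1) {
    stop("all trees must share the same leaf set", call. = FALSE)
  }
  p <- if (rule == "strict") 1 else 0.5
  cons <- ape::consensus(trees, p = p, check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- as.character(round(100 * counts / length(trees)))
  cons
}

species_tips <- function(tree, species_name, species_map) {
  sp <- species_of(tree$tip.label, species_map)
  tree$tip.label[sp == species_name]
}

#' Test whether a species is monophyletic in a tree
#'
#' A species is monophyletic when some bipartition of the (possibly
#' unrooted) tree separates exactly its accessions from all others.
#' Single-accession species are trivially monophyletic by convention, as is
#' a species comprising every leaf. On consensus trees a polytomy mixing
#' species yields `FALSE` for the species involved.
#'
#' @param tree A `phylo` tree.
#' @param species_name Species to test.
#' @param species_map Species map covering every tip label.
#' @return `TRUE` or `FALSE`.
#' @export
is_species_monophyletic <- function(tree, species_name, species_map) {
  tips <- species_tips(tree, species_name, species_map)
  if (length(tips) == 0) {
    stop("species ", shQuote(species_name), " absent from tree", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  if (length(tips) == 1 || length(tips) == n_tip) return(TRUE)
  # the terminal edge of the single non-member already separates the set
  if (length(tips) == n_tip - 1) return(TRUE)
  target <- sort(match(tips, tree$tip.label))
  parts <- ape::prop.part(tree)
  for (p in parts) {
    p <- sort(p)
    if (identical(p, target)) return(TRUE)
    if (length(p) == n_tip - length(target) &&
        identical(p, sort(setdiff(seq_len(n_tip), target)))) return(TRUE)
  }
  FALSE
}

#' Monophyletic species recovery for a tree
#'
#' Scores every species with at least one accession in the tree with
#' [is_species_monophyletic()] and reports the percentage recovered, the
#' headline statistic for comparing barcode loci.
#'
#' @param tree A `phylo` tree.
#' @param species_map Species map covering every tip label.
#' @param method Optional label (e.g. `"nj"`) carried into the result.
#' @return A list of class `recovery_report` with `per_species` (tibble:
#'   `species`, `n_accessions`, `monophyletic`) and `summary` (one-row
#'   tibble: `method`, `n_species`, `n_recovered`, `pct_recovered` to one
#'   decimal).
#' @export
species_recovery <- function(tree, species_map, method = NA_character_) {
  sp <- species_of(tree$tip.label, species_map)
  species <- sort(unique(unname(sp)))
  if (length(species) < 2) {
    stop("recovery needs at least 2 species in the tree", call. = FALSE)
  }
  flags <- vapply(species, is_species_monophyletic, logical(1),
                  tree = tree, species_map = species_map)
  per_species <- tibble::tibble(
    species = species,
    n_accessions = as.integer(table(sp)[species]),
    monophyletic = unname(flags)
  )
  summary <- tibble::tibble(
    method = method,
    n_species = length(species),
    n_recovered = sum(flags),
    pct_recovered = round(100 * sum(flags) / length(species), 1)
  )
  structure(list(per_species = per_species, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$summary$n_recovered, "/", x$summary$n_species,
      " species monophyletic (", x$summary$pct_recovered, "%)\n", sep = "")
  invisible(x)
}
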