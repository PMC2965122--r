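# Fixture builders and independent brute-force oracles used across tests.

BASES4 <- c("A", "C", "G", "T")

# random alignment as a named character vector of strings
rand_aln_strings <- function(n, L, gap_prob = 0, amb_prob = 0) {
  pool <- c(BASES4, "-", "N")
  probs <- c(rep((1 - gap_prob - amb_prob) / 4, 4), gap_prob, amb_prob)
  seqs <- replicate(n, paste(sample(pool, L, replace = TRUE, prob = probs),
                             collapse = ""))
  names(seqs) <- sprintf("acc%02d", seq_len(n))
  seqs
}

toy_species_map <- function(accessions, species) {
  as_species_map(data.frame(accession_id = accessions, species = species))
}

# --- independent per-column site classifier -------------------------------
oracle_site_class <- function(col) {
  states <- col[col %in% BASES4]
  tab <- table(states)
  c(variable = length(tab) >= 2, pic = sum(tab >= 2) >= 2)
}

# --- independent K2P via explicit per-site loop ---------------------------
oracle_k2p <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ts <- 0; tv <- 0; n <- 0
  purine <- function(x) x %in% c("A", "G")
  for (i in seq_along(av)) {
    if (!(av[i] %in% BASES4) || !(bv[i] %in% BASES4)) next
    n <- n + 1
    if (av[i] != bv[i]) {
      if (purine(av[i]) == purine(bv[i])) ts <- ts + 1 else tv <- tv + 1
    }
  }
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# --- monophyly oracle by rooting at a non-member tip ----------------------
oracle_monophyletic <- function(tree, tips) {
  all_tips <- tree$tip.label
  if (length(tips) <= 1 || length(tips) == length(all_tips)) return(TRUE)
  out <- setdiff(all_tips, tips)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  mrca <- ape::getMRCA(rooted, tips)
  clade <- ape::extract.clade(rooted, mrca)$tip.label
  setequal(clade, tips)
}

# --- split enumeration from the edge matrix (no ape helpers) --------------
oracle_splits <- function(tree) {
  n <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  splits <- lapply(internal_children, function(nd) sort(desc(nd)))
  # canonical form: the side not containing the first tip, so each split
  # has a unique representation on an unrooted tree
  lapply(splits, function(s) {
    if (tree$tip.label[1] %in% s) sort(setdiff(tree$tip.label, s)) else s
  })
}

# --- brute-force simple diagnostics straight off the alignment ------------
oracle_simple_diag <- function(mat, members, others) {
  hits <- list()
  for (j in seq_len(ncol(mat))) {
    mm <- mat[members, j]
    if (!all(mm %in% BASES4) || length(unique(mm)) != 1) next
    if (any(mat[others, j] == mm[1])) next
    hits[[length(hits) + 1]] <- c(column = j, state = mm[1])
  }
  hits
}

# --- exhaustive compound search (checks the defining condition directly) --
oracle_compound_diag <- function(mat, members, others, k_max = 3) {
  fixed_cols <- Filter(function(j) {
    mm <- mat[members, j]
    all(mm %in% BASES4) && length(unique(mm)) == 1
  }, seq_len(ncol(mat)))
  state <- vapply(fixed_cols, function(j) mat[members[1], j], character(1))
  simple <- vapply(seq_along(fixed_cols), function(i)
    !any(mat[others, fixed_cols[i]] == state[i]), logical(1))
  cand <- fixed_cols[!simple]
  cstate <- state[!simple]
  found <- list()
  for (k in 2:k_max) {
    if (length(cand) < k) break
    combos <- utils::combn(seq_along(cand), k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      carried <- vapply(others, function(o)
        all(mat[o, cand[idx]] == cstate[idx]), logical(1))
      if (any(carried)) next
      minimal <- !any(vapply(found, function(f) all(f %in% idx), logical(1)))
      if (minimal) found[[length(found) + 1]] <- idx
    }
  }
  lapply(found, function(idx) sort(cand[idx]))
}

# --- manual Mantel statistic ----------------------------------------------
oracle_mantel_r <- function(dm1, dm2) {
  stats::cor(dm1[lower.tri(dm1)], dm2[lower.tri(dm2)])
}
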