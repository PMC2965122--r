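# helper: labeled symmetric matrix from a phylo's path distances
coph_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[sort(rownames(m)), sort(rownames(m))]
}

test_that("NJ reproduces the three-taxon closed form and additive trees exactly", {
  labs <- c("a", "b", "c")
  m <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
              dimnames = list(labs, labs))
  tr <- nj_tree(m)
  # three-point formulas: x = (dab+dac-dbc)/2 etc.; path distances must
  # reproduce the input exactly
  expect_equal(coph_matrix(tr), m[sort(labs), sort(labs)], tolerance = 1e-12)

  # additive 5-taxon matrix generated from a known tree
  true <- ape::read.tree(
    text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.05):0.1,e:0.3);")
  m5 <- coph_matrix(true)
  rec <- nj_tree(m5)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  expect_equal(coph_matrix(rec), m5, tolerance = 1e-10)

  expect_error(nj_tree(m[1:2, 1:2]), "at least 3")
  m_na <- m; m_na[1, 2] <- m_na[2, 1] <- NA
  expect_error(nj_tree(m_na), "undefined")
})

test_that("NJ and UPGMA agree on ultrametric matrices", {
  set.seed(14)
  for (rep in 1:5) {
    tr <- ape::rcoal(7)
    m <- coph_matrix(tr)
    expect_equal(ape::dist.topo(ape::unroot(nj_tree(m)),
                                ape::unroot(upgma_tree(m))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("UPGMA merge heights follow average linkage", {
  two <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  tr <- upgma_tree(two)
  expect_equal(sort(tr$edge.length), c(0.1, 0.1))  # root height 0.1

  # 4-taxon hand trace: a,b merge at 0.2 -> height 0.1 each side; c joins
  # at mean(0.6, 0.8) = 0.7; d joins at mean(1.0, 1.2, 0.9) ~ 1.0333
  labs <- letters[1:4]
  m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  m["a", "b"] <- 0.2; m["a", "c"] <- 0.6; m["b", "c"] <- 0.8
  m["a", "d"] <- 1.0; m["b", "d"] <- 1.2; m["c", "d"] <- 0.9
  m <- m + t(m)
  tr4 <- upgma_tree(m)
  cm <- coph_matrix(tr4)
  expect_equal(cm["a", "b"], 0.2)
  expect_equal(cm["a", "c"], 0.7)
  expect_equal(cm["b", "c"], 0.7)
  expect_equal(cm["a", "d"], mean(c(1.0, 1.2, 0.9)), tolerance = 1e-12)

  # ultrametric input round-trips exactly
  set.seed(2)
  tru <- ape::rcoal(6)
  mu <- coph_matrix(tru)
  expect_equal(coph_matrix(upgma_tree(mu)), mu, tolerance = 1e-10)
})

test_that("negative NJ branches are clamped without changing topology", {
  # a strongly non-additive matrix known to drive one NJ branch negative
  labs <- letters[1:5]
  m <- matrix(0, 5, 5, dimnames = list(labs, labs))
  m[upper.tri(m)] <- c(0.266, 0.372, 0.573, 0.908, 0.202, 0.898, 0.945,
                       0.661, 0.629, 0.062)
  m <- m + t(m)
  raw <- ape::nj(as.dist(m))
  expect_true(any(raw$edge.length < 0))
  tr <- nj_tree(m)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(ape::dist.topo(raw, tr), 0, ignore_attr = TRUE)
})

test_that("bootstrap replicates are seeded, reproducible and well-formed", {
  set.seed(30)
  # low-divergence alignment so the K2P estimator stays in domain
  seqs <- replicate(8, paste(sample(c("A", "A", "A", "A", "G"), 120,
                                    replace = TRUE), collapse = ""))
  names(seqs) <- letters[1:8]
  aln <- locus_alignment(seqs)
  b1 <- bootstrap_trees(aln, "nj", n_replicates = 5, seed = 99)
  b2 <- bootstrap_trees(aln, "nj", n_replicates = 5, seed = 99)
  expect_equal(length(b1), 5)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))

  # zero-variation alignment: every replicate is the same all-zero tree
  flat <- locus_alignment(stats::setNames(replicate(5, strrep("A", 30)),
                                          letters[1:5]))
  bt <- bootstrap_trees(flat, "upgma", n_replicates = 3, seed = 1)
  expect_true(all(vapply(bt, function(t) all(t$edge.length == 0),
                         logical(1))))
})

test_that("bootstrap support grows with the substitutions separating a clade", {
  # two clades of 4 tips; k diagnostic columns separate them
  make_signal_aln <- function(k, L = 100) {
    block <- function(base_left, base_right) {
      c(rep(base_left, 4), rep(base_right, 4))
    }
    mat <- matrix("A", 8, L)
    for (j in seq_len(k)) mat[, j] <- block("A", "G")
    # private noise so tips are distinct
    for (i in 1:8) mat[i, 90 + i] <- "C"
    rownames(mat) <- c(paste0("L", 1:4), paste0("R", 1:4))
    locus_alignment(mat)
  }
  support_for_split <- function(aln) {
    bt <- bootstrap_trees(aln, "nj", n_replicates = 50, seed = 4)
    target <- sort(paste0("L", 1:4))
    mean(vapply(bt, function(t) {
      other <- sort(setdiff(t$tip.label, target))
      any(vapply(oracle_splits(t), function(s)
        identical(s, target) || identical(s, other), logical(1)))
    }, numeric(1)))
  }
  weak <- support_for_split(make_signal_aln(1))
  strong <- support_for_split(make_signal_aln(25))
  expect_gt(strong, weak)
  expect_gte(strong, 0.95)
})

test_that("consensus keeps shared bipartitions and annotates frequencies", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  cons <- consensus_tree(c(t1, t1, t1), rule = "strict")
  expect_equal(ape::dist.topo(cons, t1), 0, ignore_attr = TRUE)
  expect_true(all(as.numeric(cons$node.label[-1]) == 100))

  # two trees conflicting in one edge: strict consensus collapses it
  t2 <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  st <- consensus_tree(c(t1, t2), rule = "strict")
  expect_lt(st$Nnode, t1$Nnode)

  # frequencies equal brute-force split counting on random trees
  set.seed(8)
  trees <- replicate(7, ape::rtree(8, br = NULL), simplify = FALSE)
  tips <- trees[[1]]$tip.label
  trees <- lapply(trees, function(t) { t$tip.label <- tips; t })
  class(trees) <- "multiPhylo"
  maj <- consensus_tree(trees, rule = "majority50")
  # every majority split must occur in > 50% of input trees
  for (s in oracle_splits(maj)) {
    count <- sum(vapply(trees, function(t)
      any(vapply(oracle_splits(t), identical, logical(1), y = s)),
      logical(1)))
    expect_gt(count / length(trees), 0.5)
  }

  t_other <- ape::rtree(5)
  expect_error(consensus_tree(c(t1, t_other)), "leaf set")
})

test_that("monophyly agrees with a rooting-based oracle on random trees", {
  sm <- toy_species_map(c("a1", "a2", "b1", "b2"),
                        c("A", "A", "B", "B"))
  good <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  bad <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_true(is_species_monophyletic(good, "A", sm))
  expect_false(is_species_monophyletic(bad, "A", sm))
  expect_error(is_species_monophyletic(good, "Z", sm), "absent")

  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    sp <- sample(c("X", "Y", "Z"), n, replace = TRUE)
    smr <- toy_species_map(tr$tip.label, sp)
    for (s in unique(sp)) {
      tips <- tr$tip.label[sp == s]
      if (length(tips) == n) next
      expect_equal(is_species_monophyletic(tr, s, smr),
                   oracle_monophyletic(tr, tips),
                   info = paste("rep", rep, "species", s))
    }
  }
})

test_that("species recovery scores percentages and ignores relabeling", {
  tr <- ape::read.tree(text = "((a1,a2),((b1,b2),(c1,c2)));")
  sm <- toy_species_map(c("a1", "a2", "b1", "b2", "c1", "c2"),
                        rep(c("A", "B", "C"), each = 2))
  rec <- species_recovery(tr, sm, method = "nj")
  expect_equal(glance(rec)$pct_recovered, 100)

  mixed <- ape::read.tree(text = "((a1,b1),((a2,b2),(c1,c2)));")
  rec2 <- species_recovery(mixed, sm)
  expect_equal(glance(rec2)$pct_recovered, round(100 / 3, 1))
  expect_true(all(glance(rec2)$pct_recovered >= 0 &
                    glance(rec2)$pct_recovered <= 100))

  # singleton species count as recovered
  sm_single <- toy_species_map(c("a1", "a2", "b1", "b2", "c1", "c2"),
                               c("A", "A", "B", "B", "C", "D"))
  rec3 <- species_recovery(tr, sm_single)
  per <- tidy(rec3)
  expect_true(all(per$monophyletic[per$species %in% c("C", "D")]))

  # invariance under accession relabeling
  perm <- c(a1 = "x1", a2 = "x2", b1 = "y1", b2 = "y2", c1 = "z1",
            c2 = "z2")
  tr_perm <- mixed
  tr_perm$tip.label <- unname(perm[mixed$tip.label])
  sm_perm <- toy_species_map(unname(perm), rep(c("A", "B", "C"), each = 2))
  expect_equal(glance(species_recovery(tr_perm, sm_perm))$pct_recovered,
               glance(rec2)$pct_recovered)
})
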