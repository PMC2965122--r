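toy_bands <- function() {
  m <- rbind(
    a1 = c(1, 1, 0, 1, 0),
    a2 = c(1, 0, 0, 1, 0),
    b1 = c(1, 1, 0, 0, 1),
    b2 = c(1, 0, 0, 0, 1)
  )
  colnames(m) <- c("P1:B1", "P1:B2", "P1:B3", "P2:B1", "P2:B2")
  band_matrix(m)
}

test_that("polymorphism summary classifies fixed, absent and variable bands", {
  bm <- toy_bands()
  ps <- polymorphism_summary(bm)
  tot <- ps[ps$primer == "overall", ]
  # band 1 fixed, band 3 absent -> both monomorphic
  expect_equal(tot$n_bands, 5)
  expect_equal(tot$n_polymorphic, 3)
  expect_equal(tot$pct_polymorphic, 60)
  expect_equal(ps$n_polymorphic[ps$primer == "P1"], 1)
  expect_equal(ps$n_polymorphic[ps$primer == "P2"], 2)

  set.seed(19)
  for (rep in 1:10) {
    m <- matrix(rbinom(8 * 30, 1, 0.4), 8, 30,
                dimnames = list(sprintf("x%d", 1:8),
                                paste0("P1:B", 1:30)))
    bm <- band_matrix(m)
    oracle <- sum(apply(m, 2, function(col) any(col == 1) && any(col == 0)))
    expect_equal(polymorphism_summary(bm)$n_polymorphic[2], oracle)
  }
})

test_that("unique bands are private to exactly one species", {
  bm <- toy_bands()
  sm <- toy_species_map(rownames(bm), c("A", "A", "B", "B"))
  ub <- unique_bands(bm, sm)
  expect_setequal(ub$band, c("P2:B1", "P2:B2"))
  expect_equal(ub$species[ub$band == "P2:B1"], "A")
  expect_equal(ub$species[ub$band == "P2:B2"], "B")
  # band 2 is present in both species -> not unique
  expect_false("P1:B2" %in% ub$band)

  # simulator ground truth: with saturated baseline presence, only the
  # planted bands are unique, and they are all recovered
  cfg <- sim_config(aflp = list(n_primers = 3, bands_per_primer = 20,
                                base = 6, species_effect = 0,
                                region_effect = 0, n_unique_bands = 5,
                                unique_presence = 0.9), seed = 17)
  sim <- simulate_band_matrix(cfg)
  got <- unique_bands(sim$bands, sim$species_map)
  planted <- sim$truth$planted_unique
  expect_setequal(got$band, planted$band)
  expect_equal(got$species[match(planted$band, got$band)], planted$species)
})

test_that("species band distribution counts per-species presence by primer", {
  bm <- toy_bands()
  sm <- toy_species_map(rownames(bm), c("A", "A", "B", "B"))
  sbd <- species_band_distribution(bm, sm)
  expect_equal(sbd$P1[sbd$species == "A"], 2)  # bands 1 and 2
  expect_equal(sbd$P2[sbd$species == "A"], 1)
  expect_equal(sbd$P2[sbd$species == "B"], 1)

  # oracle: per-species column OR then sum; and adding an accession never
  # decreases a count
  set.seed(31)
  m <- matrix(rbinom(9 * 20, 1, 0.3), 9, 20,
              dimnames = list(sprintf("x%d", 1:9),
                              paste0(rep(c("P1", "P2"), c(12, 8)), ":B",
                                     1:20)))
  sm9 <- toy_species_map(rownames(m), rep(c("A", "B", "C"), each = 3))
  sbd9 <- species_band_distribution(band_matrix(m), sm9)
  for (s in c("A", "B", "C")) {
    sub <- m[sm9$accession_id[sm9$species == s], ]
    expect_equal(sbd9$P1[sbd9$species == s],
                 sum(apply(sub[, 1:12], 2, max)))
    expect_equal(sbd9$P2[sbd9$species == s],
                 sum(apply(sub[, 13:20], 2, max)))
  }
  grown <- rbind(m, x10 = rbinom(20, 1, 0.9))
  sm10 <- toy_species_map(rownames(grown), c(sm9$species, "A"))
  sbd10 <- species_band_distribution(band_matrix(grown), sm10)
  expect_true(all(sbd10$P1[sbd10$species == "A"] >=
                    sbd9$P1[sbd9$species == "A"]))
})

test_that("Jaccard similarity ignores joint absences and flags empty pairs", {
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_true(is.na(jaccard_similarity(c(0, 0), c(0, 0))))
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "length")

  set.seed(40)
  m <- matrix(rbinom(10 * 50, 1, 0.5), 10, 50,
              dimnames = list(sprintf("x%d", 1:10), paste0("P1:B", 1:50)))
  d <- jaccard_distance(band_matrix(m))
  # independent engine: vegan's binary Jaccard
  ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  expect_equal(d, ref, tolerance = 1e-12, ignore_attr = TRUE)
  # metric axioms on this draw
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("cophenetic correlation is exact for ultrametric input and matches Pearson", {
  set.seed(50)
  tr <- ape::rcoal(8)
  m <- ape::cophenetic.phylo(tr)
  up <- upgma_tree(m)
  expect_equal(cophenetic_correlation(up, m), 1, tolerance = 1e-10)

  # equals a direct pairwise-vector Pearson on noisy input
  noisy <- m + matrix(runif(64, 0, 0.05), 8, 8)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  up2 <- upgma_tree(noisy)
  coph <- ape::cophenetic.phylo(up2)[rownames(noisy), colnames(noisy)]
  i <- upper.tri(noisy)
  expect_equal(cophenetic_correlation(up2, noisy),
               cor(coph[i], noisy[i]), tolerance = 1e-12)
  expect_lt(cophenetic_correlation(up2, noisy), 1)
})

test_that("PCoA reproduces Euclidean configurations and reports variance shares", {
  # 3 points on a line: one positive axis explains everything
  labs <- c("p", "q", "r")
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(labs, labs))
  res <- pcoa_bands(m)
  expect_equal(res$pct_variance[1], 100)
  d_rec <- as.matrix(dist(res$coordinates$axis_1))
  expect_equal(unname(d_rec), unname(m), tolerance = 1e-10)

  # Euclidean input round-trips through the embedding
  set.seed(60)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  rownames(pts) <- sprintf("x%d", 1:7)
  dm <- as.matrix(dist(pts))
  res2 <- pcoa_bands(dm)
  coords <- as.matrix(res2$coordinates[, -1])
  expect_equal(unname(as.matrix(dist(coords))), unname(dm),
               tolerance = 1e-8)
  # embedding variance equals the positive eigenvalue total
  expect_equal(sum(scale(coords, scale = FALSE)^2),
               sum(res2$eigenvalues[res2$eigenvalues > 1e-8]),
               tolerance = 1e-8)

  # duplicated accession lands on identical coordinates
  dup <- rbind(pts, x8 = pts[1, ])
  dmd <- as.matrix(dist(dup))
  resd <- pcoa_bands(dmd)
  c1 <- unlist(resd$coordinates[resd$coordinates$accession == "x1", -1])
  c8 <- unlist(resd$coordinates[resd$coordinates$accession == "x8", -1])
  expect_equal(unname(c1), unname(c8), tolerance = 1e-8)
})

test_that("Mantel statistic is the off-diagonal Pearson correlation", {
  set.seed(70)
  n <- 12
  labs <- sprintf("x%d", 1:n)
  mk <- function() {
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    m[upper.tri(m)] <- runif(choose(n, 2))
    m + t(m)
  }
  d1 <- mk(); d2 <- mk()
  res <- mantel_test(d1, d2, n_permutations = 99, seed = 5)
  expect_equal(res$r, oracle_mantel_r(d1, d2), tolerance = 1e-12)
  expect_true(res$p_value > 0 && res$p_value <= 1)

  # identity: r = 1, p at the permutation floor
  self <- mantel_test(d1, d1, n_permutations = 99, seed = 5)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 100)

  # invariant under a common relabeling of both matrices
  perm <- sample(labs)
  res2 <- mantel_test(d1[perm, perm], d2[perm, perm],
                      n_permutations = 99, seed = 5)
  expect_equal(res2$r, res$r, tolerance = 1e-12)

  d3 <- mk()
  rownames(d3)[1] <- colnames(d3)[1] <- "other"
  expect_error(mantel_test(d1, d3), "same accessions")
})

test_that("WGS84 geographic distances behave like a metric", {
  sm <- as_species_map(data.frame(
    accession_id = c("o", "e"), species = c("s", "s"),
    lat = c(0, 0), lon = c(0, 1)))
  d <- geo_distance_matrix(sm)
  expect_equal(d["o", "o"], 0)
  expect_equal(d["o", "e"], 111.32, tolerance = 0.01)

  set.seed(80)
  for (rep in 1:10) {
    smr <- as_species_map(data.frame(
      accession_id = c("a", "b", "c"), species = "s",
      lat = runif(3, -60, 60), lon = runif(3, -179, 179)))
    dr <- geo_distance_matrix(smr)
    expect_lte(dr["a", "c"], dr["a", "b"] + dr["b", "c"] + 1e-6)
    expect_equal(dr, t(dr))
  }

  with_na <- as_species_map(data.frame(
    accession_id = c("a", "b", "c"), species = "s",
    lat = c(10, NA, 20), lon = c(10, 20, 30)))
  expect_warning(dna <- geo_distance_matrix(with_na), "excluded")
  expect_equal(rownames(dna), c("a", "c"))
  bad <- as_species_map(data.frame(accession_id = c("a", "b"),
                                   species = "s", lat = c(95, 0),
                                   lon = c(0, 0)))
  expect_error(geo_distance_matrix(bad), "out of range")
})
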