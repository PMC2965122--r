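# Seeded simulator for sequence and AFLP datasets with known species,
# region and gene-flow structure: ground truth for every pipeline stage.

# region centroids (decimal degrees, WGS84) spanning the collection range
# of a Himalayan/Indian sampling design
REGION_CENTROIDS <- data.frame(
  region = c("west_himalaya", "east_himalaya", "central_india", "south_india"),
  lat = c(32.5, 27.3, 23.3, 11.5),
  lon = c(77.0, 88.6, 80.0, 76.5)
)

#' Simulation configuration
#'
#' Defaults describe a barcode survey of a shrubby plant genus sampled
#' across four Indian biogeographic regions: 13 species with 4 accessions
#' each, a single ITS-like locus of 600 bp evolving under the Kimura
#' two-parameter model with transition/transversion ratio `kappa = 2`, an
#' interspecific tree depth giving mean interspecific K2P distances around
#' 0.011 and an intraspecific depth giving means around 0.003, and an AFLP
#' panel of 10 primer pairs with about 78 bands each, including 8 planted
#' species-unique bands. `inter_depth` is half the expected species-tree
#' pairwise path (substitutions/site); `intra_depth` is the branch length
#' from a species to each of its accessions, so conspecific pairs diverge
#' by `2 * intra_depth` in expectation. `gene_flow` is the probability that
#' an accession's haplotype is drawn from a random co-regional
#' heterospecific species instead of its own.
#'
#' @param n_species,accessions_per_species Sampling design.
#' @param n_regions Number of geographic regions (up to 4).
#' @param loci Named list of per-locus parameter lists with elements
#'   `length`, `kappa`, `inter_depth`, `intra_depth`.
#' @param gene_flow Probability in `[0, 1]`.
#' @param aflp List of AFLP parameters: `n_primers`, `bands_per_primer`,
#'   `base` (logit-scale intercept of band presence), `species_effect`,
#'   `region_effect` (logit-scale effect standard deviations),
#'   `n_unique_bands`, `unique_presence`.
#' @param gps_sd Spread (degrees) of accession coordinates around the
#'   region centroid.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 13, accessions_per_species = 4,
                       n_regions = 4,
                       loci = list(ITS = list(length = 600, kappa = 2,
                                              inter_depth = 0.004,
                                              intra_depth = 0.0015)),
                       gene_flow = 0,
                       aflp = list(n_primers = 10, bands_per_primer = 78,
                                   base = -1, species_effect = 0.5,
                                   region_effect = 1.5, n_unique_bands = 8,
                                   unique_presence = 0.9),
                       gps_sd = 0.75, seed = 1) {
  stopifnot(n_species >= 2, accessions_per_species >= 1,
            n_regions >= 1, n_regions <= nrow(REGION_CENTROIDS),
            gene_flow >= 0, gene_flow <= 1)
  for (l in loci) {
    stopifnot(l$length >= 1, l$kappa > 0, l$inter_depth >= 0,
              l$intra_depth >= 0)
  }
  structure(list(n_species = n_species,
                 accessions_per_species = accessions_per_species,
                 n_regions = n_regions, loci = loci, gene_flow = gene_flow,
                 aflp = aflp, gps_sd = gps_sd, seed = seed),
            class = "sim_config")
}

# K80 transition probabilities for a branch of expected length t
# (substitutions/site); alpha/beta scaled so the total rate is 1
k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1      # per transversion target (two of them)
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

# integer codes 1=A 2=C 3=G 4=T
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_FIRST <- c(2L, 1L, 2L, 1L)
TV_SECOND <- c(4L, 3L, 4L, 3L)

evolve_codes <- function(codes, t, kappa) {
  if (t <= 0) return(codes)
  p <- k80_probs(t, kappa)
  u <- stats::runif(length(codes))
  out <- codes
  ts <- u >= p["same"] & u < p["same"] + p["ts"]
  tv1 <- u >= p["same"] + p["ts"] & u < p["same"] + p["ts"] + p["tv"]
  tv2 <- u >= p["same"] + p["ts"] + p["tv"]
  out[ts] <- TS_PARTNER[codes[ts]]
  out[tv1] <- TV_FIRST[codes[tv1]]
  out[tv2] <- TV_SECOND[codes[tv2]]
  out
}

sim_design <- function(cfg) {
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  regions <- REGION_CENTROIDS$region[seq_len(cfg$n_regions)]
  species_region <- stats::setNames(
    regions[rep_len(seq_len(cfg$n_regions), cfg$n_species)], species)
  accession <- as.vector(vapply(species, function(s)
    paste0(s, "_", seq_len(cfg$accessions_per_species)),
    character(cfg$accessions_per_species)))
  acc_species <- rep(species, each = cfg$accessions_per_species)
  list(species = species, species_region = species_region,
       accession = accession, acc_species = acc_species)
}

sim_gps <- function(design, cfg) {
  region <- unname(design$species_region[design$acc_species])
  cent <- REGION_CENTROIDS[match(region, REGION_CENTROIDS$region), ]
  tibble::tibble(
    accession_id = design$accession,
    species = design$acc_species,
    region = region,
    lat = cent$lat + stats::rnorm(length(region), 0, cfg$gps_sd),
    lon = cent$lon + stats::rnorm(length(region), 0, cfg$gps_sd),
    section = NA_character_
  )
}

#' Simulate a multi-locus barcode sequence dataset
#'
#' Draws a pure-birth species tree, rescales it per locus so the mean
#' pairwise species path equals `2 * inter_depth`, evolves sequences
#' site-independently under the K80 substitution process, and grafts each
#' accession onto its species at depth `intra_depth`. Gene flow is modelled
#' as whole-haplotype reassignment: with probability `gene_flow` an
#' accession descends from a random co-regional heterospecific species
#' instead of its own (recorded in the truth record). Alignments are
#' gap-free by construction.
#'
#' @param cfg A [sim_config()].
#' @return A list: `alignments` (named list of [locus_alignment]),
#'   `species_map` (tibble with regions and GPS), `truth` (list with the
#'   species tree, per-locus scale factors and the `exchanged` tibble of
#'   gene-flow events).
#' @export
simulate_species_dataset <- function(cfg) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  design <- sim_design(cfg)
  phy <- ape::rphylo(cfg$n_species, birth = 1, death = 0)
  phy$tip.label <- design$species
  mean_path <- mean(ape::cophenetic.phylo(phy)[upper.tri(diag(cfg$n_species))])

  # gene flow: reassign source lineage once per accession, shared by loci
  source_species <- design$acc_species
  exchanged <- tibble::tibble(accession = character(),
                              original_species = character(),
                              donor_species = character())
  if (cfg$gene_flow > 0) {
    for (i in seq_along(design$accession)) {
      if (stats::runif(1) < cfg$gene_flow) {
        own <- design$acc_species[i]
        donors <- design$species[
          design$species != own &
            design$species_region[design$species] ==
              design$species_region[own]]
        if (length(donors) == 0) next
        donor <- donors[sample.int(length(donors), 1)]
        source_species[i] <- donor
        exchanged <- dplyr::bind_rows(exchanged, tibble::tibble(
          accession = design$accession[i], original_species = own,
          donor_species = donor))
      }
    }
  }

  alignments <- list()
  scales <- numeric(0)
  for (locus in names(cfg$loci)) {
    par <- cfg$loci[[locus]]
    scale <- if (mean_path > 0) 2 * par$inter_depth / mean_path else 0
    scales[locus] <- scale
    tr <- phy
    tr$edge.length <- tr$edge.length * scale
    n_tip <- cfg$n_species
    n_node <- n_tip + tr$Nnode
    seqs <- matrix(NA_integer_, n_node, par$length)
    root <- n_tip + 1L
    seqs[root, ] <- sample.int(4L, par$length, replace = TRUE)
    edges <- ape::reorder.phylo(tr, "cladewise")$edge
    lens <- ape::reorder.phylo(tr, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      seqs[edges[e, 2], ] <- evolve_codes(seqs[edges[e, 1], ], lens[e],
                                          par$kappa)
    }
    tip_seq <- seqs[seq_len(n_tip), , drop = FALSE]
    rownames(tip_seq) <- tr$tip.label
    acc_codes <- t(vapply(seq_along(design$accession), function(i) {
      evolve_codes(tip_seq[source_species[i], ], par$intra_depth, par$kappa)
    }, integer(par$length)))
    letters_mat <- matrix(BASES[acc_codes], nrow = nrow(acc_codes))
    rownames(letters_mat) <- design$accession
    alignments[[locus]] <- locus_alignment(letters_mat, locus_name = locus)
  }
  species_map <- sim_gps(design, cfg)
  list(alignments = alignments, species_map = species_map,
       truth = list(species_tree = phy, locus_scale = scales,
                    exchanged = exchanged, config = cfg))
}

#' Simulate an AFLP band matrix with species and region structure
#'
#' Band presence is Bernoulli with probability
#' `plogis(base + species_effect * z + region_effect * w)` where `z` and
#' `w` are standard-normal effects drawn per species-by-band and
#' region-by-band. `n_unique_bands` randomly chosen bands are planted as
#' species-unique: present (with probability `unique_presence`, and in at
#' least one accession) only in one randomly chosen species. Accession
#' coordinates are drawn around the region centroids.
#'
#' @param cfg A [sim_config()].
#' @return A list: `bands` (a [band_matrix]), `species_map` (tibble with
#'   GPS), `truth` (list with `planted_unique` tibble and the effect
#'   matrices).
#' @export
simulate_band_matrix <- function(cfg) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  design <- sim_design(cfg)
  a <- cfg$aflp
  n_bands <- a$n_primers * a$bands_per_primer
  band_id <- paste0(sprintf("P%02d", rep(seq_len(a$n_primers),
                                         each = a$bands_per_primer)),
                    ":B", sprintf("%03d", seq_len(n_bands)))
  n_acc <- length(design$accession)
  z <- matrix(stats::rnorm(cfg$n_species * n_bands), cfg$n_species, n_bands)
  regions <- REGION_CENTROIDS$region[seq_len(cfg$n_regions)]
  w <- matrix(stats::rnorm(cfg$n_regions * n_bands), cfg$n_regions, n_bands)
  sp_idx <- match(design$acc_species, design$species)
  reg_idx <- match(unname(design$species_region[design$acc_species]), regions)
  eta <- a$base + a$species_effect * z[sp_idx, , drop = FALSE] +
    a$region_effect * w[reg_idx, , drop = FALSE]
  bm <- matrix(stats::rbinom(n_acc * n_bands, 1, stats::plogis(eta)),
               n_acc, n_bands, dimnames = list(design$accession, band_id))
  planted <- tibble::tibble(band = character(), species = character())
  if (a$n_unique_bands > 0) {
    plant_cols <- sample.int(n_bands, a$n_unique_bands)
    plant_sp <- design$species[sample.int(cfg$n_species, a$n_unique_bands,
                                          replace = TRUE)]
    for (i in seq_along(plant_cols)) {
      j <- plant_cols[i]
      members <- design$acc_species == plant_sp[i]
      bm[, j] <- 0L
      bm[members, j] <- stats::rbinom(sum(members), 1, a$unique_presence)
      if (sum(bm[members, j]) == 0) bm[which(members)[1], j] <- 1L
    }
    planted <- tibble::tibble(band = band_id[plant_cols], species = plant_sp)
  }
  if (all(bm == 0)) warning("degenerate: no bands present", call. = FALSE)
  species_map <- sim_gps(design, cfg)
  list(bands = band_matrix(bm), species_map = species_map,
       truth = list(planted_unique = planted, species_effects = z,
                    region_effects = w, config = cfg))
}
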