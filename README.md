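# barcodegap

Evaluation of DNA barcode loci for plant species discrimination, with a
companion AFLP diversity analysis.

## The problem

A DNA barcode locus is useful only if interspecific divergence cleanly
exceeds intraspecific variation — the "barcoding gap". In recently
radiated or hybridizing plant genera that gap often collapses, and a locus
that works genus-wide elsewhere fails locally. `barcodegap` is for
systematists and molecular ecologists who need to *quantify* that failure
(or success) for candidate loci such as ITS, *matK*, *rbcL* and
*trnH-psbA*, using the standard battery of criteria:

* **K2P divergence.** Pairwise distances under the Kimura two-parameter
  model, d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q), with P and Q the transition
  and transversion proportions, computed after complete deletion of
  gapped/ambiguous columns.
* **Barcoding gap and discrimination.** Per species: maximum intraspecific
  vs minimum interspecific distance (pairs involving that species), the
  CBOL strict criterion `min_inter > max_intra`, inter/intra ratios, and a
  paired t-test of the gap across species. One-way ANOVA with Bonferroni
  pairwise comparisons ranks loci by divergence.
* **Monophyletic species recovery.** NJ and UPGMA trees from the K2P
  matrix, seeded column-resampling bootstrap with strict/majority-rule
  consensus, and the percentage of species forming exclusive clades —
  for single loci and for multilocus concatenations over common
  accessions.
* **Diagnostic characters.** Simple (single-position) and compound
  (2–3 positions jointly unique) species-diagnostic states, numbered in
  the coordinates of a reference sequence; supplied characters, including
  disjunctive ones, can be verified against the alignment.
* **AFLP.** Polymorphism and unique-band accounting per primer pair,
  Jaccard similarity S = a11/(a11+a10+a01), UPGMA phenogram with
  cophenetic correlation, principal coordinates analysis, and a Mantel
  test of Jaccard distance against WGS84 geodesic geographic distance.

A seeded simulator generates sequence and AFLP data sets with known
species/region structure, optional gene flow, and planted unique bands, so
every stage can be validated against ground truth without any downloads.

## Worked example

```r
library(barcodegap)

# a calibrated synthetic survey: 13 species x 4 accessions, ITS-like locus
sim <- simulate_species_dataset(sim_config(seed = 2026))
dm  <- k2p_matrix(sim$alignments$ITS)

glance(partition_divergence(dm, sim$species_map))
#>   mean_intra sd_intra n_intra mean_inter sd_inter n_inter n_undefined
#> 1    0.00335  0.00231      78     0.0118  0.00524    1248           0
```

Mean interspecific divergence (0.012) sits only ~3.5-fold above the
intraspecific mean (0.0034) — a shallow radiation. The per-species gap
statistics show what that does to identification:

```r
gs <- species_gap_stats(dm, sim$species_map)
barcode_gap_test(gs)
#>   statistic    df p_value n_species mean_gap
#> 1     -3.86    12 0.00228        13 -0.00310
```

The mean "gap" is *negative* (min-inter below max-intra, p = 0.002): there
is significant overlap, not a barcoding gap. Monophyletic recovery tells
the same story from the tree side:

```r
glance(species_recovery(nj_tree(dm), sim$species_map, "nj"))
#>   method n_species n_recovered pct_recovered
#> 1 nj            13           7          53.8
```

Only 7 of 13 species form exclusive clades. The AFLP panel, simulated with
a region effect stronger than the species effect, shows geography
structuring the genome-wide variation:

```r
ab <- simulate_band_matrix(sim_config(seed = 2026))
run_aflp_eval(ab$bands, ab$species_map, n_permutations = 999, seed = 1)
#> <aflp_eval> 52 accessions, 780 bands (100% polymorphic), 9 unique band(s)
#> cophenetic r = 0.959; Mantel r = 0.772 (p = 0.001)
```

The Mantel correlation between Jaccard and geographic distance is strongly
positive: accessions cluster by where they grow, not by what species they
are — the signature of weak reproductive isolation or introgression.

Real data enter through `read_aligned_fasta()` (one aligned FASTA per
locus), `read_species_map()` (CSV: `accession_id, species, region, lat,
lon`) and `read_band_matrix()` (CSV of 0/1 bands named `primer:band`);
`run_barcode_eval()` bundles the full sequence pipeline and
`write_report()` exports all tables (CSV) and trees (Newick).

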