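---
title: "Evaluating DNA barcode loci: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode loci: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`barcodegap` evaluates how well candidate DNA barcode loci (ITS, matK,
rbcL, trnH-psbA and similar short regions) discriminate plant species, and
complements the sequence view with an AFLP fingerprinting analysis. This
vignette describes the statistical machinery, the defaults, and the design
decisions a user should know about before trusting the output.

## The distance model

All sequence comparisons use the Kimura two-parameter (K2P) distance,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),$$

where $P$ and $Q$ are the proportions of compared sites differing by a
transition (A/G, C/T) and a transversion. K2P is the conventional model for
barcode surveys: it distinguishes the two substitution classes while
remaining essentially assumption-free at barcode-scale divergences. No
other substitution model, gamma rate heterogeneity, or model selection is
offered; at the divergences the gap analysis cares about (distances below
~0.1), model choice barely moves the estimates.

Indels and missing data are handled by **complete deletion**
(`complete_deletion()`): every alignment column carrying a gap *or an
ambiguity code* in any sequence is removed before any distance is computed,
so all pairs are compared over the same sites. The estimator can leave its
domain when sequences approach saturation ($1-2P-Q \le 0$); such pairs are
flagged undefined, excluded from every mean and SD, and counted in the
output (`n_undefined`) rather than silently propagated. Tree building
refuses matrices with undefined entries and asks the user to drop the
saturated accessions, because imputing them would fabricate topology.

Site statistics (`site_statistics()`) treat ambiguity codes (N, R, Y, ...)
as missing when counting variable and parsimony-informative columns. This
is the conservative convention — ambiguities never create variation — and
it means the percentages can sit slightly below those of software that
counts ambiguous states as real. Mean sequence length is the mean
*ungapped* length, i.e. the biological amplicon length, not the alignment
width.

## Barcoding gap, discrimination and locus comparison

For each species, `species_gap_stats()` reports the maximum intraspecific
distance, the minimum interspecific distance **over pairs involving that
species** (not the global minimum), and the ratio of the species' mean
inter- to mean intraspecific distance. Three conventions matter:

* Discrimination follows the CBOL plant working group rule with a strict
  inequality: `min_inter > max_intra`. A tie is a failure — a species whose
  closest heterospecific neighbour is exactly as distant as its most
  divergent conspecific cannot be identified reliably.
* A species with a single accession has no intraspecific pairs and is
  flagged *not evaluable* rather than being scored either way.
* The inter/intra ratio is `NA` when the species' mean intraspecific
  distance is zero; a ratio against zero is not informative and plotting
  infinities would dominate the figure.

The gap itself is tested by `barcode_gap_test()`: a paired two-sided
t-test of `min_inter` against `max_intra` across evaluable species. When
every paired difference is zero the test statistic is defined as 0 with
p = 1 (the no-gap case), a case `t.test()` itself refuses.

`anova_bonferroni()` compares divergence levels across loci with one-way
ANOVA followed by all pairwise pooled-variance t-tests, Bonferroni-adjusted
(p times the number of comparisons, capped at 1) — the plain reading of a
"Bonferroni multiple comparison test". An optional `log10` transform is
available for variance stabilisation; it requires strictly positive values
and is left to the caller's judgement.

## Trees, bootstrap and monophyletic recovery

Trees are built from the K2P matrix by neighbor joining (`nj_tree()`, via
`ape::nj`) and UPGMA (`upgma_tree()`, average-linkage `hclust`). Both
engines are deterministic; ties in the agglomeration are broken by the
engines' internal (index-order) rule, which is stable for identical input.
NJ can produce negative branch lengths on non-additive matrices; these are
clamped to zero with the deficit transferred to the daughter edges of the
affected node, preserving path lengths approximately and topology exactly.

`bootstrap_trees()` resamples alignment columns with replacement (after
complete deletion), recomputes the matrix and tree per replicate, and is
fully seeded. Replicates whose resampled matrix contains undefined
distances are skipped and counted. `consensus_tree()` offers strict and
majority-rule (>50%) consensus with bipartition frequencies annotated as
percentages.

A species is **monophyletic** (`is_species_monophyletic()`) when some
bipartition of the tree separates exactly its accessions from everything
else. Three conventions: a single-accession species is trivially
monophyletic (this keeps the denominators of recovery percentages equal to
the number of sampled species); a species whose complement is a single
accession is likewise separated (by that accession's terminal edge); and on
consensus trees a polytomy mixing species scores `FALSE`. Recovery
percentages (`species_recovery()`) are computed on the full-data
point-estimate tree, with bootstrap support reported separately on the
consensus — scoring recovery on the consensus instead is possible but
conflates resolution with support, so it is not the default.

Maximum parsimony is deliberately absent: it is a tree-search problem, not
a distance-pipeline component, and NJ/UPGMA carry the recovery comparison.

## Diagnostic characters

Character-based identification reports positions in the coordinate system
of a designated reference sequence (`map_to_reference()`): position 1 is
placed at a locus-specific origin (start of ITS1, first base of the start
codon, first spacer position), columns where the reference is gapped carry
no coordinate, and characters at unmapped columns are not reported.

A **simple** character is a single position at which all accessions of a
species (at least `min_accessions = 3`, the conventional threshold — fewer
accessions cannot distinguish fixation from sampling noise) share one
unambiguous base found in no other accession. A **compound** character is a
minimal combination of 2–3 such species-fixed states that are individually
shared with other species but jointly unique. Three rules keep the search
honest and bounded:

* Gaps or ambiguity within the species disqualify a position — fixation
  cannot be claimed on missing data. Missing data in *non-members* do not
  block a character (the accession visibly lacks the state) but are
  counted, so the user can judge the risk.
* Minimality: positions that are simple diagnostics are excluded from the
  compound search, and a combination is dropped when a sub-combination is
  already diagnostic. `k_max = 3` bounds the order, matching the range in
  which compound characters are used in practice; the combinatorial budget
  (`max_combinations`) converts a pathological search into a warning plus
  partial results instead of a hang.
* Disjunctive characters ("position 36 is G, and 66 is T *or* 86 is C")
  are **verified** (`verify_diagnostic()`) but never generated: there is no
  principled enumeration rule for disjunctions — any failure of a
  conjunction can be patched by enough alternatives — so the package checks
  claims rather than manufacturing them.

## AFLP analysis

`jaccard_distance()` computes 1 minus the Jaccard similarity
$S = a_{11}/(a_{11}+a_{10}+a_{01})$ over all bands pooled across primer
pairs — joint absences carry no information for dominant markers and are
ignored. The UPGMA phenogram is validated by the cophenetic correlation
(`cophenetic_correlation()`). PCoA (`pcoa_bands()`) is classical scaling:
double-centering of $-D^2/2$ and eigendecomposition. Jaccard distances are
generally non-Euclidean, so negative eigenvalues occur; they are reported,
no Cailliez/Lingoes correction is applied, and percent variance is
computed over the **positive** eigenvalues only — the convention is stated
here because software differs and it changes the percentages.

`geo_distance_matrix()` computes geodesics on the WGS84 ellipsoid
(Karney's algorithm via `geosphere::distGeo`, accurate well below 1 m).
`mantel_test()` correlates the two distance matrices with a one-sided
(positive association) permutation test, 999 permutations by default,
seeded; distances (not similarities) are correlated, so a positive r means
genetically distant pairs are geographically distant.

## The simulator

`sim_config()` fixes the study conditions the pipeline is validated
under: 13 species with 4 accessions each across 4 regions whose centroids
sit at realistic Indian coordinates (Western/Eastern Himalaya, central and
southern India); one ITS-like locus of 600 bp, transition/transversion
ratio $\kappa = 2$; a pure-birth species tree rescaled so the mean
species-tree path is $2 \times 0.004$, plus accession grafts at depth
0.0015 — together giving mean interspecific K2P distances near 0.011 and
intraspecific near 0.003, the magnitudes of a shallow, recently radiated
plant genus where barcoding is genuinely hard. Sequences evolve
site-independently under the exact K80 transition probabilities per branch
(no approximation at any depth). Gene flow is modelled as whole-haplotype
reassignment to a co-regional heterospecific lineage — the minimal
mechanism that mimics hybridization/introgression without coalescent
machinery. The AFLP panel has 10 primer pairs of ~78 bands (784 bands
total is the scale of a full AFLP survey), logistic band frequencies with
a region effect (1.5) deliberately stronger than the species effect (0.5)
— the geography-over-species regime — and 8 planted species-unique bands.

What the simulator does **not** emulate: indels and alignment error
(alignments are gap-free by construction, so complete deletion is
exercised only by constructed fixtures), rate heterogeneity across sites,
coalescent ancestry within species, selection, paralogy, and AFLP
homoplasy from co-migrating non-homologous fragments. Passing tests
therefore certify the arithmetic and the qualitative behaviour of the
pipeline, not robustness to these real-data complications.

```{r, eval = FALSE}
library(barcodegap)
sim <- simulate_species_dataset(sim_config(seed = 1))
dm  <- k2p_matrix(sim$alignments$ITS)
glance(partition_divergence(dm, sim$species_map))
```

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the simulator at its default
size (52 accessions, 600 bp; 780-band AFLP panels), with 4,000–5,000 bp
sequences where Monte-Carlo precision of divergence estimates is itself
under test, 10–50 bootstrap replicates where only reproducibility or
monotonicity is asserted, and 199–999 Mantel permutations. These sizes
give stable assertions at comfortable runtimes; the pipeline itself has no
built-in size limits. Exact algebraic identities (NJ on additive matrices,
UPGMA on ultrametric input, PCoA on Euclidean input) are asserted at
tolerances of 1e-8–1e-10; stochastic recovery checks use three
Monte-Carlo standard errors.

## Known limitations

* Complete deletion discards columns globally; for alignments with
  localised gappy regions, pairwise deletion (`deletion = "pairwise"` in
  `k2p_matrix()`) retains more signal but compares pairs over different
  site sets.
* The discrimination criterion and gap test treat species as fixed,
  correctly delimited units; they cannot detect that the taxonomy itself
  is wrong, only that the locus fails to separate it.
* Compound-character discovery is exhaustive only up to `k_max`; a species
  identifiable solely by a 4-site combination will be reported as lacking
  diagnostics.
* The Mantel test inherits the usual caveats about spatial autocorrelation
  inflating significance; with 13 species over 4 regions the permutation
  p-value should be read as descriptive support, not a causal claim.
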