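---
title: "Methods: distance- and character-based species delimitation for DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance- and character-based species delimitation for DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodedelim)
```

## The problem

DNA barcoding delimits animal species from short mitochondrial COI
fragments. Two complementary lines of evidence are standard when a set of
morphologically sorted specimens is examined:

1. **Distance evidence** — within a species, sequences differ little
   (intraspecific p-distances typically below a few percent); between
   species they differ much more. A *barcode gap* — every interspecific
   distance exceeding every intraspecific one — supports the morphological
   species hypothesis, and a bootstrapped neighbor-joining (NJ) tree shows
   whether each species' specimens cluster together.
2. **Character evidence** — *pure diagnostic characters*: alignment columns
   at which one species is fixed for a nucleotide that occurs in no other
   species. One such site is in principle enough to diagnose a species, and
   the set of them is a reusable molecular diagnosis.

`barcodedelim` implements this workflow end to end for a pre-aligned
barcode matrix plus a specimen table, and ships a synthetic-data generator
with planted truth so the whole pipeline can be validated without any
sequence downloads.

## Data model and the missing-state convention

An alignment is a specimen-by-site character matrix with one species label
per specimen (`barcode_alignment()`). Residues are upper-cased and `U` is
mapped to `T` on ingest. Every character outside `A/C/G/T` — gaps (`-`),
`N`, `?` and IUPAC ambiguity codes — is treated as a single **missing**
class throughout:

* distances use *pairwise deletion*: a column is dropped from one pair's
  comparison only when either member is missing there;
* site classification counts states over non-missing residues only;
* a missing residue neither supports nor contradicts a diagnosis.

Treating ambiguity codes as missing rather than as state sets is a
deliberate simplification, consistent across all three modules; software
that expands ambiguity codes can classify a handful of sites differently.
COI barcodes are protein-coding and effectively gap-free, so no aligner is
embedded: inputs are taken as aligned, and ends should be trimmed to the
common covered window beforehand (the bundled reproduction script does
this for the GenBank path).

## Distances and summaries

The uncorrected p-distance between two sequences is
`d = (# differing sites) / (# comparable sites)` — no multiple-hit
correction, matching standard barcode practice. `distance_matrix()` keeps
the per-pair comparable-site count; a pair with *zero* comparable sites is
an error naming the pair, since it signals disjoint coverage rather than a
distance of zero.

`summarize_species()` reports, per species, min/max/mean and the sample
standard deviation (denominator n−1) of (a) all unordered conspecific
pairs and (b) all distances from that species' specimens to every other
ingroup specimen — so each heterospecific pair contributes to both
species' interspecific rows, giving the familiar one-row-per-species
table. Conventions for undefined cells: intraspecific fields are `NA` for
singletons, and the intraspecific SD is `NA` when only one conspecific
pair exists (a single pair has no dispersion). Published tables vary on
this point (some print `0.000`, some `NA`, for two-specimen species); we
emit `NA` uniformly.

The `±` column in published barcode tables is ambiguous between the SD of
the pairwise values and a bootstrap standard error of the mean (MEGA's
default is a 1000-replicate site-resampling SE). We implement the printed
semantics — SD over pairwise values — and expose
`bootstrap_distance_se()` (site resampling, default 1000 replicates) for
the other reading; the two can differ noticeably for small species.

`barcode_gap()` reports per species `inter_min − intra_max`
(NA-propagating) plus the global extremes with the species attaining them;
a positive gap for every species is the distance-based delimitation
criterion.

## NJ tree and bootstrap

`nj_tree()` wraps the standard Saitou–Nei agglomeration (`ape::nj`),
deterministic given the matrix, exact on additive matrices (a property the
test suite verifies against path-length matrices of random trees up to 8
taxa). Negative branch lengths, an NJ artifact on non-additive input, are
clamped to zero with the deficit moved to the sister branch — standard
practice that keeps trees printable while approximately preserving path
lengths.

`bootstrap_support()` resamples alignment columns with replacement,
recomputes the distance matrix and NJ tree per replicate, and scores each
internal bipartition of the reference tree by the percentage of replicates
containing it, rounded to an integer percent (the convention of published
NJ figures). Three numerical choices matter:

* supports attach to **bipartitions** (unrooted splits identified by tip
  label sets), not node indices, so they survive outgroup rerooting;
* the random stream draws **column indices only**, so supports are
  reproducible given the seed and invariant to specimen input order;
* a replicate that leaves any pair with no comparable sites is redrawn
  (logged), up to 10× the replicate count, then errors.

The default replicate count is 1000 — a config default, chosen because it
makes integer percentages stable to ±1–2 for moderate supports.
`root_with_outgroup()` roots on the branch separating the outgroup when
that bipartition exists; otherwise it warns and roots on the first
outgroup tip's pendant edge. `write_newick()` renders supports as internal
node labels, omitting values below `support_min_display` (default 50, the
usual display convention) from the file but never from the tree object.
Species monophyly (`clade_support_by_species()`) is likewise judged by
bipartition, so an unrooted tree's arbitrary basal node cannot split a
species; singletons are reported trivially monophyletic with no support
value.

## Site classification and pure diagnostics

`classify_sites()` labels each column over its non-missing states:
`all_missing` (none), `constant` (one), otherwise variable, with
`parsimony_informative` meaning at least two states each carried by at
least two specimens. Counts satisfy
`constant + variable + all_missing = total`.

`pure_diagnostic_sites()` finds all (species, position, state) triples
such that every non-missing specimen of the species carries the state (at
least one specimen being non-missing), no non-missing specimen of any
other species carries it, and the column is variable overall — the
"pure simple" character of character-based delimitation. A species wholly
missing at a column cannot be diagnosed there (conservative reading of
missing data). By default outgroup specimens are excluded from the scan
(`ingroup_only = TRUE`): diagnoses are relative to the focal group, which
is how diagnostic-site figures are usually presented; set the flag off to
demand fixation against the outgroups too. *Private-but-not-fixed* states
(found in only one species but not in all its specimens) are a weaker
category, available separately via `include_private = TRUE` and never
mixed into the pure table. Positions are 1-based alignment coordinates.
`diagnostic_report()` renders the specimen-by-position grid with a logical
mask marking diagnostic cells — the machine-readable counterpart of the
shaded figure in barcode papers — with all missing states drawn as `-`.

## The synthetic generator

`simulate_dataset()` emulates the statistical shape of a multi-species
barcode study: a random ultrametric species tree is evolved from a uniform
random root sequence under a Jukes–Cantor-like model (each branch flips
each site with probability equal to the branch length, uniformly to one of
the three alternative bases); each species ancestor then receives
`n_planted_diagnostics` reserved columns where it carries a base unique to
it (all other species carry the root base there); each specimen is its
species ancestor plus a Poisson number of private mutations at
non-reserved columns; finally terminal runs may be masked as `-`,
mimicking the leading/trailing missing data of real barcode matrices.
Everything is driven by one seed; identical config + seed gives a
byte-identical FASTA.

Calibration of `paperlike_config()` — nine species with specimen counts
(7, 3, 2, 6, 3, 2, 2, 5, 5), 35 sequences, 662 sites: the species-tree
root depth is half the `interspecific_divergence` target (0.13) with joins
drawn between 40% and 90% of that depth, so interspecific p-distances land
at roughly 5–13%; `intraspecific_rate = 2` expected mutations per specimen
implies a mean pairwise intraspecific distance of about
`2 × 2 / 662 ≈ 0.6%`, ranging up to about 3% — the ranges typical of COI
barcode studies with a clean gap. Missing runs affect a quarter of
specimens, up to 40 sites.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no coalescent genealogies (within-species
variation is star-like around one ancestor), no rate heterogeneity or
codon structure, no homoplasy beyond what the substitution process
produces, no interior gaps, no sequencing error, and planted diagnostics
sit at reserved columns untouched by within-species mutation, so truth is
unambiguous by construction. Real datasets can show introgression,
incomplete lineage sorting and shared polymorphism that erode both the
barcode gap and diagnostic purity; the generator is a correctness harness,
not a population-genetic simulator.

## Validation design

The test suite validates each stage against independent oracles:
p-distances and diagnostics against naive brute-force loops on random
small alignments, NJ against path-length matrices of random trees, and
the pipeline against planted truth. The recovery study runs
`paperlike_config()` over 20 seeds with 200 bootstrap replicates each
(bootstrap percentages are then quantised at 0.5%, ample for a ≥95
threshold) and checks that all nine planted species are monophyletic,
species-clade supports reach ≥95 in at least 95% of species × seed
combinations, every species recovers at least its planted number of pure
diagnostics with masking off, and `inter_min > intra_max` holds per
species in every seed. `scripts/acceptance.R` re-runs a single such study
from scratch at a caller-supplied seed and writes the headline numbers as
JSON.

## Reproducing the published COI analysis

The package ships the 39-accession specimen table of the original
*Scaptodrosophila coracina*-group barcode study
(`inst/extdata/coracina_specimens.tsv`: 35 ingroup COI sequences across
nine species plus four outgroups). `inst/scripts/fetch_genbank.R`
downloads the accessions (network required, one time), trims to the
common covered window and runs the full pipeline with the four outgroup
species. Because the original alignment parameters are unpublished, the
exact column window — and hence exact site numbering of diagnostics — may
differ slightly from the published figure; distances, tree supports and
the diagnostic inventory are insensitive to columns outside the shared
window.

## Limitations

* No model-corrected distances in the headline path (p-distance
  throughout, as in standard barcode tables); no automatic gap
  partitioning (ABGD/ASAP) — the gap report is descriptive.
* No maximum-likelihood or Bayesian trees; NJ with bootstrap only.
* No compound (multi-site) diagnostics or tree-based character
  optimisation; pure single-site characters only.
* Ambiguity codes are missing data, which is conservative for diagnostics
  and may drop a few sites a state-set treatment would keep.

## A worked run

```{r, eval = FALSE}
res <- run_all(run_config(simulate = TRUE, sim_config = paperlike_config(),
                          bootstrap_replicates = 200, seed = 1,
                          out_dir = "barcode_run"))
res$verdicts
```

writes the distance matrices, summary and gap tables, the bootstrapped
Newick tree, clade supports, site classification, the diagnostic table,
grid and mask, and a per-species verdict table (monophyletic? ≥1 pure
diagnostic? positive gap?) under `barcode_run/`, with a log recording the
seed and package version.
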