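---
title: "Calling and characterizing bait interactomes from sonication-based 4C-seq"
author: "sonic4C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing bait interactomes from sonication-based 4C-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonic4C)
```

## The problem

Circularized chromosome conformation capture with sequencing (4C-seq) asks a
"one-versus-all" question: which genomic regions touch a chosen *bait* locus
in the nucleus? In the sonication-based variant, chromatin is cross-linked,
sheared by sonication, ligated, and amplified by inverse nested PCR from
bait-specific primers, so a sequenced fragment that spans a ligation junction
is a mosaic of bait sequence and the interacting partner. `sonic4C`
implements the downstream computation: from paired-end reads (or a
pre-aligned end-tag table) to distal interacting sites, statistically
enriched interacting domains, replicate-concordance statistics, and
anchor-centric integrative analyses against epigenomic tracks.

Because the method is defined by a chain of filters and statistics rather
than a single model fit, the package ships a synthetic-data generator that
emulates every input with a known ground truth. All statistical claims made
by the test suite are claims about recovery of planted truth or calibration
against null configurations of that generator.

## From read pairs to distal sites

The junction-calling chain applies, in order:

1. **Tag extraction** - the first 20 bp (5' end) of each mate is taken as an
   end tag; pairs with a read shorter than the tag are dropped and counted.
2. **Quality filtering** - a pair is kept only if both tags are uniquely
   mapped with MAPQ strictly greater than 20.
3. **Junction classification** - a pair with exactly one tag inside the
   ~0.6 kb bait is a junction read. The partner tag decides the class:
   another chromosome (`inter`), the same chromosome more than 10 kb from
   the bait (`distal_intra`), between 300 bp and 10 kb
   (`junction_proximal`), anything else `non_junction`. The four classes
   partition the input. Only `distal_intra` and `inter` feed downstream
   statistics; proximal junctions are recorded but excluded, since ligation
   products that close to the bait are dominated by self-circles and local
   contacts.
4. **Site merging** - partner tags on one chromosome are chained by single
   linkage while consecutive sorted positions are at most 100 bp apart; each
   chain is interpreted as PCR products of a single ligation event and
   becomes one site at the chain's median position (rounded down) with the
   chain size as read support. Sites with a single read are discarded as
   background noise.

Distance conventions are fixed and documented: bait membership is tag start
inside the bait interval; all bait distances are measured from the tag start
to the nearest bait boundary. The 100-bp rule is implemented as
single-linkage chaining rather than fixed genomic bins because chaining is
order-independent, idempotent, and matches the "single ligation event"
interpretation; a fixed-bin variant would split clusters straddling bin
boundaries. The median was chosen as the representative position because it
is robust to asymmetric PCR stacks; the convention only matters within the
+/- 50 bp tag jitter.

Alignment is deliberately out of scope: real libraries are mapped with an
external short-read aligner and consumed as a tag-pair table. For the
synthetic genome the package provides an exact-match lookup
(`align_tags_exact()`), valid there because simulated tags are verbatim
forward-strand substrings.

## Enriched interacting domains

Interaction frequency is scored per site: `C` is the number of sites (the
site itself included) within a window of length `lw = 2 Mb` centred on the
site, truncated at chromosome ends. Under a uniform background the expected
count in the window on chromosome `W` is

\[ \mu_w = N_W \, l_w / L_W , \]

with `N_W` the number of sites and `L_W` the chromosome length, and each
site receives

\[ z = (C - \mu_w) / \sqrt{\mu_w} , \]

a Poisson standardization. A binomial-variance variant,
`z = (C - mu)/sqrt(mu (1 - lw/L_W))`, is available via
`z_model = "binomial"`; the two are monotone transforms of `C` given
`(N_W, L_W, lw)`, so the permutation-based significance below is invariant
to the choice, and the Poisson form is the default for its simplicity.

Two consequences of this definition are worth knowing. First, because `C`
counts the site itself while `mu` does not, the null expectation of `z` is
slightly positive, `E[z] ~ (1 - lw/L_W)/sqrt(mu)` plus an edge-truncation
term; the permutation null reproduces the same offset, so calling is
unaffected. Second, neighbouring sites share windows, so z-scores are
strongly autocorrelated along the chromosome - another reason to calibrate
by permutation rather than against a nominal normal tail.

**Permutation FDR.** For each of 100 permutations, site positions are
redrawn uniformly per chromosome (preserving each chromosome's site count)
and z-scores are recomputed, pooling a null z distribution. The raw FDR at
an observed score `z*` is the mean per-permutation count of null scores at
or above `z*`, divided by the number of observed scores at or above `z*`,
clipped to `[0, 1]` - the standard E[V]/R plug-in estimator. Positions (not
z labels) are permuted: shuffling labels would leave the pooled z multiset
unchanged and make the estimator degenerate. Raw values are monotonized
(each site receives the best raw FDR achievable by any threshold at or
below its z) so significance is a threshold on z; the per-site counting
estimator is otherwise not monotone. Sites at FDR <= 0.05 are significant.

**Domains.** Every significant site seeds a +/- 1 Mb interval; overlapping
or book-ended seeds merge transitively; all sites inside a merged interval
become members. Domains never overlap and the result is invariant to input
order.

## Replicate concordance

Two statistics mirror standard practice. *Binned correlation*: sites are
counted in non-overlapping 2 Mb bins tiling every chromosome (zeros
included - empty bins carry replicate information; a nonzero-only option
exists) and the two replicate vectors are Pearson-correlated. *Relative
distance*: for each site of one replicate, the distance to the nearest site
of the other replicate divided by the distance between the two flanking
sites - uniform on `[0, 0.5]` under spatial independence, piled up near 0
for concordant replicates; uniformity is tested by Kolmogorov-Smirnov
against Uniform(0, 0.5). Query sites not flanked on both sides are skipped
and counted (no reflection at chromosome ends), except that a query
coinciding exactly with a reference site is 0 by definition.

## Anchor-centric integrative analyses

Every enrichment comparison follows one paradigm: compute a statistic at
the 4C sites, compute the identical statistic at matched randomly shuffled
sites, and compare the two samples with a rank or t test. The default
shuffle preserves per-chromosome site counts, removing chromosome-size
confounding; a genome-wide mode and an exclusion mask (e.g. assembly gaps)
are options. One matched shuffle is drawn per test (a pooled multi-draw
mode exists); tests are one-sided in the enrichment direction by default
and report their sidedness.

- **Peak enrichment** (`peak_enrichment()`): features counted within
  +/- 0.5 Mb of each anchor; Wilcoxon rank-sum against shuffled anchors.
  Windows truncate at chromosome ends without rescaling, so counts stay
  integers and random anchors face the same truncation.
- **TF tag enrichment** (`tf_tag_enrichment()`): ChIP tags counted within
  +/- 1 kb, scaled to 10 million library tags, control subtracted with a
  floor at 0 (a background estimate below the sample estimate carries no
  evidence of depletion at the anchor scale), Wilcoxon as above. Doubling
  every library size and every raw count leaves normalized counts unchanged.
- **Replication timing** (`replication_timing_profile()`): the
  length-weighted mean log2(early/late) over +/- 50 kb - the exact integral
  of the piecewise-constant track over the window divided by covered
  length. The default baseline is the identical window statistic at
  shuffled sites: the two samples are exchangeable under the null, so the
  rank test is calibrated. The length-weighted distribution of raw segment
  values (`baseline = "segments"`) is also available, but window means and
  raw segment values have different dispersions, which distorts the level
  of a rank-sum test; it is provided for descriptive comparisons. Segments
  with positive value are labelled early-replicating.
- **Distance densities** (`distance_density()`): signed nearest distances
  to TSS or CpG points, kernel density curves for sites and shuffled sites
  on a common grid and bandwidth, and a one-sided Wilcoxon test that
  absolute site distances are smaller ("steeper peak at 0").
- **Expression** (`gene_assignment_and_expression()`): each site is
  assigned all overlapping genes, or its single nearest gene when none
  overlaps (ties to the lower coordinate); the deduplicated gene set's FPKM
  is compared with an equally sized uniform random draw from the expression
  table by Welch's t-test. Random genes are not matched for length or
  chromosome - an unmatched draw is the natural null for "genes at
  interacting loci are more expressed".

## The synthetic study generator

`sim_config()` fixes the study conditions; `simulate_4c()` produces the
data with a complete truth table. The generator works at the abstraction
the pipeline consumes - end tags, not chemistry: it does not model
sonication fragment-size distributions or ligation biochemistry.

Defaults: three 10 Mb chromosomes; a 600 bp bait mid-chr1; 5 hotspot
regions of 50 kb holding 20 sites each plus 1000 uniform background sites
(1100 sites, matching a deeply sequenced bait library's scale); read pairs
per site shifted-geometric with mean 3 and minimum 1; 90 bp reads and 20 bp
tags; 10% noise pairs, 5% PCR duplicates, 5% MAPQ-degraded pairs. Tag
positions jitter uniformly within +/- 50 bp of their site so a merged
cluster always stays within the 100 bp rule, and planted sites keep at
least 250 bp spacing so two sites can never chain into one cluster -
without that constraint truth-exact recovery would be ill-posed, as the
merge of two adjacent truth sites would be correct behaviour. All sites are
placed more than 10 kb from the bait, so every planted interaction is
distal by the pipeline's definition. Background interaction density is a
free parameter: the biology of random intra-nuclear collisions fixes no
particular rate, so the default was chosen to give a realistic mix of
signal and noise.

Feature tracks place "active" features (enhancer-associated histone marks,
DHS, 5-hmC, pluripotency TF tags) with odds multiplied by
`track_enrichment = 10` near true sites; "repressive" marks are placed
independently of sites; replication-timing segments near sites have mean
log2 ratio +1 (sd 0.4), others 0; genes assigned to sites draw FPKM from a
lognormal with meanlog log(50) versus log(5) for the rest (the magnitude of
the expression effect is a free choice - only its direction is constrained
- and sdlog 1 gives a realistically heavy-tailed FPKM distribution). Null
configurations exist for every test: `n_hotspots = 0` for domain calling,
`track_enrichment = 1`, `timing_shift = 0` and equal FPKM parameters for
the association suite.

What the generator does *not* emulate: mappability structure, GC bias,
sequencing errors, strand effects, chromatin-domain-scale autocorrelation
of real tracks, or the bait-proximal cis-contact decay of real 4C. Passing
tests therefore demonstrate the correctness and calibration of the
computation, not robustness to every artefact of real libraries.

## Problem sizes and study conditions for the statistical checks

Three scale choices are deliberate and fixed in the test suite:

- **Null FDR calibration** runs 200 simulations of 1000 uniform sites on
  the default 3 x 10 Mb genome with default parameters (2 Mb window, 100
  permutations, FDR <= 0.05), asking that the median fraction of
  significant sites stay at or below 0.05 and the 90th percentile at or
  below 0.10.
- **Domain recovery power** uses 50 simulations of the default planted
  interactome on three 30 Mb chromosomes. The window-to-chromosome ratio
  (2 Mb / 30 Mb ~ 7%) approaches the regime of real mammalian chromosomes
  (2 Mb on 100-200 Mb, 1-2%), where a 20-site hotspot is a many-sigma
  excursion. On much smaller chromosomes the same 2 Mb window covers a
  fifth of the chromosome, the per-chromosome expectation `mu_w` absorbs
  most of the planted excess, and no threshold method can separate signal
  from background - a scale mismatch, not an implementation property.
  Expected: at least 4.5 of 5 hotspots recovered on average with at most
  one false domain per simulation.
- **Association calibration/power** uses 100 sites on three 100 Mb
  chromosomes with 1000 features per track and 2000 genes. Anchor windows
  of +/- 0.5 Mb must be small relative to inter-site spacing for an
  anchor-versus-random contrast to exist; with 1100 sites on 30 Mb the
  windows tile the whole genome and the contrast is degenerate by
  construction. The sparse large genome mirrors the real-data regime of
  thousands of sites on a ~2.6 Gb genome, and the gene count keeps gene
  density near the mammalian ~8 genes/Mb so that the genes assigned to 100
  sites are a small fraction of the expression table - at much lower
  density the "random gene" baseline is mostly interacting genes and the
  expression contrast dilutes itself.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open throughout (BED native); 1-based only
  at display.
- Window membership in `window_counts()` uses closed distance <= lw/2;
  boundary sites at exactly lw/2 are included.
- `merge_overlapping()` merges book-ended intervals (the domain-merge
  dialect); `overlap_regions()` requires a shared base, and reports
  connected components of the bipartite overlap graph (Venn semantics).
- Equidistant nearest-feature ties break to the lower coordinate;
  `nearest_feature_distance()` returns `NA` (never silent 0) for anchors on
  chromosomes without features, with a skipped-anchor count.
- Zero-variance bin vectors give `r = NA` with a warning, not an exception
  or a fabricated 0.
- Rank tests on two all-tied samples return p = 1 (no evidence) instead of
  the NaN a variance-zero normal approximation would produce. Otherwise
  ties are handled by `stats::wilcox.test`'s tie-corrected normal
  approximation (exact for small untied samples).
- All randomized operations take an explicit seed and restore the caller's
  RNG state; the full pipeline is byte-reproducible for a fixed config.

## Limitations

The z-model is a global-uniformity null per chromosome: real 4C data show
strong cis decay near the bait, which this model does not absorb (the
pipeline mitigates it by restricting to inter-chromosomal and >10 kb
contacts).
FDR granularity is limited by 100 permutations. The exact-match aligner is
for the synthetic genome only. Relative-distance edge handling skips
unflanked queries rather than reflecting, which loses a handful of values
per chromosome end.
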