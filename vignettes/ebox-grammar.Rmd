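---
title: "The E-box grammar of proneural factor binding: models and methods"
author: "eboxGrammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The E-box grammar of proneural factor binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eboxGrammar)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators emulate (and what they do not), and the numerical
and design choices made where the problem was genuinely open.

## 1. The E-box alphabet

A bHLH dimer binds the hexanucleotide CANNTG with each monomer contacting
one CAN half-site on opposing strands. Because the protein-facing surface of
a hexamer and of its reverse complement are identical, motif identity lives
on the quotient of the 16 CANNTG hexamers under reverse complementation:
10 classes, named by their two 5'→3' half-sites. Four classes are homotypic
(palindromic hexamer, a single representative: CATATG, CAGCTG, CACGTG,
CAATTG) and six heterotypic (two representatives each).

```{r}
eboxClasses()
```

Three conventions follow from this and are used everywhere:

* **Forward-strand scanning is complete.** A reverse-strand E-box is also a
  forward-strand E-box (its other spelling), so `scanEBoxes()` scans one
  strand and canonicalises. The strand-symmetry property (identical class
  multisets for a sequence and its reverse complement) is enforced by test.
* **Overlapping occurrences are all reported.** The spacing analysis needs
  every occurrence; no greedy masking is applied.
* **Hexamers containing N are not E-boxes; flanks may contain N.** Flank
  dinucleotides that run off the sequence are reported as `NN` and pooled
  into an "other" category by `flankBias()` — whether N-containing flanks
  belong in the analysis is genuinely open, so they are retained and
  reported separately rather than dropped.

The heterotypic label order (CAT-CAG but CAA-CAT) is pinned by a lookup
table: it is a naming convention, not derivable from a rule.

## 2. Coordinates, peaks and signal

In memory everything is a `GRanges` (1-based, closed); BED-family files are
converted on read and write, and narrowPeak summit offsets become absolute
positions immediately. One convention, applied once at the boundary, avoids
off-by-one drift through the many window rules below.

The consensus-peak rule for two replicates keeps an intersecting pair only
if **both summits fall within the intersection**; the consensus interval is
the intersection. Two points were open and decided here: the consensus
summit is the floor of the two summits' midpoint, and when one peak
qualifies against several in the other replicate the qualifying records are
merged by union, keeping the leftmost summit. Both choices are deterministic
and symmetric up to rounding.

`signalMatrix()` computes anchor-centred binned means weighting each track
interval by its base-pair overlap with the bin. Bins with no covered data
are `NA` — *missing*, never zero — and stay excluded from all downstream
means. This matters for methylation, where coverage exists only at CpGs.

`resizeToSummit()` clips at contig edges rather than discarding, with a
`clipped` flag, so peak counts are conserved through resizing.

## 3. Accessibility trajectories

Pseudotime-ordered cells are aggregated within cell type into pseudobulks of
`group_size = 175` cells; with 350-cell-per-type subsampling of the
developing-cortex data this yields the 8/5/7/8/2 layout (NSC, IPC, PN1, PN2,
PN3; 30 samples). A trailing remainder of at least half a group forms its
own group, otherwise it merges into the previous one (the data source is
silent; either choice affects only the final group of a type). Counts are
normalised as `log2(count / colsum * 1e6 + 1)`; the pseudocount (1) is
recorded in the object metadata. The ANOVA operates on log2 CPM — the scale
is configurable because the original choice is unstated.

**Invariance rule.** Each region is tested by classical one-way ANOVA across
cell types; regions with p ≥ 1e-6 are invariant, the rest dynamic.
Zero-variance regions are invariant by convention (Pearson r would be
undefined).

**Templates.** Dynamic regions are assigned to the binary trajectory
template they correlate with best. The template family is every binary
vector with a single contiguous run of 1s aligned to cell-type block
boundaries, excluding all-0 and all-1 — the smallest complete family
containing both canonical examples (the IPC+PN1 "transient" run and the
PN3-only "neuronal" run). For K blocks this gives K(K+1)/2 − 1 templates
(14 for the five-type layout). A run starting at the first sample is
*falling*, one ending at the last sample *neuronal*, an internal run
*transient*. Ties are broken by enumeration order, deterministically.

**Detection power.** The ANOVA gate has a hard power limit that is worth
understanding before interpreting recovery rates. The one-way F statistic
depends on the signal-to-noise ratio and on how the template splits the 30
samples: a run that differs from the rest in only 2 samples (the PN3-only
run, or the falling run closed only in PN3) has, at amplitude/noise = 4,
an expected F near 7.5 (p ≈ 3×10⁻⁴) — it can never reach p < 1e-6, at any
amplitude, because noise is specified proportional to amplitude. Such
regions are labelled invariant *by the method's own rule*, exactly as they
would be on real data. Consequently the package reports two recovery
numbers on synthetic data: recovery among regions admitted as dynamic by
the gate (the classifier's contract, ≈ 99.5%) and unconditional recovery
(≈ 75% at the default template mix, reflecting the gate's power, not a
classifier defect).

**Expression coupling.** `exprAccessCorrelation()` sorts cells by TF
expression, pools consecutive groups of 50, and correlates group-mean
expression with group-mean accessibility per region. The matching generator
`simCoupledCells()` targets this *pseudobulk-level* correlation: cell-level
noise is scaled by √(group size) so that averaging brings it back to the
intended magnitude. An unscaled bivariate construction would push every
group-level correlation toward 1 and make the target meaningless.

Other rules carried verbatim: a region is accessible in a cell cluster iff
at least 3% of cells have ≥ 1 count (inclusive); occupancy across a score
axis uses 50 equal-size quantile bins with the top/bottom fold (infinite
when the bottom bin is empty); the "scaled" Jaccard matrix divides each
query row by its row maximum (the scaling was not defined at the source;
row-max scaling makes the best match exactly 1 and is flagged as a choice).

## 4. Motif grammar statistics

All summit statistics use the signed distance d from the hexamer midpoint
(`floor((start+end)/2)`; a width-6 motif has no exact centre, and this
asymmetry of at most 1 bp is the granularity of every window rule) to the
peak summit, and require the full hexamer inside a window for membership.

* **Centrality**: motifs/bp in |d| ≤ 50 versus 250 ≤ |d| ≤ 750 (the
  half-width of 1500-bp resized peaks). Window lengths are
  2·50·n_peaks and 2·500·n_peaks. The variant with distal > 150 bp is a
  parameter setting. A class with no distal motifs reports `NA`, never
  infinity.
* **Motifs per peak**: mean count within |d| ≤ 100 per peak, with a per-bp
  fold versus motifs beyond 200 bp.
* **Flank bias**: each E-box contributes *two* half-site observations (both
  halves, each with its upstream dinucleotide read on its own strand); the
  16 dinucleotide proportions (+ "other") are compared near (≤ 100 bp) vs
  distal (> 200 bp).
* **Pair spacing**: for every ordered-by-position pair of E-boxes within
  the same peak, the gap is the number of intervening nucleotides between
  hexamer end and next hexamer start — so the over-represented spacing of
  "six nucleotides" is literally gap = 6. All pairs count, not only
  adjacent ones (unstated at the source; counting all pairs is the choice
  that needs no extra parameter), and overlapping hexamers land in an
  "overlap" bucket excluded from the proportions.
* **Score-binned enrichment**: peaks sorted into 10 score bins; the
  motif-counting window is either fixed or 0.4 of the peak length centred
  on the summit; optional per-class z-scaling across bins guards sd = 0
  rows by emitting zeros. For pre/post induction scores the fold is
  log2((post+1)/(pre+1)) — the pseudocount is a choice, recorded here.

## 5. Methylation

Methylation tracks are %CpG in [0, 100] with data only where CpGs are
covered. Profiles are `signalMatrix()` column means with SEM over anchors
with data. Per-class deltas average over covered base pairs within ±5 bp of
the hexamer midpoint (an 11-bp window); reading "5 bp around" as
midpoint-centred rather than hexamer-inclusive is a documented choice with
the alternative available via the `halfwidth` parameter. Deltas are stage B
− stage A in percentage points and are antisymmetric under swapping the
tracks; classes with no covered CpG report `NA`.

## 6. HT-SELEX enrichment

For each selection round, the statistic is the fraction of *reads* (not of
E-box-containing reads) carrying at least one representative hexamer of
each class, matched exactly on the forward strand — matching both
representatives makes class detection strand-insensitive, so whether the
original analysis also scanned reverse strands is moot. N never matches;
reads shorter than 6 bases are skipped with a warning.

`enrichmentTrend()` reports, per class: the least-squares slope across
rounds, a strict monotone-increase flag, the relative growth (last/first
round), and an `enriched` call = monotone **and** growth > 1.5. The growth
gate exists because strict monotonicity alone is weak evidence: across four
rounds a neutral class's fraction performs a small random walk and comes out
strictly increasing with probability near 1/8, so among nine neutral classes
at least one is typically "monotone" by chance. Genuine selection (odds 3
per contained hexamer per round) produces multi-fold growth and clears the
gate by an order of magnitude; neutral drift at 50,000 reads changes
fractions by a few percent at most.

## 7. Selection analysis

Within-species diversity uses SNVs with minor allele frequency ≥ 0.05
(inclusive) falling inside the hexamer (half-open interval). Between-species
divergence counts mismatched bases in the aligned hexamer against the
outgroup; any gap excludes the motif ("indel"), and motifs not covered by
the alignment are excluded with a distinct flag, so exclusion reasons remain
auditable.

**PSS/NSS ratios.** Putatively selected sites are E-boxes with |d| ≤ 50;
non-selected sites have 200 ≤ |d| ≤ 400 (bounds inclusive as printed).
Rates are counts per motif — hexamers are all 6 bp, so per-motif and per-bp
rates are proportional. Ratios with a zero denominator are missing.
`mkResample()` recomputes both ratios over seeded random subsets of a class
(without replacement); a subset lies in the *purifying* quadrant iff both
polymorphism and divergence ratios are < 1.

**Phylostratigraphy.** A motif is conserved in a species iff its aligned
hexamer equals the reference at all six positions; gaps exclude. Depth
assignment is *cumulative*: the deepest clade whose threshold and all
shallower thresholds are met (20/39 placentals, 1/3 marsupials, 1/1
monotreme, 8/16 non-mammals), "none" if the placental gate already fails.
Whether the original gating was cumulative is open; the cumulative reading
is the standard phylostratigraphic one and makes depth monotone in the set
of conserved species (a tested property). Excluded species never count
toward a conserved tally, but the required counts stay absolute.

## 8. The synthetic-data generators

Every generator is a pure function of (parameters, seed); truth tables
travel separately from the artifacts and are never read by analysis code.
Defaults are the study conditions where stated (1500-bp peaks, the
8/5/7/8/2 layout, 50-cell expression groups, four SELEX rounds, the clade
scheme); remaining magnitudes were chosen once as field-realistic and are
listed here:

* `simEBoxGenome()` — background GC 0.42 (mouse-like), per-bp planting
  rates 0.03 near / 0.01 distal for the 3× centrality condition (≈ 3 near
  motifs per peak, comparable to observed E-box counts near summits).
  Planting keeps ≥ 7 bp between hexamer starts and redraws the ±8 bp
  neighbourhood until no unintended E-box remains, so planted densities are
  interpretable as truth; requests too dense to satisfy the guard error
  out. Background E-boxes still arise at ≈ 3×10⁻⁴/bp per class outside the
  guard windows and are part of what the scanner correctly reports —
  recovered folds therefore sit a few percent below the planted ratio.
* `simPseudobulk()` — log2-scale signal `baseline 5 + amplitude 4 ×
  template + N(0, noise_sd 1)`, rounded powers of two as counts (closed ≈
  32, open ≈ 512). Noise is sd = 0.25 × amplitude, the stated SNR.
* `simSelex()` — round 1 uniform random 20-mers; each later round resamples
  with odds `retention_odds^(affinity-weighted hexamer count)`, odds 3 for
  CAT-CAT in the headline condition.
* `simConservation()` — neutral per-base rates 0.05 (both polymorphism and
  divergence, ≈ 0.3 events per motif); PSS constraint as a scalar or a
  per-class named vector; MAF drawn as 0.5·U² (low-frequency-skewed, so the
  0.05 threshold has mass on both sides); 1% of motifs receive an alignment
  indel to exercise exclusion; clade rates 0.03/0.08/0.12/0.2 increasing
  with divergence depth.
* `simMethylation()` — piecewise-constant 10-bp steps at baseline 80%,
  stage-specific dip of 60 points within ±100 bp of chosen-class sites;
  both stages share the same noise draw so a zero-dip configuration yields
  deltas of exactly zero.

**What passing on synthetic data does and does not show.** The generators
emulate the *statistical structure* the methods rely on: summit-graded
motif density, block-shaped accessibility with Gaussian log-noise,
multiplicative selection, clade-scaled substitution. They do not emulate
sequencing error, mappability artefacts, pseudotime estimation error,
linked selection or realistic branch lengths. Green tests demonstrate that
the estimators recover known truth under the stated noise model — not that
the biological conclusions transfer to any particular real dataset.

## 9. Problem sizes and determinism

The test suite and the acceptance script run the generators at
desk-friendly sizes chosen to keep binomial error well inside the asserted
bands: 100–200 peaks for centrality and spacing, 2,000 regions for
trajectories, 50,000 reads × 4 rounds for SELEX, 10,000 motifs for the
selection ratios (three seeds for the neutral null). All randomness flows
from explicit seeds; identical (parameters, seed) reproduce byte-identical
artifacts, which the suite checks via file checksums.

## 10. Known limitations

* The ANOVA invariance gate's power ceiling for 2-sample contrasts (see §3)
  is a property of the published rule, inherited deliberately.
* `pairSpacing()` enumerates all within-peak pairs, which is quadratic in
  sites per peak — fine for real peak densities, pathological only for
  adversarial inputs.
* bigWig is not parsed natively; methylation tracks are consumed as
  bedGraph (a bigWig can be converted upstream).
* The MK framework here contrasts rate ratios in PSS vs NSS windows; it
  does not estimate α or fit a population-genetic model.
* `speciesConservation()` treats any gap as exclusion, including a gap in a
  species whose remaining bases all match; this is the printed rule, at the
  cost of discarding some informative alignments.
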