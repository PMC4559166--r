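---
title: "Methods: planted-truth resequencing and convergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planted-truth resequencing and convergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotrace)
```

evotrace re-implements, as a tested and reusable pipeline, the computational
analyses used to characterise bacterial populations evolved under a chronic
stress: calling the point mutations, small indels, insertion-sequence (IS)
transpositions, large deletions and duplications that fix during roughly a
thousand generations of laboratory evolution, dating when each mutation swept,
and quantifying how strongly independently evolved lines converge in their
transcriptome and metabolome. Because the original sequencing runs are
platform-specific archives, every analysis here is driven instead by a
synthetic-data generator that plants a known event set into a synthetic
genome; the planted truth is the benchmark every caller is scored against.

## The synthetic-data generator

`generate_reference()` draws a random genome at a target GC content (default
0.508, a typical enteric-bacterium value), places non-overlapping gene
annotations, and attaches an IS catalog with an IS5-like element (1199 bp)
and an IS186-like element (1343 bp). One resident source copy of each element
is embedded in the reference sequence. This mirrors real bacterial
chromosomes, which carry multiple IS copies, and it is load-bearing: when a
transposed copy is sequenced, reads from inside the new copy align to the
resident copy, and that mis-pairing is exactly the evidence the structural
variant scan keys on (below).

`plant_events()` edits events into the sequence right-to-left so earlier
coordinates stay valid, and returns a piecewise-monotone lift-over between
reference and sample coordinates. Coordinates are 1-based and closed
throughout, matching both R string indexing and the Bioconductor convention;
all written output is likewise 1-based (BED export is converted to its
standard 0-based half-open form). Invariants enforced by tests: sample length
equals reference length plus the signed sum of event lengths, and the
lift-over round-trips exactly outside event footprints.

`simulate_mate_pairs()` draws fragment lengths from
Normal(`insert_mean`, `insert_sd`), places fragments uniformly on the
*sample* genome, and maps each end read back to *reference* coordinates
through the lift-over. The reported `distance` is the **outer distance** —
leftmost mapped base of one read to the rightmost of its mate, inclusive —
so an event-free pair measures exactly its fragment length. A read at least
50 % inside inserted novel sequence becomes a *counterpart read*: it maps to
the IS source copy (or is unmapped when the insertion has no catalog
element). The default SOLiD-style profile is 2 x 50 bp reads on a 1200 bp
insert; the insert SD default of 100 bp is a free simulator parameter, not a
published value. There is no base-level read model, no GC or mappability
bias, and no multi-mapping: the generator emits already-mapped coordinates,
which is the level of abstraction the downstream algorithms consume.

`simulate_pileups()` emits per-site depth ~ Poisson(coverage), with
variant-supporting counts Binomial(depth, `f(1-e) + (1-f)e`) at SNV sites
(`f` the population allele fraction, `e` the per-base error rate). Fixed
large deletions ablate depth across their footprint and duplications raise
it; small deletions keep full depth and emit indel-evidence counts instead,
emulating reads that align across a short gap. Expression, metabolome, OD600
and allele-frequency generators are described with their functions; the
expression generator gives every gene a smooth non-monotone trajectory
(random cubic in scaled time, zero at the parent state) *shared across
strains*, reproducing the synchronized slow expression dynamics that make
independently evolved lines converge, with an optional "divergent strain"
whose contiguous gene block is multiplied by 2 to emulate the expression
footprint of a large duplication.

What passing tests on these simulations do **not** show: robustness to
alignment artifacts, indel realignment errors, strand bias, or contamination
— none of which the generator produces. The package validates the
*algorithms* under their stated statistical assumptions, not a production
variant-calling stack.

## Point mutations and small indels

A site is called iff depth >= 10 reads, variant fraction >= 0.6, and the
one-sided binomial tail `P(X >= k | depth, e)` is below 1e-7. The 0.6
threshold keeps only mutations carried by the majority of the sequenced
population (these studies sequence mixed populations, not clones). Two
readings of "ratio" are possible — variant/total or variant/wild-type; we use
variant/total for both platforms, since a variant/wild-type ratio of 0.6
would accept 37 % minority alleles, contradicting the majority-of-cells
intent. Depth and ratio thresholds are inclusive at the printed values; the
p-value cut is strict. The binomial tail stands in for the proprietary
diBayes score: it reproduces its role (error-aware call confidence) with an
auditable formula, and tests pin it to an exhaustive-summation oracle at
1e-12 relative error.

Two platforms are called independently and reconciled by
`consensus_calls()`: agreed calls pass; discrepant calls are arbitrated by a
confirmation oracle (Sanger sequencing in the laboratory; the planted truth
table in simulations); positions the oracle cannot answer are flagged
unresolved, never silently accepted. Regions with fewer than 10 reads are
masked (`mask_low_coverage()`, strict `<`), with calls inside masks reported
separately, and variants present in the parent strain are subtracted.

## The mate-pair distance-deviation scan

Large indels are detected from the mapped-distance field: a fixed deletion of
L bp stretches every spanning pair's distance by +L, an insertion shrinks it
by L. The scan computes the genome-wide mean and n-1 standard deviation of
the outer distance, tiles the genome with overlapping windows (width =
insert mean, step = width/4, both configurable), and flags windows whose
**median** distance deviates from the mean by more than 3 SD (two-sided) with
at least 20 pairs. Overlapping flagged windows merge into regions; the
regional median is taken over the *peak* (max |z|) window, because outer
windows mix in non-spanning pairs and would bias the size estimate low.

Three numerical choices here differ from the most literal reading of the
screen and are deliberate:

* **Concordant-pair baseline.** The global mean/SD use concordant pairs only.
  Counterpart pairs measure the distance to the IS source locus — hundreds of
  kilobases — and a fraction of a percent of them inflates the SD enough
  (60-fold at desk scale) to blind the scan entirely.
* **Anchor keying.** Pairs enter windows at their fragment's flank-side
  (anchor) read. Keying by the minimum reference coordinate would send
  counterpart evidence to whichever locus is leftmost (usually the IS source,
  not the insertion); keying by both reads dilutes every window median into a
  50/50 mixture of starts and ends and nothing can cross the 3 SD line.
* **Counterpart override.** A region whose counterpart reads name one IS
  element is an insertion regardless of the sign of its median deviation.
  When the library insert is close to the element length
  (`insert_mean < size + 2 x read_length + 3 x insert_sd`), both-flank pairs
  are censored away and the regional median reflects the source-locus
  distance; the call is then reported with `size_estimate = NA` and
  `censored = TRUE` rather than a fabricated number. This is why a 1199 bp
  IS5 insertion is detectable but not sizeable on a 1200 bp library, while a
  5 kb library sizes it to a few percent.

Size estimates carry a small systematic bias at desk scale: spanning pairs
contaminate the genome-wide mean by (spanning fraction) x L, about 0.2-4 %
for the event sizes and 200-500 kb references used in the tests. On a
megabase-scale chromosome the same contamination is an order of magnitude
smaller.

The breakpoint estimate is the median of the anomalous pairs' read ends that
fall inside the region — a programmatic stand-in for the visual confirmation
used originally; it is accurate to a window, which is all the downstream
matching requires.

## Duplications from read depth

`coverage_profile()` counts read starts in non-overlapping windows (5 kb
default) and `detect_duplication()` reports maximal runs of >= 10 consecutive
windows at >= 1.5 times the genome-median window coverage. "Significantly
higher coverage" has no published threshold; ratio 1.5 over 10 windows
separates a single-copy tandem duplication (ratio 2) from Poisson noise at
any realistic coverage while staying insensitive to isolated noisy windows.

## Fixation timing and clone genotypes

Population allele frequencies are classified absent (< 0.2), polymorphic
([0.2, 0.8)) or fixed (>= 0.8). The two thresholds emulate the sensitivity
of calling a minor peak in a population Sanger chromatogram; they are not
published values and are arguments of `classify_allele_status()`. No
monotonicity is assumed — a trajectory that rises and falls (clonal
interference) is reported as observed, and the package deliberately adds no
inferential statistic on top of the descriptive timeline and the clone
genotype-group counts.

## Convergence of expression and metabolome

Expression matrices are quantile-normalised (every column receives the
across-column mean of sorted values; ties share the mean of the reference
values they span; the operation is idempotent), filtered at a quantification
limit of 100 a.u. — a gene is kept only if it exceeds the limit in *every*
sample — and expressed as log10 ratios against the parent column. PCA runs on
the gene-centred matrix by SVD, jointly over all strains and timepoints plus
the parent, so per-strain score trajectories ("orbits", anchored at the
parent) are directly comparable; fitting per strain would destroy that
comparability, which is the point of the figure. Log base 10 and Pearson
correlation on log-ratios are the package defaults wherever the original
analyses say only "log-transformed" and "correlation". Metabolite
concentrations follow the standard CE-TOFMS relative-peak-area formula
(`quantify_metabolite()`), with 50 uM chemical standards as the default
calibration point.

## Growth rates and group comparisons

The specific growth rate is the least-squares slope of ln(OD600) against
time. When no fit window is given, the contiguous sub-window of >= 4 points
with the highest R-squared is used (longest, then earliest, among ties),
which selects the whole series on clean exponentials and the exponential
phase on saturating ones; the estimator is exact on noiseless exponentials
and unbiased to < 1 % under 2 % multiplicative noise.

Groups are compared by one-way ANOVA followed by Dunnett's many-to-one test
against the control. Adjusted p-values come from the null distribution of the
maximum absolute equicorrelated multivariate-t component, evaluated by seeded
Monte-Carlo (default 1e5 draws sharing one chi-squared denominator per draw).
Monte-Carlo rather than table lookup handles arbitrary group counts and
unbalanced designs reproducibly; tests cross-check it against the
`multcomp` implementation and verify the familywise error rate stays in
[0.03, 0.07] at nominal 0.05 under a 5-group null.

## Scenario fixtures and problem sizes

`builtin_fixtures()` transcribes the per-strain event inventories of five
evolved strains (B-F): the recurrent IS5 insertion upstream of *hns*, the
IS5 disruption of *cspC*, the 88 bp *miaB* deletion, a 6775 bp twelve-gene
deletion, +1/+3 bp insertions, strain-specific SNVs, and a separate 200 kbp
duplication scenario. Chromosome positions are kept as metadata and rescaled
proportionally onto the synthetic reference; event lengths are never
rescaled. `run_scenario()` chains reference generation, planting, two pileup
platforms, dual-platform calling with truth-oracle consensus, the distance
scan with IS classification, and read-depth duplication detection, then
reconciles every call against the planted truth and reports recovery and
false-positive counts with a config hash for reproducibility.

The shipped tests and the acceptance script run at desk scale — 200 kb to
1 Mb references, 50-fold coverage, tens of thousands to a few hundred
thousand pairs — sizes chosen so the binomial and Poisson statistics the
thresholds act on are comfortably in regime while a full run takes seconds.

## Known limitations

* The generator emits mapped coordinates, not reads: alignment-level
  artifacts (soft-clipping, multi-mapping at repeats beyond the IS source
  convention, chimeric alignments) are out of scope.
* Reads from the resident IS source copy itself always map there; the
  reciprocal ambiguity of real repeats is not modelled, so the masked-region
  machinery sees less action on synthetic genomes than on real ones.
* Insertion size estimates under censored libraries are reported as `NA` by
  design; only an uncensored library sizes an IS-scale insertion.
* The duplication caller assumes a roughly uniform background; it would need
  GC correction on real data.
* Pairs straddling a tandem-duplication junction are stored with their
  coordinates sorted, as an aligner would report them; the resulting
  junction-distance anomaly is visible to the scan but duplications are
  called from read depth alone.
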