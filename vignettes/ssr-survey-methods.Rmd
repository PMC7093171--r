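---
title: "Methods: genome-wide SSR characterization and marker diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide SSR characterization and marker diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

# Scope

`ssrmine` implements the analysis stages of a genome-wide microsatellite
(SSR) survey of the kind run on newly assembled mammalian genomes:
perfect-repeat mining, motif classification, genomic-region-resolved
abundance statistics, tetranucleotide marker screening, and per-locus
population-genetic diversity statistics for a genotyped marker panel.
Because such surveys are often run on assemblies that are not publicly
deposited, the package also ships simulators that generate fully
specified genomes (with planted repeats and machine-readable truth
tables) and genotype datasets, so that every stage can be validated
without external data.

# Perfect SSR mining

A perfect SSR is an uninterrupted tandem repetition of a single 1–6 bp
unit. `find_perfect_ssrs()` reports *maximal* runs: a locus cannot be
extended on either side by a unit-phase base match. Formally, position
$i$ continues a period-$k$ run when $s_i = s_{i-k}$; a maximal region is
a maximal interval of such matches. Within one maximal period-$k$ region
only the leftmost start is left-maximal, so each region contributes at
most one candidate locus; if the leading $k$-mer is non-primitive (it is
itself a repetition of a shorter unit, e.g. `ACAC`), the region belongs
to the smaller period and is skipped — this is what guarantees a poly-A
run is reported once, as unit `A`.

Conventions, all of which are exercised against an independent
exhaustive oracle in the test suite:

* **Thresholds.** A locus must reach a minimum repeat copy number (RCN)
  per unit length; the defaults 12 / 7 / 5 / 4 / 4 / 4 (mono → hexa)
  are the widely used "systemic" criteria of genome-scale surveys. They
  are deliberately configurable (`mining_thresholds()`): published
  surveys frequently cite their criteria only by reference, so
  reproducing any particular table may require other settings.
* **Truncation.** Trailing partial units (`ACACA`) are cut back to
  complete copies for both RCN and the reported span.
* **`N` handling.** `N` is a hard terminator; it can never sit inside a
  locus or extend one. Lowercase (soft-masked) bases are ordinary bases.
* **Overlap resolution.** Candidates of different unit lengths may
  overlap (a long `(AC)n` also matches period 4). Loci are accepted
  greedily left-to-right, preferring earlier start, then smaller unit,
  then longer run; each base belongs to at most one reported locus.
  This is deterministic and matches the smallest-primitive-unit
  convention.

Repeat units that are circular permutations and/or reverse complements
of each other describe the same repeat observed in a different frame or
on the other strand, and are grouped as one type. `canonical_motif()`
returns the lexicographically smallest string over both rotation sets;
brute-force enumeration over all primitive $k$-mers
(`count_canonical_classes()`) gives 2, 4, 10, 33, 102 and 350 classes
for $k = 1..6$, which the tests assert.

# Genomic region partition

`build_region_model()` partitions every base into exactly one of five
classes — 5′UTR, CDS, intron, 3′UTR, intergenic — from a GFF3
annotation, with transposable elements (TEs) as a separate overlay that
may overlap any base class. Design choices where annotation conventions
genuinely vary:

* Introns are gaps between consecutive exons of one transcript; UTRs
  are exonic bases outside the CDS, sided by strand.
* When transcripts of a gene disagree, the longest transcript (largest
  summed exon length) defines the structure, giving a single consistent
  partition.
* Overlapping features from different genes are flattened with
  precedence CDS > 5′UTR > 3′UTR > intron.
* TEs are an overlay rather than a sixth partition class because
  surveys report TE-resident SSR counts alongside (and overlapping)
  genic/intergenic counts; TE relative abundance uses total merged TE
  length.
* A locus spanning a region boundary is assigned by its start
  coordinate, so every locus is counted exactly once. Published surveys
  rarely state their rule; start-assignment is deterministic and keeps
  per-region counts summing to the genome-wide count (an invariant the
  tests enforce).

# Survey statistics

* **Relative abundance** is loci per Mb of the sequence class searched
  (merged interval length, $10^6$ bp), the normalization that makes
  regions of unequal size comparable.
* **GC content** is computed over SSR spans only, pooled within a
  group. A perfect repeat's span GC equals its motif GC weighted by
  length, so no genome lookup is needed. (For per-region GC a
  whole-region alternative exists in principle; span-GC is the default
  because per-type GC tables in surveys are span-based.)
* **CV of RCN** is $\mathrm{CV} = S/\bar{x} \times 100\%$ with $S$ the
  standard deviation and $\bar{x}$ the mean of a group's repeat copy
  numbers. The sample SD ($n-1$) is the default since the defining
  formula does not fix the denominator; the population form is a
  switch. CV is undefined (reported `NA` with a reason) for $n < 2$ or
  zero mean, and is scale-invariant by construction.
* Tables are kept at full precision; display rounding (2 decimals for
  percentages and #/Mb) is left to the caller.

# Marker screening

`screen_candidates()` applies the criteria used for tetranucleotide
marker development: unit length 4, RCN in a configurable window
(default 7–15; where a survey quotes both an isolation window such as
10–22 and a design window, the design window is the single configurable
default), 200 bp of flank available on each side, and no other mined
SSR inside either flank. An optional exact-match uniqueness check of
each flank against the whole genome is off by default (quadratic cost).
Primer-length (18–23 bp) and product-size (190–450 bp) constraints are
recorded as metadata for downstream primer-design tools; thermodynamic
primer design itself is out of scope. Every rejection carries
machine-readable reasons, and widening the RCN window can only add
passing candidates (a monotonicity property the tests check).

# Diversity statistics

For a diploid co-dominant genotype table (`read_genotypes()`, one row
per individual, `a/b` calls, `NA` missing):

* **Ho** — fraction of typed individuals with two distinct alleles.
* **He** — Nei's unbiased gene diversity
  $\frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$ by default; the plain
  $1 - \sum p_i^2$ form is a switch, since published tables do not
  always state the convention. Note the unbiased *estimator* (computed
  from sample frequencies) has expectation $1 - \sum p_i^2$ at the true
  frequencies — this is the closed form the calibration tests compare
  against.
* **PIC** — Botstein's
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$. As a plug-in
  statistic it carries a first-order small-sample bias of about
  $-(1-\sum p_i^2)/2n$, which the calibration tests account for.
* **Ar** — allelic richness by hypergeometric rarefaction to $g$ gene
  copies, $\sum_a \left[1 - \binom{2N-N_a}{g}/\binom{2N}{g}\right]$
  (the FSTAT convention); $g$ defaults to the minimum $2N$ across loci.
  Ar is non-decreasing in $g$ and equals $k$ at $g = 2N$ — both
  verified against exhaustive subsample enumeration.
* **HWE** — the exact conditional probabilities test: given observed
  allele counts, the P value sums the probabilities of all genotype
  arrays no more probable than the observed one. The array space is
  enumerated completely when it holds at most `enum_limit` arrays
  (always feasible for two alleles); otherwise a Monte-Carlo estimate
  over random pairings of the gene copies is used with an explicit seed
  and the add-one correction, so $P \in (0, 1]$. The default of 100,000
  replicates suits single-locus analysis; the large calibration runs in
  this package use 3,000 replicates per locus, which keeps the
  Monte-Carlo standard error near the 0.01 decision threshold at about
  0.002. Monomorphic loci return $P = 1$ by convention.
* Loci with $P$ below `hwe_alpha` (default 0.01) are flagged in
  `run_popgen()` — the conventional candidates for exclusion from a
  marker panel. No multiple-testing correction is applied, mirroring
  standard marker-panel practice; users comparing many panels should
  correct externally.

# Simulators and what they do (not) show

`simulate_genome()` builds an i.i.d.-background genome at a target GC,
lays out non-overlapping multi-exon genes and random TE intervals,
scrubs the background of accidental threshold-passing repeats by
single-base substitutions, and then plants perfect SSRs — separated by
at least two clean spacer bases, each wholly inside an interval of its
target region class. A final repair pass re-mines every sequence and
breaks any remaining discrepancy (outside planted spans), so mining at
the spec thresholds returns exactly the truth table; the truth file
records coordinates, motif, RCN and region labels, and the seed is
echoed into the output headers. Identical seeds give byte-identical
outputs.

Defaults describe a compact test genome: 4 × 150 kb sequences, GC 0.42,
8 genes per sequence, ~20% TE cover, 500 planted loci biased toward
introns and intergenic sequence with an A/AC-rich motif mix — a
caricature of a mammalian genome at 1/4500 scale. What it deliberately
does *not* model: imperfect/compound repeats, repeat-length mutation
processes, realistic TE sequence content, GC isochores, or assembly
artifacts. Passing the planted-truth tests therefore demonstrates
algorithmic correctness (coordinates, classification, bookkeeping), not
robustness to the messiness of real assemblies.

`simulate_genotypes()` draws genotypes with
$P(\text{het } i,j) = 2 p_i p_j (1-F)$ and
$P(\text{hom } i) = p_i^2 + F p_i (1-p_i)$; $F = 0$ is exact HWE. The
calibration experiments use 1,000 loci at $n = 36$ individuals (a
typical captive-population genotyping design) with 2–5 alleles per
locus and Dirichlet-distributed frequencies floored at 0.05 — loci
where every allele is common enough to be observed, as in a usable
marker panel.

# Validation problem sizes

The shipped tests validate: miner/oracle identity on 100 random 5 kb
sequences plus 25 structured 2 kb cases; canonical-class enumeration
over all 5,460 motifs up to 6 bp; end-to-end recovery of 500 planted
loci on a 600 kb simulated genome; HWE calibration (rejection rate at
$\alpha = 0.01$ within three binomial standard errors of 1%) and He/PIC
recovery on 1,000 simulated loci; and exact reproduction of the
published forest musk deer survey aggregates shipped under
`inst/extdata` (genome totals, per-region totals, and the 21-locus
marker panel means).

# Known limitations

* Only perfect repeats are modeled; imperfect and compound SSRs are out
  of scope by design.
* The greedy overlap rule discards a locus that begins inside an
  already-accepted one; surveys that double-count overlapping repeats
  will report slightly higher totals.
* The exact-enumeration HWE path is exponential in allele count;
  high-k loci fall back to Monte-Carlo, whose P values carry sampling
  noise of order $1/\sqrt{\text{reps}}$.
* The flank-uniqueness screen is exact string containment, not a
  mappability model.
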