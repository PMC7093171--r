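# ssrmine

Genome-wide microsatellite (SSR) characterization and marker diversity
analysis in R.

Newly assembled genomes are routinely surveyed for perfect
microsatellites — uninterrupted tandem repetitions of 1–6 bp units — to
describe their distribution across genomic regions and to develop
polymorphic markers for population genetics. `ssrmine` implements that
whole workflow for researchers running such surveys (or re-analysing
published ones):

* **Mining.** `find_perfect_ssrs()` reports every maximal perfect
  mono- to hexanucleotide repeat above configurable copy-number minima
  (defaults 12/7/5/4/4/4), described by its smallest primitive unit,
  with `N` as a hard terminator and deterministic resolution of
  overlapping candidates.
* **Motif classes.** Units that are circular permutations and/or
  reverse complements of each other are one repeat type;
  `canonical_motif()` maps each unit to the lexicographically smallest
  representative (`GT`, `TG`, `CA` → `AC`). There are 2/4/10/33/102/350
  classes for unit lengths 1–6.
* **Regions.** `build_region_model()` partitions the genome from GFF3
  into 5′UTR / CDS / intron / 3′UTR / intergenic (every base in exactly
  one class) with a transposable-element overlay from BED;
  `assign_region()` labels each locus by its start coordinate.
* **Statistics.** Counts, percentages, relative abundance (loci/Mb),
  span GC content, repeat-copy-number (RCN) histograms, and the
  coefficient of variation CV = S/x̄ × 100% of RCN per group
  (`summarize_by_type()`, `summarize_by_region()`, `motif_ranking()`,
  `cv_of_rcn()`).
* **Marker screening.** `screen_candidates()` selects tetranucleotide
  loci with RCN 7–15 and 200 bp clean flanks and exports flanked
  sequences for primer design.
* **Diversity.** From diploid genotype tables: observed/expected
  heterozygosity (Nei's unbiased He), Botstein's PIC, rarefaction-based
  allelic richness, and Hardy–Weinberg exact tests (complete
  enumeration where feasible, seeded Monte-Carlo otherwise), with panel
  summaries (`locus_diversity()`, `panel_summary()`, `run_popgen()`).
* **Simulators.** `simulate_genome()` and `simulate_genotypes()`
  generate annotated genomes with planted, truth-tracked repeats and
  HWE genotype datasets, so every stage is testable end to end.

The package also ships, under `inst/extdata/`
(`fmd_survey_table()`), the published summary tables of a genome-wide
SSR survey of the forest musk deer (*Moschus berezovskii*) genome,
used as worked examples and arithmetic fixtures.

## Worked example

Simulate a 600 kb annotated genome with 500 planted SSRs, run the full
pipeline, and look at the genome-wide summary:

```r
library(ssrmine)

sim <- simulate_genome(genome_sim_spec(seed = 7), out_dir = tempfile())
res <- run_ssr_pipeline(sim$paths[["fasta"]], sim$paths[["gff"]],
                        sim$paths[["te"]])
res$tables$by_type
#>   type n_loci gc_percent total_length_bp relative_abundance percentage
#>   Mono    159      51.99            2364             265.00       31.8
#>     Di    133      51.78            2702             221.67       26.6
#>    Tri     99      53.72            2556             165.00       19.8
#>  Tetra     67      47.74            1856             111.67       13.4
#>  Penta     32      55.73            1055              53.33        6.4
#>   Hexa     10      52.88             486              16.67        2.0
#>  Total    500      52.02           11019             833.33      100.0
```

All 500 planted loci are recovered (the per-type counts sum to the
truth table), relative abundance is loci per Mb of the 0.6 Mb genome,
and percentages are each type's share of all loci. RCN variability per
type, genome-wide:

```r
head(res$cv[res$cv$region == "Genome", ], 3)
#>  region type   n  mean_rcn   sd_rcn cv_percent
#>  Genome Mono 159 14.867925 3.910572   26.30207
#>  Genome   Di 133 10.157895 3.069503   30.21791
#>  Genome  Tri  99  8.606061 4.222917   49.06910
```

`sum(res$candidates$passes)` gives 9 passing marker candidates out of
67 tetranucleotide loci under the default screen. The published marker
panel reproduces its printed aggregates:

```r
pub <- fmd_survey_table("markers")
panel_summary(pub[!pub$discarded, ])
#> 21 loci, 76 alleles, mean Ho 0.423, He 0.445, Ar 3.609, PIC 0.397
```

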