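# tetramerge

Harmonization of multi-caller variant calls for a tetraploid cancer
cell-line genome.

## The problem

Cataloguing every mutation in an aneuploid cell line from whole-genome
sequencing requires several complementary detection strategies, because no
single algorithm sees all variant classes: an assembly-based small-variant
caller (run at ploidy 4 to respect the hypotetraploid karyotype) finds
substitutions and small indels with genotypes; a split-read caller finds
indels, duplications, inversions and inter-chromosomal translocations with
base-precise breakpoints; a read-pair caller finds large events from
anomalous insert sizes; and a read-depth caller assigns copy number from
binned coverage. Their outputs disagree in dialect, precision and
coverage, so building one catalog means filtering each call set by its own
quality metrics, masking unreliable assembly gaps, and merging across
callers with class-aware overlap rules. `tetramerge` implements that
harmonization as a tested, reusable R pipeline, together with the
downstream database matching and damaged-gene enrichment analysis, and a
synthetic tetraploid data generator so every stage can be verified against
a known ground truth.

## The core rules

* **QC filters** (defaults, with exact inclusivity): split-read calls kept
  with supporting reads ≥ 2, summed mapping score ≥ 100 and mean mapping
  score > 10; read-pair calls kept with confidence ≥ 80 and supporting
  pairs ≥ 4, insertions dropped when the breakpoint distance exceeds the
  inserted length; read-depth CNV calls removed when either t-test
  p-value ≥ 0.01 or the zero-mapping-quality fraction ≥ 0.5.
* **Interval algebra** (0-based, half-open): indels compare by
  *reciprocal* overlap (≥ 25% of both intervals); duplications and
  inversions by *one-way* overlap (≥ 25% of the tested call);
  translocations by breakpoint distance (both ends < 1000 bp).
  Short vs long indels split at 50 bp (length ≥ 50 is long).
* **Copy number**: a bin's normalized depth `d` maps to integer CN `k`
  iff `2d ∈ [k − 0.5, k + 0.5)`. Deletion sites are CN ≤ 1 (diploid-
  relative), homozygous deletions CN = 0, duplications CN ≥ 5
  (tetraploid-relative).
* **Hierarchical merge**: precise split-read-tier calls are union-merged
  first; read-pair calls overlapping that set are dropped, the rest
  merged in; read-depth calls likewise. Insertions merge overlap-only
  with no hierarchy. CN-0 segments overlapping any small-variant call are
  discarded; survivors with > 50% reciprocal overlap with a split-read or
  read-pair deletion take that call's breakpoints.
* **Database matching**: any-overlap for short indels (dbSNP-style),
  locus + allele for substitutions, ≥ 25% reciprocal for clinical records
  (after removing zero-star records unless OMIM-submitted, and
  common-flagged records), > 25% reciprocal for population SVs
  (DGV-style), > 90% reciprocal for pathogenic SVs (dbVar-style).
* **Enrichment**: damaged genes = genes with a rare (MAF < 0.001)
  high-impact small variant ∪ genes with coding exons under a homozygous
  deletion; each gene set (size K ≥ 50) is scored by the inclusive
  hypergeometric upper tail
  `P(X ≥ k) = Σ_{i≥k} C(K,i) C(N−K, n−i) / C(N,n)` with background
  N = 26,802 genes.

## Worked example

```r
library(tetramerge)
cfg <- simulation_config(seed = 7)  # desk-scale tetraploid world, 9 Mb
report <- run_pipeline(cfg)
report
#> <tetramerge_report>
#>   seed 7 | modal CN 4 | 10 merged classes
#>   merged loci: substitution=297, short_deletion=137, short_insertion=84,
#>     long_deletion=39, long_insertion=26, duplication=22, inversion=21,
#>     intra_translocation=4, inter_translocation=3, homozygous_deletion=35
#>   hom/het = 0.522, Ts/Tv = 2.00
#>   damaged genes: 148 | top enriched set: PLANTED_SET (p = 5.75e-96)

report$db_match_summary
#>   class           n_total n_matched   pct
#> 1 substitution        297       271 91.2
#> 2 short_deletion      137        52 38.0
#> 3 short_insertion      84        35 41.7
#> 4 long_deletion        39         2  5.13
#> 5 long_insertion      26         1  3.85
#> 6 duplication         22         2  9.09
```

The report says: the depth track recovers the tetraploid baseline (modal
CN 4); the merged catalog holds one locus per true variant minus the
calls lost to QC noise and caller sensitivity; ~91% of substitutions have
a planted database match (the generator plants matches at the rates the
real catalog reports, e.g. 93% for substitutions, so the recovered rate
tracks sensitivity); and the gene set planted with inflated overlap of
the damaged-gene list ranks first by hypergeometric tail probability.

Single rules are available directly, e.g.:

```r
hypergeom_tail(51, 1009, 781, 26802)
#> [1] 0.0001050712   # prints as 0.00011 at two significant figures
assign_integer_cn(c(1.9, 0.2, 2.25))
#> [1] 4 0 5
```

## Acceptance script

`scripts/acceptance.R` regenerates the headline desk-scale quantity from
scratch: it simulates a 10 Mb tetraploid depth track (100 bp bins, 65% of
bases at the baseline level, Gaussian depth noise), converts it to
integer copy numbers and reports the modal CN with the problem size, as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

The package consumes caller *output dialects*; it does not re-implement
any caller, read alignment or effect prediction. Synthetic data carry
coordinates and support metrics only — no sequence content, reads or
alignments.
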