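---
title: "Methods: harmonizing multi-caller variant calls on a tetraploid background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing multi-caller variant calls on a tetraploid background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramerge)
```

## The model

A hypotetraploid cancer cell line carries four (or nearly four) copies of
every chromosome. Building a genome-wide mutation catalog for such a
genome combines four evidence channels, each with its own failure modes:

1. a **small-variant caller** run at ploidy 4, reporting substitutions
   and small indels with four-allele genotypes (`0/1/1/1`, ...);
2. a **split-read caller**, reporting indels of all sizes, tandem
   duplications, inversions, and inter-chromosomal translocations with
   base-precise breakpoints but no allele frequencies;
3. a **read-pair caller**, reporting large deletions, insertions,
   inversions and both translocation types from anomalous insert sizes,
   with imprecise breakpoints;
4. a **read-depth caller**, reporting integer copy number in fixed bins.

`tetramerge` assumes these channels have already run; its job is the
harmonization: per-caller QC, gap masking, class-aware overlap algebra,
a precision-ranked cross-caller merge, copy-number classification,
database matching and damaged-gene enrichment. Every operation works in
0-based half-open coordinates internally; VCF boundaries are converted on
read and write.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| min supporting reads (split-read) | 2 | reads | discard singleton split-read evidence |
| min summed mapping score | 100 | score | joint support/quality floor |
| min mean mapping score | > 10 | score | strict bound; low mean = repetitive placement |
| min confidence (read-pair) | 80 | score | published operating point of the caller |
| min supporting read pairs | 4 | pairs | noise floor for insert-size evidence |
| CNV p-value removal bound | ≥ 0.01 | p | either t-test failing voids the call |
| zero-mapq removal bound | ≥ 0.5 | fraction | half the reads unplaceable = untrustworthy depth |
| short/long cutoff | 50 | bp | structural-variant database convention; length ≥ 50 is long |
| reciprocal overlap (indels) | 25% inclusive | fraction | symmetric match criterion |
| one-way overlap (dup/inv) | 25% inclusive | fraction | the large classes only need the tested call covered |
| hom-del replacement | > 50% strict | fraction | swap CN-0 breakpoints for precise deletion calls |
| pathogenic SV match | > 90% strict | fraction | near-identity requirement for clinical annotation |
| translocation cluster radius | < 1000 | bp | both breakpoints, strict |
| MAF rarity bound | < 0.001 | fraction | strict; "rare" per a 60k-sample panel |
| minimum gene-set size | 50 | genes | smaller sets are not tested |
| background universe | 26,802 | genes | nuclear gene count of the reference annotation |
| depth bin size | 100 | bp | partition of the read-depth signal |

Inclusivity follows each rule's stated wording exactly; the boundary
conformance test in the suite pins every bound at its exact edge.

## The depth convention (and a deliberate choice)

The integer CN assignment doubles the normalized depth and bins at
half-unit cut points: CN = k iff 2d ∈ [k − 0.5, k + 0.5). The cut points
are stated without a side; this package assigns boundaries **upward**
(2d = 4.5 → CN 5) and documents it. For the doubling rule to recover a
tetraploid baseline as CN 4, a bin's normalized depth must be defined as
CN/2 — a depth track normalized to the genome *average* would put the
modal level at 1.0 and yield modal CN 2 instead. The synthetic generator
therefore fixes normalized depth = CN/2, which makes the stated rule
self-consistent; when applying the package to a real depth track, the
track must be normalized to the diploid level, not the sample average.
This ambiguity is inherent to the doubling rule and is flagged here
rather than silently resolved.

## Merge algebra decisions

Where the procedure was genuinely open, the package fixes these choices:

* **"Adjacent or overlapping"** means bookended intervals merge: under
  half-open coordinates, end-of-one equal to start-of-the-next is the
  only gap-free reading of "adjacent". Insertions are the exception —
  they merge on direct overlap only, with no adjacency and no tool
  hierarchy, keeping the longest inserted length.
* **Insertions occupy a point interval** `[pos, pos + 1)`, giving them a
  well-defined interval algebra; two insertions at neighbouring positions
  do not merge.
* **Clusters are connected components** (transitive closure) of the
  pairwise merge relation. For interval classes this is computed by a
  start-sorted sweep (exact for interval graphs); for translocations,
  whose breakpoint-distance relation does not chain, by union-find over
  explicit pairs. Single-linkage chaining is accepted.
* **Cross-tier drops use the class's own comparison rule** (reciprocal
  25% for deletions, one-way 25% for duplications and inversions,
  breakpoint distance for translocations). The merge-drop step's rule is
  not separately specified anywhere, so the comparison rule is reused.
* **Hom-del replacement ties** (two candidates above 50% reciprocal) go
  to the higher reciprocal overlap, then to the split-read caller, then
  leftmost — deterministic and precision-preferring.
* **Substitutions pass through unmerged**: only one caller reports them
  with genotypes, and cross-caller substitution merging is not part of
  the procedure.
* **Intra-chromosomal translocations are breakpoint pairs**, not spans.
  Treating their (often megabase-sized) spans as intervals would collapse
  unrelated events under the adjacency rule; clustering them by the
  1000 bp breakpoint-distance rule keeps counts faithful to the one
  caller that reports them.
* **Modal CN ties** break toward the lower copy number (determinism; real
  profiles never tie).
* The 50 bp boundary is assigned to **long** (length ≥ 50), following the
  structural-variant database convention the split references.

## The synthetic world

The generator states a desk-scale analog of the real study's conditions
and the defaults are not tuned afterwards:

* A 9 Mb, three-chromosome genome at baseline CN 4 with 2% of each
  chromosome reserved as telomeric/centromeric gaps. Truth variants of
  ten classes (counts 300 substitutions down to 3 inter-chromosomal
  translocations) are placed mutually non-overlapping outside gaps.
  Copy-number-changing classes snap to depth-bin boundaries; long
  deletions sit at CN 1, homozygous deletions at CN 0, duplications at
  CN 5–6.
* Zygosity and base changes follow the genome-wide ratios the full-scale
  catalog reports: P(homozygous) = 0.635/1.635 and P(transition) =
  2.10/3.10. Short deletions stay heterozygous because an all-allele
  deletion *is* the homozygous-deletion class, which is simulated
  separately in short (small-variant-caller-detectable) and long
  (bin-resolvable) modes.
* Caller sensitivity defaults are 0.5–0.97 by class; breakpoint jitter
  (SD 150 bp) applies to the read-pair caller and, after bin snapping, to
  the read-depth caller. Support metrics are drawn from pass-grade
  distributions except for a configurable fraction (default 15%) that
  violates exactly one QC bound — so the QC filters remove a controlled,
  known set. False positives (5% of true calls) are placed uniformly
  outside gaps with pass-grade metrics, exercising masking and merging
  without a second noise model.
* Databases are planted at the match rates the real catalog reports
  (93% substitutions, 45%/44% short deletions/insertions, ~5–8% for the
  long classes), with distractor records engineered to sit on the wrong
  side of each rule: allele-mismatched substitution records, ≥ 100 bp
  indel records excluded by the VCF-to-interval conversion, zero-star and
  common-flagged clinical records, and dbVar near-misses at ~80%
  reciprocal overlap. Array genotypes are planted at exactly 97%
  zygosity concordance. One gene set is planted with half the
  damaged-gene list among 100 uniform decoys in a 26,802-gene universe.
* One master seed drives everything through deterministically derived
  substreams; a fixed seed reproduces byte-identical files.
* Inter-chromosomal translocations occupy distinct chromosome pairs while
  pairs last, because the split-read dialect merges same-pair
  translocations into one record; re-using a pair would merge two truths
  by construction.

**What the generator does not emulate:** sequence content (REF/ALT
strings are random bases), read-level artifacts, GC bias, caller-specific
breakpoint biases, overlapping/nested true variants, and mosaicism. A
green noiseless-closure test therefore establishes that the
*harmonization logic* is exact — not that the pipeline is robust to
failure modes the generator does not model.

## Numerical choices

* The hypergeometric upper tail is inclusive, P(X ≥ k), computed via
  `stats::phyper(k − 1, ..., lower.tail = FALSE)`, which works in log
  space internally; the suite checks it against direct combinatorial
  enumeration for every admissible margin with N ≤ 25. All five printed
  enrichment p-values (0.00011, 0.00015, 0.00017, 0.00020, 0.00023)
  reproduce at two significant figures with the inclusive tail.
* Raw p-values are reported and ranked — the published table carries no
  multiplicity correction. A Benjamini–Hochberg column (`padj_bh`) is
  attached, clearly as an extra, and never drives the ranking.
* Variants with no population-frequency record count as rare: absence
  from a panel of > 60,000 samples is itself evidence of rarity.
* Gene identity is uppercase symbol equality; no alias resolution
  (documented limitation).
* Enrichment is ranked within each gene-set collection file, not across
  concatenated collections.
* Empty inputs degrade explicitly: empty call files parse to empty
  collections; an empty damaged set warns and reports p = 1 everywhere;
  ratios with zero denominators are `NA`, never `Inf`.

## Limitations

* The contribution summary computes overlap fractions between callers for
  translocations by the breakpoint rule even though the full-scale
  analysis handled those classes "in a more involved manner"; treat those
  percentages as indicative.
* Genotypes are not re-estimated for merged loci; the merged record keeps
  contributing callers and source ids, not a consensus genotype.
* Database schemas are minimal dialects carrying exactly the fields the
  matching rules need; they are not full mirrors of the live resources.
* At full genome scale the O(n·m) matching loops would need interval
  trees; at desk scale (10^2–10^5 records) the simple loops are fast and
  easier to verify against brute-force oracles.
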