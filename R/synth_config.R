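#' Default per-caller sensitivity by variant class
#'
#' Which classes each emulated caller can report, and with what
#' probability a true variant of that class is emitted. The class-caller
#' map mirrors the real tool suite: the small-variant caller sees
#' substitutions, short indels, and short homozygous deletions; the
#' split-read caller sees indels of all sizes, duplications, inversions
#' and inter-chromosomal translocations; the read-pair caller sees large
#' events including both translocation types; the read-depth caller sees
#' copy-number-changing events spanning at least two depth bins.
#'
#' @return Named list (caller) of named numeric vectors (class ->
#'   detection probability).
#' @export
default_sensitivity <- function() {
  list(
    small_variant = c(
      substitution = 0.97, short_deletion = 0.95, short_insertion = 0.95,
      homozygous_deletion = 0.95
    ),
    split_read = c(
      short_deletion = 0.90, short_insertion = 0.85,
      long_deletion = 0.85, long_insertion = 0.70,
      duplication = 0.85, inversion = 0.90, inter_translocation = 0.90
    ),
    read_pair = c(
      long_deletion = 0.70, long_insertion = 0.50, inversion = 0.60,
      intra_translocation = 0.90, inter_translocation = 0.90
    ),
    read_depth = c(
      long_deletion = 0.80, duplication = 0.80, homozygous_deletion = 0.90
    )
  )
}

default_db_config <- function() {
  list(
    # Fraction of truth variants per class planted with a population
    # database match (dbSNP-style for short classes, DGV-style for long),
    # mirroring the match rates the real catalog reports: ~93% of
    # substitutions, ~45% of short deletions, ~44% of short insertions,
    # and far lower fractions for the long structural classes.
    match_fraction = c(
      substitution = 0.93, short_deletion = 0.45, short_insertion = 0.44,
      long_deletion = 0.051, long_insertion = 0.05, duplication = 0.083
    ),
    clinvar_pathogenic = 10,   # planted pathogenic short-variant matches
    clinvar_no_criteria = 5,   # zero-star records (filtered out)
    clinvar_omim = 2,          # zero-star but OMIM-submitted (kept, benign)
    clinvar_common = 3,        # common-flagged matches (filtered out)
    dbvar_pathogenic = 4,      # long variants with > 90% reciprocal matches
    array_sites = 120,
    array_concordance = 0.97,
    array_hom_ref = 15,        # planted hom-reference records (screened out)
    array_unresolvable = 5,    # records whose rsID has no reference allele
    high_impact_fraction = 0.30,
    rare_fraction = 0.90,      # of high-impact variants, fraction rare in the panel
    maf_missing_fraction = 0.25, # rare variants absent from the panel entirely
    exon_hit_fraction = 0.85,  # hom-dels planted with an overlapping coding exon
    n_genes = 26802,           # background universe: hg19 nuclear genes
    planted_set_size = 400,
    planted_overlap_fraction = 0.5,
    n_decoy_sets = 100,
    decoy_size_range = c(50, 2000),
    n_extra_records = 50       # per-database non-matching distractor records
  )
}

#' Build a simulation configuration
#'
#' Describes the synthetic tetraploid genome, its true variants, the four
#' emulated callers' behaviour and the planted databases. Defaults state
#' a desk-scale analog of the real study's world: a mostly copy-number-4
#' genome, nine truth variant classes plus homozygous deletions, 100 bp
#' depth bins, support-metric noise calibrated so the QC filters remove
#' `qc_fail_rate` of calls, and a homozygous/heterozygous balance and
#' transition/transversion balance matching the reported genome-wide
#' ratios (0.635 and 2.10).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param baseline_cn Baseline (modal) copy number, default 4.
#' @param variant_counts Named vector: true variant count per class.
#' @param size_ranges Named list of `c(min, max)` length ranges (bp).
#'   CNV-class variants are snapped to depth-bin boundaries.
#' @param homdel_long_fraction Fraction of homozygous deletions drawn
#'   from the long (bin-resolvable) size range.
#' @param sensitivity Per-caller, per-class detection probabilities;
#'   see [default_sensitivity()].
#' @param jitter_sd Breakpoint jitter SD (bp) for the imprecise callers
#'   (read-pair; read-depth after bin snapping).
#' @param qc_fail_rate Fraction of emitted calls given support metrics
#'   that fail that caller's QC filter.
#' @param fp_rate False-positive calls per caller, as a fraction of its
#'   true calls; placed uniformly outside assembly gaps with pass-grade
#'   metrics.
#' @param depth_noise_sd Gaussian noise SD on the normalized depth track
#'   (normalized-depth units; baseline depth is CN/2 = 2.0).
#' @param bin_size Depth bin width (bp), default 100.
#' @param min_gap Minimum spacing enforced between placed truth variants.
#' @param hom_fraction Probability a small variant is homozygous
#'   (all four alleles alternate).
#' @param ts_fraction Probability a substitution is a transition.
#' @param gap_fraction Fraction of each chromosome reserved as
#'   centromeric/telomeric gap regions.
#' @param other_cn_fraction Fraction of the genome assigned to background
#'   (non-baseline) copy-number levels, spread over `other_cn_levels`.
#' @param other_cn_levels Integer CN levels used for background segments.
#' @param db Database/gene-set planting parameters; see
#'   [default_db_config()] for fields.
#' @param seed Master random seed; all emitter substreams derive from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    chrom_lengths = c(chr1 = 4e6, chr2 = 3e6, chr3 = 2e6),
    baseline_cn = 4L,
    variant_counts = c(
      substitution = 300, short_deletion = 120, short_insertion = 80,
      long_deletion = 40, long_insertion = 25, duplication = 20,
      inversion = 20, intra_translocation = 6, inter_translocation = 3,
      homozygous_deletion = 20
    ),
    size_ranges = list(
      short_deletion = c(1, 49), short_insertion = c(1, 49),
      long_deletion = c(100, 8000), long_insertion = c(50, 500),
      duplication = c(1000, 30000), inversion = c(500, 20000),
      homozygous_deletion_short = c(10, 45),
      homozygous_deletion_long = c(200, 2000)
    ),
    homdel_long_fraction = 0.3,
    sensitivity = default_sensitivity(),
    jitter_sd = 150,
    qc_fail_rate = 0.15,
    fp_rate = 0.05,
    depth_noise_sd = 0.1,
    bin_size = 100L,
    min_gap = 200L,
    hom_fraction = 0.635 / 1.635,
    ts_fraction = 2.10 / 3.10,
    gap_fraction = 0.02,
    other_cn_fraction = 0,
    other_cn_levels = c(1L, 2L, 3L, 5L, 6L),
    db = default_db_config(),
    seed = 1L) {
  db_defaults <- default_db_config()
  for (nm in names(db_defaults)) {
    if (!nm %in% names(db)) db[[nm]] <- db_defaults[[nm]]
  }
  full_counts <- setNames(rep(0, length(TRUTH_CLASSES)), TRUTH_CLASSES)
  full_counts[names(variant_counts)] <- variant_counts
  config <- structure(list(
    chrom_lengths = chrom_lengths, baseline_cn = as.integer(baseline_cn),
    variant_counts = full_counts, size_ranges = size_ranges,
    homdel_long_fraction = homdel_long_fraction, sensitivity = sensitivity,
    jitter_sd = jitter_sd, qc_fail_rate = qc_fail_rate, fp_rate = fp_rate,
    depth_noise_sd = depth_noise_sd, bin_size = as.integer(bin_size),
    min_gap = as.integer(min_gap), hom_fraction = hom_fraction,
    ts_fraction = ts_fraction, gap_fraction = gap_fraction,
    other_cn_fraction = other_cn_fraction, other_cn_levels = other_cn_levels,
    db = db, seed = as.integer(seed)
  ), class = "simulation_config")
  validate_config(config)
  config
}

validate_config <- function(config) {
  with(config, {
    if (any(variant_counts < 0)) stop("variant counts must be >= 0")
    if (!all(names(variant_counts) %in% TRUTH_CLASSES)) {
      stop("unknown variant class in variant_counts")
    }
    if (jitter_sd < 0) stop("jitter_sd must be >= 0")
    if (bin_size < 1) stop("bin_size must be >= 1")
    if (any(chrom_lengths < bin_size)) stop("chromosome lengths must be >= bin_size")
    if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
    if (qc_fail_rate < 0 || qc_fail_rate > 1) stop("qc_fail_rate must be in [0, 1]")
    if (depth_noise_sd < 0) stop("depth_noise_sd must be >= 0")
    if (other_cn_fraction < 0 || other_cn_fraction >= 1) {
      stop("other_cn_fraction must be in [0, 1)")
    }
  })
  invisible(config)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d chromosome(s), %.1f Mb, baseline CN %d, seed %d\n",
    length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6, x$baseline_cn, x$seed
  ))
  counts <- x$variant_counts[x$variant_counts > 0]
  cat("  truth variants:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}
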