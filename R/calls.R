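#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical caller identifiers, in merge-precedence order. The first two
# (assembly/split-read based) resolve breakpoints at base precision and
# form tier 1 of the hierarchical merge; read-pair evidence is tier 2 and
# binned read-depth evidence tier 3.
CALLERS <- c("small_variant", "split_read", "read_pair", "read_depth")
CALLER_TIER <- c(small_variant = 1L, split_read = 1L, read_pair = 2L, read_depth = 3L)

# Variant classes of the unified call model. Size-resolved classes
# (short_/long_ deletion and insertion) appear after split_by_length();
# parsers emit the raw classes.
CALL_CLASSES <- c(
  "substitution", "deletion", "insertion", "duplication", "inversion",
  "intra_translocation", "inter_translocation"
)

TRUTH_CLASSES <- c(
  "substitution", "short_deletion", "short_insertion", "long_deletion",
  "long_insertion", "duplication", "inversion", "intra_translocation",
  "inter_translocation", "homozygous_deletion"
)

CALL_COLUMNS <- c(
  "call_id", "caller", "class", "chrom", "start", "end", "length",
  "chrom2", "pos2", "ref", "alt", "genotype", "zygosity",
  "supporting_reads", "summed_mapq", "mean_mapq",
  "confidence", "supporting_pairs", "bp_distance",
  "pval1", "pval2", "q0", "cn"
)

#' Empty unified call table
#'
#' Returns a zero-row tibble with the full column set of the unified
#' variant-call model. Metric fields that a caller does not report are
#' `NA` (the tabular rendering of "absent, never defaulted").
#'
#' @return A zero-row tibble.
#' @export
empty_calls <- function() {
  tibble(
    call_id = character(), caller = character(), class = character(),
    chrom = character(), start = double(), end = double(), length = double(),
    chrom2 = character(), pos2 = double(),
    ref = character(), alt = character(), genotype = character(),
    zygosity = character(),
    supporting_reads = double(), summed_mapq = double(), mean_mapq = double(),
    confidence = double(), supporting_pairs = double(), bp_distance = double(),
    pval1 = double(), pval2 = double(), q0 = double(), cn = double()
  )
}

# Coerce a partial call table to the canonical column set/order, filling
# absent metric columns with NA of the right type.
as_calls <- function(df) {
  template <- empty_calls()
  df <- as_tibble(df)
  for (col in CALL_COLUMNS) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(template[[col]][NA_integer_], length.out = nrow(df))
    }
  }
  df[, CALL_COLUMNS]
}

# Split a "0/1/1/1"-style genotype into an integer allele vector.
gt_alleles <- function(gt) {
  lapply(strsplit(gt, "[/|]"), as.integer)
}

#' Classify a polyploid genotype as homozygous or heterozygous
#'
#' A locus is homozygous-alternate when every allele is the same
#' non-reference allele (for ploidy 4: `1/1/1/1`); any mix of reference
#' and alternate alleles (or of two alternates) is heterozygous; all-zero
#' genotypes are reference.
#'
#' @param gt Character vector of genotypes, e.g. `"0/1/1/1"`.
#' @return Character vector: `"hom"`, `"het"` or `"ref"`.
#' @export
gt_zygosity <- function(gt) {
  vapply(gt_alleles(gt), function(a) {
    if (all(a == 0L)) "ref"
    else if (length(unique(a)) == 1L && a[1] > 0L) "hom"
    else "het"
  }, character(1))
}

# sample() without the scalar-x surprise: always samples from the vector.
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# Deterministic substream seeding: one master seed, per-component offsets.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 1000003 + 1) * 1009 + k) %% 2147483562L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
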