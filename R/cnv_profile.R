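#' Construct a binned copy-number profile
#'
#' A profile holds the normalized read-depth track in fixed-width bins
#' plus the bin size. Under this package's depth convention a bin's
#' normalized depth is CN/2, so the tetraploid baseline sits at depth 2.0
#' and the multiply-by-two integer assignment recovers the copy number.
#' Bins must tile each chromosome without overlap; the trailing bin may
#' be shorter than `bin_size`.
#'
#' @param bins Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `depth` (normalized read depth, >= 0).
#' @param bin_size Bin width in bp (default 100).
#' @return An object of class `cn_profile`.
#' @export
cn_profile <- function(bins, bin_size = 100) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(bins)))
  if (nrow(bins) == 0L) stop("empty profile: at least one bin is required")
  if (any(bins$depth < 0, na.rm = TRUE)) stop("negative normalized depth")
  bins <- as_tibble(bins)[order(bins$chrom, bins$start), ]
  by_chrom <- split(bins, bins$chrom)
  for (b in by_chrom) {
    if (any(b$start[-1] != b$end[-nrow(b)])) {
      stop("bins must tile each chromosome without gaps or overlap")
    }
  }
  structure(list(bins = bins, bin_size = bin_size), class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf(
    "<cn_profile> %d bins of %d bp across %d chromosome(s), %.0f bases\n",
    nrow(x$bins), x$bin_size, length(unique(x$bins$chrom)),
    sum(x$bins$end - x$bins$start)
  ))
  invisible(x)
}

#' Assign an integer copy number to a normalized depth value
#'
#' The normalized depth is doubled and the result is binned at half-unit
#' cut points (0.5, 1.5, 2.5, ...): CN = k exactly when 2d lies in
#' `[k - 0.5, k + 0.5)`. Cut points assign upward (2d = 4.5 gives CN 5);
#' depths below 0.25 give CN 0.
#'
#' @param d Numeric vector of normalized depths (>= 0).
#' @return Integer copy numbers.
#' @examples
#' assign_integer_cn(c(1.9, 0.2, 2.25)) # 4, 0, 5
#' @export
assign_integer_cn <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("normalized depth must be >= 0")
  as.integer(floor(2 * d + 0.5))
}

#' Derive maximal integer-CN segments from a profile
#'
#' Each bin is converted to an integer CN and maximal runs of equal CN
#' within a chromosome are collapsed into segments.
#'
#' @param profile A [cn_profile()].
#' @return Tibble with columns `chrom`, `start`, `end`, `cn`.
#' @export
derive_cn_segments <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  bins <- profile$bins
  bins$cn <- assign_integer_cn(bins$depth)
  out <- lapply(split(bins, bins$chrom), function(b) {
    r <- rle(b$cn)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    tibble(
      chrom = b$chrom[1], start = b$start[idx_start],
      end = b$end[idx_end], cn = r$values
    )
  })
  out <- dplyr::bind_rows(out)
  out[order(out$chrom, out$start), ]
}

#' Label copy-number segments as deletion / homozygous / duplication sites
#'
#' Deletions are defined relative to a *diploid* genome (CN <= 1), which
#' keeps read-depth deletion calls comparable with the breakpoint-based
#' callers; homozygous deletions are complete losses (CN = 0, a subset of
#' deletions on any ploidy background). Duplications are defined relative
#' to the *tetraploid* baseline (CN >= 5).
#'
#' @param segments Tibble from [derive_cn_segments()], or a [cn_profile()]
#'   (segments are derived first).
#' @return The segment tibble with logical columns `deletion`,
#'   `homozygous`, `duplication`.
#' @export
classify_cn_segments <- function(segments) {
  if (inherits(segments, "cn_profile")) segments <- derive_cn_segments(segments)
  segments$deletion <- segments$cn <= 1
  segments$homozygous <- segments$cn == 0
  segments$duplication <- segments$cn >= 5
  segments
}

#' Modal copy number of a profile
#'
#' The integer CN state covering the largest number of bases. Ties break
#' toward the lower copy number, for determinism.
#'
#' @param profile A [cn_profile()].
#' @return Integer scalar.
#' @export
modal_copy_number <- function(profile) {
  h <- cn_genome_fraction_histogram(profile)
  h <- h[order(-h$bases, h$cn), ]
  as.integer(h$cn[1])
}

#' Genome fraction per copy-number state
#'
#' @param profile A [cn_profile()].
#' @return Tibble with columns `cn`, `bases`, `fraction`; fractions sum
#'   to 1 over the covered genome.
#' @export
cn_genome_fraction_histogram <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  bins <- profile$bins
  cn <- assign_integer_cn(bins$depth)
  width <- bins$end - bins$start
  bases <- tapply(width, cn, sum)
  out <- tibble(
    cn = as.integer(names(bases)),
    bases = as.numeric(bases),
    fraction = as.numeric(bases) / sum(width)
  )
  out[order(out$cn), ]
}

#' Read a bedGraph depth track into a copy-number profile
#'
#' @param path Path to a 4-column bedGraph file (`chrom start end depth`,
#'   0-based half-open).
#' @param bin_size Bin width in bp.
#' @return A [cn_profile()].
#' @export
read_depth_track <- function(path, bin_size = 100) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    depth = gr$score
  )
  cn_profile(bins, bin_size)
}

#' Write CN segments as a BED file with CN in the score column
#'
#' @param segments Segment tibble (`chrom`, `start`, `end`, `cn`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cn_segments_bed <- function(segments, path) {
  df <- data.frame(
    chrom = segments$chrom, start = segments$start, end = segments$end,
    name = sprintf("cn_segment_%d", seq_len(nrow(segments))),
    score = segments$cn
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
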