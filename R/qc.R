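#' Quality-control thresholds
#'
#' Bundles every per-caller QC bound with the published defaults. Each
#' bound's inclusivity follows the stated rule exactly: split-read calls
#' are kept with >= 2 supporting reads, a summed mapping score >= 100 and
#' a mean mapping score strictly > 10; read-pair calls are removed below
#' confidence 80 or below 4 supporting read pairs (so >= 80 and >= 4 are
#' kept), and read-pair insertions with breakpoint distance greater than
#' the inserted length are removed; read-depth CNV calls are removed when
#' either t-test p-value is >= 0.01 or the zero-mapping-quality fraction
#' is >= 0.5 (removal bounds inclusive).
#'
#' @param min_supporting_reads Minimum split-read supporting reads (kept at >=).
#' @param min_summed_mapq Minimum summed mapping score (kept at >=).
#' @param min_mean_mapq Exclusive minimum mean mapping score (kept at >).
#' @param min_confidence Minimum read-pair confidence (kept at >=).
#' @param min_read_pairs Minimum supporting read pairs (kept at >=).
#' @param max_cnv_pvalue Removal bound on CNV t-test p-values (removed at >=).
#' @param max_q0_fraction Removal bound on zero-mapq fraction (removed at >=).
#' @param short_long_cutoff Short/long indel length split (long at >=).
#' @param translocation_max_dist Exclusive breakpoint-distance bound for
#'   translocation merging (bp).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_supporting_reads = 2,
                          min_summed_mapq = 100,
                          min_mean_mapq = 10,
                          min_confidence = 80,
                          min_read_pairs = 4,
                          max_cnv_pvalue = 0.01,
                          max_q0_fraction = 0.5,
                          short_long_cutoff = 50,
                          translocation_max_dist = 1000) {
  th <- list(
    min_supporting_reads = min_supporting_reads,
    min_summed_mapq = min_summed_mapq,
    min_mean_mapq = min_mean_mapq,
    min_confidence = min_confidence,
    min_read_pairs = min_read_pairs,
    max_cnv_pvalue = max_cnv_pvalue,
    max_q0_fraction = max_q0_fraction,
    short_long_cutoff = short_long_cutoff,
    translocation_max_dist = translocation_max_dist
  )
  if (any(unlist(th) < 0)) stop("all thresholds must be >= 0")
  structure(th, class = "qc_thresholds")
}

filter_result <- function(calls, keep, reason) {
  removed <- calls[!keep, , drop = FALSE]
  retained <- calls[keep, , drop = FALSE]
  attr(retained, "removed") <- tibble(
    call_id = removed$call_id,
    reason = if (nrow(removed) > 0) reason[!keep] else character(0)
  )
  retained
}

#' Filter split-read calls on support metrics
#'
#' Retained exactly when supporting reads >= 2, summed mapping score
#' >= 100, and mean mapping score (summed / reads) strictly > 10. Calls
#' missing any of the three metrics are rejected as unscorable.
#'
#' @param calls Unified call tibble from the split-read dialect.
#' @param thresholds A [qc_thresholds()].
#' @return Retained calls; removed calls (with reasons) in the
#'   `"removed"` attribute.
#' @export
filter_split_read_calls <- function(calls, thresholds = qc_thresholds()) {
  scorable <- !is.na(calls$supporting_reads) & !is.na(calls$summed_mapq) &
    !is.na(calls$mean_mapq)
  pass <- scorable &
    calls$supporting_reads >= thresholds$min_supporting_reads &
    calls$summed_mapq >= thresholds$min_summed_mapq &
    calls$mean_mapq > thresholds$min_mean_mapq
  reason <- ifelse(!scorable, "unscorable", "support_below_threshold")
  filter_result(calls, pass, reason)
}

#' Filter read-pair calls on confidence, support and the insertion rule
#'
#' Retained exactly when confidence >= 80 and supporting pairs >= 4, and,
#' for insertions, when the reported breakpoint distance does not exceed
#' the inserted length.
#'
#' @inheritParams filter_split_read_calls
#' @return Retained calls; removed ones in the `"removed"` attribute.
#' @export
filter_read_pair_calls <- function(calls, thresholds = qc_thresholds()) {
  scorable <- !is.na(calls$confidence) & !is.na(calls$supporting_pairs)
  is_ins <- calls$class == "insertion"
  ins_ok <- !is_ins | (!is.na(calls$bp_distance) & !is.na(calls$length) &
                         calls$bp_distance <= calls$length)
  pass <- scorable &
    calls$confidence >= thresholds$min_confidence &
    calls$supporting_pairs >= thresholds$min_read_pairs &
    ins_ok
  reason <- ifelse(!scorable, "unscorable",
                   ifelse(!ins_ok, "insertion_breakpoint_distance",
                          "support_below_threshold"))
  filter_result(calls, pass, reason)
}

#' Filter read-depth CNV calls on t-test p-values and mapping quality
#'
#' Removed when either t-test p-value is >= 0.01 ("either" semantics) or
#' the fraction of zero-mapping-quality reads is >= 0.5; both removal
#' bounds are inclusive. Calls missing a p-value are rejected as
#' unscorable.
#'
#' @inheritParams filter_split_read_calls
#' @return Retained calls; removed ones in the `"removed"` attribute.
#' @export
filter_cnv_calls <- function(calls, thresholds = qc_thresholds()) {
  scorable <- !is.na(calls$pval1) & !is.na(calls$pval2) & !is.na(calls$q0)
  pass <- scorable &
    calls$pval1 < thresholds$max_cnv_pvalue &
    calls$pval2 < thresholds$max_cnv_pvalue &
    calls$q0 < thresholds$max_q0_fraction
  reason <- ifelse(!scorable, "unscorable", "depth_signal_unreliable")
  filter_result(calls, pass, reason)
}

#' Mask calls overlapping assembly gap regions
#'
#' Structural variant calls sharing at least one base with a centromeric
#' or telomeric gap interval are removed — except inter-chromosomal
#' translocations, which are always retained (their breakpoints commonly
#' abut unresolved sequence yet the chromosome-pair evidence stands).
#'
#' @param calls Unified call tibble.
#' @param gaps Tibble of gap intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_bed_intervals()].
#' @return Retained calls; removed ones in the `"removed"` attribute.
#' @export
mask_gap_regions <- function(calls, gaps) {
  in_gap <- overlaps_any(calls$chrom, calls$start, calls$end,
                         gaps$chrom, gaps$start, gaps$end)
  # intra-chromosomal translocations: second breakpoint also checked
  is_itx <- calls$class == "intra_translocation"
  if (any(is_itx)) {
    in_gap[is_itx] <- in_gap[is_itx] | overlaps_any(
      calls$chrom2[is_itx], calls$pos2[is_itx], calls$pos2[is_itx] + 1,
      gaps$chrom, gaps$start, gaps$end
    )
  }
  keep <- !in_gap | calls$class == "inter_translocation"
  filter_result(calls, keep, rep("gap_overlap", nrow(calls)))
}

#' Split indel calls into short and long classes
#'
#' Short means length strictly below the cutoff; length >= cutoff is
#' long, following the structural-variant database convention for the
#' 50 bp boundary.
#'
#' @param calls Insertion/deletion calls with a `length` column.
#' @param cutoff Length cutoff in bp (default 50).
#' @return List with elements `short` and `long`.
#' @export
split_by_length <- function(calls, cutoff = 50) {
  stopifnot(all(calls$class %in% c("deletion", "insertion")))
  list(short = calls[calls$length < cutoff, , drop = FALSE],
       long = calls[calls$length >= cutoff, , drop = FALSE])
}

# Pairwise merge of one within-caller cluster into a single call row.
# Interval classes take the union span; insertions keep the longest
# inserted length; translocation clusters keep the leftmost member's
# breakpoint pair as the representative (a span union of breakpoints
# would be meaningless).
collapse_cluster <- function(rows) {
  if (rows$class[1] %in% c("intra_translocation", "inter_translocation")) {
    return(rows[order(rows$chrom, rows$start), ][1, , drop = FALSE])
  }
  out <- rows[1, , drop = FALSE]
  out$start <- min(rows$start)
  out$end <- max(rows$end)
  if (out$class[1] == "insertion") {
    out$end <- out$start + 1
    out$length <- max(rows$length)
  } else if (!all(is.na(rows$length))) {
    out$length <- out$end - out$start
  }
  out
}

#' Merge redundant calls within one caller and class
#'
#' Within-caller merge rules, applied per caller dialect:
#' split-read insertions merge on direct overlap of their point loci,
#' keeping the longest inserted length; split-read inter-chromosomal
#' translocations collapse to one record per (unordered) chromosome pair;
#' read-pair translocations cluster when both breakpoints lie strictly
#' within 1000 bp of each other (connected components of that relation);
#' every other class merges adjacent-or-overlapping calls. Clusters are
#' transitive closures, so the result is independent of input order and
#' idempotent.
#'
#' @param calls Unified call tibble from a single caller and single class.
#' @param thresholds A [qc_thresholds()] (for the translocation distance).
#' @return Merged call tibble; each row carries its source ids in the
#'   list column `merged_ids`.
#' @export
within_caller_merge <- function(calls, thresholds = qc_thresholds()) {
  if (nrow(calls) == 0L) {
    calls$merged_ids <- list()
    return(calls)
  }
  if (length(unique(calls$caller)) > 1L || length(unique(calls$class)) > 1L) {
    stop("within_caller_merge expects calls from a single caller and class")
  }
  caller <- calls$caller[1]
  class <- calls$class[1]
  if (class == "inter_translocation" && caller == "split_read") {
    cl <- match(paste(calls$chrom, calls$chrom2), unique(paste(calls$chrom, calls$chrom2)))
  } else if (class %in% c("inter_translocation", "intra_translocation")) {
    pairs <- which(outer(seq_len(nrow(calls)), seq_len(nrow(calls)), function(i, j) {
      i < j & breakpoint_match(
        calls$chrom[i], calls$start[i], calls$chrom2[i], calls$pos2[i],
        calls$chrom[j], calls$start[j], calls$chrom2[j], calls$pos2[j],
        thresholds$translocation_max_dist
      )
    }), arr.ind = TRUE)
    cl <- components_from_pairs(nrow(calls), pairs[, 1], pairs[, 2])
  } else if (class == "insertion") {
    cl <- cluster_intervals(calls$chrom, calls$start, calls$end, adjacent = FALSE)
  } else {
    cl <- cluster_intervals(calls$chrom, calls$start, calls$end, adjacent = TRUE)
  }
  merged <- lapply(split(seq_len(nrow(calls)), cl), function(idx) {
    rows <- calls[idx, , drop = FALSE]
    out <- collapse_cluster(rows)
    out$merged_ids <- list(sort(rows$call_id))
    out
  })
  out <- dplyr::bind_rows(merged)
  out[order(out$chrom, out$start), ]
}

#' Genome-wide small-variant summary ratios
#'
#' Computes the homozygous/heterozygous locus ratio over all small
#' variants with genotypes, and the transition/transversion ratio over
#' substitutions. Transitions are A<->G and C<->T; every other base
#' change is a transversion. A ratio with a zero denominator is `NA`.
#'
#' @param calls Unified small-variant calls (with `genotype`, and
#'   `ref`/`alt` for substitutions).
#' @return List with `hom_het_ratio`, `ts_tv_ratio`, and the four counts.
#' @export
variant_summary_stats <- function(calls) {
  zyg <- calls$zygosity
  if (all(is.na(zyg)) && nrow(calls) > 0) zyg <- gt_zygosity(calls$genotype)
  n_hom <- sum(zyg == "hom", na.rm = TRUE)
  n_het <- sum(zyg == "het", na.rm = TRUE)
  subs <- calls[calls$class == "substitution" & !is.na(calls$ref) & !is.na(calls$alt), ]
  is_ts <- toupper(subs$alt) == TS_PARTNER[toupper(subs$ref)]
  n_ts <- sum(is_ts, na.rm = TRUE)
  n_tv <- sum(!is_ts, na.rm = TRUE)
  list(
    hom_het_ratio = if (n_het > 0) n_hom / n_het else NA_real_,
    ts_tv_ratio = if (n_tv > 0) n_ts / n_tv else NA_real_,
    n_hom = n_hom, n_het = n_het, n_ts = n_ts, n_tv = n_tv
  )
}
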