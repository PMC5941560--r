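#' Overlap rule for a variant class
#'
#' Returns the comparison rule used when matching two calls of the given
#' class across callers: reciprocal 25% (inclusive) for deletions and
#' insertions; one-way 25% (inclusive, asymmetric: is the tested call
#' covered?) for the larger duplication and inversion classes; a
#' breakpoint-distance rule (both ends strictly within 1000 bp) for
#' translocations; exact locus identity for substitutions.
#'
#' @param class Variant class string.
#' @param f Overlap fraction for the interval rules.
#' @param max_dist Breakpoint distance bound (bp).
#' @return A list describing the rule (`kind`, `f` or `max_dist`).
#' @export
class_overlap_rule <- function(class, f = 0.25, max_dist = 1000) {
  if (class %in% c("deletion", "insertion", "short_deletion", "long_deletion",
                   "short_insertion", "long_insertion", "homozygous_deletion")) {
    list(kind = "reciprocal", f = f)
  } else if (class %in% c("duplication", "inversion")) {
    list(kind = "one_way", f = f)
  } else if (class %in% c("intra_translocation", "inter_translocation")) {
    list(kind = "breakpoint", max_dist = max_dist)
  } else if (class == "substitution") {
    list(kind = "exact")
  } else {
    stop(sprintf("no overlap rule for class '%s'", class))
  }
}

# Does call row `a` match locus row `b` under `rule`? Both are rows of
# tibbles with chrom/start/end (+ chrom2/pos2 for breakpoint rules).
match_under_rule <- function(rule, a_chrom, a_start, a_end, a_chrom2, a_pos2,
                             b_chrom, b_start, b_end, b_chrom2, b_pos2) {
  if (rule$kind == "reciprocal") {
    reciprocal_match(a_start, a_end, b_start, b_end, f = rule$f,
                     chrom1 = a_chrom, chrom2 = b_chrom)
  } else if (rule$kind == "one_way") {
    oneway_match(a_start, a_end, b_start, b_end, f = rule$f,
                 chrom1 = a_chrom, chrom2 = b_chrom)
  } else if (rule$kind == "breakpoint") {
    breakpoint_match(a_chrom, a_start, a_chrom2, a_pos2,
                     b_chrom, b_start, b_chrom2, b_pos2, rule$max_dist)
  } else {
    a_chrom == b_chrom & a_start == b_start & a_end == b_end
  }
}

calls_to_loci <- function(calls) {
  ids <- if ("merged_ids" %in% names(calls)) {
    calls$merged_ids
  } else {
    as.list(calls$call_id)
  }
  tibble(
    class = calls$class, chrom = calls$chrom, start = calls$start,
    end = calls$end, chrom2 = calls$chrom2, pos2 = calls$pos2,
    tier = unname(CALLER_TIER[calls$caller]),
    callers = as.list(calls$caller), source_ids = ids,
    provenance = ""
  )
}

cluster_loci <- function(loci, class, max_dist = 1000) {
  if (nrow(loci) == 0L) return(loci)
  if (class %in% c("intra_translocation", "inter_translocation")) {
    pairs <- which(outer(seq_len(nrow(loci)), seq_len(nrow(loci)), function(i, j) {
      i < j & breakpoint_match(
        loci$chrom[i], loci$start[i], loci$chrom2[i], loci$pos2[i],
        loci$chrom[j], loci$start[j], loci$chrom2[j], loci$pos2[j], max_dist
      )
    }), arr.ind = TRUE)
    cl <- components_from_pairs(nrow(loci), pairs[, 1], pairs[, 2])
  } else {
    cl <- cluster_intervals(loci$chrom, loci$start, loci$end, adjacent = TRUE)
  }
  out <- lapply(split(seq_len(nrow(loci)), cl), function(idx) {
    rows <- loci[idx, , drop = FALSE]
    rep_row <- rows[order(rows$tier, rows$start), ][1, , drop = FALSE]
    tibble(
      class = rows$class[1], chrom = rows$chrom[1],
      start = if (class %in% c("intra_translocation", "inter_translocation"))
        rep_row$start else min(rows$start),
      end = if (class %in% c("intra_translocation", "inter_translocation"))
        rep_row$end else max(rows$end),
      chrom2 = rep_row$chrom2, pos2 = rep_row$pos2,
      tier = min(rows$tier),
      callers = list(sort(unique(unlist(rows$callers)))),
      source_ids = list(sort(unique(unlist(rows$source_ids)))),
      provenance = paste(setdiff(unique(rows$provenance), ""), collapse = ";")
    )
  })
  out <- dplyr::bind_rows(out)
  out[order(out$chrom, out$start), ]
}

#' Hierarchical cross-caller merge of one variant class
#'
#' Precision-ranked merge: base-precise calls (small-variant and
#' split-read callers, tier 1) are union-merged first; read-pair calls
#' (tier 2) that overlap the tier-1 set under the class's comparison
#' rule are dropped and the remainder merged in; read-depth calls
#' (tier 3) are treated likewise against the accumulated set. Loci merge
#' when adjacent or overlapping (breakpoint-distance clusters for
#' translocations). Input must be QC-filtered, gap-masked,
#' within-caller-merged and of a single class.
#'
#' @param calls Unified call tibble (one class, any mix of callers).
#' @param f Overlap fraction of the class comparison rule (default 0.25).
#' @param max_dist Translocation breakpoint-distance bound (default 1000).
#' @return Merged locus tibble: `class`, `chrom`, `start`, `end`,
#'   `chrom2`/`pos2` (translocations), `callers` and `source_ids` (list
#'   columns), `provenance`. Dropped lower-tier calls are recorded in the
#'   `"dropped"` attribute (`call_id`, `reason`).
#' @export
hierarchical_merge <- function(calls, f = 0.25, max_dist = 1000) {
  if (nrow(calls) == 0L) {
    loci <- calls_to_loci(calls)
    attr(loci, "dropped") <- tibble(call_id = character(), reason = character())
    return(loci)
  }
  class <- unique(calls$class)
  if (length(class) > 1L) {
    stop("hierarchical_merge expects calls of a single class; got: ",
         paste(class, collapse = ", "))
  }
  rule <- class_overlap_rule(class, f = f, max_dist = max_dist)
  tiers <- unname(CALLER_TIER[calls$caller])
  loci <- NULL
  dropped <- list()
  for (t in sort(unique(tiers))) {
    ct <- calls_to_loci(calls[tiers == t, , drop = FALSE])
    if (!is.null(loci) && nrow(loci) > 0L && nrow(ct) > 0L) {
      keep <- vapply(seq_len(nrow(ct)), function(i) {
        !any(match_under_rule(
          rule, ct$chrom[i], ct$start[i], ct$end[i], ct$chrom2[i], ct$pos2[i],
          loci$chrom, loci$start, loci$end, loci$chrom2, loci$pos2
        ))
      }, logical(1))
      if (any(!keep)) {
        dropped[[length(dropped) + 1L]] <- tibble(
          call_id = unlist(ct$source_ids[!keep]),
          reason = sprintf("overlaps_higher_precision_tier%d_set", t)
        )
      }
      ct <- ct[keep, , drop = FALSE]
    }
    pool <- if (is.null(loci)) ct else dplyr::bind_rows(loci, ct)
    loci <- cluster_loci(pool, class, max_dist = max_dist)
  }
  attr(loci, "dropped") <- if (length(dropped) > 0) dplyr::bind_rows(dropped) else
    tibble(call_id = character(), reason = character())
  loci
}

#' Merge insertion calls across callers
#'
#' Insertions merge only on direct overlap of their point loci — no
#' adjacency, no precedence between tools. The longest inserted length
#' in each cluster is retained.
#'
#' @param calls Insertion calls (point intervals, `length` = inserted bp).
#' @return Merged locus tibble with an `ins_length` column.
#' @export
merge_insertions <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- calls_to_loci(calls)
    out$ins_length <- double(0)
    return(out)
  }
  stopifnot(all(calls$class == "insertion"))
  cl <- cluster_intervals(calls$chrom, calls$start, calls$end, adjacent = FALSE)
  out <- lapply(split(seq_len(nrow(calls)), cl), function(idx) {
    rows <- calls[idx, , drop = FALSE]
    ids <- if ("merged_ids" %in% names(rows)) {
      sort(unique(unlist(rows$merged_ids)))
    } else {
      sort(rows$call_id)
    }
    tibble(
      class = "insertion", chrom = rows$chrom[1],
      start = min(rows$start), end = max(rows$end),
      chrom2 = NA_character_, pos2 = NA_real_,
      tier = min(unname(CALLER_TIER[rows$caller])),
      callers = list(sort(unique(rows$caller))),
      source_ids = list(ids), provenance = "",
      ins_length = max(rows$length)
    )
  })
  out <- dplyr::bind_rows(out)
  out[order(out$chrom, out$start), ]
}

#' Merge homozygous deletions from the small-variant and read-depth callers
#'
#' Three steps: (1) CN-0 segments that share any base with *any*
#' small-variant-caller call are discarded (a complete loss admits no
#' small-variant evidence inside it, so such segments are read-depth
#' false positives); (2) surviving CN-0 segments with strictly greater
#' than 50% reciprocal overlap with a split-read or read-pair deletion
#' are replaced by that deletion's more precise breakpoints (best
#' candidate by reciprocal overlap, ties to the split-read caller, then
#' leftmost); (3) the result is merged, adjacent-or-overlapping, with the
#' small-variant caller's homozygous-deletion calls.
#'
#' @param homdel_calls Small-variant-caller homozygous-deletion calls
#'   (deletions with all-alternate genotype).
#' @param cn0_segments CN = 0 segments (`chrom`, `start`, `end`), e.g.
#'   from [derive_cn_segments()].
#' @param split_read_dels,read_pair_dels QC-filtered deletion calls from
#'   the breakpoint-based structural callers (replacement candidates).
#' @param small_variant_calls All small-variant-caller calls (used for
#'   the removal screen in step 1).
#' @return Merged homozygous-deletion locus tibble with provenance;
#'   removed CN-0 segments are recorded in the `"dropped"` attribute.
#' @export
merge_homozygous_deletions <- function(homdel_calls, cn0_segments,
                                       split_read_dels, read_pair_dels,
                                       small_variant_calls) {
  seg <- as_tibble(cn0_segments)
  dropped <- tibble(segment = character(), reason = character())
  if (nrow(seg) > 0L) {
    seg_id <- sprintf("cn0_%s_%d_%d", seg$chrom, as.integer(seg$start),
                      as.integer(seg$end))
    hit <- overlaps_any(seg$chrom, seg$start, seg$end,
                        small_variant_calls$chrom, small_variant_calls$start,
                        small_variant_calls$end)
    dropped <- tibble(segment = seg_id[hit],
                      reason = "overlaps_small_variant_call")
    seg <- seg[!hit, , drop = FALSE]
    seg_id <- seg_id[!hit]
  } else {
    seg_id <- character(0)
  }

  candidates <- dplyr::bind_rows(
    if (nrow(split_read_dels) > 0) split_read_dels[split_read_dels$class == "deletion", ],
    if (nrow(read_pair_dels) > 0) read_pair_dels[read_pair_dels$class == "deletion", ]
  )
  loci <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    row <- tibble(
      class = "homozygous_deletion", chrom = seg$chrom[i],
      start = seg$start[i], end = seg$end[i],
      chrom2 = NA_character_, pos2 = NA_real_, tier = 3L,
      callers = list("read_depth"), source_ids = list(seg_id[i]),
      provenance = ""
    )
    if (!is.null(candidates) && nrow(candidates) > 0L) {
      ov <- overlap_bp(seg$start[i], seg$end[i], candidates$start,
                       candidates$end, seg$chrom[i], candidates$chrom)
      frac <- pmin(ov / (seg$end[i] - seg$start[i]),
                   ov / (candidates$end - candidates$start))
      ok <- which(frac > 0.5)
      if (length(ok) > 0L) {
        best <- ok[order(-frac[ok],
                         candidates$caller[ok] != "split_read",
                         candidates$start[ok])][1]
        row$start <- candidates$start[best]
        row$end <- candidates$end[best]
        row$tier <- unname(CALLER_TIER[candidates$caller[best]])
        row$callers <- list(sort(unique(c("read_depth", candidates$caller[best]))))
        row$source_ids <- list(sort(c(seg_id[i], candidates$call_id[best])))
        row$provenance <- sprintf("cn0_replaced_by_%s", candidates$caller[best])
      }
    }
    loci[[i]] <- row
  }
  pool <- dplyr::bind_rows(c(loci, list(
    if (nrow(homdel_calls) > 0L) {
      hd <- calls_to_loci(homdel_calls)
      hd$class <- "homozygous_deletion"
      hd
    }
  )))
  out <- if (is.null(pool) || nrow(pool) == 0L) {
    empty <- calls_to_loci(empty_calls())
    empty
  } else {
    cluster_loci(pool, "homozygous_deletion")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Per-caller contribution summary for one merged class
#'
#' For each caller: the number of (within-caller-merged) calls it
#' supplied, the fraction of those calls that overlap any other caller's
#' calls under the class comparison rule, and the merged locus total.
#'
#' @param merged Merged locus tibble for the class.
#' @param calls The class's per-caller input calls (one tibble).
#' @param f,max_dist Rule parameters, as in [hierarchical_merge()].
#' @return Tibble: `class`, `caller`, `n_calls`, `overlap_frac`,
#'   `merged_total`.
#' @export
summarize_contributions <- function(merged, calls, f = 0.25, max_dist = 1000) {
  class <- if (nrow(calls) > 0) calls$class[1] else
    if (nrow(merged) > 0) merged$class[1] else NA_character_
  callers <- unique(calls$caller)
  rows <- lapply(callers, function(cal) {
    mine <- calls[calls$caller == cal, , drop = FALSE]
    others <- calls[calls$caller != cal, , drop = FALSE]
    frac <- if (nrow(others) == 0L || is.na(class) || class == "substitution") {
      if (class %in% "substitution") NA_real_ else 0
    } else {
      rule <- class_overlap_rule(class, f = f, max_dist = max_dist)
      mean(vapply(seq_len(nrow(mine)), function(i) {
        any(match_under_rule(
          rule, mine$chrom[i], mine$start[i], mine$end[i],
          mine$chrom2[i], mine$pos2[i],
          others$chrom, others$start, others$end, others$chrom2, others$pos2
        ))
      }, logical(1)))
    }
    tibble(class = class, caller = cal, n_calls = nrow(mine),
           overlap_frac = frac, merged_total = nrow(merged))
  })
  dplyr::bind_rows(rows)
}

#' Variant size distribution summaries per class and caller
#'
#' @param calls Unified call tibble (any mix of classes/callers).
#' @return Tibble of length quantiles per (class, caller).
#' @export
size_distributions <- function(calls) {
  calls <- calls[!is.na(calls$length), , drop = FALSE]
  if (nrow(calls) == 0L) {
    return(tibble(class = character(), caller = character(), n = integer(),
                  min = double(), q25 = double(), median = double(),
                  q75 = double(), max = double()))
  }
  dplyr::summarise(
    dplyr::group_by(calls, .data$class, .data$caller),
    n = dplyr::n(),
    min = min(.data$length), q25 = stats::quantile(.data$length, 0.25),
    median = stats::median(.data$length),
    q75 = stats::quantile(.data$length, 0.75), max = max(.data$length),
    .groups = "drop"
  )
}
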