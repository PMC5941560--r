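#' Overlap between genomic intervals in base pairs
#'
#' All interval arithmetic in this package uses 0-based, half-open
#' coordinates (`[start, end)`), the BED convention. Intervals on different
#' chromosomes share zero bases by contract.
#'
#' @param start1,end1 Integer vectors, first interval set.
#' @param start2,end2 Integer vectors, second interval set.
#' @param chrom1,chrom2 Optional chromosome names; when both are supplied,
#'   pairs on different chromosomes report 0 bp.
#' @return Integer vector of shared base counts (never negative).
#' @examples
#' overlap_bp(0, 100, 50, 150)  # 50
#' overlap_bp(0, 100, 100, 200) # 0: half-open intervals only touch
#' @export
overlap_bp <- function(start1, end1, start2, end2, chrom1 = NULL, chrom2 = NULL) {
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    ov[as.character(chrom1) != as.character(chrom2)] <- 0
  }
  ov
}

#' Reciprocal overlap test
#'
#' Two intervals match when their shared bases cover at least (or, with
#' `strict = TRUE`, more than) fraction `f` of *each* interval's own length.
#' This is the symmetric criterion used for short-indel cross-caller
#' comparison (f = 0.25, inclusive), homozygous-deletion breakpoint
#' replacement (f = 0.5, strict), and pathogenic structural-variant
#' database matching (f = 0.9, strict).
#'
#' @inheritParams overlap_bp
#' @param f Required overlap fraction of each interval, in (0, 1].
#' @param strict Logical; `TRUE` demands overlap strictly greater than
#'   `f * length`, `FALSE` (default) allows equality.
#' @return Logical vector.
#' @export
reciprocal_match <- function(start1, end1, start2, end2, f = 0.25,
                             strict = FALSE, chrom1 = NULL, chrom2 = NULL) {
  stopifnot(f > 0, f <= 1)
  ov <- overlap_bp(start1, end1, start2, end2, chrom1, chrom2)
  len1 <- end1 - start1
  len2 <- end2 - start2
  if (strict) {
    ov > f * len1 & ov > f * len2
  } else {
    ov >= f * len1 & ov >= f * len2
  }
}

#' One-way overlap test
#'
#' Asymmetric criterion used for the larger variant classes (duplications,
#' inversions): interval `a` is matched when at least fraction `f` of *its
#' own* length is covered by `b`, regardless of `b`'s length.
#'
#' @inheritParams reciprocal_match
#' @return Logical vector answering "is interval 1 matched?".
#' @export
oneway_match <- function(start1, end1, start2, end2, f = 0.25,
                         strict = FALSE, chrom1 = NULL, chrom2 = NULL) {
  stopifnot(f > 0, f <= 1)
  ov <- overlap_bp(start1, end1, start2, end2, chrom1, chrom2)
  len1 <- end1 - start1
  if (strict) ov > f * len1 else ov >= f * len1
}

#' Breakpoint-pair match for translocations
#'
#' Two translocation calls match when they span the same (unordered)
#' chromosome pair and both breakpoints lie strictly closer than
#' `max_dist` bp. Breakpoint pairs are expected in canonical order
#' (see [canonical_breakpoints()]), so positions compare positionally.
#'
#' @param chromA1,posA1,chromA2,posA2 First call's breakpoint pair.
#' @param chromB1,posB1,chromB2,posB2 Second call's breakpoint pair.
#' @param max_dist Exclusive distance bound in bp (default 1000).
#' @return Logical vector.
#' @export
breakpoint_match <- function(chromA1, posA1, chromA2, posA2,
                             chromB1, posB1, chromB2, posB2,
                             max_dist = 1000) {
  same_pair <- chromA1 == chromB1 & chromA2 == chromB2
  same_pair & abs(posA1 - posB1) < max_dist & abs(posA2 - posB2) < max_dist
}

#' Put a breakpoint pair in canonical order
#'
#' Orders the two ends of a translocation so that the lexicographically
#' smaller (chromosome, position) comes first, making breakpoint-pair
#' comparison independent of reporting order.
#'
#' @param chrom1,pos1,chrom2,pos2 Breakpoint pair vectors.
#' @return A list with components `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
canonical_breakpoints <- function(chrom1, pos1, chrom2, pos2) {
  swap <- chrom1 > chrom2 | (chrom1 == chrom2 & pos1 > pos2)
  swap[is.na(swap)] <- FALSE
  list(
    chrom1 = ifelse(swap, chrom2, chrom1),
    pos1 = ifelse(swap, pos2, pos1),
    chrom2 = ifelse(swap, chrom1, chrom2),
    pos2 = ifelse(swap, pos1, pos2)
  )
}

#' Cluster intervals by overlap (optionally allowing bookended neighbours)
#'
#' Single sweep over start-sorted intervals; connected components of the
#' pairwise overlap graph fall out exactly because interval graphs chain.
#' With `adjacent = TRUE` bookended intervals (end of one equals start of
#' the next, zero gap) join the same cluster, the reading of
#' "adjacent or overlapping" under half-open coordinates.
#'
#' @param chrom,start,end Parallel vectors describing the intervals.
#' @param adjacent Logical; merge bookended intervals too (default `TRUE`).
#' @return Integer cluster ids in input order (1-based, dense).
#' @export
cluster_intervals <- function(chrom, start, end, adjacent = TRUE) {
  n <- length(start)
  if (n == 0L) return(integer(0))
  ids <- integer(n)
  ord <- order(as.character(chrom), start, end)
  cur <- 0L
  cur_chrom <- NA_character_
  cur_end <- -Inf
  for (i in ord) {
    joins <- !is.na(cur_chrom) && as.character(chrom[i]) == cur_chrom &&
      (if (adjacent) start[i] <= cur_end else start[i] < cur_end)
    if (joins) {
      cur_end <- max(cur_end, end[i])
    } else {
      cur <- cur + 1L
      cur_chrom <- as.character(chrom[i])
      cur_end <- end[i]
    }
    ids[i] <- cur
  }
  ids
}

# Connected components over an explicit pair list (union-find with path
# compression). Used where the merge predicate is not an interval-graph
# relation (translocation breakpoint distance), so the sweep above does
# not apply.
components_from_pairs <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    while (parent[x] != r) {
      nx <- parent[x]
      parent[x] <<- r
      x <- nx
    }
    r
  }
  for (k in seq_along(i)) {
    a <- find(i[k])
    b <- find(j[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# TRUE for each query interval that shares >= 1 bp with any subject
# interval on the same chromosome.
overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- logical(length(q_start))
  if (length(s_start) == 0L || length(q_start) == 0L) return(out)
  s_split <- split(seq_along(s_start), as.character(s_chrom))
  for (i in seq_along(q_start)) {
    idx <- s_split[[as.character(q_chrom[i])]]
    if (is.null(idx)) next
    out[i] <- any(s_start[idx] < q_end[i] & s_end[idx] > q_start[i])
  }
  out
}
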