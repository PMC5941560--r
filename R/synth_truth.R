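#' Synthetic assembly gap regions
#'
#' Places telomeric gaps at both chromosome ends and a centromeric gap in
#' the middle of each chromosome, consuming `gap_fraction` of the
#' chromosome in total (one quarter per telomere, one half for the
#' centromere), snapped to depth-bin boundaries.
#'
#' @param config A [simulation_config()].
#' @return Tibble with `chrom`, `start`, `end`, `name`.
#' @export
gap_regions <- function(config) {
  bin <- config$bin_size
  out <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    tel <- max(bin, floor(config$gap_fraction * len / 4 / bin) * bin)
    cen <- max(bin, floor(config$gap_fraction * len / 2 / bin) * bin)
    cen_start <- floor((len / 2 - cen / 2) / bin) * bin
    tibble(
      chrom = ch,
      start = c(0, cen_start, len - tel),
      end = c(tel, cen_start + cen, len),
      name = c("telomere_p", "centromere", "telomere_q")
    )
  })
  dplyr::bind_rows(out)
}

# Rejection-sample `n` non-overlapping intervals of the given sizes,
# avoiding `reserved` intervals padded by `pad`. Returns the placements
# and the updated reservation ledger. Chromosomes are drawn proportional
# to length. `align` snaps starts (and implicitly ends, since CNV sizes
# are bin multiples) to bin boundaries.
place_intervals <- function(n, sizes, config, reserved, pad, align = FALSE,
                            class = "variant") {
  if (n == 0L) {
    return(list(placed = tibble(chrom = character(), start = double(), end = double()),
                reserved = reserved))
  }
  chroms <- names(config$chrom_lengths)
  probs <- config$chrom_lengths / sum(config$chrom_lengths)
  placed <- vector("list", n)
  for (i in seq_len(n)) {
    size <- sizes[i]
    ok <- FALSE
    for (attempt in seq_len(2000L)) {
      ch <- sample(chroms, 1, prob = probs)
      len <- config$chrom_lengths[[ch]]
      if (len <= size + 2 * config$bin_size) next
      start <- floor(stats::runif(1, min = 0, max = len - size))
      if (align) start <- floor(start / config$bin_size) * config$bin_size
      end <- start + size
      res <- reserved[reserved$chrom == ch, , drop = FALSE]
      if (nrow(res) == 0L ||
          !any(res$start - pad < end & res$end + pad > start)) {
        placed[[i]] <- tibble(chrom = ch, start = start, end = end)
        reserved <- dplyr::bind_rows(reserved, placed[[i]])
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "could not place %s interval %d of %d (size %d bp): chromosomes too small or too crowded",
        class, i, n, as.integer(size)
      ))
    }
  }
  list(placed = dplyr::bind_rows(placed), reserved = reserved)
}

sample_sizes <- function(n, range) {
  if (n == 0L) return(numeric(0))
  floor(stats::runif(n, range[1], range[2] + 1))
}

# Bin-aligned sizes for CNV classes: multiples of bin_size within range.
sample_sizes_binned <- function(n, range, bin) {
  if (n == 0L) return(numeric(0))
  lo <- max(1L, ceiling(range[1] / bin))
  hi <- max(lo, floor(range[2] / bin))
  resample(seq(lo, hi), n, replace = TRUE) * bin
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

sample_substitution_alleles <- function(n, ts_fraction) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is_ts <- stats::runif(n) < ts_fraction
  alt <- character(n)
  alt[is_ts] <- TS_PARTNER[ref[is_ts]]
  for (i in which(!is_ts)) {
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"), c(ref[i], TS_PARTNER[[ref[i]]])), 1)
  }
  list(ref = ref, alt = alt)
}

#' Simulate ground-truth variants and the copy-number segment map
#'
#' Places all configured truth variants mutually non-overlapping (with at
#' least `min_gap` bp spacing) outside the assembly gap regions.
#' Copy-number-changing classes (long deletions at CN 1, homozygous
#' deletions at CN 0, duplications at CN 5-6) are snapped to depth-bin
#' boundaries and, together with any background CN segments requested via
#' `other_cn_fraction`, overlay the baseline to form the CN segment map
#' covering every chromosome. Translocation breakpoints are padded so
#' that distinct truth translocations never fall within the 1000 bp
#' merge radius of each other.
#'
#' @param config A [simulation_config()].
#' @return An object of class `tetramerge_truth`: a list with `variants`
#'   (tibble of truth records keyed by `truth_id`), `cn_segments`
#'   (tibble `chrom`, `start`, `end`, `cn` tiling the genome), `gaps`
#'   (gap region tibble) and `config`.
#' @export
simulate_truth <- function(config) {
  validate_config(config)
  with_seed(derive_seed(config$seed, 1L), simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  gaps <- gap_regions(config)
  reserved <- gaps[, c("chrom", "start", "end")]
  counts <- config$variant_counts
  bin <- config$bin_size
  pad <- config$min_gap
  rows <- list()

  interval_class <- function(class, n, sizes, align = FALSE, cn = NA_integer_,
                             pad_extra = 0) {
    res <- place_intervals(n, sizes, config, reserved, pad + pad_extra,
                           align = align, class = class)
    reserved <<- res$reserved
    if (n == 0L) return(invisible(NULL))
    placed <- res$placed
    rows[[class]] <<- tibble(
      class = class, chrom = placed$chrom, start = placed$start,
      end = placed$end, length = placed$end - placed$start,
      cn = as.integer(cn)
    )
    invisible(NULL)
  }

  # -- substitutions: single-base loci -----------------------------------
  n <- counts[["substitution"]]
  if (n > 0) {
    res <- place_intervals(n, rep(1, n), config, reserved, pad, class = "substitution")
    reserved <- res$reserved
    alleles <- sample_substitution_alleles(n, config$ts_fraction)
    rows$substitution <- tibble(
      class = "substitution", chrom = res$placed$chrom,
      start = res$placed$start, end = res$placed$end, length = 1,
      cn = NA_integer_, ref = alleles$ref, alt = alleles$alt
    )
  }

  interval_class("short_deletion", counts[["short_deletion"]],
                 sample_sizes(counts[["short_deletion"]], config$size_ranges$short_deletion))
  interval_class("long_deletion", counts[["long_deletion"]],
                 sample_sizes_binned(counts[["long_deletion"]],
                                     config$size_ranges$long_deletion, bin),
                 align = TRUE, cn = 1L, pad_extra = bin)
  interval_class("duplication", counts[["duplication"]],
                 sample_sizes_binned(counts[["duplication"]],
                                     config$size_ranges$duplication, bin),
                 align = TRUE, cn = NA_integer_, pad_extra = bin)
  if (!is.null(rows$duplication)) {
    rows$duplication$cn <- sample(c(5L, 6L), nrow(rows$duplication),
                                  replace = TRUE, prob = c(0.8, 0.2))
  }
  interval_class("inversion", counts[["inversion"]],
                 sample_sizes(counts[["inversion"]], config$size_ranges$inversion))

  # homozygous deletions: a short, small-variant-caller-detectable mode
  # plus a long, bin-resolvable mode
  n <- counts[["homozygous_deletion"]]
  if (n > 0) {
    n_long <- round(config$homdel_long_fraction * n)
    n_short <- n - n_long
    interval_class("homozygous_deletion_short", n_short,
                   sample_sizes(n_short, config$size_ranges$homozygous_deletion_short),
                   cn = 0L)
    interval_class("homozygous_deletion_long", n_long,
                   sample_sizes_binned(n_long, config$size_ranges$homozygous_deletion_long, bin),
                   align = TRUE, cn = 0L, pad_extra = bin)
    homdel <- dplyr::bind_rows(rows$homozygous_deletion_short, rows$homozygous_deletion_long)
    rows$homozygous_deletion_short <- NULL
    rows$homozygous_deletion_long <- NULL
    if (!is.null(homdel) && nrow(homdel) > 0) {
      homdel$class <- "homozygous_deletion"
      rows$homozygous_deletion <- homdel
    }
  }

  # insertions occupy a point locus; length is the inserted length
  for (cls in c("short_insertion", "long_insertion")) {
    n <- counts[[cls]]
    if (n == 0) next
    res <- place_intervals(n, rep(1, n), config, reserved, pad, class = cls)
    reserved <- res$reserved
    rows[[cls]] <- tibble(
      class = cls, chrom = res$placed$chrom, start = res$placed$start,
      end = res$placed$end,
      length = sample_sizes(n, config$size_ranges[[cls]]),
      cn = NA_integer_
    )
  }

  # translocations: breakpoint pairs, padded beyond the 1000 bp merge
  # radius so distinct truth events never cluster
  place_breakpoint <- function(ch) {
    len <- config$chrom_lengths[[ch]]
    for (attempt in seq_len(2000L)) {
      pos <- floor(stats::runif(1, config$bin_size, len - 1))
      res <- reserved[reserved$chrom == ch, , drop = FALSE]
      if (!any(res$start - (pad + 1200) < pos + 1 & res$end + (pad + 1200) > pos)) {
        reserved <<- dplyr::bind_rows(reserved,
                                      tibble(chrom = ch, start = pos, end = pos + 1))
        return(pos)
      }
    }
    stop(sprintf("could not place translocation breakpoint on %s", ch))
  }
  trans <- list()
  chroms <- names(config$chrom_lengths)
  n <- counts[["intra_translocation"]]
  if (n > 0) {
    ch <- resample(chroms, n, replace = TRUE)
    bp1 <- vapply(ch, place_breakpoint, double(1))
    bp2 <- vapply(ch, place_breakpoint, double(1))
    bp <- canonical_breakpoints(ch, bp1, ch, bp2)
    trans$intra_translocation <- tibble(
      class = "intra_translocation", chrom = bp$chrom1, start = bp$pos1,
      end = bp$pos1 + 1, length = NA_real_, cn = NA_integer_,
      chrom2 = bp$chrom2, pos2 = bp$pos2
    )
  }
  n <- counts[["inter_translocation"]]
  if (n > 0) {
    if (length(chroms) < 2) {
      stop("inter-chromosomal translocations require at least two chromosomes")
    }
    # distinct chromosome pairs while they last: the split-read caller
    # collapses same-pair translocations, so reusing a pair merges truths
    pairs_mat <- utils::combn(chroms, 2)
    sel <- pairs_mat[, resample(seq_len(ncol(pairs_mat)), n,
                                replace = n > ncol(pairs_mat)), drop = FALSE]
    bp1 <- vapply(sel[1, ], place_breakpoint, double(1))
    bp2 <- vapply(sel[2, ], place_breakpoint, double(1))
    bp <- canonical_breakpoints(sel[1, ], bp1, sel[2, ], bp2)
    trans$inter_translocation <- tibble(
      class = "inter_translocation", chrom = bp$chrom1, start = bp$pos1,
      end = bp$pos1 + 1, length = NA_real_, cn = NA_integer_,
      chrom2 = bp$chrom2, pos2 = bp$pos2
    )
  }
  rows <- c(rows, trans)

  variants <- dplyr::bind_rows(rows)
  if (nrow(variants) == 0L) {
    variants <- tibble(
      class = character(), chrom = character(), start = double(),
      end = double(), length = double(), cn = integer(),
      ref = character(), alt = character(), chrom2 = character(),
      pos2 = double(), alt_count = integer(), truth_id = character()
    )
  }
  for (col in c("ref", "alt", "chrom2")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  if (!"pos2" %in% names(variants)) variants$pos2 <- NA_real_

  # allele counts out of 4 for the small-variant classes
  # short deletions stay heterozygous: an all-allele deletion IS the
  # homozygous-deletion class, which is simulated separately
  small <- variants$class %in% c("substitution", "short_insertion")
  variants$alt_count <- NA_integer_
  n_small <- sum(small)
  if (n_small > 0) {
    hom <- stats::runif(n_small) < config$hom_fraction
    ac <- ifelse(hom, 4L, sample(1:3, n_small, replace = TRUE))
    variants$alt_count[small] <- as.integer(ac)
  }
  het_del <- variants$class == "short_deletion"
  if (any(het_del)) {
    variants$alt_count[het_del] <- as.integer(sample(1:3, sum(het_del), replace = TRUE))
  }
  variants$alt_count[variants$class == "homozygous_deletion"] <- 4L

  variants <- variants[order(match(variants$class, TRUTH_CLASSES),
                             variants$chrom, variants$start), ]
  if (nrow(variants) > 0) {
    variants$truth_id <- sprintf("truth_%04d", seq_len(nrow(variants)))
  }
  variants <- variants[, c("truth_id", "class", "chrom", "start", "end",
                           "length", "cn", "ref", "alt", "alt_count",
                           "chrom2", "pos2")]

  # background CN segments (non-baseline levels not tied to a variant)
  background <- tibble(chrom = character(), start = double(), end = double(),
                       cn = integer())
  if (config$other_cn_fraction > 0) {
    target <- config$other_cn_fraction * sum(config$chrom_lengths)
    covered <- 0
    lvl_i <- 0L
    seg_rows <- list()
    while (covered < target) {
      size <- sample(20:100, 1) * bin
      res <- place_intervals(1, size, config, reserved, pad, align = TRUE,
                             class = "background_cn")
      reserved <- res$reserved
      lvl_i <- lvl_i + 1L
      seg_rows[[lvl_i]] <- tibble(
        chrom = res$placed$chrom, start = res$placed$start, end = res$placed$end,
        cn = config$other_cn_levels[(lvl_i - 1L) %% length(config$other_cn_levels) + 1L]
      )
      covered <- covered + size
    }
    background <- dplyr::bind_rows(seg_rows)
  }

  cn_events <- dplyr::bind_rows(
    variants[!is.na(variants$cn), c("chrom", "start", "end", "cn")],
    background
  )
  cn_segments <- build_cn_segment_map(cn_events, config)

  structure(list(
    variants = variants, cn_segments = cn_segments,
    background_cn = background, gaps = gaps, config = config
  ), class = "tetramerge_truth")
}

# Tile each chromosome with the baseline CN, overlaying the (mutually
# non-overlapping) CN-altering events.
build_cn_segment_map <- function(events, config) {
  out <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    starts <- c(0, ev$end)
    ends <- c(ev$start, len)
    base <- tibble(chrom = ch, start = starts, end = ends,
                   cn = config$baseline_cn)
    base <- base[base$end > base$start, ]
    seg <- dplyr::bind_rows(base, ev)
    seg <- seg[order(seg$start), ]
    # collapse runs of equal CN (events at baseline CN would split runs)
    keep_id <- cumsum(c(TRUE, seg$cn[-1] != seg$cn[-nrow(seg)] |
                          seg$start[-1] != seg$end[-nrow(seg)]))
    dplyr::summarise(
      dplyr::group_by(seg, id = keep_id),
      chrom = ch, start = min(.data$start), end = max(.data$end),
      cn = .data$cn[1], .groups = "drop"
    )[, c("chrom", "start", "end", "cn")]
  })
  dplyr::bind_rows(out)
}

#' @export
print.tetramerge_truth <- function(x, ...) {
  cat(sprintf("<tetramerge_truth> %d truth variants, %d CN segments, seed %d\n",
              nrow(x$variants), nrow(x$cn_segments), x$config$seed))
  print(table(x$variants$class))
  invisible(x)
}
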