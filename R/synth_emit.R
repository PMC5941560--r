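#' Perfect per-caller sensitivity
#'
#' [default_sensitivity()] with every detection probability set to 1;
#' used by noiseless configurations.
#' @return Named list of named numeric vectors.
#' @export
perfect_sensitivity <- function() {
  lapply(default_sensitivity(), function(s) {
    s[] <- 1
    s
  })
}

#' Noiseless simulation configuration
#'
#' Convenience wrapper around [simulation_config()] with jitter 0,
#' perfect sensitivity, no false positives, no QC-failing metrics and a
#' noise-free depth track. In this limit the merged call set must equal
#' the ground truth exactly, which the test suite exploits as a closure
#' check of the whole pipeline.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
noiseless_config <- function(...) {
  args <- list(...)
  defaults <- list(
    jitter_sd = 0, qc_fail_rate = 0, fp_rate = 0, depth_noise_sd = 0,
    sensitivity = perfect_sensitivity()
  )
  for (nm in names(defaults)) if (!nm %in% names(args)) args[[nm]] <- defaults[[nm]]
  do.call(simulation_config, args)
}

# Which emulated caller can report which truth class, given the variant
# length. Size limits mirror the real tools: the assembly-based
# small-variant caller is limited to small events (here <= 150 bp), the
# read-pair caller to events >= 50 bp, the read-depth caller to events
# spanning at least two depth bins.
caller_eligible <- function(caller, class, length, bin_size) {
  switch(caller,
    small_variant = class %in% c("substitution", "short_deletion", "short_insertion") |
      (class == "homozygous_deletion" & !is.na(length) & length <= 150),
    split_read = class %in% c(
      "short_deletion", "short_insertion", "long_deletion", "long_insertion",
      "duplication", "inversion", "inter_translocation"
    ),
    read_pair = class %in% c("intra_translocation", "inter_translocation") |
      (class %in% c("long_deletion", "long_insertion", "inversion") &
         !is.na(length) & length >= 50),
    read_depth = class %in% c("long_deletion", "duplication", "homozygous_deletion") &
      !is.na(length) & length >= 2 * bin_size
  )
}

random_bases <- function(n) {
  vapply(n, function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = ""), character(1))
}

gt_string <- function(alt_count) {
  vapply(alt_count, function(a) paste(c(rep("0", 4 - a), rep("1", a)), collapse = "/"),
         character(1))
}

# Support metrics for the split-read dialect. Pass draws always satisfy
# (reads >= 2, summed >= 100, summed/reads > 10); fail draws violate
# exactly one of the three bounds.
split_read_metrics <- function(n, fail) {
  reads <- 2 + stats::rpois(n, 8)
  mean_target <- stats::runif(n, 11, 60)
  summed <- pmax(100, round(reads * mean_target))
  for (i in which(fail)) {
    mode <- sample(3, 1)
    if (mode == 1) {
      reads[i] <- 1
      summed[i] <- sample(100:300, 1)
    } else if (mode == 2) {
      reads[i] <- 2 + stats::rpois(1, 3)
      summed[i] <- sample(20:99, 1)
    } else {
      reads[i] <- sample(11:20, 1)
      summed[i] <- sample(100:(10 * reads[i]), 1) # mean <= 10
    }
  }
  list(reads = reads, summed = summed)
}

read_pair_metrics <- function(n, fail, ins_len) {
  conf <- stats::runif(n, 80, 99.5)
  pairs <- 4 + stats::rpois(n, 6)
  bp_dist <- rep(NA_real_, n)
  has <- !is.na(ins_len)
  bp_dist[has] <- pmin(floor(stats::runif(sum(has), 0, ins_len[has] + 1)),
                       ins_len[has])
  for (i in which(fail)) {
    modes <- if (!is.na(ins_len[i])) 1:3 else 1:2
    mode <- sample(modes, 1)
    if (mode == 1) conf[i] <- stats::runif(1, 20, 79.9)
    else if (mode == 2) pairs[i] <- sample(1:3, 1)
    else bp_dist[i] <- ins_len[i] + sample(10:200, 1)
  }
  list(confidence = conf, pairs = pairs, bp_distance = bp_dist)
}

read_depth_metrics <- function(n, fail) {
  p1 <- stats::runif(n, 1e-6, 0.009)
  p2 <- stats::runif(n, 1e-6, 0.009)
  q0 <- stats::runif(n, 0, 0.45)
  for (i in which(fail)) {
    mode <- sample(3, 1)
    if (mode == 1) p1[i] <- stats::runif(1, 0.01, 0.5)
    else if (mode == 2) p2[i] <- stats::runif(1, 0.01, 0.5)
    else q0[i] <- stats::runif(1, 0.5, 0.9)
  }
  list(p1 = p1, p2 = p2, q0 = q0)
}

jitter_pos <- function(pos, sd, lo, hi) {
  if (sd == 0) return(pmin(pmax(pos, lo), hi))
  pmin(pmax(round(pos + stats::rnorm(length(pos), 0, sd)), lo), hi)
}

# Sample false-positive loci uniformly over the genome, excluding gaps.
sample_fp_loci <- function(n, sizes, config, gaps, align = FALSE) {
  if (n == 0L) return(tibble(chrom = character(), start = double(), end = double()))
  chroms <- names(config$chrom_lengths)
  probs <- config$chrom_lengths / sum(config$chrom_lengths)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(2000L)) {
      ch <- sample(chroms, 1, prob = probs)
      len <- config$chrom_lengths[[ch]]
      if (len <= sizes[i] + 1) next
      start <- floor(stats::runif(1, 0, len - sizes[i]))
      if (align) start <- floor(start / config$bin_size) * config$bin_size
      end <- start + sizes[i]
      g <- gaps[gaps$chrom == ch, , drop = FALSE]
      if (!any(g$start < end & g$end > start)) {
        rows[[i]] <- tibble(chrom = ch, start = start, end = end)
        break
      }
    }
    if (is.null(rows[[i]])) stop("could not place false-positive call outside gaps")
  }
  dplyr::bind_rows(rows)
}

#' Emit the four emulated caller call sets from a truth set
#'
#' Every truth variant is emitted by each eligible caller with that
#' caller's configured sensitivity. Breakpoints are exact for the
#' small-variant and split-read emitters, jittered for the read-pair
#' emitter, and jittered-then-bin-snapped for the read-depth emitter.
#' Support metrics are drawn from pass-grade distributions, except that a
#' `qc_fail_rate` fraction of calls receives metrics that violate exactly
#' one QC bound. False positives are placed uniformly outside gap
#' regions with pass-grade metrics. The depth track is CN/2 per bin plus
#' Gaussian noise. A manifest links every emitted call to its truth
#' record or flags it as a false positive.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The same [simulation_config()] used for the truth.
#' @return A list of dialect tables: `small_variant` (VCF-style rows),
#'   `split_read`, `read_pair`, `read_depth_cnv` (caller tables),
#'   `depth_track` (binned depth tibble) and `manifest`.
#' @export
emit_caller_callsets <- function(truth, config) {
  stopifnot(inherits(truth, "tetramerge_truth"))
  with_seed(derive_seed(config$seed, 2L), emit_callsets_impl(truth, config))
}

emit_callsets_impl <- function(truth, config) {
  tv <- truth$variants
  bin <- config$bin_size
  manifest <- list()
  eligible_any <- rep(FALSE, nrow(tv))

  detect <- function(caller) {
    if (nrow(tv) == 0L) return(tv[0, ])
    elig <- caller_eligible(caller, tv$class, tv$length, bin)
    eligible_any <<- eligible_any | elig
    sens <- vapply(tv$class, function(cl) {
      s <- config$sensitivity[[caller]]
      if (cl %in% names(s)) s[[cl]] else 0
    }, double(1))
    hit <- elig & stats::runif(nrow(tv)) < sens
    tv[hit, , drop = FALSE]
  }

  # ---- small-variant caller (VCF dialect, ploidy-4 GT) ------------------
  sv <- detect("small_variant")
  n_fp <- round(config$fp_rate * nrow(sv))
  fp_class <- if (n_fp > 0) sample(c("substitution", "short_deletion", "short_insertion"),
                                   n_fp, replace = TRUE) else character(0)
  fp_sizes <- rep(1, n_fp)
  fp_sizes[fp_class == "short_deletion"] <-
    sample_sizes(sum(fp_class == "short_deletion"), config$size_ranges$short_deletion)
  fp_loci <- sample_fp_loci(n_fp, fp_sizes, config, truth$gaps)
  if (n_fp > 0) {
    alleles <- sample_substitution_alleles(n_fp, config$ts_fraction)
    fp <- tibble(
      truth_id = NA_character_, class = fp_class, chrom = fp_loci$chrom,
      start = fp_loci$start,
      end = ifelse(fp_class == "short_deletion", fp_loci$end, fp_loci$start + 1),
      length = ifelse(fp_class == "short_insertion",
                      sample_sizes(n_fp, config$size_ranges$short_insertion),
                      fp_sizes),
      cn = NA_integer_, ref = alleles$ref, alt = alleles$alt,
      alt_count = ifelse(fp_class != "short_deletion" &
                           stats::runif(n_fp) < config$hom_fraction, 4L,
                         sample(1:3, n_fp, replace = TRUE)),
      chrom2 = NA_character_, pos2 = NA_real_
    )
    sv <- dplyr::bind_rows(sv, fp)
  }
  small_variant <- emit_vcf_rows(sv)
  if (nrow(small_variant) > 0) {
    small_variant$call_id <- sprintf("small_variant_%05d", seq_len(nrow(small_variant)))
  }
  manifest$small_variant <- tibble(
    caller = "small_variant", call_id = small_variant$call_id,
    truth_id = sv$truth_id, class = sv$class, qc_fail = FALSE
  )

  # ---- split-read caller ------------------------------------------------
  sr <- detect("split_read")
  n_fp <- round(config$fp_rate * nrow(sr))
  if (n_fp > 0) {
    fp_class <- sample(c("short_deletion", "long_deletion", "short_insertion",
                         "duplication", "inversion"), n_fp, replace = TRUE)
    fp_sizes <- vapply(fp_class, function(cl) {
      rng <- config$size_ranges[[cl]]
      if (cl %in% c("short_insertion", "long_insertion")) 1 else sample_sizes(1, rng)
    }, double(1))
    fp_loci <- sample_fp_loci(n_fp, fp_sizes, config, truth$gaps)
    fp <- tibble(
      truth_id = NA_character_, class = fp_class, chrom = fp_loci$chrom,
      start = fp_loci$start, end = fp_loci$end,
      length = ifelse(fp_class == "short_insertion",
                      sample_sizes(n_fp, config$size_ranges$short_insertion),
                      fp_sizes),
      cn = NA_integer_, ref = NA_character_, alt = NA_character_,
      alt_count = NA_integer_, chrom2 = NA_character_, pos2 = NA_real_
    )
    sr <- dplyr::bind_rows(sr, fp)
  }
  fail <- stats::runif(nrow(sr)) < config$qc_fail_rate
  met <- split_read_metrics(nrow(sr), fail)
  type_map <- c(
    short_deletion = "DEL", long_deletion = "DEL", short_insertion = "INS",
    long_insertion = "INS", duplication = "TD", inversion = "INV",
    inter_translocation = "CTX"
  )
  is_ins <- sr$class %in% c("short_insertion", "long_insertion")
  is_ctx <- sr$class == "inter_translocation"
  split_read <- tibble(
    call_id = if (nrow(sr) > 0) sprintf("split_read_%05d", seq_len(nrow(sr))) else character(0),
    chrom = sr$chrom,
    start = sr$start + 1,
    end = ifelse(is_ins | is_ctx, sr$start + 1, sr$end),
    type = unname(type_map[sr$class]),
    length = ifelse(is_ctx, NA_real_, sr$length),
    supporting_reads = met$reads,
    summed_mapq = met$summed,
    chrom2 = sr$chrom2,
    pos2 = ifelse(is_ctx, sr$pos2 + 1, NA_real_)
  )
  manifest$split_read <- tibble(
    caller = "split_read", call_id = split_read$call_id,
    truth_id = sr$truth_id, class = sr$class, qc_fail = fail
  )

  # ---- read-pair caller -------------------------------------------------
  rp <- detect("read_pair")
  n_fp <- round(config$fp_rate * nrow(rp))
  if (n_fp > 0) {
    fp_class <- sample(c("long_deletion", "inversion"), n_fp, replace = TRUE)
    fp_sizes <- vapply(fp_class, function(cl) sample_sizes(1, config$size_ranges[[cl]]),
                       double(1))
    fp_loci <- sample_fp_loci(n_fp, fp_sizes, config, truth$gaps)
    fp <- tibble(
      truth_id = NA_character_, class = fp_class, chrom = fp_loci$chrom,
      start = fp_loci$start, end = fp_loci$end, length = fp_sizes,
      cn = NA_integer_, ref = NA_character_, alt = NA_character_,
      alt_count = NA_integer_, chrom2 = NA_character_, pos2 = NA_real_
    )
    rp <- dplyr::bind_rows(rp, fp)
  }
  fail <- stats::runif(nrow(rp)) < config$qc_fail_rate
  is_ins <- rp$class == "long_insertion"
  is_trans <- rp$class %in% c("intra_translocation", "inter_translocation")
  ins_len <- ifelse(is_ins, rp$length, NA_real_)
  met <- read_pair_metrics(nrow(rp), fail, ins_len)
  chrom_len <- function(ch) unname(config$chrom_lengths[ch])
  j <- config$jitter_sd
  p1 <- numeric(nrow(rp))
  p2 <- numeric(nrow(rp))
  if (nrow(rp) > 0) {
    p1 <- jitter_pos(rp$start, j, 1, chrom_len(rp$chrom) - 2)
    end_like <- ifelse(is_trans, rp$pos2, ifelse(is_ins, rp$start, rp$end))
    hi2 <- ifelse(is_trans & rp$class == "inter_translocation",
                  chrom_len(rp$chrom2) - 1, chrom_len(rp$chrom) - 1)
    p2 <- jitter_pos(end_like, j, 1, hi2)
    # keep intervals non-degenerate for the interval classes
    fixup <- !is_ins & !is_trans & p2 - p1 < 50
    p2[fixup] <- p1[fixup] + (rp$end - rp$start)[fixup]
    p2[is_ins] <- p1[is_ins]
  }
  type_map_rp <- c(
    long_deletion = "DEL", long_insertion = "INS", inversion = "INV",
    intra_translocation = "ITX", inter_translocation = "CTX"
  )
  read_pair <- tibble(
    call_id = if (nrow(rp) > 0) sprintf("read_pair_%05d", seq_len(nrow(rp))) else character(0),
    chrom = rp$chrom,
    pos1 = p1 + 1,
    chrom2 = ifelse(rp$class == "inter_translocation", rp$chrom2, rp$chrom),
    pos2 = ifelse(is_ins, p1 + 1, p2 + ifelse(is_trans, 1, 0)),
    type = unname(type_map_rp[rp$class]),
    size = ifelse(is_trans, NA_real_, ifelse(is_ins, rp$length, p2 - p1)),
    confidence = met$confidence,
    supporting_pairs = met$pairs,
    bp_distance = met$bp_distance
  )
  manifest$read_pair <- tibble(
    caller = "read_pair", call_id = read_pair$call_id,
    truth_id = rp$truth_id, class = rp$class, qc_fail = fail
  )

  # ---- read-depth caller ------------------------------------------------
  rd <- detect("read_depth")
  n_fp <- round(config$fp_rate * nrow(rd))
  if (n_fp > 0) {
    fp_class <- sample(c("long_deletion", "duplication"), n_fp, replace = TRUE)
    fp_sizes <- vapply(fp_class, function(cl) {
      sample_sizes_binned(1, config$size_ranges[[cl]], bin)
    }, double(1))
    fp_loci <- sample_fp_loci(n_fp, fp_sizes, config, truth$gaps, align = TRUE)
    fp <- tibble(
      truth_id = NA_character_, class = fp_class, chrom = fp_loci$chrom,
      start = fp_loci$start, end = fp_loci$end, length = fp_sizes,
      cn = ifelse(fp_class == "duplication", 5L, 1L),
      ref = NA_character_, alt = NA_character_, alt_count = NA_integer_,
      chrom2 = NA_character_, pos2 = NA_real_
    )
    rd <- dplyr::bind_rows(rd, fp)
  }
  fail <- stats::runif(nrow(rd)) < config$qc_fail_rate
  met <- read_depth_metrics(nrow(rd), fail)
  s_snap <- e_snap <- numeric(nrow(rd))
  if (nrow(rd) > 0) {
    chrom_max <- unname(config$chrom_lengths[rd$chrom])
    s_jit <- if (config$jitter_sd == 0) rd$start else rd$start + stats::rnorm(nrow(rd), 0, config$jitter_sd)
    e_jit <- if (config$jitter_sd == 0) rd$end else rd$end + stats::rnorm(nrow(rd), 0, config$jitter_sd)
    s_snap <- pmin(pmax(round(s_jit / bin) * bin, 0), chrom_max - bin)
    e_snap <- pmin(pmax(round(e_jit / bin) * bin, s_snap + bin), chrom_max)
  }
  read_depth_cnv <- tibble(
    call_id = if (nrow(rd) > 0) sprintf("read_depth_%05d", seq_len(nrow(rd))) else character(0),
    chrom = rd$chrom,
    start = s_snap + 1,
    end = e_snap,
    type = ifelse(rd$class == "duplication", "duplication", "deletion"),
    cn = rd$cn,
    normalized_depth = rd$cn / 2,
    p_val1 = met$p1, p_val2 = met$p2, q0 = met$q0
  )
  manifest$read_depth <- tibble(
    caller = "read_depth", call_id = read_depth_cnv$call_id,
    truth_id = rd$truth_id, class = rd$class, qc_fail = fail
  )

  # truth variants no caller can represent
  unrep <- !eligible_any & nrow(tv) > 0
  if (any(unrep)) {
    warning(sprintf("%d truth variant(s) not representable by any caller", sum(unrep)))
    manifest$unrepresentable <- tibble(
      caller = NA_character_, call_id = NA_character_,
      truth_id = tv$truth_id[unrep], class = tv$class[unrep], qc_fail = NA
    )
  }

  depth_track <- make_depth_track(truth$cn_segments, config)

  list(
    small_variant = small_variant, split_read = split_read,
    read_pair = read_pair, read_depth_cnv = read_depth_cnv,
    depth_track = depth_track, manifest = dplyr::bind_rows(manifest)
  )
}

# VCF-style rows (1-based POS, REF/ALT strings, ploidy-4 GT) from truth
# records of the small-variant classes.
emit_vcf_rows <- function(sv) {
  if (nrow(sv) == 0L) {
    return(tibble(call_id = character(), chrom = character(), pos = double(),
                  id = character(), ref = character(), alt = character(),
                  qual = double(), gt = character()))
  }
  pos <- ref <- alt <- character(nrow(sv))
  pos <- numeric(nrow(sv))
  for (i in seq_len(nrow(sv))) {
    cl <- sv$class[i]
    if (cl == "substitution") {
      pos[i] <- sv$start[i] + 1
      ref[i] <- sv$ref[i]
      alt[i] <- sv$alt[i]
    } else if (cl %in% c("short_deletion", "homozygous_deletion")) {
      # deleted span [start, end): POS is the 1-based anchor base before it
      pos[i] <- sv$start[i]
      anchor <- random_bases(1)
      ref[i] <- paste0(anchor, random_bases(sv$end[i] - sv$start[i]))
      alt[i] <- anchor
    } else { # short_insertion at point [start, start + 1)
      pos[i] <- sv$start[i]
      anchor <- random_bases(1)
      ref[i] <- anchor
      alt[i] <- paste0(anchor, random_bases(sv$length[i]))
    }
  }
  tibble(
    call_id = NA_character_, chrom = sv$chrom, pos = pos, id = ".",
    ref = ref, alt = alt, qual = round(stats::runif(nrow(sv), 50, 2000), 1),
    gt = gt_string(sv$alt_count)
  )
}

# Normalized depth per bin: length-weighted mean of CN/2 over the bin,
# plus Gaussian noise, floored at 0.
make_depth_track <- function(cn_segments, config) {
  bin <- config$bin_size
  out <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin)
    ends <- pmin(starts + bin, len)
    depth_sum <- numeric(length(starts))
    seg <- cn_segments[cn_segments$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(seg))) {
      first <- max(1L, as.integer(seg$start[k] %/% bin) + 1L)
      last <- min(length(starts), as.integer((seg$end[k] - 1) %/% bin) + 1L)
      if (last < first) next
      idx <- first:last
      ov <- pmin(ends[idx], seg$end[k]) - pmax(starts[idx], seg$start[k])
      depth_sum[idx] <- depth_sum[idx] + ov * seg$cn[k] / 2
    }
    depth <- depth_sum / (ends - starts)
    if (config$depth_noise_sd > 0) {
      depth <- depth + stats::rnorm(length(depth), 0, config$depth_noise_sd)
    }
    tibble(chrom = ch, start = starts, end = ends, depth = pmax(0, depth))
  })
  dplyr::bind_rows(out)
}
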