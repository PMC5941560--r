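test_that("zero-count configuration yields an empty truth set on a uniform CN-4 map", {
  cfg <- simulation_config(variant_counts = c(substitution = 0), seed = 5)
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr$variants), 0L)
  expect_true(all(tr$cn_segments$cn == 4L))
  expect_equal(
    sum(tr$cn_segments$end - tr$cn_segments$start),
    sum(cfg$chrom_lengths)
  )
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$variants, t2$variants)
  expect_identical(t1$cn_segments, t2$cn_segments)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("requested counts and size ranges are honored exactly", {
  cfg <- simulation_config(
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e6),
    variant_counts = c(long_deletion = 50),
    size_ranges = list(long_deletion = c(1000, 10000)),
    seed = 9
  )
  tr <- simulate_truth(cfg)
  ld <- tr$variants[tr$variants$class == "long_deletion", ]
  expect_equal(nrow(ld), 50L)
  expect_true(all(ld$length >= 1000 & ld$length <= 10000))
  expect_true(all(ld$end - ld$start == ld$length))
  expect_true(all(ld$cn == 1L))
})

test_that("overcrowded chromosomes raise a sizing error naming the class", {
  cfg <- simulation_config(
    chrom_lengths = c(chr1 = 50000),
    variant_counts = c(duplication = 100, inter_translocation = 0),
    size_ranges = list(duplication = c(2000, 5000)),
    seed = 1
  )
  expect_error(simulate_truth(cfg), "duplication")
})

test_that("truth variants never overlap each other or gap regions", {
  cfg <- small_config(seed = 13)
  tr <- simulate_truth(cfg)
  iv <- tr$variants[!tr$variants$class %in%
                      c("intra_translocation", "inter_translocation"), ]
  for (ch in unique(iv$chrom)) {
    v <- iv[iv$chrom == ch, ]
    v <- v[order(v$start), ]
    if (nrow(v) > 1) expect_true(all(v$start[-1] >= v$end[-nrow(v)]))
    g <- tr$gaps[tr$gaps$chrom == ch, ]
    for (i in seq_len(nrow(v))) {
      expect_false(any(g$start < v$end[i] & g$end > v$start[i]))
    }
  }
})

test_that("noiseless emission reproduces truth breakpoints exactly", {
  cfg <- small_noiseless_config(seed = 21)
  tr <- simulate_truth(cfg)
  cs <- emit_caller_callsets(tr, cfg)
  man <- cs$manifest
  # sensitivity 1, fp 0: every call links to a truth record
  expect_true(all(!is.na(man$truth_id)))
  expect_true(all(!man$qc_fail))
  # read-pair breakpoints equal truth (1-based pos1 = 0-based start + 1)
  rp <- dplyr::inner_join(cs$read_pair, man[man$caller == "read_pair", ],
                          by = "call_id")
  tv <- tr$variants
  truth_start <- tv$start[match(rp$truth_id, tv$truth_id)]
  expect_equal(rp$pos1, truth_start + 1)
})

test_that("ploidy-4 genotypes encode the planted allele count", {
  cfg <- small_noiseless_config(seed = 2)
  tr <- simulate_truth(cfg)
  cs <- emit_caller_callsets(tr, cfg)
  man <- cs$manifest[cs$manifest$caller == "small_variant", ]
  sv <- dplyr::inner_join(cs$small_variant, man, by = "call_id")
  tv <- tr$variants
  ac <- tv$alt_count[match(sv$truth_id, tv$truth_id)]
  n_alt <- vapply(strsplit(sv$gt, "/"), function(a) sum(a == "1"), integer(1))
  expect_equal(n_alt, ac)
  # all-alternate truths carry four identical alternate alleles
  expect_true(all(sv$gt[ac == 4] == "1/1/1/1"))
})

test_that("noiseless depth track is exactly CN/2, with CN-0 segments at zero", {
  cfg <- small_noiseless_config(seed = 4)
  tr <- simulate_truth(cfg)
  cs <- emit_caller_callsets(tr, cfg)
  dt <- cs$depth_track
  seg0 <- tr$cn_segments[tr$cn_segments$cn == 0 &
                           tr$cn_segments$end - tr$cn_segments$start >= 2 * cfg$bin_size, ]
  expect_gt(nrow(seg0), 0)
  for (i in seq_len(nrow(seg0))) {
    bins <- dt[dt$chrom == seg0$chrom[i] & dt$start >= seg0$start[i] &
                 dt$end <= seg0$end[i], ]
    expect_true(all(bins$depth == 0))
  }
  base_bins <- dt[overlaps_any(dt$chrom, dt$start, dt$end,
                               tr$cn_segments$chrom[tr$cn_segments$cn == 4],
                               tr$cn_segments$start[tr$cn_segments$cn == 4],
                               tr$cn_segments$end[tr$cn_segments$cn == 4]) &
                    !overlaps_any(dt$chrom, dt$start, dt$end,
                                  tr$cn_segments$chrom[tr$cn_segments$cn != 4],
                                  tr$cn_segments$start[tr$cn_segments$cn != 4],
                                  tr$cn_segments$end[tr$cn_segments$cn != 4]), ]
  expect_true(all(base_bins$depth == 2))
})

test_that("manifest is complete: every emitted call links to truth or is a false positive", {
  cfg <- small_config(seed = 31)
  tr <- simulate_truth(cfg)
  cs <- emit_caller_callsets(tr, cfg)
  man <- cs$manifest[!is.na(cs$manifest$call_id), ]
  emitted <- c(cs$small_variant$call_id, cs$split_read$call_id,
               cs$read_pair$call_id, cs$read_depth_cnv$call_id)
  expect_setequal(man$call_id, emitted)
  expect_equal(anyDuplicated(man$call_id), 0L)
  expect_true(all(is.na(man$truth_id) | man$truth_id %in% tr$variants$truth_id))
})

test_that("unrepresentable truth classes are flagged with a warning", {
  cfg <- simulation_config(
    variant_counts = c(homozygous_deletion = 5),
    size_ranges = list(homozygous_deletion_short = c(160, 180),
                       homozygous_deletion_long = c(160, 199)),
    homdel_long_fraction = 0,
    seed = 3
  )
  tr <- simulate_truth(cfg)
  expect_warning(cs <- emit_caller_callsets(tr, cfg), "not representable")
  man <- cs$manifest
  expect_equal(sum(is.na(man$call_id)), 5L)
})

test_that("database planting covers the spec'd fraction and plants the enriched set", {
  cfg <- small_config(seed = 17)
  tr <- simulate_truth(cfg)
  dbs <- emit_databases(tr, cfg)
  man <- dbs$manifest
  subs_planted <- man[man$db == "dbsnp" & man$expect_match, ]
  n_sub <- sum(tr$variants$class == "substitution")
  expect_equal(sum(tr$variants$truth_id[tr$variants$class == "substitution"] %in%
                     subs_planted$truth_id),
               round(cfg$db$match_fraction[["substitution"]] * n_sub))
  expect_true("PLANTED_SET" %in% names(dbs$gene_sets))
  expect_equal(length(dbs$gene_sets$PLANTED_SET), cfg$db$planted_set_size)
  expect_gte(length(intersect(dbs$gene_sets$PLANTED_SET, dbs$damaged_truth)), 1)
  # zero planting propagates to zero matches
  cfg0 <- small_config(seed = 18)
  cfg0$db$match_fraction[] <- 0
  cfg0$db$clinvar_pathogenic <- 0
  cfg0$db$dbvar_pathogenic <- 0
  dbs0 <- emit_databases(simulate_truth(cfg0), cfg0)
  expect_equal(sum(dbs0$manifest$expect_match[dbs0$manifest$db %in%
                                                c("dbsnp", "dgv", "dbvar")]), 0L)
})
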