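test_that("parsing round-trips the synthetic bundle against the manifest", {
  cfg <- small_config(seed = 23)
  dir <- file.path(tempdir(), "roundtrip")
  b <- simulate_bundle(cfg, dir)
  man <- read_manifest(b$paths[["manifest"]])
  man <- man[!is.na(man$call_id), ]
  for (dialect in c("small_variant", "split_read", "read_pair")) {
    key <- if (dialect == "read_pair") "read_pair" else dialect
    calls <- parse_callset(b$paths[[key]], dialect)
    expect_equal(nrow(calls), sum(man$caller == dialect), info = dialect)
    expect_setequal(calls$call_id, man$call_id[man$caller == dialect])
  }
  rd <- parse_callset(b$paths[["read_depth_cnv"]], "read_depth")
  expect_equal(nrow(rd), sum(man$caller == "read_depth"))
  # coordinates survive the write/parse cycle exactly (noiseless check)
  cfgn <- small_noiseless_config(seed = 23)
  bn <- simulate_bundle(cfgn, file.path(tempdir(), "roundtrip_n"))
  sr <- parse_callset(bn$paths[["split_read"]], "split_read")
  manN <- bn$callsets$manifest[bn$callsets$manifest$caller == "split_read", ]
  tv <- bn$truth$variants
  joined <- dplyr::inner_join(sr, manN[, c("call_id", "truth_id")], by = "call_id")
  ti <- match(joined$truth_id, tv$truth_id)
  not_trans <- joined$class != "inter_translocation"
  expect_equal(joined$start[not_trans], unname(tv$start[ti][not_trans]))
  unlink(c(dir, file.path(tempdir(), "roundtrip_n")), recursive = TRUE)
})

test_that("ploidy-4 VCF genotypes parse into allele lists and zygosity", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample",
    "chr1\t100\tv1\tA\tG\t99\tPASS\t.\tGT\t0/1/1/1",
    "chr1\t200\tv2\tACGT\tA\t99\tPASS\t.\tGT\t1/1/1/1",
    "chr1\t300\tv3\tA\tACGT\t99\tPASS\t.\tGT\t0/0/0/1"
  ), path)
  calls <- parse_callset(path, "small_variant")
  expect_equal(calls$class, c("substitution", "deletion", "insertion"))
  expect_equal(calls$genotype[1], "0/1/1/1")
  expect_equal(calls$zygosity, c("het", "hom", "het"))
  # coordinate conversion: substitution locus [99,100); deletion [200,203)
  expect_equal(calls$start, c(99, 200, 300))
  expect_equal(calls$end, c(100, 203, 301))
  expect_equal(calls$length, c(1, 3, 3))
})

test_that("empty call files with valid headers parse to empty collections", {
  cfg <- simulation_config(variant_counts = c(substitution = 0), seed = 2)
  dir <- file.path(tempdir(), "empty_bundle")
  b <- simulate_bundle(cfg, dir)
  for (d in c("small_variant", "split_read", "read_pair")) {
    key <- d
    expect_equal(nrow(parse_callset(b$paths[[key]], d)), 0L, info = d)
  }
  expect_equal(nrow(parse_callset(b$paths[["read_depth_cnv"]], "read_depth")), 0L)
  unlink(dir, recursive = TRUE)
})

test_that("malformed records and unknown dialects error informatively", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("call_id", "chrom", "start", "end", "type", "length",
            "supporting_reads", "summed_mapq", "chrom2", "pos2"), collapse = "\t"),
    "c1\tchr1\t100\tnot_a_number\tDEL\t50\t5\t200\tNA\tNA"
  ), path)
  expect_error(parse_callset(path, "split_read"), "line 2.*end|end.*line 2")
  expect_error(parse_callset(path, "no_such_dialect"), "unknown caller dialect")
  expect_error(parse_callset("/nonexistent/file.tsv", "split_read"), "not found")
})

test_that("split-read filter applies the exact inclusive/exclusive bounds", {
  calls <- make_calls("split_read", "deletion", "chr1",
                      c(0, 0, 0, 0), c(10, 10, 10, 10),
                      supporting_reads = c(2, 10, 1, 2),
                      summed_mapq = c(100, 100, 500, 99),
                      mean_mapq = c(50, 10, 500, 49.5))
  kept <- filter_split_read_calls(calls)
  # reads 2/summed 100/mean 50 kept; mean exactly 10 removed (strict >);
  # reads 1 removed; summed 99 removed
  expect_equal(kept$call_id, "split_read_001")
  removed <- attr(kept, "removed")
  expect_equal(nrow(removed), 3L)
  expect_true(all(removed$reason == "support_below_threshold"))
  # missing metric: unscorable
  calls$mean_mapq[1] <- NA
  kept2 <- filter_split_read_calls(calls)
  expect_true("unscorable" %in% attr(kept2, "removed")$reason)
})

test_that("read-pair filter enforces confidence, pairs, and the insertion rule", {
  dels <- make_calls("read_pair", "deletion", "chr1", c(0, 0), c(100, 100),
                     confidence = c(80, 79), supporting_pairs = c(4, 10))
  kept <- filter_read_pair_calls(dels)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 80)
  ins <- make_calls("read_pair", "insertion", "chr1", c(0, 0), c(1, 1),
                    length = c(100, 100), confidence = c(90, 90),
                    supporting_pairs = c(8, 8), bp_distance = c(100, 150))
  kept_ins <- filter_read_pair_calls(ins)
  # distance equal to the inserted length is allowed; greater is removed
  expect_equal(nrow(kept_ins), 1L)
  expect_equal(kept_ins$bp_distance, 100)
})

test_that("CNV filter removes on either p-value or q0, bounds inclusive", {
  calls <- make_calls("read_depth", "deletion", "chr1", rep(0, 4), rep(1000, 4),
                      pval1 = c(0.005, 0.005, 0.001, 0.0099),
                      pval2 = c(0.001, 0.02, 0.001, 0.0099),
                      q0 = c(0.1, 0.1, 0.5, 0.499))
  kept <- filter_cnv_calls(calls)
  expect_equal(kept$call_id, c("read_depth_001", "read_depth_004"))
})

test_that("QC filters are monotone in their thresholds", {
  cfg <- small_config(seed = 37, qc_fail_rate = 0.4)
  b <- simulate_bundle(cfg, file.path(tempdir(), "mono"))
  sr <- parse_callset(b$paths[["split_read"]], "split_read")
  rp <- parse_callset(b$paths[["read_pair"]], "read_pair")
  rd <- parse_callset(b$paths[["read_depth_cnv"]], "read_depth")
  base <- qc_thresholds()
  for (i in 1:10) {
    harder <- qc_thresholds(
      min_supporting_reads = base$min_supporting_reads + i,
      min_summed_mapq = base$min_summed_mapq + 10 * i,
      min_mean_mapq = base$min_mean_mapq + i,
      min_confidence = base$min_confidence + i,
      min_read_pairs = base$min_read_pairs + i,
      max_cnv_pvalue = base$max_cnv_pvalue / (i + 1),
      max_q0_fraction = base$max_q0_fraction / (i + 1)
    )
    expect_lte(nrow(filter_split_read_calls(sr, harder)),
               nrow(filter_split_read_calls(sr, base)))
    expect_lte(nrow(filter_read_pair_calls(rp, harder)),
               nrow(filter_read_pair_calls(rp, base)))
    expect_lte(nrow(filter_cnv_calls(rd, harder)),
               nrow(filter_cnv_calls(rd, base)))
  }
  unlink(file.path(tempdir(), "mono"), recursive = TRUE)
})

test_that("gap masking removes any-overlap calls but spares inter-chromosomal translocations", {
  gaps <- tibble::tibble(chrom = "chr1", start = c(150, 200), end = c(160, 300))
  calls <- make_calls("split_read", "deletion", "chr1",
                      c(100, 100, 500), c(200, 200, 600))
  calls$class <- c("deletion", "inter_translocation", "deletion")
  calls$chrom2 <- c(NA, "chr2", NA)
  calls$pos2 <- c(NA, 50, NA)
  kept <- mask_gap_regions(calls, gaps)
  # [100,200) hits gap [150,160): removed; same span as translocation: kept;
  # [500,600) clear: kept
  expect_setequal(kept$call_id, c("split_read_002", "split_read_003"))
  # half-open: deletion ending where a gap starts does not overlap
  touch <- make_calls("split_read", "deletion", "chr1", 100, 200)
  expect_equal(nrow(mask_gap_regions(touch,
                                     tibble::tibble(chrom = "chr1", start = 200, end = 300))), 1L)
  # masking and filtering commute (both are per-call predicates)
  cfg <- small_config(seed = 41)
  b <- simulate_bundle(cfg, file.path(tempdir(), "commute"))
  sr <- parse_callset(b$paths[["split_read"]], "split_read")
  g <- read_bed_intervals(b$paths[["gaps"]])
  a <- mask_gap_regions(filter_split_read_calls(sr), g)
  bb <- filter_split_read_calls(mask_gap_regions(sr, g))
  expect_setequal(a$call_id, bb$call_id)
  unlink(file.path(tempdir(), "commute"), recursive = TRUE)
})

test_that("the 50 bp cutoff assigns length >= 50 to the long class", {
  calls <- make_calls("split_read", "deletion", "chr1",
                      c(0, 100, 300), c(49, 150, 301))
  calls$length <- c(49, 50, 1)
  calls$class <- c("deletion", "deletion", "insertion")
  out <- split_by_length(calls)
  expect_setequal(out$short$length, c(49, 1))
  expect_equal(out$long$length, 50)
})

test_that("within-caller merge applies each caller's documented rule", {
  # split-read insertions: direct overlap, longest length wins
  ins <- make_calls("split_read", "insertion", "chr1", c(100, 100, 102),
                    c(101, 101, 103), length = c(5, 9, 7))
  m <- within_caller_merge(ins)
  expect_equal(nrow(m), 2L)
  expect_equal(m$length[m$start == 100], 9)
  # split-read translocations: one record per chromosome pair
  ctx <- make_calls("split_read", "inter_translocation", "chr1",
                    c(100, 5e5, 100), c(101, 5e5 + 1, 101))
  ctx$chrom2 <- c("chr2", "chr2", "chr3")
  ctx$pos2 <- c(1000, 8000, 1000)
  m2 <- within_caller_merge(ctx)
  expect_equal(nrow(m2), 2L)
  # read-pair translocations: both breakpoints < 1000 bp apart
  rpt <- make_calls("read_pair", "inter_translocation", "chr1",
                    c(1000, 1800, 4000), c(1001, 1801, 4001))
  rpt$chrom2 <- "chr2"
  rpt$pos2 <- c(5000, 5600, 9000)
  m3 <- within_caller_merge(rpt)
  expect_equal(nrow(m3), 2L)
  # other classes: adjacent-or-overlapping
  dels <- make_calls("split_read", "deletion", "chr1", c(0, 100, 300),
                     c(100, 200, 400))
  m4 <- within_caller_merge(dels)
  expect_equal(nrow(m4), 2L)
  expect_equal(m4$start, c(0, 300))
  expect_equal(m4$end, c(200, 400))
  # contract violation on mixed input
  mixed <- dplyr::bind_rows(ins, dels)
  expect_error(within_caller_merge(mixed), "single caller and class")
})

test_that("within-caller merge is idempotent and order-independent", {
  set.seed(55)
  for (i in 1:20) {
    calls <- random_tier(sample(5:30, 1), "split_read", "deletion")
    m1 <- within_caller_merge(calls)
    m2 <- within_caller_merge(calls[sample(nrow(calls)), ])
    expect_equal(m1[, c("chrom", "start", "end")],
                 m2[, c("chrom", "start", "end")])
    m3 <- within_caller_merge(m1)
    expect_equal(m1[, c("chrom", "start", "end")],
                 m3[, c("chrom", "start", "end")])
  }
})

test_that("summary ratios implement the hom/het and Ts/Tv definitions", {
  calls <- make_calls("small_variant", "substitution", "chr1",
                      c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
  calls$ref <- c("A", "A", "C", "A", "G", "C")
  calls$alt <- c("G", "C", "T", "T", "A", "A")
  calls$genotype <- c("1/1/1/1", "0/1/1/1", "1/1/1/1", "0/0/0/1",
                      "0/1/1/1", "1/1/1/1")
  calls$zygosity <- gt_zygosity(calls$genotype)
  s <- variant_summary_stats(calls)
  # transitions: A->G, C->T, G->A = 3; transversions: A->C, A->T, C->A = 3
  expect_equal(s$ts_tv_ratio, 1)
  expect_equal(s$hom_het_ratio, 3 / 3)
  # undefined ratios (zero denominator) reported as NA
  s2 <- variant_summary_stats(calls[1, ]) # one hom transition call
  expect_true(is.na(s2$hom_het_ratio))
  expect_true(is.na(s2$ts_tv_ratio))
})
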