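test_that("hierarchical precedence drops overlapping lower-tier calls", {
  t1 <- make_calls("split_read", "deletion", "chr1", 0, 100)
  t2 <- make_calls("read_pair", "deletion", "chr1", 50, 150)
  m <- hierarchical_merge(dplyr::bind_rows(t1, t2))
  # reciprocal 50%: read-pair call dropped, locus keeps tier-1 span
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 100))
  expect_equal(m$callers[[1]], "split_read")
  expect_equal(attr(m, "dropped")$call_id, "read_pair_001")

  t2b <- make_calls("read_pair", "deletion", "chr1", 500, 600)
  m2 <- hierarchical_merge(dplyr::bind_rows(t1, t2b))
  expect_equal(nrow(m2), 2L)
  expect_equal(lapply(m2$callers, identity),
               list("split_read", "read_pair"))
  expect_error(hierarchical_merge(dplyr::bind_rows(
    t1, make_calls("read_pair", "inversion", "chr1", 5, 10))), "single class")
})

test_that("non-overlapping lower-tier calls merge in when adjacent", {
  t1 <- make_calls("split_read", "deletion", "chr1", 0, 100)
  t2 <- make_calls("read_pair", "deletion", "chr1", 100, 400)
  # reciprocal overlap 0: not dropped; bookended, so merged into one locus
  m <- hierarchical_merge(dplyr::bind_rows(t1, t2))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 400))
  expect_setequal(m$callers[[1]], c("split_read", "read_pair"))
})

test_that("duplication/inversion tiers use the one-way rule against the merged set", {
  # small lower-tier call fully inside a big tier-1 inversion: dropped
  t1 <- make_calls("split_read", "inversion", "chr1", 0, 10000)
  t2 <- make_calls("read_pair", "inversion", "chr1", 4000, 4400)
  m <- hierarchical_merge(dplyr::bind_rows(t1, t2))
  expect_equal(nrow(m), 1L)
  expect_equal(attr(m, "dropped")$call_id, "read_pair_001")
  # big lower-tier call covering a small tier-1 one by < 25% of itself:
  # kept and union-merged (they overlap)
  t3 <- make_calls("read_pair", "inversion", "chr1", 9900, 60000)
  m2 <- hierarchical_merge(dplyr::bind_rows(t1, t3))
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(0, 60000))
  expect_setequal(m2$callers[[1]], c("split_read", "read_pair"))
})

test_that("merge engine equals the brute-force three-stage oracle on random instances", {
  set.seed(404)
  for (i in 1:120) {
    class <- sample(c("deletion", "duplication", "inversion"), 1)
    t1 <- random_tier(sample(0:20, 1), "split_read", class)
    t2 <- random_tier(sample(0:20, 1), "read_pair", class)
    t3 <- if (class == "inversion") random_tier(0, "read_depth", class) else
      random_tier(sample(0:10, 1), "read_depth", class)
    got <- hierarchical_merge(dplyr::bind_rows(t1, t2, t3))
    want <- oracle_hierarchical_merge(t1, t2, t3, class)
    expect_equal(nrow(got), nrow(want), info = sprintf("instance %d (%s)", i, class))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(lapply(got$source_ids, sort), lapply(want$ids, sort))
  }
})

test_that("hierarchical merge is idempotent and respects precedence invariants", {
  set.seed(505)
  for (i in 1:30) {
    class <- sample(c("deletion", "duplication"), 1)
    calls <- dplyr::bind_rows(
      random_tier(sample(1:15, 1), "split_read", class),
      random_tier(sample(1:15, 1), "read_pair", class),
      random_tier(sample(0:8, 1), "read_depth", class)
    )
    m <- hierarchical_merge(calls)
    # output loci are pairwise non-adjacent and non-overlapping
    for (ch in unique(m$chrom)) {
      v <- m[m$chrom == ch, ]
      v <- v[order(v$start), ]
      if (nrow(v) > 1) expect_true(all(v$start[-1] > v$end[-nrow(v)]))
    }
    # idempotence: feeding loci back as tier-1 calls changes nothing
    again <- make_calls("split_read", class, m$chrom, m$start, m$end)
    m2 <- hierarchical_merge(again)
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
    # precedence: no dropped call is needed to cover a merged locus, and
    # every input call is dropped or assigned to exactly one locus
    assigned <- unlist(m$source_ids)
    dropped <- attr(m, "dropped")$call_id
    expect_setequal(c(assigned, dropped), calls$call_id)
    expect_equal(anyDuplicated(c(assigned, dropped)), 0L)
    expect_lte(nrow(m), nrow(calls))
  }
})

test_that("insertion merging is overlap-only with no hierarchy", {
  a <- make_calls("small_variant", "insertion", "chr1", 100, 101, length = 12)
  b <- make_calls("split_read", "insertion", "chr1", 100, 101, length = 20)
  m <- merge_insertions(dplyr::bind_rows(a, b))
  expect_equal(nrow(m), 1L)
  expect_setequal(m$callers[[1]], c("small_variant", "split_read"))
  expect_equal(m$ins_length, 20)
  # adjacent points do not merge
  c2 <- make_calls("split_read", "insertion", "chr1", 101, 102, length = 5)
  m2 <- merge_insertions(dplyr::bind_rows(a, c2))
  expect_equal(nrow(m2), 2L)
  # random sets agree with the exhaustive overlap-clustering oracle
  set.seed(66)
  for (i in 1:25) {
    n <- sample(2:20, 1)
    pos <- sample(50, n, replace = TRUE)
    calls <- make_calls(sample(c("small_variant", "split_read", "read_pair"),
                               n, replace = TRUE)[1], "insertion",
                        "chr1", pos, pos + 1, length = sample(40, n, replace = TRUE))
    calls$caller <- sample(c("small_variant", "split_read"), n, replace = TRUE)
    got <- merge_insertions(calls)
    want <- oracle_cluster(tibble::tibble(chrom = calls$chrom, start = calls$start,
                                          end = calls$end, ids = as.list(calls$call_id)),
                           adjacent = FALSE)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(got$start, want$start)
  }
})

test_that("homozygous-deletion pipeline filters, swaps, and merges as specified", {
  sv_calls <- make_calls("small_variant", "substitution", "chr1", 500, 501)
  cn0 <- tibble::tibble(chrom = "chr1", start = c(0, 20000, 50000),
                        end = c(10000, 21000, 52000))
  sr <- make_calls("split_read", "deletion", "chr1", 20010, 20990)
  rp <- make_calls("read_pair", "deletion", "chr1", c(20005, 50100), c(20900, 51800))
  homdel <- make_calls("small_variant", "deletion", "chr1", 90000, 90030,
                       genotype = "1/1/1/1", zygosity = "hom")
  m <- merge_homozygous_deletions(homdel, cn0, sr, rp, sv_calls)
  # [0,10000) overlaps the substitution: removed
  expect_equal(attr(m, "dropped")$segment, "cn0_chr1_0_10000")
  # [20000,21000): split-read candidate at 98% reciprocal beats the
  # read-pair candidate (higher overlap), breakpoints swapped in
  swapped <- m[m$provenance == "cn0_replaced_by_split_read", ]
  expect_equal(nrow(swapped), 1L)
  expect_equal(c(swapped$start, swapped$end), c(20010, 20990))
  # [50000,52000): only read-pair candidate at ~85% > 50%: swapped too
  swapped2 <- m[m$provenance == "cn0_replaced_by_read_pair", ]
  expect_equal(c(swapped2$start, swapped2$end), c(50100, 51800))
  # small-variant hom-del calls merge in untouched
  expect_true(any(m$start == 90000 & m$end == 90030))
  expect_equal(nrow(m), 3L)
})

test_that("CN0 replacement needs strictly more than 50% reciprocal overlap", {
  no_sv <- make_calls("small_variant", "substitution", "chr2", 1, 2)
  cn0 <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  at_half <- make_calls("split_read", "deletion", "chr1", 0, 500)
  m <- merge_homozygous_deletions(tetramerge::empty_calls(), cn0, at_half,
                                  tetramerge::empty_calls(), no_sv)
  # reciprocal overlap exactly 50% of the segment: not replaced
  expect_equal(m$provenance, "")
  expect_equal(c(m$start, m$end), c(0, 1000))
  over_half <- make_calls("split_read", "deletion", "chr1", 0, 510)
  m2 <- merge_homozygous_deletions(tetramerge::empty_calls(), cn0, over_half,
                                   tetramerge::empty_calls(), no_sv)
  expect_equal(m2$provenance, "cn0_replaced_by_split_read")
})

test_that("contribution summaries report per-caller overlap fractions", {
  a <- make_calls("split_read", "deletion", "chr1", c(0, 1000), c(100, 1100))
  m <- hierarchical_merge(a)
  s1 <- summarize_contributions(m, a)
  expect_equal(s1$overlap_frac, 0)
  expect_equal(s1$merged_total, 2L)
  b <- a
  b$caller <- "read_pair"
  b$call_id <- sub("split_read", "read_pair", b$call_id)
  both <- dplyr::bind_rows(a, b)
  s2 <- summarize_contributions(hierarchical_merge(both), both)
  expect_equal(s2$overlap_frac, c(1, 1))
  expect_true(all(s2$merged_total <= nrow(both)))
})
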