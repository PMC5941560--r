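db_records <- function(class, chrom, start, end, ...) {
  n <- length(start)
  tibble::tibble(
    db = "test", record_id = sprintf("rec_%03d", seq_len(n)),
    class = class, chrom = chrom, start = as.double(start),
    end = as.double(end), ...
  )
}

test_that("VCF indel conversion follows the anchor-base coordinate arithmetic", {
  iv <- vcf_indel_to_interval(
    pos = c(100, 100, 100, 50),
    ref = c("ACGT", "A", "A", paste(rep("A", 121), collapse = "")),
    alt = c("A", "ACGT", "G", "A")
  )
  expect_equal(iv$class[1:3], c("deletion", "insertion", "substitution"))
  expect_equal(c(iv$start[1], iv$end[1]), c(100, 103))
  expect_equal(c(iv$start[2], iv$end[2]), c(100, 101))
  expect_equal(c(iv$start[3], iv$end[3]), c(99, 100))
  # 120 bp deletion: excluded from short-variant matching
  expect_true(is.na(iv$class[4]))
  # symbolic alleles excluded
  expect_true(is.na(vcf_indel_to_interval(10, "A", "<DEL>")$class))
})

test_that("short-variant matching uses any-overlap for indels, locus+allele for substitutions", {
  recs <- db_records(c("deletion", "substitution", "substitution"), "chr1",
                     c(149, 99, 200), c(160, 100, 201),
                     alt = c(NA, "G", "T"))
  vars <- tibble::tibble(
    class = c("deletion", "substitution", "substitution", "deletion"),
    chrom = "chr1", start = c(100, 99, 200, 300), end = c(150, 100, 201, 340),
    alt = c(NA, "G", "G", NA)
  )
  out <- match_short_variants(vars, recs)
  # deletion [100,150) vs record [149,160): 1 bp overlap is a match
  expect_equal(out$matched, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$match_record[1], "rec_001")
})

test_that("clinical record filtering implements the zero-star/OMIM/common rules", {
  recs <- tibble::tibble(
    record_id = sprintf("r%d", 1:4),
    assertion_criteria = c(FALSE, FALSE, TRUE, TRUE),
    submitter = c("OMIM", "lab_x", "clingen", "clingen"),
    common = c(FALSE, FALSE, FALSE, TRUE)
  )
  kept <- filter_clinical_records(recs)
  expect_setequal(kept$record_id, c("r1", "r3"))
  # filtering before matching equals matching then discarding filtered hits
  vars <- tibble::tibble(class = "deletion", chrom = "chr1",
                         start = c(0, 500), end = c(100, 600))
  recs2 <- db_records("deletion", "chr1", c(0, 500), c(100, 600),
                      assertion_criteria = c(TRUE, FALSE),
                      submitter = "lab_x", common = FALSE)
  a <- match_clinical_short(vars, filter_clinical_records(recs2))
  b <- match_clinical_short(vars, recs2)
  b$matched <- b$matched &
    b$match_record %in% filter_clinical_records(recs2)$record_id
  expect_equal(a$matched, b$matched)
})

test_that("clinical short matching requires 25% reciprocal overlap inclusive", {
  vars <- tibble::tibble(class = "deletion", chrom = "chr1",
                         start = c(0, 0), end = c(100, 100))
  recs <- db_records("deletion", "chr1", c(0, 90), c(100, 400))
  out <- match_clinical_short(vars[1, ], recs[1, , drop = FALSE])
  expect_true(out$matched)
  # overlap 10 bp = 10% of one and 3.2% of the other: no match
  out2 <- match_clinical_short(vars[2, ], recs[2, , drop = FALSE])
  expect_false(out2$matched)
})

test_that("population and pathogenic long-variant rules are strict at their bounds", {
  vars <- tibble::tibble(class = "deletion", chrom = "chr1", start = 0, end = 1000)
  # exactly 25% reciprocal: strict rule says no match
  expect_false(match_long_population(vars, db_records("deletion", "chr1", 750, 1750))$matched)
  expect_true(match_long_population(vars, db_records("deletion", "chr1", 749, 1749))$matched)
  # identity matches; different class does not
  expect_true(match_long_population(vars, db_records("deletion", "chr1", 0, 1000))$matched)
  expect_false(match_long_population(vars, db_records("duplication", "chr1", 0, 1000))$matched)
  # pathogenic rule: 95% reciprocal matches, 80% does not, exactly 90% does not
  path_rec <- function(s, e) db_records("deletion", "chr1", s, e, clin_sig = "Pathogenic")
  expect_true(match_pathogenic_long(vars, path_rec(50, 1000))$matched)
  expect_false(match_pathogenic_long(vars, path_rec(200, 1200))$matched)
  expect_false(match_pathogenic_long(vars, path_rec(100, 1000))$matched)
  # benign records are ignored entirely
  expect_false(match_pathogenic_long(
    vars, db_records("deletion", "chr1", 0, 1000, clin_sig = "Benign"))$matched)
})

test_that("random long-variant matches agree with the per-base oracle", {
  set.seed(31)
  for (i in 1:200) {
    s1 <- sample(1000, 1); e1 <- s1 + sample(500, 1)
    s2 <- sample(1000, 1); e2 <- s2 + sample(500, 1)
    ov <- overlap_bp_oracle(s1, e1, s2, e2)
    want25 <- ov > 0.25 * (e1 - s1) && ov > 0.25 * (e2 - s2)
    want90 <- ov > 0.90 * (e1 - s1) && ov > 0.90 * (e2 - s2)
    vars <- tibble::tibble(class = "deletion", chrom = "chr1", start = s1, end = e1)
    expect_equal(match_long_population(
      vars, db_records("deletion", "chr1", s2, e2))$matched, want25)
    expect_equal(match_pathogenic_long(
      vars, db_records("deletion", "chr1", s2, e2, clin_sig = "Pathogenic"))$matched,
      want90)
  }
})

test_that("array comparison screens records and scores zygosity concordance", {
  subs <- tibble::tibble(class = "substitution", chrom = "chr1",
                         start = c(99, 199, 299),
                         genotype = c("1/1/1/1", "0/1/1/1", "0/0/1/1"),
                         zygosity = c("hom", "het", "het"))
  array <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = "chr1", pos = c(100, 200, 300, 400, 500),
    allele1 = c("A", "G", "C", "G", "T"),
    allele2 = c("A", "C", "C", "G", "T")
  )
  refs <- tibble::tibble(rsid = c("rs1", "rs2", "rs3", "rs4"),
                         ref = c("C", "G", "T", "G"))
  cmp <- compare_array_genotypes(subs, array, refs)
  # rs5 unresolved, rs4 hom-ref: screened out
  expect_equal(cmp$n_dropped_unresolved, 1L)
  expect_equal(cmp$n_dropped_hom_ref, 1L)
  expect_equal(nrow(cmp$screened), 3L)
  # rs1 hom/hom agree, rs2 het/het agree, rs3 hom vs het disagree
  expect_equal(sort(cmp$shared$rsid), c("rs1", "rs2", "rs3"))
  expect_equal(cmp$agreement, 2 / 3)
})

test_that("planted array concordance is recovered exactly from a constructed fixture", {
  cfg <- small_noiseless_config(seed = 29)
  b <- simulate_bundle(cfg, file.path(tempdir(), "arr"))
  rep <- run_pipeline(cfg, bundle = b)
  man <- b$dbs$manifest
  planted <- man[man$db == "array" & !is.na(man$truth_id), ]
  expect_equal(rep$array_comparison$agreement, mean(planted$expect_match))
  unlink(file.path(tempdir(), "arr"), recursive = TRUE)
})

test_that("planted database match fractions are recovered through the pipeline", {
  cfg <- small_noiseless_config(seed = 47)
  b <- simulate_bundle(cfg, file.path(tempdir(), "planted"))
  rep <- run_pipeline(cfg, bundle = b)
  man <- b$dbs$manifest
  tv <- b$truth$variants
  planted_ids <- function(db) unique(man$truth_id[man$db == db & man$expect_match])
  for (cls in c("substitution", "short_deletion", "short_insertion")) {
    want <- sum(tv$truth_id[tv$class == cls] %in% planted_ids("dbsnp"))
    got <- sum(rep$db_results[[cls]]$matched)
    expect_equal(got, want, info = cls)
  }
  for (cls in c("long_deletion", "long_insertion", "duplication")) {
    want <- sum(tv$truth_id[tv$class == cls] %in% planted_ids("dgv"))
    got <- sum(rep$db_results[[cls]]$matched)
    expect_equal(got, want, info = cls)
  }
  # ten pathogenic clinical matches planted, ten reported
  expect_equal(nrow(rep$clinvar_pathogenic), cfg$db$clinvar_pathogenic)
  # dbVar pathogenic matches: planted count, near-misses excluded
  expect_equal(sum(rep$dbvar_pathogenic$matched),
               sum(man$db == "dbvar" & man$expect_match))
  # match percentages are consistent with the summary table
  summ <- rep$db_match_summary
  expect_true(all(summ$pct >= 0 & summ$pct <= 100, na.rm = TRUE))
  unlink(file.path(tempdir(), "planted"), recursive = TRUE)
})
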