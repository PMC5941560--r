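# Encode an interval-model variant back into VCF (pos, ref, alt) fields.
interval_to_vcf_fields <- function(class, start, end, ins_len = NULL,
                                   ref = NULL, alt = NULL) {
  n <- length(class)
  pos <- numeric(n)
  out_ref <- character(n)
  out_alt <- character(n)
  for (i in seq_len(n)) {
    if (class[i] == "substitution") {
      pos[i] <- start[i] + 1
      out_ref[i] <- ref[i]
      out_alt[i] <- alt[i]
    } else if (class[i] == "deletion") {
      pos[i] <- start[i]
      anchor <- random_bases(1)
      out_ref[i] <- paste0(anchor, random_bases(end[i] - start[i]))
      out_alt[i] <- anchor
    } else {
      pos[i] <- start[i]
      anchor <- random_bases(1)
      out_ref[i] <- anchor
      out_alt[i] <- paste0(anchor, random_bases(ins_len[i]))
    }
  }
  list(pos = pos, ref = out_ref, alt = out_alt)
}

# Random loci that do not overlap any interval in `avoid` (padded by 1 bp)
# and stay outside gaps.
distractor_loci <- function(n, sizes, config, gaps, avoid) {
  out <- vector("list", n)
  blocked <- dplyr::bind_rows(gaps[, c("chrom", "start", "end")],
                              avoid[, c("chrom", "start", "end")])
  chroms <- names(config$chrom_lengths)
  probs <- config$chrom_lengths / sum(config$chrom_lengths)
  for (i in seq_len(n)) {
    for (attempt in seq_len(2000L)) {
      ch <- sample(chroms, 1, prob = probs)
      len <- config$chrom_lengths[[ch]]
      start <- floor(stats::runif(1, 1, len - sizes[i] - 1))
      end <- start + sizes[i]
      b <- blocked[blocked$chrom == ch, , drop = FALSE]
      if (!any(b$start - 1 < end & b$end + 1 > start)) {
        out[[i]] <- tibble(chrom = ch, start = start, end = end)
        break
      }
    }
    if (is.null(out[[i]])) stop("could not place database distractor record")
  }
  dplyr::bind_rows(out)
}

#' Emit synthetic external databases, annotations and gene sets
#'
#' Builds dbSNP-, ClinVar-, DGV- and dbVar-style databases, an effect
#' annotation table with population MAFs, an exon model, array genotypes
#' and GMT gene sets, all planted against the truth set so that every
#' downstream matching rule has a known expected outcome: a configured
#' fraction of truth variants per class receives a matching record;
#' ClinVar-style records include zero-star, OMIM-submitted and
#' common-flagged distractors; pathogenic long-variant records are
#' planted above (and near-misses below) the 90% reciprocal bound; one
#' gene set is planted with inflated overlap with the damaged-gene truth
#' list among uniform decoy sets.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The matching [simulation_config()].
#' @return List of database tables, gene sets, the damaged-gene truth
#'   list and a planting manifest (`db`, `record_id`, `truth_id`,
#'   `expect_match`).
#' @export
emit_databases <- function(truth, config) {
  stopifnot(inherits(truth, "tetramerge_truth"))
  with_seed(derive_seed(config$seed, 3L), emit_databases_impl(truth, config))
}

emit_databases_impl <- function(truth, config) {
  tv <- truth$variants
  dbc <- config$db
  gaps <- truth$gaps
  manifest <- list()
  note <- function(db, ids, truth_ids, expect) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      db = db, record_id = ids, truth_id = truth_ids, expect_match = expect
    )
  }

  universe <- sprintf("G%05d", seq_len(dbc$n_genes))
  rs_counter <- 0L
  next_rs <- function(n) {
    ids <- sprintf("rs%07d", rs_counter + seq_len(n))
    rs_counter <<- rs_counter + n
    ids
  }

  # ---- dbSNP-style records (short classes) ------------------------------
  dbsnp_rows <- list()
  short_classes <- c("substitution", "short_deletion", "short_insertion")
  for (cls in short_classes) {
    sub <- tv[tv$class == cls, , drop = FALSE]
    n_match <- round(dbc$match_fraction[[cls]] * nrow(sub))
    if (nrow(sub) == 0L) next
    pick <- sub[sample(nrow(sub), n_match), , drop = FALSE]
    if (n_match == 0L) next
    if (cls == "substitution") {
      enc <- list(pos = pick$start + 1, ref = pick$ref, alt = pick$alt)
    } else if (cls == "short_deletion") {
      # shift within the deletion so that >= 1 bp overlap always remains
      shift <- vapply(pick$length, function(L) {
        resample(seq(-min(3, L - 1), min(3, L - 1)), 1)
      }, double(1))
      enc <- interval_to_vcf_fields(rep("deletion", n_match),
                                    pick$start + shift, pick$end + shift)
    } else {
      enc <- interval_to_vcf_fields(rep("insertion", n_match),
                                    pick$start, pick$end, ins_len = pick$length)
    }
    ids <- next_rs(n_match)
    dbsnp_rows[[cls]] <- tibble(
      chrom = pick$chrom, pos = enc$pos, id = ids, ref = enc$ref,
      alt = enc$alt, gt = NA_character_
    )
    note("dbsnp", ids, pick$truth_id, TRUE)
  }
  smalls <- tv[tv$class %in% short_classes, , drop = FALSE]
  # allele-mismatch distractors at unmatched substitution loci
  matched_ids <- unlist(lapply(manifest, function(m) m$truth_id))
  un_sub <- tv[tv$class == "substitution" & !(tv$truth_id %in% matched_ids), ]
  n_mm <- min(10L, nrow(un_sub))
  if (n_mm > 0) {
    mm <- un_sub[sample(nrow(un_sub), n_mm), , drop = FALSE]
    other_alt <- vapply(seq_len(n_mm), function(i) {
      sample(setdiff(c("A", "C", "G", "T"), c(mm$ref[i], mm$alt[i])), 1)
    }, character(1))
    ids <- next_rs(n_mm)
    dbsnp_rows$allele_mismatch <- tibble(
      chrom = mm$chrom, pos = mm$start + 1, id = ids, ref = mm$ref,
      alt = other_alt, gt = NA_character_
    )
    note("dbsnp", ids, mm$truth_id, FALSE)
  }
  # plain distractors away from every truth small variant
  n_extra <- dbc$n_extra_records
  extra <- distractor_loci(n_extra, rep(1, n_extra), config, gaps, smalls)
  alleles <- sample_substitution_alleles(n_extra, config$ts_fraction)
  ids <- next_rs(n_extra)
  dbsnp_rows$extra <- tibble(
    chrom = extra$chrom, pos = extra$start + 1, id = ids,
    ref = alleles$ref, alt = alleles$alt, gt = NA_character_
  )
  note("dbsnp", ids, NA_character_, FALSE)
  # over-length indel records (>= 100 bp): excluded by conversion even
  # though they overlap truth long deletions
  long_del <- tv[tv$class == "long_deletion", , drop = FALSE]
  n_long <- min(3L, nrow(long_del))
  if (n_long > 0) {
    ld <- long_del[sample(nrow(long_del), n_long), , drop = FALSE]
    enc <- interval_to_vcf_fields(rep("deletion", n_long), ld$start,
                                  pmin(ld$end, ld$start + 150))
    ids <- next_rs(n_long)
    dbsnp_rows$overlength <- tibble(
      chrom = ld$chrom, pos = enc$pos, id = ids, ref = enc$ref,
      alt = enc$alt, gt = NA_character_
    )
    note("dbsnp", ids, ld$truth_id, FALSE)
  }
  dbsnp <- dplyr::bind_rows(dbsnp_rows)

  # ---- ClinVar-style records -------------------------------------------
  clin_rows <- list()
  pool <- smalls
  take <- function(n) {
    n <- min(n, nrow(pool))
    idx <- sample(nrow(pool), n)
    out <- pool[idx, , drop = FALSE]
    pool <<- pool[-idx, , drop = FALSE]
    out
  }
  encode_small <- function(rows) {
    cls <- ifelse(rows$class == "substitution", "substitution",
                  ifelse(rows$class == "short_deletion", "deletion", "insertion"))
    interval_to_vcf_fields(cls, ifelse(cls == "substitution", rows$start, rows$start),
                           rows$end, ins_len = rows$length,
                           ref = rows$ref, alt = rows$alt)
  }
  add_clinvar <- function(rows, clin_sig, criteria, submitter, common, expect) {
    if (nrow(rows) == 0L) return(invisible(NULL))
    enc <- encode_small(rows)
    ids <- next_rs(nrow(rows))
    clin_rows[[length(clin_rows) + 1L]] <<- tibble(
      chrom = rows$chrom, pos = enc$pos, id = ids, ref = enc$ref, alt = enc$alt,
      gt = NA_character_, clin_sig = clin_sig, criteria = criteria,
      submitter = submitter, common = common
    )
    note("clinvar", ids, rows$truth_id, expect)
  }
  add_clinvar(take(dbc$clinvar_pathogenic), "Pathogenic", TRUE, "clingen", FALSE, TRUE)
  add_clinvar(take(dbc$clinvar_no_criteria), "Pathogenic", FALSE, "lab_x", FALSE, FALSE)
  add_clinvar(take(dbc$clinvar_omim), "Benign", FALSE, "OMIM", FALSE, TRUE)
  add_clinvar(take(dbc$clinvar_common), "Pathogenic", TRUE, "clingen", TRUE, FALSE)
  clinvar <- dplyr::bind_rows(clin_rows)
  if (nrow(clinvar) == 0L) {
    clinvar <- tibble(
      chrom = character(), pos = double(), id = character(), ref = character(),
      alt = character(), gt = character(), clin_sig = character(),
      criteria = logical(), submitter = character(), common = logical()
    )
  }

  # ---- DGV-style population SV records ---------------------------------
  long_classes <- c("long_deletion", "long_insertion", "duplication")
  dgv_rows <- list()
  rec_counter <- 0L
  next_rec <- function(prefix, n) {
    ids <- sprintf("%s_%05d", prefix, rec_counter + seq_len(n))
    rec_counter <<- rec_counter + n
    ids
  }
  for (cls in long_classes) {
    sub <- tv[tv$class == cls, , drop = FALSE]
    frac <- if (cls %in% names(dbc$match_fraction)) dbc$match_fraction[[cls]] else 0
    n_match <- round(frac * nrow(sub))
    if (n_match == 0L) next
    pick <- sub[sample(nrow(sub), n_match), , drop = FALSE]
    if (cls == "long_insertion") {
      start0 <- pick$start
      end0 <- pick$end
    } else {
      # shift by ~10% of length: reciprocal overlap ~90%, comfortably > 25%
      shift <- round(0.1 * pick$length)
      start0 <- pick$start + shift
      end0 <- pick$end + shift
    }
    ids <- next_rec("dgv", n_match)
    dgv_rows[[cls]] <- tibble(
      record_id = ids, chrom = pick$chrom, start = start0 + 1, end = end0,
      type = ifelse(cls == "long_deletion", "deletion",
                    ifelse(cls == "duplication", "duplication", "insertion"))
    )
    if (cls == "long_insertion") {
      dgv_rows[[cls]]$start <- pick$start + 1
      dgv_rows[[cls]]$end <- pick$start + 1
    }
    note("dgv", ids, pick$truth_id, TRUE)
  }
  longs <- tv[tv$class %in% long_classes, , drop = FALSE]
  n_extra <- dbc$n_extra_records
  sizes <- sample_sizes(n_extra, c(500, 20000))
  extra <- distractor_loci(n_extra, sizes, config, gaps, longs)
  ids <- next_rec("dgv", n_extra)
  dgv_rows$extra <- tibble(
    record_id = ids, chrom = extra$chrom, start = extra$start + 1,
    end = extra$end,
    type = sample(c("deletion", "duplication", "insertion"), n_extra, replace = TRUE)
  )
  note("dgv", ids, NA_character_, FALSE)
  dgv <- dplyr::bind_rows(dgv_rows)

  # ---- dbVar-style pathogenic records ----------------------------------
  dbvar_rows <- list()
  pool_long <- tv[tv$class %in% c("long_deletion", "duplication"), , drop = FALSE]
  n_path <- min(dbc$dbvar_pathogenic, nrow(pool_long))
  if (n_path > 0) {
    idx <- sample(nrow(pool_long), n_path)
    pick <- pool_long[idx, , drop = FALSE]
    pool_long <- pool_long[-idx, , drop = FALSE]
    shift <- pmax(1, round(0.02 * pick$length)) # reciprocal ~98% > 90%
    ids <- next_rec("dbvar", n_path)
    dbvar_rows$pathogenic <- tibble(
      record_id = ids, chrom = pick$chrom, start = pick$start + shift + 1,
      end = pick$end + shift,
      type = ifelse(pick$class == "long_deletion", "deletion", "duplication"),
      clin_sig = "Pathogenic"
    )
    note("dbvar", ids, pick$truth_id, TRUE)
  }
  n_near <- min(2L, nrow(pool_long))
  if (n_near > 0) {
    pick <- pool_long[sample(nrow(pool_long), n_near), , drop = FALSE]
    shift <- round(0.2 * pick$length) # reciprocal ~80% < 90%: no match
    ids <- next_rec("dbvar", n_near)
    dbvar_rows$near_miss <- tibble(
      record_id = ids, chrom = pick$chrom, start = pick$start + shift + 1,
      end = pick$end + shift,
      type = ifelse(pick$class == "long_deletion", "deletion", "duplication"),
      clin_sig = "Pathogenic"
    )
    note("dbvar", ids, pick$truth_id, FALSE)
  }
  dbvar <- dplyr::bind_rows(dbvar_rows)
  if (nrow(dbvar) == 0L) {
    dbvar <- tibble(record_id = character(), chrom = character(),
                    start = double(), end = double(), type = character(),
                    clin_sig = character())
  }

  # ---- effect annotations + MAF ----------------------------------------
  genes_needed <- nrow(smalls) + sum(tv$class == "homozygous_deletion") + 60
  gene_pool <- sample(universe, min(genes_needed, length(universe)))
  gene_i <- 0L
  next_genes <- function(n) {
    out <- gene_pool[gene_i + seq_len(n)]
    gene_i <<- gene_i + n
    out
  }
  ann <- NULL
  damaged_high <- character(0)
  if (nrow(smalls) > 0) {
    n_s <- nrow(smalls)
    hi <- stats::runif(n_s) < dbc$high_impact_fraction
    effect <- ifelse(hi, sample(HIGH_IMPACT_EFFECTS, n_s, replace = TRUE),
                     sample(c("missense_variant", "synonymous_variant"), n_s,
                            replace = TRUE, prob = c(0.6, 0.4)))
    rare <- hi & stats::runif(n_s) < dbc$rare_fraction
    maf <- numeric(n_s)
    maf[rare] <- stats::runif(sum(rare), 0, 0.00099)
    maf[rare & stats::runif(n_s) < dbc$maf_missing_fraction] <- NA_real_
    maf[hi & !rare] <- stats::runif(sum(hi & !rare), 0.001, 0.05)
    maf[!hi] <- ifelse(stats::runif(sum(!hi)) < 0.5, NA_real_,
                       stats::runif(sum(!hi), 0, 0.5))
    ann <- tibble(
      variant_id = smalls$truth_id, gene = next_genes(n_s), effect = effect,
      maf = maf
    )
    damaged_high <- sort(unique(ann$gene[hi & (is.na(ann$maf) | ann$maf < 0.001)]))
  } else {
    ann <- tibble(variant_id = character(), gene = character(),
                  effect = character(), maf = double())
  }

  # ---- exon model -------------------------------------------------------
  exon_rows <- list()
  homdels <- tv[tv$class == "homozygous_deletion", , drop = FALSE]
  damaged_homdel <- character(0)
  if (nrow(homdels) > 0) {
    hit <- stats::runif(nrow(homdels)) < dbc$exon_hit_fraction
    g <- next_genes(nrow(homdels))
    exon_rows$homdel <- tibble(
      chrom = homdels$chrom,
      start = ifelse(hit,
                     pmax(0, homdels$start - 20),
                     homdels$end + 100),
      end = ifelse(hit,
                   pmax(0, homdels$start - 20) + pmax(150, round(homdels$length / 2)),
                   homdels$end + 250),
      gene = g
    )
    damaged_homdel <- sort(unique(g[hit]))
  }
  n_bg <- 50L
  bg_sizes <- sample_sizes(n_bg, c(100, 300))
  bg <- distractor_loci(n_bg, bg_sizes, config, gaps,
                        if (nrow(homdels) > 0) homdels else
                          tibble(chrom = character(), start = double(), end = double()))
  exon_rows$background <- tibble(chrom = bg$chrom, start = bg$start,
                                 end = bg$end, gene = next_genes(n_bg))
  exons <- dplyr::bind_rows(exon_rows)

  damaged_truth <- union_damaged_genes(damaged_high, damaged_homdel)

  # ---- gene sets --------------------------------------------------------
  n_damaged <- length(damaged_truth)
  k_planted <- min(n_damaged, round(dbc$planted_overlap_fraction * n_damaged))
  set_size <- max(dbc$planted_set_size, k_planted)
  planted <- c(
    resample(damaged_truth, k_planted),
    resample(setdiff(universe, damaged_truth), set_size - k_planted)
  )
  gene_sets <- list(PLANTED_SET = sort(planted))
  for (i in seq_len(dbc$n_decoy_sets)) {
    sz <- sample(dbc$decoy_size_range[1]:dbc$decoy_size_range[2], 1)
    gene_sets[[sprintf("DECOY_%03d", i)]] <- sort(sample(universe, sz))
  }

  # ---- array genotypes --------------------------------------------------
  dbsnp_sub <- dbsnp[nchar(dbsnp$ref) == 1 & nchar(dbsnp$alt) == 1, , drop = FALSE]
  sub_truth <- tv[tv$class == "substitution", , drop = FALSE]
  sub_truth$pos <- sub_truth$start + 1
  planted_sub <- dplyr::inner_join(
    dbsnp_sub[, c("id", "chrom", "pos", "ref", "alt")],
    sub_truth[, c("chrom", "pos", "alt_count", "truth_id")],
    by = c("chrom", "pos")
  )
  n_arr <- min(dbc$array_sites, nrow(planted_sub))
  array_rows <- list()
  if (n_arr > 0) {
    pick <- planted_sub[sample(nrow(planted_sub), n_arr), , drop = FALSE]
    n_conc <- round(dbc$array_concordance * n_arr)
    concordant <- c(rep(TRUE, n_conc), rep(FALSE, n_arr - n_conc))[sample(n_arr)]
    truth_hom <- pick$alt_count == 4L
    array_hom <- ifelse(concordant, truth_hom, !truth_hom)
    array_rows$planted <- tibble(
      rsid = pick$id, chrom = pick$chrom, pos = pick$pos,
      allele1 = ifelse(array_hom, pick$alt, pick$ref),
      allele2 = pick$alt
    )
    note("array", pick$id, pick$truth_id, concordant)
  }
  n_hr <- min(dbc$array_hom_ref, nrow(dbsnp_sub))
  if (n_hr > 0) {
    hr <- dbsnp_sub[sample(nrow(dbsnp_sub), n_hr), , drop = FALSE]
    array_rows$hom_ref <- tibble(
      rsid = hr$id, chrom = hr$chrom, pos = hr$pos,
      allele1 = hr$ref, allele2 = hr$ref
    )
    note("array", hr$id, NA_character_, FALSE)
  }
  if (dbc$array_unresolvable > 0) {
    ids <- sprintf("rs_unknown_%03d", seq_len(dbc$array_unresolvable))
    array_rows$unresolvable <- tibble(
      rsid = ids, chrom = names(config$chrom_lengths)[1],
      pos = seq_len(dbc$array_unresolvable) + 5000,
      allele1 = "A", allele2 = "C"
    )
    note("array", ids, NA_character_, FALSE)
  }
  array_genotypes <- dplyr::bind_rows(array_rows)

  ref_alleles <- tibble(rsid = dbsnp$id, ref = dbsnp$ref)

  list(
    dbsnp = dbsnp, clinvar = clinvar, dgv = dgv, dbvar = dbvar,
    annotations = ann[, c("variant_id", "gene", "effect")],
    exac_maf = ann[, c("variant_id", "maf")],
    exons = exons, gene_sets = gene_sets, universe = universe,
    array_genotypes = array_genotypes, ref_alleles = ref_alleles,
    damaged_truth = damaged_truth,
    damaged_high_truth = damaged_high, damaged_homdel_truth = damaged_homdel,
    manifest = dplyr::bind_rows(manifest)
  )
}

#' Write the synthetic database bundle to disk
#'
#' @param dbs Result of [emit_databases()].
#' @param dir Output directory.
#' @param config The [simulation_config()] (contig headers).
#' @return Named character vector of written paths.
#' @export
write_database_files <- function(dbs, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dbsnp = file.path(dir, "dbsnp.vcf"),
    clinvar = file.path(dir, "clinvar.vcf"),
    dgv = file.path(dir, "dgv.tsv"),
    dbvar = file.path(dir, "dbvar.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    exac_maf = file.path(dir, "exac_maf.tsv"),
    exons = file.path(dir, "exons.bed"),
    array = file.path(dir, "array_genotypes.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    db_manifest = file.path(dir, "db_manifest.tsv")
  )
  write_vcf_file(dbs$dbsnp, paths["dbsnp"], config$chrom_lengths,
                 with_genotypes = FALSE, ids = dbs$dbsnp$id)
  cv <- dbs$clinvar
  info <- sprintf(
    "CLNSIG=%s;SUBMITTER=%s%s%s", cv$clin_sig, cv$submitter,
    ifelse(cv$criteria, ";CRITERIA", ""), ifelse(cv$common, ";COMMON", "")
  )
  info_lines <- c(
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=SUBMITTER,Number=1,Type=String,Description=\"Submitting organisation\">",
    "##INFO=<ID=CRITERIA,Number=0,Type=Flag,Description=\"Assertion criteria provided\">",
    "##INFO=<ID=COMMON,Number=0,Type=Flag,Description=\"Annotated as a common variant\">"
  )
  write_vcf_file(cv, paths["clinvar"], config$chrom_lengths,
                 info_lines = info_lines, with_genotypes = FALSE,
                 info = info, ids = cv$id)
  write_tsv_file(dbs$dgv, paths["dgv"])
  write_tsv_file(dbs$dbvar, paths["dbvar"])
  write_tsv_file(dbs$annotations, paths["annotations"])
  write_tsv_file(dbs$exac_maf, paths["exac_maf"])
  write_bed_intervals(dbs$exons, paths["exons"], name = dbs$exons$gene)
  write_tsv_file(dbs$array_genotypes, paths["array"])
  write_gmt(dbs$gene_sets, paths["gmt"])
  write_tsv_file(dbs$manifest, paths["db_manifest"])
  paths
}
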