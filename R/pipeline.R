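#' Simulate a complete synthetic bundle on disk
#'
#' Runs [simulate_truth()], [emit_caller_callsets()] and
#' [emit_databases()] under the configuration's master seed and writes
#' every output file: the four caller call sets, the depth track, the
#' truth manifest, the databases, annotations, exon/gap BEDs and gene
#' sets. With a fixed seed the bundle is byte-identical across runs.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return List of class `tetramerge_bundle`: `truth`, `callsets`, `dbs`,
#'   `paths` (named file paths) and `config`.
#' @export
simulate_bundle <- function(config, dir) {
  truth <- simulate_truth(config)
  callsets <- emit_caller_callsets(truth, config)
  dbs <- emit_databases(truth, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_caller_files(callsets, dir, config),
    write_database_files(dbs, dir, config),
    gaps = file.path(dir, "gaps.bed")
  )
  write_bed_intervals(truth$gaps, paths["gaps"], name = truth$gaps$name)
  truth_path <- file.path(dir, "truth_variants.tsv")
  write_tsv_file(truth$variants, truth_path)
  seg_path <- file.path(dir, "truth_cn_segments.tsv")
  write_tsv_file(truth$cn_segments, seg_path)
  paths <- c(paths, truth_variants = truth_path, truth_cn_segments = seg_path)
  structure(list(truth = truth, callsets = callsets, dbs = dbs,
                 paths = paths, config = config),
            class = "tetramerge_bundle")
}

# Split parsed small-variant calls into the pieces the merge stages
# need: substitutions, non-homozygous deletions, insertions, and
# homozygous deletions (all-alternate genotype deletions).
partition_small_variants <- function(calls) {
  hom_del <- calls$class == "deletion" & calls$zygosity == "hom"
  list(
    substitutions = calls[calls$class == "substitution", , drop = FALSE],
    deletions = calls[calls$class == "deletion" & !hom_del, , drop = FALSE],
    insertions = calls[calls$class == "insertion", , drop = FALSE],
    homdels = calls[hom_del, , drop = FALSE]
  )
}

merge_class_group <- function(calls_list, class_label) {
  calls <- dplyr::bind_rows(calls_list)
  if (nrow(calls) == 0L) {
    return(hierarchical_merge(empty_calls()))
  }
  merged_within <- dplyr::bind_rows(lapply(
    split(calls, paste(calls$caller, calls$class)),
    within_caller_merge
  ))
  out <- if (unique(calls$class)[1] == "insertion") {
    merge_insertions(merged_within)
  } else {
    hierarchical_merge(merged_within)
  }
  out$class <- class_label
  out
}

#' Run the full harmonization pipeline on a synthetic bundle
#'
#' Orchestrates the end-to-end analysis: simulate (or reuse) a bundle;
#' parse the four caller files; apply per-caller QC filters and gap
#' masking; merge within callers; split indels at 50 bp; derive the
#' copy-number profile from the depth track; merge hierarchically across
#' callers (with the dedicated homozygous-deletion pipeline); match the
#' merged catalog against the planted databases; build the damaged-gene
#' set and test gene-set enrichment. Returns a run report with per-stage
#' counts, the merged catalog, contribution and match summaries, the CN
#' histogram, enrichment results and file checksums. Reruns with the
#' same configuration and seed reproduce identical outputs.
#'
#' @param config A [simulation_config()].
#' @param dir Working directory for the bundle files (default: a fresh
#'   subdirectory of `tempdir()`).
#' @param bundle Optionally, an existing [simulate_bundle()] result to
#'   reuse instead of simulating again.
#' @param thresholds QC thresholds, default [qc_thresholds()].
#' @return A list of class `tetramerge_report`.
#' @export
run_pipeline <- function(config = simulation_config(), dir = NULL,
                         bundle = NULL, thresholds = qc_thresholds()) {
  if (is.null(dir)) {
    dir <- file.path(tempdir(), sprintf("tetramerge_run_%d", config$seed))
  }
  if (is.null(bundle)) bundle <- simulate_bundle(config, dir)
  paths <- bundle$paths

  # ---- parse ------------------------------------------------------------
  sv_calls <- parse_callset(paths[["small_variant"]], "small_variant")
  sr_calls <- parse_callset(paths[["split_read"]], "split_read")
  rp_calls <- parse_callset(paths[["read_pair"]], "read_pair")
  rd_calls <- parse_callset(paths[["read_depth_cnv"]], "read_depth")
  gaps <- read_bed_intervals(paths[["gaps"]])
  manifest <- read_manifest(paths[["manifest"]])
  counts <- list(parsed = c(
    small_variant = nrow(sv_calls), split_read = nrow(sr_calls),
    read_pair = nrow(rp_calls), read_depth = nrow(rd_calls)
  ))

  # ---- QC + masking -----------------------------------------------------
  removed_log <- list()
  log_removed <- function(stage, calls) {
    rm <- attr(calls, "removed")
    if (!is.null(rm) && nrow(rm) > 0) {
      rm$stage <- stage
      removed_log[[length(removed_log) + 1L]] <<- rm
    }
    calls
  }
  sr_calls <- log_removed("split_read_qc", filter_split_read_calls(sr_calls, thresholds))
  rp_calls <- log_removed("read_pair_qc", filter_read_pair_calls(rp_calls, thresholds))
  rd_calls <- log_removed("read_depth_qc", filter_cnv_calls(rd_calls, thresholds))
  sr_calls <- log_removed("split_read_mask", mask_gap_regions(sr_calls, gaps))
  rp_calls <- log_removed("read_pair_mask", mask_gap_regions(rp_calls, gaps))
  rd_calls <- log_removed("read_depth_mask", mask_gap_regions(rd_calls, gaps))
  counts$qc <- c(
    small_variant = nrow(sv_calls), split_read = nrow(sr_calls),
    read_pair = nrow(rp_calls), read_depth = nrow(rd_calls)
  )

  # ---- size split -------------------------------------------------------
  sv_parts <- partition_small_variants(sv_calls)
  cutoff <- thresholds$short_long_cutoff
  sr_indels <- split_by_length(
    sr_calls[sr_calls$class %in% c("deletion", "insertion"), ], cutoff)
  rp_indels <- split_by_length(
    rp_calls[rp_calls$class %in% c("deletion", "insertion"), ], cutoff)
  sv_dels <- split_by_length(sv_parts$deletions, cutoff)
  sv_ins <- split_by_length(sv_parts$insertions, cutoff)
  rd_dels <- rd_calls[rd_calls$class == "deletion" & rd_calls$cn >= 1, , drop = FALSE]

  # ---- copy-number profile ---------------------------------------------
  profile <- read_depth_track(paths[["depth_track"]], bundle$config$bin_size)
  segments <- classify_cn_segments(profile)
  cn0 <- segments[segments$homozygous, c("chrom", "start", "end"), drop = FALSE]
  cn0 <- log_removed("cn0_mask", mask_gap_regions(
    as_calls(tibble(call_id = sprintf("cn0_%d", seq_len(nrow(cn0))),
                    caller = "read_depth", class = "deletion",
                    chrom = cn0$chrom, start = cn0$start, end = cn0$end,
                    length = cn0$end - cn0$start)), gaps))

  # ---- cross-caller merge ----------------------------------------------
  pick <- function(df, cls) df[df$class == cls, , drop = FALSE]
  sr_class <- function(cls) pick(sr_calls, cls)
  rp_class <- function(cls) pick(rp_calls, cls)
  merged <- list(
    substitution = merge_class_group(list(sv_parts$substitutions), "substitution"),
    short_deletion = merge_class_group(list(sv_dels$short, sr_indels$short[
      sr_indels$short$class == "deletion", ]), "short_deletion"),
    short_insertion = merge_class_group(list(sv_ins$short, sr_indels$short[
      sr_indels$short$class == "insertion", ]), "short_insertion"),
    long_deletion = merge_class_group(list(
      sr_indels$long[sr_indels$long$class == "deletion", ],
      rp_indels$long[rp_indels$long$class == "deletion", ],
      rd_dels
    ), "long_deletion"),
    long_insertion = merge_class_group(list(
      sr_indels$long[sr_indels$long$class == "insertion", ],
      rp_indels$long[rp_indels$long$class == "insertion", ]
    ), "long_insertion"),
    duplication = merge_class_group(list(sr_class("duplication"),
                                         pick(rd_calls, "duplication")), "duplication"),
    inversion = merge_class_group(list(sr_class("inversion"), rp_class("inversion")),
                                  "inversion"),
    intra_translocation = merge_class_group(list(rp_class("intra_translocation")),
                                            "intra_translocation"),
    inter_translocation = merge_class_group(list(sr_class("inter_translocation"),
                                                 rp_class("inter_translocation")),
                                            "inter_translocation")
  )
  homdel_within <- if (nrow(sv_parts$homdels) > 0) {
    within_caller_merge(sv_parts$homdels)
  } else {
    sv_parts$homdels
  }
  sr_dels_all <- dplyr::bind_rows(lapply(
    split(pick(sr_calls, "deletion"), pick(sr_calls, "deletion")$caller),
    within_caller_merge
  ))
  rp_dels_all <- dplyr::bind_rows(lapply(
    split(pick(rp_calls, "deletion"), pick(rp_calls, "deletion")$caller),
    within_caller_merge
  ))
  merged$homozygous_deletion <- merge_homozygous_deletions(
    homdel_within, cn0[, c("chrom", "start", "end")],
    if (nrow(sr_dels_all) > 0) sr_dels_all else empty_calls(),
    if (nrow(rp_dels_all) > 0) rp_dels_all else empty_calls(),
    sv_calls
  )
  counts$merged <- vapply(merged, nrow, integer(1))

  # ---- contribution table (per-tool comparison) -------------------------
  contributions <- dplyr::bind_rows(lapply(names(merged), function(cls) {
    inputs <- switch(cls,
      substitution = sv_parts$substitutions,
      short_deletion = dplyr::bind_rows(sv_dels$short, sr_indels$short[
        sr_indels$short$class == "deletion", ]),
      short_insertion = dplyr::bind_rows(sv_ins$short, sr_indels$short[
        sr_indels$short$class == "insertion", ]),
      long_deletion = dplyr::bind_rows(sr_indels$long[
        sr_indels$long$class == "deletion", ],
        rp_indels$long[rp_indels$long$class == "deletion", ], rd_dels),
      long_insertion = dplyr::bind_rows(sr_indels$long[
        sr_indels$long$class == "insertion", ],
        rp_indels$long[rp_indels$long$class == "insertion", ]),
      duplication = dplyr::bind_rows(sr_class("duplication"),
                                     pick(rd_calls, "duplication")),
      inversion = dplyr::bind_rows(sr_class("inversion"), rp_class("inversion")),
      intra_translocation = rp_class("intra_translocation"),
      inter_translocation = dplyr::bind_rows(sr_class("inter_translocation"),
                                             rp_class("inter_translocation")),
      homozygous_deletion = sv_parts$homdels
    )
    out <- summarize_contributions(merged[[cls]], inputs)
    if (nrow(out) > 0) out$class <- cls
    out
  }))

  # ---- database matching -----------------------------------------------
  dbsnp <- read_database_vcf(paths[["dbsnp"]], db = "dbsnp")
  clinvar <- filter_clinical_records(read_database_vcf(paths[["clinvar"]], db = "clinvar"))
  dgv <- read_sv_database_table(paths[["dgv"]], db = "dgv")
  dbvar <- read_sv_database_table(paths[["dbvar"]], db = "dbvar")

  short_loci <- function(m, cls) {
    out <- m
    out$class <- cls
    out
  }
  sub_loci <- sv_parts$substitutions[, c("class", "chrom", "start", "end", "alt",
                                         "genotype", "zygosity")]
  db_results <- list(
    substitution = match_short_variants(sub_loci, dbsnp),
    short_deletion = match_short_variants(
      short_loci(merged$short_deletion, "deletion"), dbsnp),
    short_insertion = match_short_variants(
      short_loci(merged$short_insertion, "insertion"), dbsnp),
    long_deletion = match_long_population(
      short_loci(merged$long_deletion, "deletion"), dgv),
    long_insertion = match_long_population(
      short_loci(merged$long_insertion, "insertion"), dgv),
    duplication = match_long_population(merged$duplication, dgv)
  )
  match_summary <- db_match_summary(db_results)

  clin_short <- dplyr::bind_rows(
    sub_loci[, c("class", "chrom", "start", "end", "alt")],
    short_loci(merged$short_deletion, "deletion")[, c("class", "chrom", "start", "end")],
    short_loci(merged$short_insertion, "insertion")[, c("class", "chrom", "start", "end")]
  )
  clin_matches <- match_clinical_short(clin_short, clinvar)
  pathogenic_short <- clin_matches[
    clin_matches$matched &
      clin_matches$match_record %in% clinvar$record_id[clinvar$clin_sig %in% "Pathogenic"], ,
    drop = FALSE]

  path_long <- dplyr::bind_rows(
    short_loci(merged$long_deletion, "deletion")[, c("class", "chrom", "start", "end")],
    merged$duplication[, c("class", "chrom", "start", "end")]
  )
  pathogenic_long <- match_pathogenic_long(path_long, dbvar)

  array <- read_array_genotypes(paths[["array"]])
  array_cmp <- compare_array_genotypes(sub_loci, array,
                                       tibble(rsid = dbsnp$rsid, ref = dbsnp$ref))

  # ---- damaged genes + enrichment --------------------------------------
  ann <- read_annotations(paths[["annotations"]], paths[["exac_maf"]])
  exons <- read_bed_intervals(paths[["exons"]])
  names(exons)[names(exons) == "name"] <- "gene"
  genes_high <- select_rare_high_impact(ann)
  genes_homdel <- genes_under_homdel(merged$homozygous_deletion, exons)
  damaged <- union_damaged_genes(genes_high, genes_homdel)
  gene_sets <- read_gmt(paths[["gmt"]])
  enrichment <- enrich_gene_sets(damaged, gene_sets,
                                 N = bundle$config$db$n_genes)

  report <- structure(list(
    config = bundle$config, paths = paths,
    counts = counts,
    removed = if (length(removed_log) > 0) dplyr::bind_rows(removed_log) else
      tibble(call_id = character(), reason = character(), stage = character()),
    merged = merged,
    contributions = contributions,
    summary_stats = variant_summary_stats(sv_calls),
    cn_histogram = cn_genome_fraction_histogram(profile),
    modal_cn = modal_copy_number(profile),
    cn_segments = segments,
    db_results = db_results,
    db_match_summary = match_summary,
    clinvar_pathogenic = pathogenic_short,
    dbvar_pathogenic = pathogenic_long,
    array_comparison = array_cmp[c("agreement", "n_dropped_unresolved",
                                   "n_dropped_hom_ref")],
    damaged_genes = damaged,
    enrichment = enrichment,
    manifest = manifest,
    checksums = tools::md5sum(unname(paths))
  ), class = "tetramerge_report")
  report
}

#' @export
print.tetramerge_report <- function(x, ...) {
  cat("<tetramerge_report>\n")
  cat(sprintf("  seed %d | modal CN %d | %d merged classes\n",
              x$config$seed, x$modal_cn, length(x$merged)))
  cat("  merged loci:", paste(sprintf("%s=%d", names(x$counts$merged),
                                      x$counts$merged), collapse = ", "), "\n")
  ss <- x$summary_stats
  cat(sprintf("  hom/het = %.3f, Ts/Tv = %.2f\n",
              ss$hom_het_ratio, ss$ts_tv_ratio))
  cat(sprintf("  damaged genes: %d | top enriched set: %s (p = %.3g)\n",
              length(x$damaged_genes),
              x$enrichment$set[1], x$enrichment$p[1]))
  invisible(x)
}
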