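#' @importFrom utils write.table read.delim
NULL

write_vcf_file <- function(rows, path, contigs, info_lines = character(0),
                           with_genotypes = TRUE, info = NULL, ids = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    info_lines,
    if (with_genotypes) "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (with_genotypes) c("FORMAT", "sample")), collapse = "\t")
  )
  body <- character(0)
  if (nrow(rows) > 0) {
    ord <- order(rows$chrom, rows$pos)
    rows <- rows[ord, ]
    if (!is.null(info)) info <- info[ord]
    if (!is.null(ids)) ids <- ids[ord]
    body <- paste(
      rows$chrom, format(rows$pos, scientific = FALSE, trim = TRUE),
      if (is.null(ids)) rows$id else ids,
      rows$ref, rows$alt,
      if ("qual" %in% names(rows)) rows$qual else ".",
      "PASS",
      if (is.null(info)) "." else info,
      sep = "\t"
    )
    if (with_genotypes) body <- paste(body, "GT", rows$gt, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a caller call-set bundle to disk
#'
#' Writes the small-variant VCF (ploidy-4 genotypes), the split-read and
#' read-pair caller tables, the read-depth CNV table and bedGraph depth
#' track, and the JSON-lines truth manifest.
#'
#' @param callsets Result of [emit_caller_callsets()].
#' @param dir Output directory (created if missing).
#' @param config The [simulation_config()] (for contig headers).
#' @return Named character vector of the written paths.
#' @export
write_caller_files <- function(callsets, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    small_variant = file.path(dir, "small_variant.vcf"),
    split_read = file.path(dir, "split_read_calls.tsv"),
    read_pair = file.path(dir, "read_pair_calls.tsv"),
    read_depth_cnv = file.path(dir, "read_depth_cnv.tsv"),
    depth_track = file.path(dir, "depth_track.bedgraph"),
    manifest = file.path(dir, "truth_manifest.jsonl")
  )
  sv <- callsets$small_variant
  write_vcf_file(sv, paths["small_variant"], config$chrom_lengths,
                 ids = sv$call_id)
  write_tsv_file(callsets$split_read, paths["split_read"])
  write_tsv_file(callsets$read_pair, paths["read_pair"])
  write_tsv_file(callsets$read_depth_cnv, paths["read_depth_cnv"])
  dt <- callsets$depth_track
  writeLines(paste(dt$chrom, format(dt$start, scientific = FALSE, trim = TRUE),
                   format(dt$end, scientific = FALSE, trim = TRUE),
                   formatC(dt$depth, format = "f", digits = 4), sep = "\t"),
             paths["depth_track"])
  writeLines(vapply(seq_len(nrow(callsets$manifest)), function(i) {
    jsonlite::toJSON(as.list(callsets$manifest[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1)), paths["manifest"])
  paths
}

#' Read a JSON-lines truth manifest
#'
#' @param path Path to `truth_manifest.jsonl`.
#' @return Tibble with one row per emitted call.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dplyr::bind_rows(lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as_tibble(x)
  }))
}

#' Read a BED file of named intervals
#'
#' @param path BED path (0-based half-open on disk, kept that way).
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  nm <- tryCatch(gr$name, error = function(e) NULL)
  if (!is.null(nm)) out$name <- nm
  out
}

write_bed_intervals <- function(df, path, name = NULL, score = NULL) {
  n <- nrow(df)
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = if (!is.null(name)) name else sprintf("feature_%d", seq_len(n)),
    score = if (!is.null(score)) score else 0
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

required_columns <- list(
  split_read = c("call_id", "chrom", "start", "end", "type", "length",
                 "supporting_reads", "summed_mapq"),
  read_pair = c("call_id", "chrom", "pos1", "chrom2", "pos2", "type", "size",
                "confidence", "supporting_pairs"),
  read_depth = c("call_id", "chrom", "start", "end", "type", "cn",
                 "normalized_depth", "p_val1", "p_val2", "q0")
)

check_dialect_table <- function(df, path, dialect, numeric_cols) {
  req <- required_columns[[dialect]]
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s for dialect '%s'",
                 path, paste(missing, collapse = ", "), dialect))
  }
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("%s: malformed record at line %d, field '%s': '%s'",
                   path, bad[1] + 1L, col, df[[col]][bad[1]]))
    }
    df[[col]] <- vals
  }
  df
}

#' Parse a caller output file into the unified call model
#'
#' Supported dialects: `"small_variant"` (VCF 4.x with ploidy-4 GT),
#' `"split_read"`, `"read_pair"` and `"read_depth"` (tab-separated caller
#' tables; 1-based inclusive coordinates on disk). All coordinates are
#' converted to 0-based half-open intervals; insertions become point
#' intervals at their anchor with `length` holding the inserted length;
#' translocation breakpoint pairs land in (`chrom`, `start`) and
#' (`chrom2`, `pos2`). The split-read mean mapping score is derived as
#' summed score / supporting reads.
#'
#' @param path File path.
#' @param dialect One of the four dialect names.
#' @return A unified call tibble (see [empty_calls()] for columns).
#' @export
parse_callset <- function(path, dialect) {
  if (!file.exists(path)) stop(sprintf("call-set file not found: %s", path))
  switch(dialect,
    small_variant = parse_small_variant_vcf(path),
    split_read = parse_split_read_table(path),
    read_pair = parse_read_pair_table(path),
    read_depth = parse_read_depth_table(path),
    stop(sprintf("unknown caller dialect '%s'", dialect))
  )
}

parse_small_variant_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  n <- nrow(vcf)
  if (n == 0L) return(empty_calls())
  gr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(gr) # 1-based POS
  chrom <- as.character(GenomicRanges::seqnames(gr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt_list) != 1L)) {
    stop(sprintf("%s: multi-allelic records must be decomposed before parsing", path))
  }
  alt <- as.character(unlist(alt_list))
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1])
  ids <- names(gr)
  nref <- nchar(ref)
  nalt <- nchar(alt)
  class <- ifelse(nref == 1 & nalt == 1, "substitution",
                  ifelse(nref > nalt, "deletion", "insertion"))
  start <- ifelse(class == "substitution", pos - 1, pos)
  end <- ifelse(class == "substitution", pos,
                ifelse(class == "deletion", pos + (nref - nalt), pos + 1))
  len <- ifelse(class == "substitution", 1, abs(nref - nalt))
  as_calls(tibble(
    call_id = ids, caller = "small_variant", class = class,
    chrom = chrom, start = as.double(start), end = as.double(end),
    length = as.double(len), ref = ref, alt = alt, genotype = gt,
    zygosity = gt_zygosity(gt)
  ))
}

parse_split_read_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (nrow(df) == 0L) return(empty_calls())
  df <- check_dialect_table(df, path, "split_read",
                            c("start", "end", "length", "supporting_reads",
                              "summed_mapq", "pos2"))
  class_map <- c(DEL = "deletion", INS = "insertion", TD = "duplication",
                 INV = "inversion", CTX = "inter_translocation")
  unknown <- setdiff(unique(df$type), names(class_map))
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown split-read call type '%s'", path, unknown[1]))
  }
  class <- unname(class_map[df$type])
  is_ins <- class == "insertion"
  is_ctx <- class == "inter_translocation"
  as_calls(tibble(
    call_id = df$call_id, caller = "split_read", class = class,
    chrom = df$chrom,
    start = df$start - 1,
    end = ifelse(is_ins | is_ctx, df$start, df$end),
    length = df$length,
    chrom2 = ifelse(is_ctx, df$chrom2, NA_character_),
    pos2 = ifelse(is_ctx, df$pos2 - 1, NA_real_),
    supporting_reads = df$supporting_reads,
    summed_mapq = df$summed_mapq,
    mean_mapq = df$summed_mapq / df$supporting_reads
  ))
}

parse_read_pair_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (nrow(df) == 0L) return(empty_calls())
  df <- check_dialect_table(df, path, "read_pair",
                            c("pos1", "pos2", "size", "confidence",
                              "supporting_pairs", "bp_distance"))
  class_map <- c(DEL = "deletion", INS = "insertion", INV = "inversion",
                 ITX = "intra_translocation", CTX = "inter_translocation")
  unknown <- setdiff(unique(df$type), names(class_map))
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown read-pair call type '%s'", path, unknown[1]))
  }
  class <- unname(class_map[df$type])
  is_ins <- class == "insertion"
  is_trans <- class %in% c("intra_translocation", "inter_translocation")
  as_calls(tibble(
    call_id = df$call_id, caller = "read_pair", class = class,
    chrom = df$chrom,
    start = df$pos1 - 1,
    end = ifelse(is_ins, df$pos1, ifelse(is_trans, df$pos1, df$pos2)),
    length = ifelse(is_trans, NA_real_, df$size),
    chrom2 = ifelse(is_trans, df$chrom2, NA_character_),
    pos2 = ifelse(is_trans, df$pos2 - 1, NA_real_),
    confidence = df$confidence,
    supporting_pairs = df$supporting_pairs,
    bp_distance = df$bp_distance
  ))
}

parse_read_depth_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (nrow(df) == 0L) return(empty_calls())
  df <- check_dialect_table(df, path, "read_depth",
                            c("start", "end", "cn", "normalized_depth",
                              "p_val1", "p_val2", "q0"))
  class <- ifelse(df$type == "duplication", "duplication", "deletion")
  as_calls(tibble(
    call_id = df$call_id, caller = "read_depth", class = class,
    chrom = df$chrom,
    start = df$start - 1,
    end = df$end,
    length = df$end - df$start + 1,
    cn = df$cn,
    pval1 = df$p_val1, pval2 = df$p_val2, q0 = df$q0
  ))
}
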