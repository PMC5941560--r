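#' Convert VCF-style indel records to BED-style intervals
#'
#' Deletions map to the span of deleted bases (the REF span minus the
#' anchor base); insertions map to a point interval at the anchor.
#' Records whose length is `max_len` or more are excluded from
#' short-variant matching (returned with `NA` coordinates), as are
#' symbolic alleles.
#'
#' @param pos 1-based VCF POS.
#' @param ref,alt REF and ALT allele strings (biallelic; decompose
#'   multi-allelic records first).
#' @param max_len Exclusive length bound for short-variant conversion
#'   (default 100 bp).
#' @return Tibble with `class` (`"substitution"`, `"deletion"`,
#'   `"insertion"` or `NA`), `start`, `end` (0-based half-open) and
#'   `length`; excluded records have `NA` coordinates.
#' @export
vcf_indel_to_interval <- function(pos, ref, alt, max_len = 100) {
  symbolic <- grepl("[][<>]", alt) | grepl("[][<>]", ref)
  nref <- nchar(ref)
  nalt <- nchar(alt)
  class <- ifelse(symbolic, NA_character_,
                  ifelse(nref == 1 & nalt == 1, "substitution",
                         ifelse(nref > nalt, "deletion", "insertion")))
  len <- ifelse(class == "substitution", 1, abs(nref - nalt))
  too_long <- !is.na(class) & class != "substitution" & len >= max_len
  class[too_long] <- NA_character_
  start <- ifelse(class == "substitution", pos - 1,
                  ifelse(class == "deletion", pos, pos))
  end <- ifelse(class == "substitution", pos,
                ifelse(class == "deletion", pos + (nref - nalt), pos + 1))
  start[is.na(class)] <- NA_real_
  end[is.na(class)] <- NA_real_
  tibble(class = class, start = as.double(start), end = as.double(end),
         length = ifelse(is.na(class), NA_real_, as.double(len)))
}

match_first_record <- function(variants, records, pred) {
  matched <- logical(nrow(variants))
  match_record <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    hits <- which(pred(i))
    if (length(hits) > 0L) {
      matched[i] <- TRUE
      match_record[i] <- records$record_id[hits[1]]
    }
  }
  variants$matched <- matched
  variants$match_record <- match_record
  variants
}

#' Match short variants against a dbSNP-style database
#'
#' Substitutions match on identical locus *and* identical alternate
#' allele (position alone is not enough). Short insertions and deletions
#' match any database indel record sharing at least one base with the
#' variant locus.
#'
#' @param variants Tibble of short variant loci: `class`, `chrom`,
#'   `start`, `end`, and `alt` for substitutions.
#' @param records Database record tibble (see [read_database_vcf()]).
#' @return `variants` with logical `matched` and `match_record` columns.
#' @export
match_short_variants <- function(variants, records) {
  subs <- records$class %in% "substitution"
  indel <- records$class %in% c("deletion", "insertion")
  match_first_record(variants, records, function(i) {
    if (variants$class[i] == "substitution") {
      subs & records$chrom == variants$chrom[i] &
        records$start == variants$start[i] &
        records$alt == variants$alt[i]
    } else {
      indel & records$chrom == variants$chrom[i] &
        overlap_bp(variants$start[i], variants$end[i],
                   records$start, records$end) >= 1
    }
  })
}

#' Filter clinical database records before matching
#'
#' Records without assertion criteria (zero-star review status) are
#' removed unless submitted by OMIM, whose submissions derive from
#' literature curation; records flagged as common variants are removed
#' regardless.
#'
#' @param records Clinical database record tibble with logical
#'   `assertion_criteria` and `common` columns and a `submitter` column.
#' @return Retained records.
#' @export
filter_clinical_records <- function(records) {
  keep <- (records$assertion_criteria | toupper(records$submitter) == "OMIM") &
    !records$common
  records[keep & !is.na(keep), , drop = FALSE]
}

#' Match short variants against filtered clinical records
#'
#' Substitutions require locus and allele identity; insertions and
#' deletions require 25% reciprocal overlap (inclusive).
#'
#' @inheritParams match_short_variants
#' @param f Reciprocal overlap fraction (default 0.25).
#' @return `variants` with `matched` and `match_record` columns.
#' @export
match_clinical_short <- function(variants, records, f = 0.25) {
  subs <- records$class %in% "substitution"
  indel <- records$class %in% c("deletion", "insertion")
  match_first_record(variants, records, function(i) {
    if (variants$class[i] == "substitution") {
      subs & records$chrom == variants$chrom[i] &
        records$start == variants$start[i] &
        records$alt == variants$alt[i]
    } else {
      indel & reciprocal_match(variants$start[i], variants$end[i],
                               records$start, records$end, f = f,
                               strict = FALSE,
                               chrom1 = variants$chrom[i],
                               chrom2 = records$chrom)
    }
  })
}

#' Match long variants against a population structural-variant database
#'
#' Duplications, long insertions and long deletions match same-class
#' records at strictly greater than 25% reciprocal overlap.
#'
#' @param variants Long variant loci (`class`, `chrom`, `start`, `end`).
#' @param records DGV-style record tibble.
#' @param f Reciprocal fraction, exceeded strictly (default 0.25).
#' @return `variants` with `matched` and `match_record` columns.
#' @export
match_long_population <- function(variants, records, f = 0.25) {
  match_first_record(variants, records, function(i) {
    records$class == variants$class[i] &
      reciprocal_match(variants$start[i], variants$end[i],
                       records$start, records$end, f = f, strict = TRUE,
                       chrom1 = variants$chrom[i], chrom2 = records$chrom)
  })
}

#' Annotate long variants as pathogenic by database match
#'
#' A long variant is annotated pathogenic when it has strictly greater
#' than 90% reciprocal overlap with a pathogenic record.
#'
#' @param variants Long variant loci.
#' @param records dbVar-style records; rows whose `clin_sig` is not
#'   `"Pathogenic"` are ignored.
#' @param f Reciprocal fraction, exceeded strictly (default 0.90).
#' @return `variants` with `matched` and `match_record` columns.
#' @export
match_pathogenic_long <- function(variants, records, f = 0.90) {
  if ("clin_sig" %in% names(records)) {
    records <- records[records$clin_sig %in% "Pathogenic", , drop = FALSE]
  }
  match_first_record(variants, records, function(i) {
    records$class == variants$class[i] &
      reciprocal_match(variants$start[i], variants$end[i],
                       records$start, records$end, f = f, strict = TRUE,
                       chrom1 = variants$chrom[i], chrom2 = records$chrom)
  })
}

#' Compare tetraploid substitution genotypes with array genotypes
#'
#' Array records are first screened: genotypes whose rsID cannot be
#' resolved to a reference allele are dropped, as are records homozygous
#' for the reference allele. Agreement is then computed on loci shared
#' with the substitution set as zygosity concordance: a tetraploid
#' all-alternate genotype corresponds to an array homozygous genotype;
#' any mixed tetraploid genotype corresponds to an array heterozygote.
#'
#' @param substitutions Substitution calls with `chrom`, `start` (0-based
#'   locus) and `genotype` (or `zygosity`).
#' @param array_genotypes Tibble: `rsid`, `chrom`, `pos` (1-based),
#'   `allele1`, `allele2`.
#' @param ref_alleles Tibble mapping `rsid` to `ref` allele.
#' @return List: `screened` (surviving array records with an
#'   `array_zygosity` column), `shared` (joined loci with both zygosity
#'   calls and logical `agree`), `agreement` (fraction of shared loci in
#'   agreement), `n_dropped_unresolved`, `n_dropped_hom_ref`.
#' @export
compare_array_genotypes <- function(substitutions, array_genotypes, ref_alleles) {
  ar <- dplyr::left_join(array_genotypes, ref_alleles[, c("rsid", "ref")],
                         by = "rsid")
  unresolved <- is.na(ar$ref)
  hom_ref <- !unresolved & ar$allele1 == ar$ref & ar$allele2 == ar$ref
  screened <- ar[!unresolved & !hom_ref, , drop = FALSE]
  screened$array_zygosity <- ifelse(screened$allele1 == screened$allele2, "hom", "het")
  subs <- substitutions
  if (!"zygosity" %in% names(subs) || all(is.na(subs$zygosity))) {
    subs$zygosity <- gt_zygosity(subs$genotype)
  }
  subs$pos <- subs$start + 1
  shared <- dplyr::inner_join(
    screened[, c("rsid", "chrom", "pos", "array_zygosity")],
    subs[, c("chrom", "pos", "zygosity")],
    by = c("chrom", "pos")
  )
  agree <- shared$array_zygosity == shared$zygosity
  shared$agree <- agree
  list(
    screened = screened, shared = shared,
    agreement = if (nrow(shared) > 0) mean(agree) else NA_real_,
    n_dropped_unresolved = sum(unresolved),
    n_dropped_hom_ref = sum(hom_ref)
  )
}

#' Database match-rate summary per variant class
#'
#' @param results Named list (one element per variant class) of tibbles
#'   carrying a logical `matched` column, as returned by the matching
#'   functions.
#' @return Tibble: `class`, `n_total`, `n_matched`, `pct`.
#' @export
db_match_summary <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    tibble(class = nm, n_total = nrow(r), n_matched = sum(r$matched),
           pct = if (nrow(r) > 0) 100 * mean(r$matched) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Read a database VCF into the record model
#'
#' Reads dbSNP- or ClinVar-style VCFs. Indels are converted to intervals
#' with [vcf_indel_to_interval()] (records of 100 bp or longer are
#' dropped from short-variant matching). Clinical INFO fields, when
#' declared in the header, populate `clin_sig` (`CLNSIG`),
#' `assertion_criteria` (`CRITERIA` flag), `submitter` (`SUBMITTER`) and
#' `common` (`COMMON` flag).
#'
#' @param path VCF path.
#' @param db Database label stored in the `db` column.
#' @param max_len Length bound passed to [vcf_indel_to_interval()].
#' @return DatabaseRecord tibble.
#' @export
read_database_vcf <- function(path, db = "dbsnp", max_len = 100) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  gr <- SummarizedExperiment::rowRanges(vcf)
  n <- nrow(vcf)
  pos <- GenomicRanges::start(gr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt_list) != 1L)) {
    stop(sprintf("%s: multi-allelic records must be decomposed first", path))
  }
  alt <- as.character(unlist(alt_list))
  iv <- vcf_indel_to_interval(pos, ref, alt, max_len = max_len)
  info <- VariantAnnotation::info(vcf)
  get_info <- function(key, default) {
    if (key %in% names(info)) info[[key]] else rep(default, n)
  }
  out <- tibble(
    db = db,
    record_id = names(gr),
    rsid = names(gr),
    class = iv$class,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = iv$start, end = iv$end, length = iv$length,
    ref = ref, alt = alt,
    clin_sig = as.character(get_info("CLNSIG", NA_character_)),
    assertion_criteria = as.logical(get_info("CRITERIA", NA)),
    submitter = as.character(get_info("SUBMITTER", NA_character_)),
    common = as.logical(get_info("COMMON", NA)),
    af = as.numeric(get_info("AF", NA_real_))
  )
  out[!is.na(out$class), , drop = FALSE]
}

#' Read a DGV/dbVar-style structural-variant table
#'
#' Tab-separated with columns `record_id`, `chrom`, `start`, `end`
#' (1-based inclusive), `type` (`deletion`, `duplication`, `insertion`)
#' and, for dbVar-style files, `clin_sig`.
#'
#' @param path File path.
#' @param db Database label.
#' @return DatabaseRecord tibble (0-based half-open intervals; insertion
#'   records become point intervals).
#' @export
read_sv_database_table <- function(path, db = "dgv") {
  df <- read.delim(path, colClasses = "character")
  if (nrow(df) == 0L) {
    return(tibble(db = character(), record_id = character(), class = character(),
                  chrom = character(), start = double(), end = double(),
                  clin_sig = character()))
  }
  for (col in c("start", "end")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      stop(sprintf("%s: malformed record at line %d, field '%s'", path,
                   bad[1] + 1L, col))
    }
    df[[col]] <- vals
  }
  type_map <- c(deletion = "deletion", duplication = "duplication",
                insertion = "insertion", long_deletion = "deletion")
  class <- unname(type_map[df$type])
  is_ins <- class %in% "insertion"
  tibble(
    db = db, record_id = df$record_id, class = class, chrom = df$chrom,
    start = ifelse(is_ins, df$start - 1, df$start - 1),
    end = ifelse(is_ins, df$start, df$end),
    clin_sig = if ("clin_sig" %in% names(df)) df$clin_sig else NA_character_
  )
}

#' Read an array-genotype TSV
#'
#' Columns: `rsid`, `chrom`, `pos` (1-based), `allele1`, `allele2`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_array_genotypes <- function(path) {
  df <- read.delim(path, colClasses = "character")
  df$pos <- as.numeric(df$pos)
  as_tibble(df)
}

#' Read variant effect annotations (with population MAF)
#'
#' Columns: `variant_id`, `gene`, `effect` and optionally `maf`
#' (`NA` when the variant is absent from the population panel).
#'
#' @param path Annotation TSV; `maf_path` an optional two-column
#'   (`variant_id`, `maf`) table joined on `variant_id`.
#' @param maf_path Optional MAF table path.
#' @return Tibble ready for [select_rare_high_impact()].
#' @export
read_annotations <- function(path, maf_path = NULL) {
  df <- as_tibble(read.delim(path, colClasses = "character"))
  if (!is.null(maf_path)) {
    maf <- read.delim(maf_path, colClasses = "character")
    maf$maf <- as.numeric(maf$maf)
    df <- dplyr::left_join(df, as_tibble(maf), by = "variant_id")
  } else if ("maf" %in% names(df)) {
    df$maf <- as.numeric(df$maf)
  }
  df
}
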