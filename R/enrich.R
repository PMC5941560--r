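#' @importFrom stats phyper setNames p.adjust
NULL

# Effect categories counted as "high impact": all predicted to truncate or
# abolish the protein product.
HIGH_IMPACT_EFFECTS <- c(
  "stop_gained", "stop_lost", "start_lost", "splice_acceptor_variant",
  "splice_donor_variant", "exon_loss_variant", "frameshift_variant"
)

#' Genes carrying a rare, high-impact small variant
#'
#' Keeps variants whose predicted effect is in the high-impact category
#' set (stop gained/lost, start lost, splice acceptor/donor, exon loss,
#' frameshift) and whose population minor allele frequency is strictly
#' below `maf_cutoff`. Variants absent from the population panel carry no
#' frequency; absence from a panel of tens of thousands of samples is
#' itself evidence of rarity, so missing MAF counts as rare.
#'
#' @param annotations Tibble with columns `variant_id`, `gene`, `effect`
#'   and `maf` (numeric, `NA` when the variant has no population record).
#' @param maf_cutoff Exclusive rarity bound on MAF (default 0.001).
#' @return Character vector of distinct, uppercased gene symbols.
#' @export
select_rare_high_impact <- function(annotations, maf_cutoff = 0.001) {
  stopifnot(all(c("gene", "effect") %in% names(annotations)))
  maf <- if ("maf" %in% names(annotations)) annotations$maf else rep(NA_real_, nrow(annotations))
  keep <- annotations$effect %in% HIGH_IMPACT_EFFECTS &
    (is.na(maf) | maf < maf_cutoff)
  sort(unique(toupper(annotations$gene[keep])))
}

#' Genes whose coding exons fall under a homozygous deletion
#'
#' A gene is included when any of its coding exons shares at least one
#' base with a homozygous-deletion locus; intron-only hits do not count.
#'
#' @param homdel_loci Tibble of homozygous-deletion loci with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param exons Tibble of coding exons with columns `chrom`, `start`,
#'   `end`, `gene`.
#' @return Character vector of distinct, uppercased gene symbols.
#' @export
genes_under_homdel <- function(homdel_loci, exons) {
  if (nrow(exons) == 0L || nrow(homdel_loci) == 0L) return(character(0))
  hit <- overlaps_any(
    exons$chrom, exons$start, exons$end,
    homdel_loci$chrom, homdel_loci$start, homdel_loci$end
  )
  sort(unique(toupper(exons$gene[hit])))
}

#' Union of damaged-gene lists
#'
#' @param ... Character vectors of gene symbols.
#' @return Deduplicated, uppercase-normalized union.
#' @export
union_damaged_genes <- function(...) {
  sort(unique(toupper(unlist(list(...), use.names = FALSE))))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` members of a `K`-gene set when sampling `n` genes without
#' replacement from a universe of `N`. The tail is inclusive of `k`;
#' `stats::phyper` evaluates it in log space internally, so small tails
#' are computed stably.
#'
#' @param k Observed overlap count.
#' @param K Gene-set size.
#' @param n Damaged-set (draw) size.
#' @param N Background universe size.
#' @return Tail probability in (0, 1].
#' @examples
#' hypergeom_tail(51, 1009, 781, 26802) # ~1.1e-4
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0 | N < 1)) {
    stop("impossible hypergeometric margins: need 0 <= k <= min(K, n) and K, n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of the damaged-gene set
#'
#' Tests each gene set for enrichment of damaged genes with an inclusive
#' upper-tail hypergeometric probability against a fixed background
#' universe. Sets smaller than `min_set` genes are not considered. Raw
#' p-values drive the ranking; a Benjamini-Hochberg column (`padj_bh`)
#' is attached for convenience but is not used for ordering.
#'
#' @param damaged Character vector of damaged gene symbols.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]). Membership is matched on uppercased symbols.
#' @param N Background universe size (default 26802, the number of
#'   hg19 nuclear genes).
#' @param min_set Minimum gene-set size considered (default 50).
#' @return Tibble with one row per tested set, sorted by ascending `p`:
#'   `set`, `K` (set size), `n` (damaged size), `N`, `k` (overlap),
#'   `genes` (list column of overlapping symbols), `p`, `padj_bh`.
#' @export
enrich_gene_sets <- function(damaged, gene_sets, N = 26802, min_set = 50) {
  damaged <- unique(toupper(damaged))
  if (length(damaged) == 0L) {
    warning("empty damaged gene set: all enrichment p-values are 1")
  }
  if (length(damaged) > N) {
    stop("damaged set larger than the background universe")
  }
  sets <- lapply(gene_sets, function(g) unique(toupper(g)))
  K <- vapply(sets, length, integer(1))
  keep <- K >= min_set
  sets <- sets[keep]
  K <- K[keep]
  ov <- lapply(sets, intersect, damaged)
  k <- vapply(ov, length, integer(1))
  p <- vapply(seq_along(sets), function(i) {
    hypergeom_tail(k[i], K[i], length(damaged), N)
  }, double(1))
  res <- tibble(
    set = names(sets), K = unname(K), n = length(damaged), N = N, k = unname(k),
    genes = lapply(ov, sort), p = p, padj_bh = p.adjust(p, method = "BH")
  )
  res[order(res$p, res$set), ]
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed GMT record in %s at line %d: fewer than 3 fields", path, bad[1]))
  }
  setNames(lapply(fields, function(f) f[-(1:2)]), vapply(fields, `[`, character(1), 1))
}

#' Write gene sets as GMT
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "synthetic") {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
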