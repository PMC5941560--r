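# Shared fixtures: small configs and a brute-force merge oracle kept
# deliberately independent of the package's merge implementation.

small_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    chrom_lengths = c(chr1 = 1.2e6, chr2 = 8e5),
    variant_counts = c(
      substitution = 60, short_deletion = 30, short_insertion = 20,
      long_deletion = 12, long_insertion = 8, duplication = 6,
      inversion = 6, intra_translocation = 2, inter_translocation = 1,
      homozygous_deletion = 8
    ),
    seed = seed
  )
  for (nm in names(defaults)) if (!nm %in% names(args)) args[[nm]] <- defaults[[nm]]
  do.call(simulation_config, args)
}

small_noiseless_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    jitter_sd = 0, qc_fail_rate = 0, fp_rate = 0, depth_noise_sd = 0,
    sensitivity = perfect_sensitivity()
  )
  for (nm in names(defaults)) if (!nm %in% names(args)) args[[nm]] <- defaults[[nm]]
  do.call(small_config, c(list(seed = seed), args))
}

# Minimal unified call tibble builder for hand-rolled cases.
make_calls <- function(caller, class, chrom, start, end, ...) {
  n <- max(length(start), length(chrom))
  df <- tibble::tibble(
    call_id = sprintf("%s_%03d", caller, seq_len(n)),
    caller = caller, class = class, chrom = chrom,
    start = as.double(start), end = as.double(end), ...
  )
  if (!"length" %in% names(df)) df$length <- df$end - df$start
  tetramerge:::as_calls(df)
}

# ---- brute-force oracles ---------------------------------------------

# Per-base overlap counter on explicit base sets.
overlap_bp_oracle <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, length.out = e1 - s1), seq(s2, length.out = e2 - s2)))
}

# Exhaustive-enumeration upper-tail hypergeometric: enumerate all C(N, n)
# draws is infeasible, but summing the pmf from combinatorics is exact.
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Brute-force three-stage hierarchical merge. Applies the stage logic by
# exhaustive pairwise checks: repeated pairwise clustering to a fixed
# point instead of a sweep, and explicit pairwise drop tests.
oracle_match <- function(class, a, b, f = 0.25) {
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  if (a$chrom != b$chrom) ov <- 0
  if (class %in% c("deletion", "insertion")) {
    ov >= f * (a$end - a$start) && ov >= f * (b$end - b$start)
  } else {
    ov >= f * (a$end - a$start)
  }
}

oracle_cluster <- function(df, adjacent = TRUE) {
  n <- nrow(df)
  if (n == 0) return(df)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] == cl[j]) next
      same_chrom <- df$chrom[i] == df$chrom[j]
      touch <- if (adjacent) {
        df$start[i] <= df$end[j] && df$start[j] <= df$end[i]
      } else {
        df$start[i] < df$end[j] && df$start[j] < df$end[i]
      }
      if (same_chrom && touch) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(cl), function(c0) {
    rows <- df[cl == c0, , drop = FALSE]
    tibble::tibble(
      chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end),
      ids = list(sort(unlist(rows$ids)))
    )
  })
  dplyr::bind_rows(out)
}

oracle_hierarchical_merge <- function(tier1, tier2, tier3, class, f = 0.25) {
  as_df <- function(d) {
    if (is.null(d) || nrow(d) == 0) {
      return(tibble::tibble(chrom = character(), start = double(),
                            end = double(), ids = list()))
    }
    tibble::tibble(chrom = d$chrom, start = d$start, end = d$end,
                   ids = as.list(d$call_id))
  }
  loci <- oracle_cluster(as_df(tier1))
  for (tier in list(tier2, tier3)) {
    td <- as_df(tier)
    keep <- rep(TRUE, nrow(td))
    for (i in seq_len(nrow(td))) {
      for (j in seq_len(nrow(loci))) {
        if (oracle_match(class, td[i, ], loci[j, ], f)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    loci <- oracle_cluster(dplyr::bind_rows(loci, td[keep, , drop = FALSE]))
  }
  loci[order(loci$chrom, loci$start), ]
}

random_tier <- function(n, caller, class, chrom = "chr1", max_pos = 5000) {
  start <- sample(max_pos, n, replace = TRUE)
  width <- sample(200, n, replace = TRUE)
  make_calls(caller, class, chrom, start, start + width)
}
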