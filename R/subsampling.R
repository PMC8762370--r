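## Sub-sampling (rarefying) to even depth, at the read level (pre-ASV) or
## the count level (post-ASV), plus analytic rarefaction curves and the
## sample-retention rules applied before cross-scenario comparisons.

#' Sub-sample a count table to even depth (post-ASV)
#'
#' Each sample with at least `depth` reads is replaced by a multivariate
#' hypergeometric draw (sampling reads without replacement) summing exactly
#' to `depth`; shallower samples are dropped and recorded in the
#' `"dropped_samples"` attribute. Draws come from per-sample streams keyed
#' by sample identifier, so results do not depend on sample order.
#'
#' @param table a `count_table`.
#' @param depth target depth (positive integer).
#' @param seed integer seed.
#' @return the sub-sampled `count_table` (empty ASV columns dropped), with
#'   attribute `dropped_samples` naming removed samples.
#' @export
subsample_counts <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  abort_if(depth < 1, "`depth` must be at least 1")
  depths <- sample_depths(table)
  keep <- names(depths)[depths >= depth]
  dropped <- setdiff(names(depths), keep)
  abort_if(length(keep) == 0,
           "no sample has at least ", depth, " reads; table would be empty")
  m <- unclass(table)[keep, , drop = FALSE]
  out <- matrix(0L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  for (s in keep) {
    row <- m[s, ]
    pos <- which(row > 0)
    idx <- rep.int(pos, row[pos])
    take <- with_seed(derive_seed(seed, "subsample", s),
                      sample(idx, depth))
    tab <- tabulate(take, nbins = ncol(m))
    out[s, ] <- as.integer(tab)
  }
  res <- drop_empty_asvs(structure_count_table(out))
  attr(res, "dropped_samples") <- dropped
  res
}

#' Sub-sample raw reads to even depth (pre-ASV)
#'
#' Uniform without-replacement sample of exactly `depth` reads per sample;
#' samples with fewer reads are dropped and logged. Tabulating the result
#' follows the same multivariate hypergeometric law as [subsample_counts()]
#' applied to the tabulated reads.
#'
#' @param reads a `read_table`.
#' @param depth target depth (positive integer).
#' @param seed integer seed.
#' @return the sub-sampled `read_table` with attribute `dropped_samples`.
#' @export
subsample_reads <- function(reads, depth, seed = 1L) {
  stopifnot(inherits(reads, "read_table"))
  abort_if(depth < 1, "`depth` must be at least 1")
  keep <- names(reads)[lengths(reads) >= depth]
  dropped <- setdiff(names(reads), keep)
  abort_if(length(keep) == 0,
           "no sample has at least ", depth, " reads; table would be empty")
  out <- lapply(keep, function(s) {
    with_seed(derive_seed(seed, "subsample", s),
              reads[[s]][sample.int(length(reads[[s]]), depth)])
  })
  names(out) <- keep
  res <- read_table(out)
  attr(res, "dropped_samples") <- dropped
  res
}

#' Expected richness under sub-sampling (analytic rarefaction)
#'
#' Hurlbert's expectation of the number of ASVs observed in a
#' without-replacement sub-sample of size `m` from a sample with per-ASV
#' counts `counts_row`:
#' `E[S_m] = sum_i (1 - choose(N - N_i, m) / choose(N, m))`,
#' evaluated in log space for numerical stability.
#'
#' @param counts_row non-negative integer vector of per-ASV counts.
#' @param m sub-sample size(s), each between 1 and `sum(counts_row)`.
#' @return numeric vector of expected richness values, one per `m`.
#' @export
#' @examples
#' expected_richness(c(2, 1), 2)  # 1 + 2/3
expected_richness <- function(counts_row, m) {
  abort_if(!is_count_vector(counts_row), "counts must be non-negative integers")
  n <- sum(counts_row)
  abort_if(n < 1, "empty sample")
  abort_if(any(m < 1 | m > n), "`m` must lie in [1, ", n, "]")
  ni <- counts_row[counts_row > 0]
  vapply(m, function(mm) {
    # lchoose(k, mm) = -Inf when k < mm, so absent-in-subsample probability
    # underflows cleanly to 0 for ASVs with too few complement reads
    p_absent <- exp(lchoose(n - ni, mm) - lchoose(n, mm))
    sum(1 - p_absent)
  }, numeric(1))
}

#' Analytic rarefaction curves for every sample
#'
#' Evaluates [expected_richness()] on an evenly spaced integer grid from 1
#' to each sample's depth. A curve that flattens (plateaus) before full
#' depth suggests the sample covers its source community; a curve still
#' climbing at full depth does not.
#'
#' @param table a `count_table`.
#' @param grid_points number of depths per sample (at least 2).
#' @return a data frame with columns `sample_id`, `depth`,
#'   `expected_richness`, class `rarefaction_curves`.
#' @export
rarefaction_curve <- function(table, grid_points = 20L) {
  stopifnot(inherits(table, "count_table"))
  abort_if(grid_points < 2, "`grid_points` must be at least 2")
  m <- unclass(table)
  pieces <- lapply(rownames(m), function(s) {
    n <- sum(m[s, ])
    grid <- unique(pmax(1L, as.integer(round(
      seq(1, n, length.out = grid_points)))))
    data.frame(sample_id = s, depth = grid,
               expected_richness = expected_richness(m[s, ], grid),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("rarefaction_curves", class(out))
  out
}

#' Terminal slope of the analytic rarefaction curve
#'
#' Average slope of expected richness over the last decile of depth,
#' `(E[S_N] - E[S_{0.9 N}]) / (0.1 N)` per sample. Small terminal slopes
#' indicate a plateau; large ones a curve still climbing at full depth.
#'
#' @param table a `count_table`.
#' @param decile fraction of depth forming the terminal window.
#' @return named numeric vector of per-sample slopes.
#' @export
terminal_slope <- function(table, decile = 0.1) {
  stopifnot(inherits(table, "count_table"))
  abort_if(decile <= 0 || decile >= 1, "`decile` must be in (0, 1)")
  m <- unclass(table)
  slopes <- vapply(rownames(m), function(s) {
    n <- sum(m[s, ])
    lo <- max(1L, as.integer(round((1 - decile) * n)))
    if (lo >= n) return(0)
    vals <- expected_richness(m[s, ], c(lo, n))
    (vals[2] - vals[1]) / (n - lo)
  }, numeric(1))
  slopes
}

#' Cross-scenario sample retention
#'
#' A sample is retained iff it has at least `min_full` reads in the full
#' (not sub-sampled) table, is present in every scenario table, and has at
#' least `min_sub` reads in each of them. Samples lost to sub-sampling in
#' any single scenario are excluded everywhere, so scenario summaries are
#' computed on one shared sample set.
#'
#' @param full_table the full-data `count_table`.
#' @param scenario_tables list of per-scenario `count_table`s.
#' @param min_full minimum full-data depth (default 10000).
#' @param min_sub minimum per-scenario depth (default 2000).
#' @return character vector of retained sample identifiers.
#' @export
retention_filter <- function(full_table, scenario_tables,
                             min_full = 10000L, min_sub = 2000L) {
  stopifnot(inherits(full_table, "count_table"))
  full_depths <- sample_depths(full_table)
  retained <- names(full_depths)[full_depths >= min_full]
  for (tab in scenario_tables) {
    stopifnot(inherits(tab, "count_table"))
    d <- sample_depths(tab)
    retained <- retained[retained %in% names(d)[d >= min_sub]]
  }
  retained
}
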