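## Singleton-handling abstraction of the denoising pipelines. Real
## denoisers (DADA2, deblur) discard low-support sequences through an error
## model; the mechanism that matters for richness is reducible to a count
## threshold applied either per sample (sample-wise / unpooled processing)
## or on pooled totals across samples. Prior sequence lists exempt matching
## ASVs from the threshold.

#' Specification of a denoising filter
#'
#' @param mode `"samplewise"` (each sample filtered independently, the
#'   DADA2/deblur default) or `"pooled"` (evidence shared across samples).
#' @param min_count sample-wise retention threshold: a cell survives iff its
#'   count is at least `min_count`. The default 2 discards singletons;
#'   `min_count = 1` is the keep-singletons (deblur min-size 1) setting.
#' @param min_total pooled retention threshold on ASV column totals.
#' @param prior optional character vector of ASV identifiers exempt from
#'   the threshold (the denoiser's prior sequence list).
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(mode = c("samplewise", "pooled"),
                        min_count = 2L, min_total = 2L, prior = NULL) {
  mode <- match.arg(mode)
  abort_if(min_count < 1 || min_total < 1, "thresholds must be at least 1")
  if (!is.null(prior)) prior <- unique(as.character(prior))
  structure(list(mode = mode, min_count = as.integer(min_count),
                 min_total = as.integer(min_total), prior = prior),
            class = "filter_spec")
}

#' Sample-wise (unpooled) singleton filter
#'
#' Each cell is zeroed iff its count is below `min_count` and its ASV is not
#' in the prior list; all other cells are untouched. This is the abstraction
#' of independent per-sample denoising: a sequence observed once in one
#' sample and five times in another is discarded only in the first.
#'
#' @param table a `count_table`.
#' @param min_count retention threshold (default 2: singletons discarded).
#' @param prior optional ASV identifiers exempt from the threshold.
#' @return the filtered `count_table`; all-zero ASV columns are dropped.
#' @export
#' @examples
#' tab <- count_table(matrix(c(1L, 5L), 2, 1,
#'                    dimnames = list(c("s1", "s2"), "a")))
#' filter_samplewise(tab, 2)            # 'a' lost from s1, kept in s2
#' filter_samplewise(tab, 2, prior = "a")  # prior rescues the singleton
filter_samplewise <- function(table, min_count = 2L, prior = NULL) {
  stopifnot(inherits(table, "count_table"))
  abort_if(min_count < 1, "`min_count` must be at least 1")
  m <- unclass(table)
  protected <- colnames(m) %in% prior
  kill <- m < min_count & !matrix(protected, nrow(m), ncol(m), byrow = TRUE)
  m[kill] <- 0L
  out <- drop_empty_asvs(structure_count_table(m))
  attr(out, "filter_spec") <- filter_spec("samplewise", min_count = min_count,
                                          prior = prior)
  out
}

#' Pooled singleton filter
#'
#' An ASV column is dropped entirely iff its total count over all samples is
#' below `min_total` and it is not in the prior list. Retained columns are
#' unchanged in every cell, so per-sample singletons survive whenever the
#' sequence has support elsewhere -- the pooled-processing retention rule.
#'
#' @param table a `count_table`.
#' @param min_total retention threshold on column totals (default 2).
#' @param prior optional ASV identifiers exempt from the threshold.
#' @return the filtered `count_table`.
#' @export
filter_pooled <- function(table, min_total = 2L, prior = NULL) {
  stopifnot(inherits(table, "count_table"))
  abort_if(min_total < 1, "`min_total` must be at least 1")
  m <- unclass(table)
  keep <- colSums(m) >= min_total | colnames(m) %in% prior
  out <- drop_empty_asvs(structure_count_table(m[, keep, drop = FALSE]))
  attr(out, "filter_spec") <- filter_spec("pooled", min_total = min_total,
                                          prior = prior)
  out
}

#' Apply a filter specification
#'
#' Dispatches to [filter_samplewise()] or [filter_pooled()] according to the
#' spec's mode; the spec is recorded on the result for provenance.
#'
#' @param table a `count_table`.
#' @param spec a [filter_spec()].
#' @return the filtered `count_table` with the spec attached as an attribute.
#' @export
apply_filter <- function(table, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$mode,
         samplewise = filter_samplewise(table, spec$min_count, spec$prior),
         pooled = filter_pooled(table, spec$min_total, spec$prior),
         stop("unknown filter mode: ", spec$mode, call. = FALSE))
}

#' Extract a prior sequence set from a baseline table
#'
#' The ASVs retained by a baseline (no-prior, no-sub-sampling) run serve as
#' the prior list for the prior-informed scenarios.
#'
#' @param table a `count_table` (the retained baseline output).
#' @return character vector of ASV identifiers with positive total count.
#' @export
extract_prior <- function(table) {
  stopifnot(inherits(table, "count_table"))
  colnames(table)[colSums(unclass(table)) > 0]
}
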