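## FASTA-backed sequence catalogues (ASV id -> nucleotide string) and the
## run configuration object. The analysis itself only needs ASV identity;
## nucleotides exist so tables can round-trip through FASTA-keyed tools.

#' Read a sequence catalogue from FASTA
#'
#' Headers (up to the first whitespace) become ASV identifiers.
#'
#' @param path path to a FASTA file.
#' @param allow_n also accept the ambiguity symbol `N` in sequences.
#' @return named character vector mapping ASV identifier to sequence.
#' @export
read_fasta <- function(path, allow_n = FALSE) {
  abort_if(!file.exists(path), "file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  abort_if(anyDuplicated(ids) > 0, "duplicate FASTA header: ",
           ids[duplicated(ids)][1])
  seqs <- as.character(set)
  names(seqs) <- ids
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), seqs)
  abort_if(any(bad), "non-", alphabet, " symbol in sequence for: ",
           ids[bad][1])
  abort_if(any(nchar(seqs) == 0), "empty sequence in FASTA")
  seqs
}

#' Write a sequence catalogue to FASTA
#'
#' @param catalog named character vector (identifier -> sequence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalog, path) {
  abort_if(is.null(names(catalog)) || anyDuplicated(names(catalog)) > 0,
           "catalog must have unique names")
  set <- Biostrings::BStringSet(catalog)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Generate random ASV sequences for a count table
#'
#' Synthetic tables use opaque ASV identifiers; when FASTA export is wanted
#' this attaches a random nucleotide sequence (fixed length, default 250 nt,
#' the usual post-truncation amplicon length) to each identifier.
#'
#' @param asv_ids character vector of identifiers.
#' @param length sequence length in nucleotides.
#' @param seed integer seed.
#' @return named character vector usable with [write_fasta()].
#' @export
random_sequences <- function(asv_ids, length = 250L, seed = 1L) {
  abort_if(anyDuplicated(asv_ids) > 0, "duplicate ASV identifiers")
  with_seed(derive_seed(seed, "sequences"), {
    seqs <- vapply(seq_along(asv_ids), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- asv_ids
  seqs
}

#' Analysis configuration
#'
#' Bundles the knobs of a scenario-grid run. `subsample_depth = "auto"`
#' resolves to the minimum full depth among samples passing `min_full_depth`,
#' the usual rarefying-to-the-shallowest-sample rule. Samples are retained
#' only with at least `min_full_depth` reads in the full data and at least
#' `min_sub_depth` reads after sub-sampling. The `upstream` list records
#' read-processing settings (e.g. `maxEE`, `truncLen`, `trimLeft`) for
#' provenance only; nothing in this package consumes them.
#'
#' @param seed master integer seed.
#' @param subsample_depth positive integer, or `"auto"`.
#' @param min_full_depth minimum full-data depth for sample retention.
#' @param min_sub_depth minimum post-sub-sampling depth for retention.
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @param min_count sample-wise filter threshold (retain count >= min_count).
#' @param min_total pooled filter threshold on ASV column totals.
#' @param rare_threshold abundance boundary between rare and abundant ASVs
#'   for the ACE estimator.
#' @param upstream named list of provenance-only upstream settings.
#' @return an `analysis_config` object.
#' @export
analysis_config <- function(seed = 1L,
                            subsample_depth = "auto",
                            min_full_depth = 10000L,
                            min_sub_depth = 2000L,
                            correlation_method = c("spearman", "pearson"),
                            min_count = 2L,
                            min_total = 2L,
                            rare_threshold = 10L,
                            upstream = list()) {
  correlation_method <- match.arg(correlation_method)
  numeric_depth <- !identical(subsample_depth, "auto")
  if (numeric_depth) {
    abort_if(!is.numeric(subsample_depth) || subsample_depth < 1,
             "`subsample_depth` must be a positive integer or \"auto\"")
    subsample_depth <- as.integer(subsample_depth)
  }
  abort_if(min_sub_depth > min_full_depth,
           "`min_sub_depth` must not exceed `min_full_depth`")
  abort_if(numeric_depth && subsample_depth < min_sub_depth,
           "`subsample_depth` below `min_sub_depth`")
  structure(list(seed = as.integer(seed),
                 subsample_depth = subsample_depth,
                 min_full_depth = as.integer(min_full_depth),
                 min_sub_depth = as.integer(min_sub_depth),
                 correlation_method = correlation_method,
                 min_count = as.integer(min_count),
                 min_total = as.integer(min_total),
                 rare_threshold = as.integer(rare_threshold),
                 upstream = upstream),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path path to a YAML file.
#' @return [read_config()] returns an `analysis_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
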