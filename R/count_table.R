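## Core containers: the samples x ASVs count table and the per-sample read
## multiset. The count table is the central exchange object of the pipeline;
## every filter and sub-sampling operation consumes and produces one.

#' Construct a samples-by-ASVs count table
#'
#' The count table is an integer matrix with samples as rows and amplicon
#' sequence variants (ASVs) as columns. Row sums are the per-sample
#' sequencing depths. Identifiers must be unique and counts non-negative
#' integers.
#'
#' @param counts numeric matrix of non-negative integers (samples x ASVs).
#' @param sample_ids,asv_ids optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return a `count_table` object (an integer matrix subclass).
#' @export
#' @examples
#' count_table(matrix(c(1, 5, 0, 3), 2, 2,
#'                    dimnames = list(c("s1", "s2"), c("a", "b"))))
count_table <- function(counts, sample_ids = rownames(counts),
                        asv_ids = colnames(counts)) {
  abort_if(!is.matrix(counts), "`counts` must be a matrix")
  abort_if(is.null(sample_ids) || is.null(asv_ids),
           "sample and ASV identifiers are required (dimnames or arguments)")
  rownames(counts) <- as.character(sample_ids)
  colnames(counts) <- as.character(asv_ids)
  validate_count_table(structure_count_table(counts))
}

structure_count_table <- function(m) {
  abort_if(!is_count_vector(as.vector(m)),
           "counts must be non-negative integers")
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- character(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- character(ncol(m))
  class(m) <- c("count_table", class(matrix()))
  m
}

validate_count_table <- function(tab) {
  abort_if(anyDuplicated(rownames(tab)) > 0, "duplicate sample identifiers")
  abort_if(anyDuplicated(colnames(tab)) > 0, "duplicate ASV identifiers")
  tab
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d ASVs, depths %s..%s\n",
              nrow(x), ncol(x),
              if (nrow(x)) min(rowSums(x)) else NA,
              if (nrow(x)) max(rowSums(x)) else NA))
  invisible(x)
}

#' Per-sample sequencing depths
#'
#' @param table a `count_table`.
#' @return named integer vector of row sums (reads per sample).
#' @export
sample_depths <- function(table) {
  stopifnot(inherits(table, "count_table"))
  d <- rowSums(unclass(table))
  storage.mode(d) <- "integer"
  d
}

#' Drop all-zero ASV columns
#'
#' Mirrors what a real pipeline's feature table contains: an ASV with no
#' reads left after filtering is simply absent.
#'
#' @param table a `count_table`.
#' @return the table without all-zero columns.
#' @export
drop_empty_asvs <- function(table) {
  stopifnot(inherits(table, "count_table"))
  keep <- colSums(unclass(table)) > 0
  structure_count_table(unclass(table)[, keep, drop = FALSE])
}

#' Restrict a count table to a set of ASV identifiers
#'
#' @param table a `count_table`.
#' @param asv_ids character vector of ASV identifiers to keep; identifiers
#'   absent from the table are ignored.
#' @return the restricted `count_table`.
#' @export
restrict_asvs <- function(table, asv_ids) {
  stopifnot(inherits(table, "count_table"))
  keep <- colnames(table)[colnames(table) %in% asv_ids]
  structure_count_table(unclass(table)[, keep, drop = FALSE])
}

#' Read a count table from a TSV file
#'
#' The native layout has one row per sample: the first column holds the
#' sample identifier and the header holds the ASV identifiers. The
#' transposed layout (ASVs as rows, common in feature-table exports) is
#' accepted via `dialect` and normalised to samples x ASVs.
#'
#' @param path path to a tab-delimited file.
#' @param dialect `"tsv_samples_by_asvs"` (default) or
#'   `"tsv_asvs_by_samples"` for the transposed layout.
#' @return a `count_table`.
#' @export
read_count_table <- function(path,
                             dialect = c("tsv_samples_by_asvs",
                                         "tsv_asvs_by_samples")) {
  dialect <- match.arg(dialect)
  abort_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 ncol = ncol(m), dimnames = dimnames(m)))
  if (length(num)) {
    bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("malformed count at row '%s', column '%s': '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]],
                   m[bad[1, 1], bad[1, 2]]), call. = FALSE)
    }
  }
  rownames(num) <- ids
  if (dialect == "tsv_asvs_by_samples") num <- t(num)
  validate_count_table(structure_count_table(num))
}

#' Write a count table to a TSV file
#'
#' Writes the native samples-by-ASVs layout; all-zero ASV columns are
#' dropped first. Reading the file back yields an identical table.
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  ids <- c(rownames(table), colnames(table))
  abort_if(any(grepl("[\t\n]", ids)),
           "identifiers must not contain tabs or newlines")
  if (nrow(table) > 0) table <- drop_empty_asvs(table)
  df <- data.frame(sample_id = rownames(table), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(table), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-sample read multiset
#'
#' A `read_table` represents raw (pre-ASV) reads as a per-sample multiset of
#' sequence identifiers; it is the object pre-ASV sub-sampling acts on.
#' Within-sample read order carries no information.
#'
#' @param reads named list of character vectors, one per sample.
#' @return a `read_table` object.
#' @export
read_table <- function(reads) {
  abort_if(!is.list(reads) || is.null(names(reads)) || any(names(reads) == ""),
           "`reads` must be a named list of character vectors")
  abort_if(anyDuplicated(names(reads)) > 0, "duplicate sample identifiers")
  abort_if(!all(vapply(reads, is.character, logical(1))),
           "each sample's reads must be a character vector of identifiers")
  structure(reads, class = "read_table")
}

#' @export
print.read_table <- function(x, ...) {
  cat(sprintf("read_table: %d samples, %s reads total\n",
              length(x), format(sum(lengths(x)), big.mark = ",")))
  invisible(x)
}

#' Tabulate a read multiset into a count table
#'
#' The bridge between the pre-ASV (read) and post-ASV (count) worlds:
#' per-sample read totals are preserved exactly.
#'
#' @param reads a `read_table`.
#' @return a `count_table` whose row sums equal the per-sample read counts.
#' @export
tabulate_reads <- function(reads) {
  stopifnot(inherits(reads, "read_table"))
  asvs <- sort(unique(unlist(reads, use.names = FALSE)))
  m <- matrix(0L, nrow = length(reads), ncol = length(asvs),
              dimnames = list(names(reads), asvs))
  for (s in names(reads)) {
    if (length(reads[[s]])) {
      tab <- table(factor(reads[[s]], levels = asvs))
      m[s, ] <- as.integer(tab)
    }
  }
  validate_count_table(structure_count_table(m))
}

#' Expand a count table into a read multiset
#'
#' Right inverse of [tabulate_reads()]: each count becomes that many copies
#' of the ASV identifier.
#'
#' @param table a `count_table`.
#' @return a `read_table`.
#' @export
expand_reads <- function(table) {
  stopifnot(inherits(table, "count_table"))
  asvs <- colnames(table)
  reads <- lapply(rownames(table), function(s) {
    rep.int(asvs, unclass(table)[s, ])
  })
  names(reads) <- rownames(table)
  read_table(reads)
}
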