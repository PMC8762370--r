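## Alpha-diversity indices, each computed from a shared per-sample
## components object (read total, singleton/doubleton tallies, rare/abundant
## split, abundance-frequency spectrum). Estimators that are undefined on an
## input (ACE with coverage 0, Margalef with a single read) return an
## explicit undefined marker rather than a silent NaN.

#' Per-sample diversity components
#'
#' Tallies the quantities every index below is built from: total reads `N`,
#' observed ASVs `Sobs`, singletons `Sn1` (count exactly 1), doubletons
#' `Sn2` (count exactly 2), the rare/abundant split at `rare_threshold`
#' (rare: 1 <= count <= threshold; abundant: count > threshold), the rare
#' read total `Nrare`, and the abundance-frequency spectrum `freq`
#' (`freq[i]` = number of ASVs with count `i`).
#'
#' @param counts_row non-negative integer vector of per-ASV counts with at
#'   least one positive entry.
#' @param rare_threshold abundance boundary for the rare/abundant split
#'   (default 10, the classical ACE convention, inclusive on the rare side).
#' @return a `div_components` list.
#' @export
#' @examples
#' div_components(c(5, 3, 1, 1))
div_components <- function(counts_row, rare_threshold = 10L) {
  abort_if(!is_count_vector(counts_row), "counts must be non-negative integers")
  pos <- counts_row[counts_row > 0]
  abort_if(length(pos) == 0, "empty sample (all counts zero)")
  freq_tab <- table(pos)
  freq <- as.integer(freq_tab)
  names(freq) <- names(freq_tab)
  abund_vals <- as.integer(names(freq))
  rare <- abund_vals <= rare_threshold
  structure(list(
    N = sum(pos),
    Sobs = length(pos),
    Sn1 = sum(pos == 1),
    Sn2 = sum(pos == 2),
    Sabund = sum(freq[!rare]),
    Srare = sum(freq[rare]),
    Nrare = sum(abund_vals[rare] * freq[rare]),
    freq = freq,
    rare_threshold = as.integer(rare_threshold)
  ), class = "div_components")
}

#' Hill number of order q
#'
#' `(sum_i p_i^q)^(1/(1-q))` for `q != 1`, with the continuous limit
#' `exp(-sum_i p_i log p_i)` at `q = 1`. Order 0 is observed richness,
#' order 1 the exponential of Shannon entropy, order 2 inverse Simpson.
#'
#' @param p relative abundances summing to 1 (zeros are ignored).
#' @param q non-negative order.
#' @return the Hill number.
#' @export
hill_number <- function(p, q) {
  abort_if(any(p < 0), "relative abundances must be non-negative")
  abort_if(abs(sum(p) - 1) > 1e-9, "relative abundances must sum to 1")
  abort_if(q < 0, "`q` must be non-negative")
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Shannon entropy
#'
#' `H' = -sum_i p_i ln p_i` (natural log). The first-order Hill number is
#' `exp(H')`; both are reported by [diversity_profile()].
#'
#' @param p relative abundances summing to 1 (zeros are ignored).
#' @return the entropy in nats.
#' @export
shannon_entropy <- function(p) {
  abort_if(any(p < 0), "relative abundances must be non-negative")
  abort_if(abs(sum(p) - 1) > 1e-9, "relative abundances must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Inverse Simpson index
#'
#' `1 / sum_i p_i^2`, the Hill number of order 2.
#'
#' @inheritParams shannon_entropy
#' @return the inverse Simpson concentration.
#' @export
inverse_simpson <- function(p) hill_number(p, 2)

#' Chao1 richness estimator (bias-corrected)
#'
#' `Sobs + Sn1 (Sn1 - 1) / (2 (Sn2 + 1))`; defined for all inputs,
#' including `Sn2 = 0`. With no singletons it collapses to `Sobs` exactly --
#' which is why it adds nothing on data whose singletons a denoiser already
#' removed.
#'
#' @param components a [div_components()] object.
#' @return the Chao1 estimate.
#' @export
chao1 <- function(components) {
  stopifnot(inherits(components, "div_components"))
  with(components, Sobs + Sn1 * (Sn1 - 1) / (2 * (Sn2 + 1)))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator:
#' `C_ACE = 1 - Sn1 / Nrare`;
#' `gamma^2 = max((Srare / C_ACE) * sum_{i<=k} i (i-1) F_i /
#'   (Nrare (Nrare - 1)) - 1, 0)`;
#' `ACE = Sabund + Srare / C_ACE + (Sn1 / C_ACE) * gamma^2`,
#' with `k` the rare threshold and `F_i` the number of ASVs of count `i`.
#' Undefined (marker returned) when every rare read is a singleton
#' (`C_ACE = 0`) or when `Nrare < 2` with rare ASVs present.
#'
#' @param components a [div_components()] object.
#' @return the ACE estimate, or an undefined marker (see [is_undefined()]).
#' @export
ace <- function(components) {
  stopifnot(inherits(components, "div_components"))
  cm <- components
  if (cm$Srare == 0) return(cm$Sabund)
  if (cm$Nrare < 2) {
    return(undefined_value("single rare read: Nrare(Nrare-1) = 0"))
  }
  c_ace <- 1 - cm$Sn1 / cm$Nrare
  if (c_ace == 0) {
    return(undefined_value("all rare reads are singletons: C_ACE = 0"))
  }
  abund_vals <- as.integer(names(cm$freq))
  rare <- abund_vals <= cm$rare_threshold
  sum_ii1 <- sum(abund_vals[rare] * (abund_vals[rare] - 1) * cm$freq[rare])
  gamma2 <- max((cm$Srare / c_ace) * sum_ii1 /
                  (cm$Nrare * (cm$Nrare - 1)) - 1, 0)
  cm$Sabund + cm$Srare / c_ace + (cm$Sn1 / c_ace) * gamma2
}

#' Good's coverage
#'
#' `1 - Sn1 / N`: the estimated fraction of the community's reads belonging
#' to observed ASVs. Exactly 1 whenever the sample has no singletons, so
#' singleton-free (sample-wise denoised) data always claims full coverage.
#'
#' @param components a [div_components()] object.
#' @return coverage in \[0, 1\].
#' @export
goods_coverage <- function(components) {
  stopifnot(inherits(components, "div_components"))
  with(components, 1 - Sn1 / N)
}

#' Margalef's diversity index
#'
#' `(Sobs - 1) / ln N`. Depth-sensitive by construction: with `Sobs` fixed
#' it increases as `N` decreases, which is why sub-sampling can inflate it.
#'
#' @param components a [div_components()] object.
#' @return the index, or an undefined marker when `N = 1`.
#' @export
margalef <- function(components) {
  stopifnot(inherits(components, "div_components"))
  if (components$N < 2) return(undefined_value("N = 1: ln(N) = 0"))
  with(components, (Sobs - 1) / log(N))
}

#' Menhinick's diversity index
#'
#' `Sobs / sqrt(N)`; shares Margalef's depth sensitivity with a stronger
#' denominator effect.
#'
#' @param components a [div_components()] object.
#' @return the index.
#' @export
menhinick <- function(components) {
  stopifnot(inherits(components, "div_components"))
  with(components, Sobs / sqrt(N))
}

#' Full alpha-diversity profile of a count table
#'
#' Computes, per sample: observed richness, Shannon entropy `H'` and its
#' exponential (the order-1 Hill number, reported separately because the
#' two are often conflated), inverse Simpson, Chao1, ACE, Good's coverage,
#' Margalef and Menhinick, plus the singleton/doubleton tallies they derive
#' from. Undefined estimators yield `NA` with the matching `*_defined` flag
#' set to `FALSE`; they are never silently dropped.
#'
#' @param table a `count_table` with no empty samples.
#' @param rare_threshold ACE rare/abundant boundary (default 10).
#' @return a data frame with one row per sample.
#' @export
diversity_profile <- function(table, rare_threshold = 10L) {
  stopifnot(inherits(table, "count_table"))
  m <- unclass(table)
  empty <- rownames(m)[rowSums(m) == 0]
  abort_if(length(empty) > 0, "empty sample(s): ",
           paste(empty, collapse = ", "))
  rows <- lapply(rownames(m), function(s) {
    row <- m[s, ]
    cm <- div_components(row, rare_threshold)
    p <- row[row > 0] / cm$N
    h <- shannon_entropy(p)
    a <- ace(cm)
    mg <- margalef(cm)
    data.frame(
      sample_id = s,
      depth = cm$N,
      observed_richness = cm$Sobs,
      singletons = cm$Sn1,
      doubletons = cm$Sn2,
      shannon_entropy = h,
      hill_q1 = exp(h),
      inverse_simpson = inverse_simpson(p),
      chao1 = chao1(cm),
      ace = as.numeric(a),
      ace_defined = !is_undefined(a),
      goods_coverage = goods_coverage(cm),
      margalef = as.numeric(mg),
      margalef_defined = !is_undefined(mg),
      menhinick = menhinick(cm),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
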